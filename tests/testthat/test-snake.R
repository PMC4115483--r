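test_that("energy terms match their definitions on hand-worked cases", {
  # elasticity: mean spacing minus distance to the predecessor, signed
  expect_equal(elasticity_energy(c(0, 0), c(3, 4), d_bar = 6), 1)
  expect_equal(elasticity_energy(c(0, 0), c(3, 4), d_bar = 2), -3)
  # curvature: squared second difference
  expect_equal(curvature_energy(c(0, 0), c(1, 1), c(2, 2)), 0)
  expect_equal(curvature_energy(c(0, 0), c(1, 0), c(0, 2)), 4 + 4)
  # combined: the weighted sum
  w <- energy_weights(alpha = 2, beta = 3, gamma = 4)
  expect_equal(combined_energy(1, 10, -5, w), 2 + 30 - 20)
  expect_error(energy_weights(alpha = 0), "alpha")
})

test_that("image energy is zero on flat frames and minimal on an edge", {
  flat <- matrix(100, 20, 20)
  expect_true(all(image_energy_field(flat, 2) == 0))
  step <- matrix(0, 21, 21); step[, 11:21] <- 200
  f <- image_energy_field(step, 2)
  expect_true(all(f <= 0))
  # the strongest (most negative) energy lies on the vertical edge
  expect_equal(which.min(f[11, ]), 11, tolerance = 1)
  expect_true(all(f[1, ] == 0) && all(f[, 1] == 0))
})

test_that("snake state stitches movable upper and fixed lower points", {
  init <- structure(list(upper = cbind(x = 1:3, y = 5),
                         lower = cbind(x = 1:3, y = 9)),
                    class = "initial_points")
  st <- snake_state(init)
  expect_equal(nrow(st$points), 6)
  expect_equal(st$movable, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # lower points are reversed so the polyline is spatially continuous
  expect_equal(st$points[4, ], c(x = 3, y = 9))
  expect_equal(st$points[6, ], c(x = 1, y = 9))
})

test_that("a greedy sweep never moves fixed points and stays at strict optima", {
  init <- structure(list(upper = cbind(x = c(5, 10, 15), y = 5),
                         lower = cbind(x = c(5, 10, 15), y = 8)),
                    class = "initial_points")
  st <- snake_state(init)
  flat <- matrix(0, 20, 20)
  out <- snake_step(st, flat, snake_config())
  expect_equal(out$points[!out$movable, ], st$points[!st$movable, ])
  # deep energy wells exactly at the current positions: nothing moves
  well <- flat
  well[cbind(st$points[st$movable, 2], st$points[st$movable, 1])] <- -1000
  out2 <- snake_step(st, well, snake_config())
  expect_equal(out2$moved_last, 0L)
  expect_equal(out2$points, st$points)
})

test_that("a point descends to the strongest nearby edge energy", {
  field <- matrix(0, 15, 15)
  field[9, 8] <- -100  # a deep well one row below the middle point
  init <- structure(list(upper = cbind(x = c(6, 8, 10), y = 8),
                         lower = cbind(x = c(6, 8, 10), y = 12)),
                    class = "initial_points")
  st <- snake_step(snake_state(init), field,
                   snake_config(weights = energy_weights(gamma = 50)))
  expect_equal(unname(st$points[2, ]), c(8, 9))
})

test_that("sweeps match the brute-force serial greedy oracle exactly", {
  set.seed(21)
  fr <- generate_midsagittal_frame(default_archetypes()$e, seed = 21)
  pre <- preprocess_config()
  plane <- palatal_plane(fr$truth$ans, fr$truth$pns)
  mask <- extract_cavity_mask(fr$frame, pre)
  segs <- filter_segments(label_segments(mask), fr$truth$jaw_mask, pre)
  init <- select_initial_points(select_cavity_component(segs, plane))
  cfg <- snake_config(max_iter = 5)
  field <- image_energy_field(fr$frame, cfg$weights$sigma)
  state <- run_snake(fr$frame, init, cfg, field = field, keep_history = TRUE)
  expect_equal(replay_mismatches(state, field, cfg), 0L)
})

test_that("the snake converges on a phantom and reports its run", {
  fr <- generate_midsagittal_frame(default_archetypes()$i, seed = 2)
  pre <- preprocess_config()
  plane <- palatal_plane(fr$truth$ans, fr$truth$pns)
  mask <- extract_cavity_mask(fr$frame, pre)
  segs <- filter_segments(label_segments(mask), fr$truth$jaw_mask, pre)
  init <- select_initial_points(select_cavity_component(segs, plane))
  state <- run_snake(fr$frame, init)
  expect_true(state$converged)
  expect_equal(state$iterations, length(state$moved_history))
  expect_lt(state$moved_history[state$iterations],
            0.1 * nrow(state$points))
  ctr <- snake_contour(state)
  expect_equal(nrow(ctr), 30)
  expect_lt(mean_dist_to_curve(ctr, fr$truth$tongue_contour), 2)
})

test_that("the displacement stopping rule also terminates", {
  fr <- generate_midsagittal_frame(default_archetypes()$o, seed = 5)
  pre <- preprocess_config()
  plane <- palatal_plane(fr$truth$ans, fr$truth$pns)
  mask <- extract_cavity_mask(fr$frame, pre)
  segs <- filter_segments(label_segments(mask), fr$truth$jaw_mask, pre)
  init <- select_initial_points(select_cavity_component(segs, plane))
  state <- run_snake(fr$frame, init,
                     snake_config(stop_rule = "displacement",
                                  stop_fraction = 0.05))
  expect_true(state$converged)
  expect_lt(state$displacement_last, 0.05)
})

test_that("initial points outside the frame are rejected", {
  init <- structure(list(upper = cbind(x = c(1, 50), y = 2),
                         lower = cbind(x = c(1, 50), y = 3)),
                    class = "initial_points")
  expect_error(run_snake(matrix(0, 10, 10), init), "outside")
})
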