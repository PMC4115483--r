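test_that("cavity threshold sits at the configured fraction of the range", {
  fr <- vt_frame(matrix(c(10, 110), 2, 2))
  expect_equal(compute_threshold(fr), 0.06 * 100 + 10)
  expect_equal(compute_threshold(fr, factor = 0.5), 60)
  flat <- vt_frame(matrix(7, 3, 3))
  expect_equal(compute_threshold(flat), 7)
})

test_that("cavity mask marks dark pixels and opening removes specks", {
  px <- matrix(200, 20, 20)
  px[5:15, 5:15] <- 0        # a real cavity
  px[2, 18] <- 0             # an isolated dark speck
  fr <- vt_frame(px)
  mask <- extract_cavity_mask(fr, preprocess_config(open_radius = 1))
  # opening with the plus-shaped radius-1 disc rounds the 4 square corners
  expect_equal(sum(mask[5:15, 5:15]), 121 - 4)
  expect_true(all(mask[6:14, 6:14] == 1))
  expect_equal(mask[5, 5], 0)
  expect_equal(mask[2, 18], 0)  # speck opened away
  raw <- extract_cavity_mask(fr, preprocess_config(open_radius = 0))
  expect_equal(raw[2, 18], 1)   # survives without opening
})

test_that("segment labelling is 8-connected", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1   # diagonal touch
  m[5, 5] <- 1                 # separate
  segs <- label_segments(m)
  expect_length(segs$sizes, 2)
  expect_equal(segs$labels[2, 2], segs$labels[3, 3])
  expect_false(segs$labels[5, 5] == segs$labels[2, 2])
  expect_equal(sort(segs$sizes), c(1, 2))
})

test_that("segment filtering drops small and jaw-adjacent components", {
  m <- matrix(0, 30, 30)
  m[2:11, 2:11] <- 1          # 100 px, keep
  m[20:22, 20:22] <- 1        # 9 px, too small
  m[2:11, 20:27] <- 1         # 80 px but near the jaw
  jaw <- matrix(0, 30, 30)
  jaw[1, 29] <- 1
  cfg <- preprocess_config(min_size = 50, jaw_radius = 3)
  out <- filter_segments(label_segments(m), jaw, cfg)
  expect_length(out$sizes, 1)
  expect_equal(out$sizes, 100)
  expect_true(all(out$labels[2:11, 2:11] == 1))
  expect_error(filter_segments(label_segments(m), matrix(0, 5, 5), cfg),
               "shape")
})

test_that("segment contours equal the brute-force morphological gradient", {
  set.seed(3)
  for (k in 1:25) {
    m <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_identical(segment_contours(m), oracle_contour(m))
  }
  expect_identical(segment_contours(matrix(0, 4, 4)), matrix(0, 4, 4))
})

test_that("oral-cavity selection prefers the component below the palatal plane", {
  m <- matrix(0, 40, 40)
  m[5:9, 10:30] <- 1     # nasal: above the plane, bigger
  m[20:23, 10:30] <- 1   # oral: below the plane
  segs <- label_segments(m)
  plane <- palatal_plane(c(5, 15), c(35, 15))
  oral <- select_cavity_component(segs, plane)
  expect_equal(sum(oral[20:23, 10:30]), 4 * 21)
  expect_equal(sum(oral), 4 * 21)
  # without a plane the larger non-border component wins
  any_comp <- select_cavity_component(segs)
  expect_equal(sum(any_comp), 5 * 21)
  # border-touching components never qualify
  b <- matrix(0, 10, 10); b[1, 1:5] <- 1
  expect_error(select_cavity_component(label_segments(b)), "qualifies")
})

test_that("initial points trace the cavity boundary anterior to posterior", {
  m <- matrix(0, 30, 50)
  m[10:20, 5:45] <- 1
  init <- select_initial_points(m, n_upper = 10, n_lower = 5,
                                close_radius = 0)
  expect_s3_class(init, "initial_points")
  expect_equal(dim(init$upper), c(10, 2))
  expect_equal(dim(init$lower), c(5, 2))
  expect_true(all(init$upper[, 2] == 10))
  expect_true(all(init$lower[, 2] == 20))
  expect_false(is.unsorted(init$upper[, 1]))
  expect_false(is.unsorted(init$lower[, 1]))
  expect_equal(unname(init$upper[1, 1]), 5)
  expect_equal(unname(init$upper[10, 1]), 45)
  expect_error(select_initial_points(matrix(0, 5, 5)), "empty")
  two <- matrix(0, 20, 20); two[3:6, 3:6] <- 1; two[14:17, 14:17] <- 1
  expect_error(select_initial_points(two, close_radius = 0),
               "exactly one component")
})

test_that("median pre-filtering recovers the mask under heavy noise", {
  arch <- default_archetypes(noise_sd = 25.5)$a
  fr <- generate_midsagittal_frame(arch, seed = 4)
  noisy_cfg <- preprocess_config(median_radius = 2, open_radius = 1)
  mask <- extract_cavity_mask(fr$frame, noisy_cfg)
  segs <- filter_segments(label_segments(mask), fr$truth$jaw_mask, noisy_cfg)
  oral <- select_cavity_component(segs,
                                  palatal_plane(fr$truth$ans, fr$truth$pns))
  truth <- fr$truth$airway_mask
  jaccard <- sum(oral & truth) / sum(oral | truth)
  expect_gt(jaccard, 0.6)
})

test_that("point CSVs round trip through write_points_csv", {
  pts <- cbind(x = c(3, 7), y = c(11, 13))
  path <- tempfile(fileext = ".csv")
  write_points_csv(pts, path, frame_index = 2)
  df <- read.csv(path)
  expect_equal(df$col, c(3, 7))
  expect_equal(df$row, c(11, 13))
  expect_equal(df$frame_index, c(2, 2))
  unlink(path)
})
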