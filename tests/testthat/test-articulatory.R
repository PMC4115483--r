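test_that("constriction distances and lip aperture follow their definitions", {
  tongue <- cbind(x = 10:20, y = 50)
  palate <- cbind(x = 10:20, y = 40)
  m <- measure_parameters(tongue, palate, c(5, 45), c(5, 57),
                          resolution = 1)
  expect_equal(m$ttcl, 10)   # tip at (10,50), nearest palate point (10,40)
  expect_equal(m$tbcl, 10)   # parallel lines: constant 10 px
  expect_equal(m$la, 12)
  # resolution converts px to mm
  m2 <- measure_parameters(tongue, palate, c(5, 45), c(5, 57),
                           resolution = 2)
  expect_equal(m2$ttcl, 5)
})

test_that("the tongue body is the posterior arc and takes the minimum", {
  # tongue dips then approaches the palate posteriorly
  tongue <- cbind(x = c(0, 10, 20, 30, 40), y = c(50, 55, 52, 45, 42))
  palate <- cbind(x = 0:40, y = 40)
  m <- measure_parameters(tongue, palate, c(0, 41), c(0, 55), resolution = 1)
  expect_equal(m$tbcl, 2)    # nearest posterior point is (40,42)
  expect_equal(m$ttcl, 10)   # tip is the anterior-most point (0,50)
})

test_that("perpendicular mode measures to the palatal plane line", {
  tongue <- cbind(x = c(5, 15), y = c(20, 30))
  palate <- cbind(x = 100, y = 100)  # far away; must be ignored in this mode
  plane <- palatal_plane(c(0, 10), c(40, 10))
  m <- measure_parameters(tongue, palate, c(0, 0), c(0, 8), resolution = 1,
                          plane = plane, distance_mode = "perpendicular")
  expect_equal(m$ttcl, 10)
  expect_equal(m$tbcl, 20)
  expect_error(measure_parameters(tongue, palate, c(0, 0), c(0, 8),
                                  distance_mode = "perpendicular"),
               "palatal_plane")
})

test_that("frame summaries reproduce textbook sample statistics", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  s <- summarize_frames(x, "a", "M", "TTCL")
  expect_equal(s$mean, 5)
  expect_equal(s$variance, sum((x - 5)^2) / 7)
  expect_equal(s$std, sqrt(s$variance))
  expect_equal(s$n, 8)
  expect_false(s$degenerate)
  expect_warning(s1 <- summarize_frames(3, "a", "M", "LA"), "single frame")
  expect_true(s1$degenerate)
  expect_equal(s1$std, 0)
  expect_error(summarize_frames(numeric(0)), "non-empty")
  expect_error(summarize_frames(c(1, NA)), "finite")
})

test_that("vowel ranking sorts ascending means with label tie-breaks", {
  mk <- function(v, m) summarize_frames(c(m, m), v, "M", "LA")
  s <- list(mk("u", 3), mk("a", 12), mk("i", 7), mk("e", 7))
  expect_equal(rank_vowels(s, "LA"), c("u", "e", "i", "a"))
  expect_error(rank_vowels(s, "TTCL"), "no summaries")
  expect_error(rank_vowels(c(s, list(mk("u", 9))), "LA"), "duplicate")
})

test_that("reference tables load with the expected structure", {
  tab <- articulatory_table()
  expect_equal(nrow(tab), 36)
  expect_setequal(unique(tab$vowel), c("a", "e", "schwa", "i", "o", "u"))
  expect_setequal(unique(tab$parameter), c("TTCL", "TBCL", "LA"))
  expect_setequal(unique(tab$gender), c("M", "F"))
  expect_true(all(paste0("frame", 1:7) %in% names(tab)))
  fmt <- formant_table()
  expect_equal(nrow(fmt), 24)
  expect_setequal(unique(fmt$formant), c("F1", "F2"))
  expect_true(all(fmt$mean_hz > 100 & fmt$mean_hz < 3000))
  sums <- reference_summaries()
  expect_length(sums, 36)
  expect_true(all(vapply(sums, function(s) s$n == 7, TRUE)))
})

test_that("measurement objects reject impossible values", {
  expect_error(articulatory_measurement(-1, 2, 3), "finite")
  expect_error(articulatory_measurement(1, Inf, 3), "finite")
  expect_error(measure_parameters(cbind(numeric(0), numeric(0)),
                                  cbind(1, 1), c(0, 0), c(0, 1)),
               "non-empty")
})
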