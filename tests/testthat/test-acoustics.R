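test_that("audio segments and analysis settings validate their inputs", {
  seg <- audio_segment(sin(1:100), rate = 8000)
  expect_equal(seg$duration, 100 / 8000)
  expect_error(audio_segment(numeric(0)), "non-empty")
  expect_error(audio_segment(c(1, NA)), "finite")
  st <- formant_settings_for("M")
  expect_equal(st$max_formant, 5000)
  expect_equal(formant_settings_for("F")$max_formant, 5500)
  expect_equal(st$n_formants, 5L)
  expect_equal(st$window, 0.025)
  expect_equal(st$dyn_range, 30)
})

test_that("LPC recovers the resonances of a single window", {
  seg <- synthesize_vowel(120, c(500, 1500, 2500, 3500, 4500), seed = 9,
                          duration = 0.025 * 4)
  w <- audio_segment(seg$samples[1:round(0.025 * seg$rate)], seg$rate)
  f <- frame_formants(w, formant_settings_for("M"))
  expect_gte(length(f), 2)
  expect_lt(abs(f[1] - 500) / 500, 0.1)
  expect_lt(abs(f[2] - 1500) / 1500, 0.1)
  expect_false(is.unsorted(f))
  # silence yields no formants
  expect_length(frame_formants(audio_segment(rep(0, 600), 10000),
                               formant_settings()), 0)
})

test_that("window count is exactly the floor of duration over window length", {
  for (dur in c(0.5, 0.49, 0.275, 0.026)) {
    seg <- synthesize_vowel(120, c(500, 1500), duration = dur, seed = 1)
    fs <- average_formants(seg, formant_settings_for("M"))
    expect_identical(fs$n_points, floor(dur / 0.025))
  }
  short <- audio_segment(rep(0.1, 100), rate = 20000)  # 5 ms
  expect_error(average_formants(short), "shorter")
})

test_that("the dynamic-range gate drops silent windows", {
  seg <- synthesize_vowel(120, c(500, 1500, 2500), duration = 0.25, seed = 2)
  padded <- audio_segment(c(seg$samples, rep(1e-5, length(seg$samples))),
                          seg$rate)
  fs <- average_formants(padded, formant_settings_for("M"))
  expect_lt(fs$n_used, fs$n_points)
  expect_gte(fs$n_used, 10)
})

test_that("averaged formants track the synthesis targets", {
  targets <- c(420, 1230)
  seg <- synthesize_vowel(120, c(targets, neutral_upper_formants("M")),
                          seed = 3)
  fs <- average_formants(seg, formant_settings_for("M"))
  expect_lt(abs(fs$f_mean[1] - targets[1]) / targets[1], 0.05)
  expect_lt(abs(fs$f_mean[2] - targets[2]) / targets[2], 0.05)
  expect_true(all(fs$f_std[1:2] >= 0))
})

test_that("articulatory-acoustic correlation reports r, slope and sign", {
  artic <- data.frame(vowel = rep(c("a", "e", "i", "o"), 2),
                      gender = rep("M", 8),
                      parameter = rep(c("TBCL", "TTCL"), each = 4),
                      mean = c(10, 8, 4, 7, 9, 6, 3, 11))
  formants <- data.frame(vowel = rep(c("a", "e", "i", "o"), 2),
                         gender = "M",
                         formant = rep(c("F1", "F2"), each = 4),
                         mean_hz = c(700, 550, 300, 500, 1200, 1700, 2300, 900))
  out <- correlate_articulatory_acoustic(artic, formants)
  expect_equal(nrow(out), 2)
  r1 <- out$r[out$parameter == "TBCL"]
  expect_gt(r1, 0)
  expect_equal(out$sign[out$parameter == "TBCL"], "+")
  expect_lt(out$r[out$parameter == "TTCL"], 0)
  expect_equal(out$n, c(4, 4))
  # perfectly linear data gives |r| = 1 and the generating slope
  lin_a <- data.frame(vowel = c("a", "e", "i"), gender = "M",
                      parameter = "TBCL", mean = c(1, 2, 3))
  lin_f <- data.frame(vowel = c("a", "e", "i"), gender = "M",
                      formant = "F1", mean_hz = c(100, 200, 300))
  lin <- correlate_articulatory_acoustic(
    rbind(lin_a, transform(lin_a, parameter = "TTCL")),
    rbind(lin_f, transform(lin_f, formant = "F2")))
  expect_equal(lin$r[lin$parameter == "TBCL"], 1)
  expect_equal(lin$slope[lin$parameter == "TBCL"], 100)
  # too few matched vowels is an error, not a silent NA
  expect_error(correlate_articulatory_acoustic(lin_a[1:2, ], lin_f),
               "at least 3")
  expect_error(correlate_articulatory_acoustic(lin_a["vowel"], lin_f),
               "missing columns")
})

test_that("WAV files round trip through the PCM16 reader and writer", {
  set.seed(5)
  seg <- audio_segment(runif(4000, -0.9, 0.9), rate = 16000)
  path <- tempfile(fileext = ".wav")
  write_wav(seg, path)
  back <- read_wav(path)
  expect_equal(back$rate, 16000)
  expect_length(back$samples, 4000)
  expect_lt(max(abs(back$samples - seg$samples)), 1 / 32767)
  unlink(path)
  bad <- tempfile(fileext = ".wav")
  writeBin(as.raw(1:32), bad)
  expect_error(read_wav(bad), "RIFF")
  unlink(bad)
})

test_that("vowel synthesis validates formant specifications", {
  expect_error(synthesize_vowel(120, c(1500, 500)), "ascending")
  expect_error(synthesize_vowel(120, c(500, 11000)), "Nyquist")
  s1 <- synthesize_vowel(120, c(500, 1500), seed = 7)
  s2 <- synthesize_vowel(120, c(500, 1500), seed = 7)
  expect_identical(s1$samples, s2$samples)  # deterministic per seed
  expect_equal(max(abs(s1$samples)), 1)     # peak normalized
})
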