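#' Audio segment
#'
#' @param samples Numeric vector of amplitudes (typically in `[-1, 1]`).
#' @param rate Sampling rate in Hz (default 20000, the recording rate this
#'   package targets).
#' @return A list of class `audio_segment` with `samples`, `rate`,
#'   `bit_depth` and `duration` (seconds).
#' @export
audio_segment <- function(samples, rate = 20000) {
  samples <- as.numeric(samples)
  if (length(samples) == 0 || any(!is.finite(samples)))
    stop("'samples' must be a non-empty finite vector", call. = FALSE)
  stopifnot(rate > 0)
  structure(list(samples = samples, rate = rate, bit_depth = 16L,
                 duration = length(samples) / rate),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment> %.3f s at %g Hz (%d samples)\n",
              x$duration, x$rate, length(x$samples)))
  invisible(x)
}

#' Formant analysis settings
#'
#' The standard settings for sustained-vowel analysis: maximum formant
#' frequency 5000 Hz for male and 5500 Hz for female voices, five formants,
#' 25 ms analysis windows and a 30 dB dynamic range below which windows are
#' treated as silent.
#'
#' @param max_formant Maximum formant frequency in Hz.
#' @param n_formants Number of formants extracted per window.
#' @param window Window length in seconds.
#' @param dyn_range Dynamic range in dB for the silence gate.
#' @param preemphasis First-order pre-emphasis coefficient.
#' @param bw_max Maximum admissible formant bandwidth in Hz.
#' @return A list of class `formant_settings`.
#' @export
formant_settings <- function(max_formant = 5000, n_formants = 5,
                             window = 0.025, dyn_range = 30,
                             preemphasis = 0.98, bw_max = 400) {
  stopifnot(max_formant > 0, n_formants >= 1, window > 0, dyn_range > 0,
            preemphasis >= 0, preemphasis < 1, bw_max > 0)
  structure(list(max_formant = max_formant, n_formants = as.integer(n_formants),
                 window = window, dyn_range = dyn_range,
                 preemphasis = preemphasis, bw_max = bw_max),
            class = "formant_settings")
}

#' Gender-specific default formant settings
#'
#' @param gender `"M"` (5000 Hz ceiling) or `"F"` (5500 Hz).
#' @param ... Further arguments passed to [formant_settings()].
#' @return A [formant_settings()].
#' @export
formant_settings_for <- function(gender = c("M", "F"), ...) {
  gender <- match.arg(gender)
  formant_settings(max_formant = if (gender == "M") 5000 else 5500, ...)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Formant frequencies of one analysis window
#'
#' Linear-predictive formant estimation: the window is resampled to twice
#' the maximum formant frequency, pre-emphasized, Hann-windowed and fitted
#' with an autocorrelation LPC model of order `2 * n_formants + 2`
#' (Levinson-Durbin). Complex pole pairs give candidate resonances; those
#' inside `(0, max_formant)` with bandwidth below `bw_max` are kept,
#' ascending, up to `n_formants` values.
#'
#' @param window_samples An [audio_segment()] holding one analysis window.
#' @param settings A [formant_settings()].
#' @return Ascending numeric vector of formant frequencies in Hz (empty for
#'   a silent window).
#' @export
frame_formants <- function(window_samples, settings = formant_settings()) {
  stopifnot(inherits(window_samples, "audio_segment"),
            inherits(settings, "formant_settings"))
  x <- window_samples$samples
  fs <- window_samples$rate
  if (sqrt(mean(x^2)) == 0) return(numeric(0))
  p <- 2L * settings$n_formants + 2L
  fs2 <- 2 * settings$max_formant
  if (fs2 != fs) {
    g <- .gcd(round(fs2), round(fs))
    x <- signal::resample(x, round(fs2) / g, round(fs) / g)
  }
  if (length(x) < 2 * p)
    stop("window too short for LPC order ", p, call. = FALSE)
  x <- x - mean(x)
  x <- c(x[1], x[-1] - settings$preemphasis * x[-length(x)])
  x <- x * signal::hanning(length(x))
  r <- as.numeric(stats::acf(x, lag.max = p, type = "covariance",
                             plot = FALSE, demean = FALSE)$acf)
  if (r[1] <= 0) return(numeric(0))
  # Levinson-Durbin recursion
  a <- 1; e <- r[1]
  for (i in seq_len(p)) {
    k <- -sum(a * r[(i + 1):2]) / e
    a <- c(a, 0) + k * rev(c(a, 0))
    e <- e * (1 - k^2)
    if (e <= 0) return(numeric(0))
  }
  rts <- polyroot(rev(a))
  f <- Arg(rts) * fs2 / (2 * pi)
  bw <- -log(pmax(Mod(rts), .Machine$double.eps)) * fs2 / pi
  keep <- Im(rts) > 0 & f > 0 & f < settings$max_formant & bw < settings$bw_max
  out <- sort(f[keep])
  out[seq_len(min(settings$n_formants, length(out)))]
}

#' Average formants over a whole utterance
#'
#' The segment is cut into `floor(duration / window)` consecutive
#' non-overlapping windows. Windows whose RMS lies more than `dyn_range` dB
#' below the loudest window are gated out as silence; the remaining windows'
#' formant estimates are averaged per formant index.
#'
#' @param segment An [audio_segment()] at least one window long.
#' @param settings A [formant_settings()].
#' @param vowel,gender Labels carried into the summary.
#' @return A list of class `formant_summary` with `f_mean`, `f_std`
#'   (per-formant across-window statistics), `n_points` (window count),
#'   `n_used` (windows passing the gate) and `per_window` (list of
#'   per-window estimates).
#' @export
average_formants <- function(segment, settings = formant_settings(),
                             vowel = NA, gender = NA) {
  stopifnot(inherits(segment, "audio_segment"))
  if (segment$duration < settings$window)
    stop("segment shorter than one analysis window", call. = FALSE)
  wl <- round(settings$window * segment$rate)
  n_points <- floor(segment$duration / settings$window)
  rmss <- vapply(seq_len(n_points), function(i)
    sqrt(mean(segment$samples[((i - 1) * wl + 1):(i * wl)]^2)), 1)
  gate <- max(rmss) * 10^(-settings$dyn_range / 20)
  ests <- lapply(seq_len(n_points), function(i) {
    if (rmss[i] < gate) return(numeric(0))
    frame_formants(audio_segment(segment$samples[((i - 1) * wl + 1):(i * wl)],
                                 rate = segment$rate), settings)
  })
  kmax <- max(lengths(ests), 0)
  if (kmax == 0) stop("no voiced windows found", call. = FALSE)
  stat <- function(k, f) {
    v <- unlist(lapply(ests, function(e) if (length(e) >= k) e[k]))
    f(v)
  }
  f_mean <- vapply(seq_len(kmax), stat, 1, f = mean)
  f_std <- vapply(seq_len(kmax), stat, 1,
                  f = function(v) if (length(v) > 1) stats::sd(v) else 0)
  structure(list(vowel = vowel, gender = gender, f_mean = f_mean,
                 f_std = f_std, n_points = n_points,
                 n_used = sum(lengths(ests) > 0), per_window = ests),
            class = "formant_summary")
}

#' @export
print.formant_summary <- function(x, ...) {
  cat(sprintf("<formant_summary> %s/%s over %d windows: %s Hz\n",
              x$vowel, x$gender, x$n_points,
              paste(sprintf("F%d=%.0f", seq_along(x$f_mean), x$f_mean),
                    collapse = " ")))
  invisible(x)
}

#' Correlate articulatory and acoustic vowel summaries
#'
#' For each gender, pairs per-vowel articulatory means with per-vowel formant
#' means and reports the Pearson correlation and least-squares slope of the
#' two relations of interest: tongue body constriction location against F1
#' (expected positive: a higher TBCL means a lower, more open tongue body and
#' a higher F1) and tongue tip constriction location against F2 (expected
#' negative: back vowels have a high TTCL and a low F2).
#'
#' @param artic Data frame with columns `vowel`, `gender`, `parameter`,
#'   `mean` (mm), e.g. built from [reference_summaries()] or a pipeline run.
#' @param formants Data frame with columns `vowel`, `gender`, `formant`,
#'   `mean_hz`, as returned by [formant_table()].
#' @return Data frame with one row per gender and relation: columns
#'   `gender`, `parameter`, `formant`, `r`, `slope`, `n`, `sign`.
#' @export
correlate_articulatory_acoustic <- function(artic, formants) {
  need <- function(df, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                           call. = FALSE)
  }
  need(artic, c("vowel", "gender", "parameter", "mean"))
  need(formants, c("vowel", "gender", "formant", "mean_hz"))
  pairs <- list(c("TBCL", "F1"), c("TTCL", "F2"))
  out <- list()
  for (g in unique(artic$gender)) {
    for (pr in pairs) {
      a <- artic[artic$gender == g & artic$parameter == pr[1], ]
      f <- formants[formants$gender == g & formants$formant == pr[2], ]
      m <- merge(a, f, by = "vowel")
      if (nrow(m) < 3)
        stop("need at least 3 matched vowels for ", g, " ", pr[1], "/", pr[2],
             call. = FALSE)
      r <- stats::cor(m$mean, m$mean_hz)
      slope <- unname(stats::coef(stats::lm(mean_hz ~ mean, data = m))[2])
      out[[length(out) + 1L]] <- data.frame(
        gender = g, parameter = pr[1], formant = pr[2], r = r, slope = slope,
        n = nrow(m), sign = ifelse(r > 0, "+", ifelse(r < 0, "-", "0")))
    }
  }
  do.call(rbind, out)
}

# --- minimal RIFF/PCM WAV IO ------------------------------------------------

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF reader for the recording format this package targets
#' (PCM, 16-bit, single channel; the first channel of multi-channel files
#' is used).
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_segment()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE")
    stop("not a WAVE file", call. = FALSE)
  rate <- NULL; n_channels <- 1L; bits <- 16L; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", sz / 2, 2, endian = "little", signed = FALSE)
      n_channels <- fmt[2]
      rate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
      if (bits != 16) stop("only 16-bit PCM supported", call. = FALSE)
    } else if (id == "data") {
      samples <- readBin(con, "integer", sz / 2, 2, endian = "little")
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (!is.null(rate) && !is.null(samples)) break
  }
  if (is.null(rate) || is.null(samples))
    stop("malformed WAV file", call. = FALSE)
  if (n_channels > 1)
    samples <- samples[seq(1, length(samples), by = n_channels)]
  audio_segment(samples / 32767, rate = rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param segment An [audio_segment()]; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @export
write_wav <- function(segment, path) {
  stopifnot(inherits(segment, "audio_segment"))
  s <- as.integer(round(pmin(pmax(segment$samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")          # PCM, mono
  writeBin(as.integer(segment$rate), con, 4, endian = "little")
  writeBin(as.integer(segment$rate * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")         # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(s, con, 2, endian = "little")
  invisible(path)
}
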