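#' Vowel archetype for the midsagittal phantom
#'
#' An archetype describes the synthetic vocal-tract posture used to render
#' phantom frames: the tongue surface as control points in a normalized unit
#' box (x anterior to posterior; y the airway gap between palate and tongue,
#' 1 = the widest gap the phantom renders), the lip aperture, and the
#' acquisition-degradation parameters.
#'
#' @param label Vowel label, one of `"a","e","schwa","i","o","u"` (free-form
#'   labels are allowed for custom shapes).
#' @param tongue_control_points Two-column matrix of `(x, gap)` control
#'   points in `[0, 1]`, ordered anterior to posterior.
#' @param lip_gap Normalized lip aperture in `[0, 1]`.
#' @param blur_sigma Gaussian blur (px at 256 px frame size) emulating motion
#'   blur and partial-volume softening.
#' @param noise_sd Additive Gaussian noise standard deviation in intensity
#'   units (0--255 scale).
#' @return A list of class `vowel_archetype`.
#' @export
vowel_archetype <- function(label, tongue_control_points, lip_gap,
                            blur_sigma = 0.5, noise_sd = 4) {
  cp <- as.matrix(tongue_control_points)
  if (ncol(cp) != 2 || nrow(cp) < 2)
    stop("need at least two (x, gap) control points", call. = FALSE)
  if (is.unsorted(cp[, 1]))
    stop("control points must be ordered anterior to posterior", call. = FALSE)
  if (any(cp < 0) || any(cp > 1) || lip_gap < 0 || lip_gap > 1)
    stop("control points and lip_gap must lie in the unit box", call. = FALSE)
  if (blur_sigma < 0 || noise_sd < 0)
    stop("blur_sigma and noise_sd must be >= 0", call. = FALSE)
  structure(list(label = label, tongue_control_points = cp, lip_gap = lip_gap,
                 blur_sigma = blur_sigma, noise_sd = noise_sd),
            class = "vowel_archetype")
}

#' Default vowel archetypes
#'
#' Six hand-designed postures reproducing the qualitative articulatory
#' relations of sustained vowel production: back raising for /o/, /u/ and
#' /e/, front raising for /i/ and the central vowel, the widest cavity and
#' lips for /a/, the narrowest lips for /u/. The airway gap stays within the
#' capture range of the tracking energy (about 6--10 px at 256 px frame
#' size), as in near-closed sustained articulation.
#'
#' @param blur_sigma,noise_sd Degradation overrides applied to every
#'   archetype.
#' @return Named list of [vowel_archetype()] objects.
#' @export
default_archetypes <- function(blur_sigma = 0.5, noise_sd = 4) {
  gapmax <- 12  # px at 256; gap = y * gapmax
  lipmax <- 16  # px at 256; aperture = lip_gap * lipmax
  cp <- function(...) cbind(c(0, 1 / 3, 2 / 3, 1), c(...) / gapmax)
  shapes <- list(
    a     = list(cp(9, 9.5, 10, 10), 12 / lipmax),
    e     = list(cp(8, 7.8, 7.4, 7), 11 / lipmax),
    schwa = list(cp(7, 7.3, 7.7, 8), 8 / lipmax),
    i     = list(cp(6, 6, 6, 6),     7 / lipmax),
    o     = list(cp(10, 9, 8, 7),    5 / lipmax),
    u     = list(cp(9, 8, 7, 7),     3 / lipmax))
  out <- lapply(names(shapes), function(v)
    vowel_archetype(v, shapes[[v]][[1]], shapes[[v]][[2]],
                    blur_sigma = blur_sigma, noise_sd = noise_sd))
  names(out) <- names(shapes)
  out
}

# Intensity palette of the phantom (0-255 scale). Tissue is bright muscle;
# air is near-black; the thin palate renders at intermediate intensity
# between the dark oral and nasal cavities; a small bright fat marker pins
# the intensity maximum.
.phantom_int <- list(tissue = 200, air = 2, palate = 120, marker = 255)

#' Render a midsagittal phantom frame with known geometry
#'
#' The frame contains bright soft tissue, a dark oral airway between the
#' tongue surface (the archetype's spline) and a thin palate strip, a dark
#' nasal cavity above the palate, a dark jaw below the tongue, a dark lip
#' aperture pocket anteriorly, and a bright fat marker. Gaussian blur and
#' additive noise emulate acquisition degradation. All ground-truth geometry
#' (tongue contour, palate trace, landmarks, airway and jaw masks, and the
#' articulatory measurements implied by them) is returned alongside.
#'
#' @param arch A [vowel_archetype()].
#' @param size Frame side length in pixels (square frame, >= 64).
#' @param seed Integer seed; output is deterministic per
#'   `(arch, size, seed)`.
#' @param resolution Pixels per mm recorded in the frame (default 1.057).
#' @param gap_shift Optional per-column additive perturbation (px) of the
#'   airway gap, used by [generate_frame_sequence()].
#' @param frame_index Frame index recorded in the output frame.
#' @return A list with elements `frame` (a [vt_frame()]) and `truth` (class
#'   `phantom_truth`: `tongue_contour`, `palate_trace` two-column `(x, y)`
#'   matrices; `ans`, `pns`, `upper_lip`, `lower_lip` points; `airway_mask`,
#'   `jaw_mask` 0/1 matrices; `expected_measurements`, an
#'   `articulatory_measurement` computed analytically from the geometry).
#' @export
generate_midsagittal_frame <- function(arch, size = 256, seed = 0,
                                       resolution = 1.057, gap_shift = NULL,
                                       frame_index = 0L) {
  stopifnot(inherits(arch, "vowel_archetype"))
  size <- as.integer(size)
  if (size < 64) stop("frame size must be >= 64", call. = FALSE)
  cp <- arch$tongue_control_points
  if (nrow(unique(cp)) < 2)
    stop("degenerate tongue control points", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sc <- size / 256
  ints <- .phantom_int
  img <- matrix(ints$tissue, size, size)

  xs <- round(60 * sc):round(200 * sc)          # airway columns
  t01 <- (xs - min(xs)) / diff(range(xs))
  y_pal <- round((100 + 6 * sin(pi * t01)) * sc) # airway top row
  gap <- stats::spline(cp[, 1], cp[, 2] * 12, xout = t01, method = "natural")$y * sc
  if (!is.null(gap_shift)) gap <- gap + gap_shift
  gap <- pmin(pmax(round(gap), 4), round(14 * sc))
  y_tongue <- y_pal + gap                        # first tongue row

  pal_h <- max(2L, round(3 * sc))                # palate strip thickness
  nas_h <- max(4L, round(8 * sc))                # nasal cavity height
  for (i in seq_along(xs)) {
    x <- xs[i]
    img[(y_pal[i] - pal_h - nas_h):(y_pal[i] - pal_h - 1), x] <- ints$air
    img[(y_pal[i] - pal_h):(y_pal[i] - 1), x] <- ints$palate
    img[y_pal[i]:(y_tongue[i] - 1), x] <- ints$air
  }
  # jaw (dark bone) well below the tongue
  jaw_rows <- round(180 * sc):round(205 * sc)
  jaw_cols <- round(80 * sc):round(150 * sc)
  img[jaw_rows, jaw_cols] <- ints$air
  # bright fat marker (pins IM_max)
  img[round(30 * sc):round(38 * sc), round(225 * sc):round(233 * sc)] <- ints$marker
  # lip aperture: dark pocket anterior of a bright tip/teeth bridge
  lip_gap <- max(2L, round(arch$lip_gap * 16 * sc))
  lip_rows <- round(98 * sc):(round(98 * sc) + lip_gap - 1L)
  lip_cols <- round(40 * sc):round(52 * sc)
  img[lip_rows, lip_cols] <- ints$air

  img <- gaussian_blur(img, arch$blur_sigma * sc)
  if (arch$noise_sd > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, arch$noise_sd), size, size)
  img <- pmin(pmax(img, 0), 255)

  airway <- matrix(0, size, size)
  for (i in seq_along(xs)) airway[y_pal[i]:(y_tongue[i] - 1), xs[i]] <- 1
  jaw <- matrix(0, size, size)
  jaw[jaw_rows, jaw_cols] <- 1

  lip_x <- round(mean(lip_cols))
  truth <- structure(list(
    tongue_contour = cbind(x = xs, y = y_tongue),
    palate_trace = cbind(x = xs, y = y_pal - 1),
    ans = c(x = xs[1], y = y_pal[1] - 1),
    pns = c(x = xs[length(xs)], y = y_pal[length(xs)] - 1),
    upper_lip = c(x = lip_x, y = min(lip_rows) - 1),
    lower_lip = c(x = lip_x, y = max(lip_rows) + 1),
    airway_mask = airway, jaw_mask = jaw,
    vowel = arch$label), class = "phantom_truth")
  truth$expected_measurements <- .measure_from_truth(truth, resolution,
                                                     frame_index)
  list(frame = vt_frame(img, resolution = resolution,
                        frame_index = as.integer(frame_index)),
       truth = truth)
}

# Analytic articulatory measurements from phantom geometry; mirrors the
# operational definitions in measure_parameters() but works directly on the
# generating polylines.
.measure_from_truth <- function(truth, resolution, frame_index) {
  tongue <- truth$tongue_contour
  palate <- truth$palate_trace
  tip <- tongue[which.min(tongue[, 1]), ]
  ttcl <- min(sqrt((palate[, 1] - tip[1])^2 + (palate[, 2] - tip[2])^2))
  s <- c(0, cumsum(sqrt(diff(tongue[, 1])^2 + diff(tongue[, 2])^2)))
  post <- tongue[s >= s[length(s)] * 0.5, , drop = FALSE]
  tbcl <- min(apply(post, 1, function(p)
    min(sqrt((palate[, 1] - p[1])^2 + (palate[, 2] - p[2])^2))))
  la <- sqrt(sum((truth$upper_lip - truth$lower_lip)^2))
  articulatory_measurement(ttcl / resolution, tbcl / resolution,
                           la / resolution, frame_index)
}

#' Generate a jittered sequence of phantom frames
#'
#' Renders `n_frames` frames of the same archetype with small random tongue
#' perturbations: each frame's airway gap profile is shifted by a uniform
#' offset in `[-jitter/2, jitter/2]` plus a smooth random-phase undulation of
#' amplitude `jitter/2`, so no perturbation exceeds `jitter` px. Per-frame
#' ground truth is regenerated accordingly.
#'
#' @inheritParams generate_midsagittal_frame
#' @param n_frames Number of frames (>= 1).
#' @param jitter Maximum tongue perturbation in px (0 = identical frames,
#'   noise aside).
#' @return List of `n_frames` elements, each a `list(frame, truth)` pair.
#' @export
generate_frame_sequence <- function(arch, n_frames = 7, jitter = 1, size = 256,
                                    seed = 0, resolution = 1.057) {
  stopifnot(n_frames >= 1, jitter >= 0)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  meta <- lapply(seq_len(n_frames), function(k)
    list(offset = stats::runif(1, -jitter / 2, jitter / 2),
         amp = jitter / 2, phase = stats::runif(1, 0, 1),
         sub = sample.int(1e6, 1)))
  xs_n <- length(round(60 * size / 256):round(200 * size / 256))
  t01 <- seq(0, 1, length.out = xs_n)
  lapply(seq_len(n_frames), function(k) {
    m <- meta[[k]]
    shift <- m$offset + m$amp * sin(2 * pi * (t01 + m$phase))
    generate_midsagittal_frame(arch, size = size, seed = m$sub,
                               resolution = resolution, gap_shift = shift,
                               frame_index = k - 1L)
  })
}

#' Synthesize a vowel waveform with known formants
#'
#' Source-filter synthesis: an impulse train at `f0` is shaped by a leaky
#' integrator (-6 dB/oct glottal rolloff) and passed through a cascade of
#' two-pole resonators at the requested formant frequencies and bandwidths,
#' then peak-normalized. A low-level seeded noise floor keeps the spectrum
#' full-rank for analysis.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param formants Ascending resonance frequencies in Hz, all below
#'   `rate / 2`.
#' @param bandwidths Resonance bandwidths in Hz (recycled defaults
#'   60, 90, 120, 160, 200 when missing).
#' @param duration Duration in seconds (> 0).
#' @param rate Sampling rate in Hz (default 20000).
#' @param seed Integer seed for the noise floor.
#' @param noise_amp Noise floor amplitude relative to unit peak.
#' @param rolloff Leaky-integrator coefficient of the glottal source model.
#' @return An [audio_segment()].
#' @export
synthesize_vowel <- function(f0, formants, bandwidths = NULL, duration = 0.5,
                             rate = 20000, seed = 0, noise_amp = 1e-3,
                             rolloff = 0.98) {
  stopifnot(f0 > 0, duration > 0, rate > 0, length(formants) >= 1)
  if (is.unsorted(formants))
    stop("formants must be ascending", call. = FALSE)
  if (any(formants >= rate / 2))
    stop("formant at or above the Nyquist frequency", call. = FALSE)
  if (is.null(bandwidths))
    bandwidths <- c(60, 90, 120, 160, 200)[seq_along(formants)]
  stopifnot(length(bandwidths) == length(formants), all(bandwidths > 0))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- round(duration * rate)
  x <- numeric(n)
  x[round(seq(1, n, by = rate / f0))] <- 1
  x <- as.numeric(stats::filter(x, rolloff, method = "recursive"))
  for (k in seq_along(formants)) {
    r <- exp(-pi * bandwidths[k] / rate)
    th <- 2 * pi * formants[k] / rate
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  if (noise_amp > 0) x <- x + noise_amp * max(abs(x)) * stats::rnorm(n)
  audio_segment(x / max(abs(x)), rate = rate)
}
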