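#' Palatal reference plane
#'
#' The measurement coordinate frame: the line from the anterior nasal spine
#' (ANS) to the posterior nasal spine (PNS) in the midsagittal slice.
#'
#' @param ans,pns Length-2 `(x, y)` pixel coordinates; must differ.
#' @return A list of class `palatal_plane`.
#' @export
palatal_plane <- function(ans, pns) {
  ans <- as.numeric(ans); pns <- as.numeric(pns)
  stopifnot(length(ans) == 2, length(pns) == 2)
  if (all(ans == pns)) stop("ANS and PNS must differ", call. = FALSE)
  structure(list(ans = ans, pns = pns), class = "palatal_plane")
}

#' Per-frame articulatory measurement
#'
#' @param ttcl,tbcl,la Tongue tip constriction location, tongue body
#'   constriction location and lip aperture, in millimetres (>= 0, finite).
#' @param frame_index Frame identifier.
#' @return A list of class `articulatory_measurement`.
#' @export
articulatory_measurement <- function(ttcl, tbcl, la, frame_index = 0L) {
  ttcl <- unname(ttcl); tbcl <- unname(tbcl); la <- unname(la)
  v <- c(ttcl = ttcl, tbcl = tbcl, la = la)
  if (any(!is.finite(v)) || any(v < 0))
    stop("measurements must be finite and >= 0", call. = FALSE)
  structure(list(ttcl = ttcl, tbcl = tbcl, la = la,
                 frame_index = as.integer(frame_index)),
            class = "articulatory_measurement")
}

#' @export
print.articulatory_measurement <- function(x, ...) {
  cat(sprintf("<articulatory_measurement> frame %d: TTCL %.3f mm, TBCL %.3f mm, LA %.3f mm\n",
              x$frame_index, x$ttcl, x$tbcl, x$la))
  invisible(x)
}

point_to_set_dist <- function(p, set) {
  min(sqrt((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2))
}

point_to_line_dist <- function(p, a, b) {
  ab <- b - a
  abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / sqrt(sum(ab^2))
}

#' Measure TTCL, TBCL and LA from tracked contours
#'
#' Operational definitions (the conventions of this package):
#' * TTCL: distance from the tongue tip landmark -- the anterior-most tongue
#'   contour point -- to the palate trace.
#' * TBCL: minimum distance from the posterior part of the tongue contour
#'   (beyond `body_fraction` of its arc length) to the palate trace.
#' * LA: distance between the upper- and lower-lip landmarks.
#'
#' Distances are computed in pixels and reported in millimetres
#' (`px / resolution`). With `distance_mode = "euclidean"` (default) tongue
#' points are measured to the nearest palate-trace point; with
#' `"perpendicular"` they are measured orthogonally to the ANS-PNS palatal
#' plane, which must then be supplied.
#'
#' @param tongue Two-column `(x, y)` matrix of tongue contour points,
#'   anterior to posterior.
#' @param palate Two-column `(x, y)` matrix of palate trace points.
#' @param upper_lip,lower_lip Length-2 `(x, y)` lip landmarks.
#' @param resolution Pixels per millimetre (> 0).
#' @param plane Optional [palatal_plane()]; required for
#'   `distance_mode = "perpendicular"`.
#' @param body_fraction Arc-length fraction splitting tip from body
#'   (default 0.5).
#' @param distance_mode `"euclidean"` or `"perpendicular"`.
#' @param frame_index Frame identifier carried into the result.
#' @return An [articulatory_measurement()] in millimetres.
#' @examples
#' tongue <- cbind(10:20, 50)
#' palate <- cbind(10:20, 40)
#' m <- measure_parameters(tongue, palate, c(5, 45), c(5, 57))
#' m$ttcl  # 10 px at 1.057 px/mm = 9.461 mm
#' @export
measure_parameters <- function(tongue, palate, upper_lip, lower_lip,
                               resolution = 1.057, plane = NULL,
                               body_fraction = 0.5,
                               distance_mode = c("euclidean", "perpendicular"),
                               frame_index = 0L) {
  distance_mode <- match.arg(distance_mode)
  tongue <- as.matrix(tongue); palate <- as.matrix(palate)
  if (nrow(tongue) == 0 || nrow(palate) == 0)
    stop("tongue and palate contours must be non-empty", call. = FALSE)
  stopifnot(resolution > 0, body_fraction > 0, body_fraction < 1)
  if (distance_mode == "perpendicular" && is.null(plane))
    stop("perpendicular mode needs a palatal_plane", call. = FALSE)
  dfun <- if (distance_mode == "euclidean")
    function(p) point_to_set_dist(p, palate)
  else
    function(p) point_to_line_dist(p, plane$ans, plane$pns)
  tip <- tongue[which.min(tongue[, 1]), ]
  ttcl_px <- dfun(tip)
  if (nrow(tongue) > 1) {
    s <- c(0, cumsum(sqrt(diff(tongue[, 1])^2 + diff(tongue[, 2])^2)))
    post <- tongue[s >= s[length(s)] * body_fraction, , drop = FALSE]
  } else post <- tongue
  tbcl_px <- min(apply(post, 1, dfun))
  la_px <- sqrt(sum((as.numeric(upper_lip) - as.numeric(lower_lip))^2))
  articulatory_measurement(ttcl_px / resolution, tbcl_px / resolution,
                           la_px / resolution, frame_index)
}

#' Summarize per-frame measurements for one vowel
#'
#' Sample statistics over the frames of one vowel/parameter cell: arithmetic
#' mean, sample (n-1) variance and its square root. Values are kept at full
#' precision; round only for presentation.
#'
#' @param values Numeric vector of per-frame measurements in mm (non-empty).
#' @param vowel,gender,parameter Labels carried into the summary
#'   (`parameter` is one of `"TTCL"`, `"TBCL"`, `"LA"`).
#' @return A list of class `vowel_summary` with `per_frame`, `mean`, `std`,
#'   `variance`, `n` and a `degenerate` flag (`TRUE` when `n = 1`, in which
#'   case std and variance are reported as 0 with a warning).
#' @examples
#' s <- summarize_frames(c(19.47, 21.57, 25.25, 28.67, 27.88, 24.73, 20.78),
#'                       "a", "M", "TTCL")
#' round(c(s$mean, s$std, s$variance), 4)
#' @export
summarize_frames <- function(values, vowel = NA, gender = NA, parameter = NA) {
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)))
    stop("'values' must be a non-empty finite vector", call. = FALSE)
  degenerate <- length(values) == 1
  if (degenerate) {
    warning("single frame: std and variance reported as 0", call. = FALSE)
    v <- 0
  } else v <- stats::var(values)
  structure(list(vowel = vowel, gender = gender, parameter = parameter,
                 per_frame = values, mean = mean(values), std = sqrt(v),
                 variance = v, n = length(values), degenerate = degenerate),
            class = "vowel_summary")
}

#' @export
print.vowel_summary <- function(x, ...) {
  cat(sprintf("<vowel_summary> %s/%s %s: n=%d mean=%.4f std=%.4f var=%.4f\n",
              x$vowel, x$gender, x$parameter, x$n, x$mean, x$std, x$variance))
  invisible(x)
}

#' Rank vowels by the mean of one articulatory parameter
#'
#' @param summaries List of [summarize_frames()] results, one per vowel, all
#'   for the same gender and parameter.
#' @param parameter Parameter to rank on; summaries for other parameters are
#'   rejected.
#' @return Character vector of vowel labels sorted by ascending mean; ties
#'   are broken by vowel label.
#' @export
rank_vowels <- function(summaries, parameter) {
  keep <- Filter(function(s) identical(s$parameter, parameter), summaries)
  if (length(keep) == 0)
    stop("no summaries for parameter ", parameter, call. = FALSE)
  vowels <- vapply(keep, function(s) as.character(s$vowel), "")
  if (anyDuplicated(vowels))
    stop("duplicate vowel in summaries", call. = FALSE)
  means <- vapply(keep, function(s) s$mean, 1)
  vowels[order(means, vowels)]
}

#' Reference articulatory measurements table
#'
#' Per-frame TTCL/TBCL/LA measurements (mm) for six sustained vowels of one
#' male and one female speaker, seven consecutive MR frames each, with the
#' published summary statistics. Shipped as a CSV fixture.
#'
#' @return Data frame with columns `vowel`, `gender`, `parameter`,
#'   `frame1..frame7`, `mean`, `std`, `variance`.
#' @export
articulatory_table <- function() {
  utils::read.csv(system.file("extdata", "articulatory_measurements.csv",
                              package = "tonguetrack"),
                  stringsAsFactors = FALSE)
}

#' Reference formant-frequency table
#'
#' Mean F1 and F2 (Hz, with across-window standard deviations) of the same
#' six vowels for the male and female speaker.
#'
#' @return Data frame with columns `vowel`, `gender`, `formant`, `mean_hz`,
#'   `std_hz`.
#' @export
formant_table <- function() {
  utils::read.csv(system.file("extdata", "formant_frequencies.csv",
                              package = "tonguetrack"),
                  stringsAsFactors = FALSE)
}

#' Summaries of the reference articulatory table
#'
#' Applies [summarize_frames()] to every row of [articulatory_table()].
#'
#' @return List of `vowel_summary` objects (36 cells).
#' @export
reference_summaries <- function() {
  tab <- articulatory_table()
  lapply(seq_len(nrow(tab)), function(i)
    summarize_frames(as.numeric(tab[i, paste0("frame", 1:7)]),
                     tab$vowel[i], tab$gender[i], tab$parameter[i]))
}
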