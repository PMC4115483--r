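#' Preprocessing configuration
#'
#' Parameters of the morphological pipeline that turns a raw midsagittal
#' frame into a cavity mask and the snake's initial points.
#'
#' @param threshold_factor Fraction of the frame's dynamic range added to the
#'   minimum intensity to form the cavity threshold (default 0.06).
#' @param open_radius Disc radius (px) of the opening applied to the
#'   thresholded mask; removes noise specks and hair-thin connections.
#' @param close_radius Disc radius (px) of the closing applied to the selected
#'   cavity component before its boundary is sampled; fills pinholes.
#' @param min_size Minimum component size (px) kept by [filter_segments()].
#' @param jaw_radius Disc radius (px) by which the jaw mask is dilated when
#'   discarding jaw-adjacent segments.
#' @param n_upper,n_lower Number of movable (upper) and fixed (lower) initial
#'   points sampled from the cavity boundary.
#' @param median_radius Radius of an optional edge-preserving median filter
#'   applied before thresholding (0 = off). Intended for low-SNR data; the
#'   default pipeline thresholds the raw frame.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(threshold_factor = 0.06, open_radius = 2,
                              close_radius = 3, min_size = 50, jaw_radius = 5,
                              n_upper = 30, n_lower = 15, median_radius = 0) {
  stopifnot(threshold_factor >= 0, open_radius >= 0, close_radius >= 0,
            min_size >= 0, jaw_radius >= 0, n_upper >= 3, n_lower >= 3,
            median_radius >= 0)
  structure(list(threshold_factor = threshold_factor, open_radius = open_radius,
                 close_radius = close_radius, min_size = min_size,
                 jaw_radius = jaw_radius, n_upper = as.integer(n_upper),
                 n_lower = as.integer(n_lower), median_radius = median_radius),
            class = "preprocess_config")
}

#' Cavity intensity threshold
#'
#' The oral and nasal cavities are air and image as near-black, so a threshold
#' slightly above the frame minimum separates them from tissue:
#' `th = factor * (max - min) + min` with `factor = 0.06` by default.
#'
#' @param frame A [vt_frame()].
#' @param factor Fraction of the dynamic range (default 0.06).
#' @return Scalar threshold, guaranteed inside `[min, max]` of the frame.
#' @examples
#' fr <- vt_frame(matrix(c(0, 255), 2, 2))
#' compute_threshold(fr)  # 15.3
#' @export
compute_threshold <- function(frame, factor = 0.06) {
  stopifnot(inherits(frame, "vt_frame"))
  im_min <- min(frame$pixels)
  im_max <- max(frame$pixels)
  factor * (im_max - im_min) + im_min
}

#' Extract the dark-cavity mask of a frame
#'
#' Marks pixels at or below the cavity threshold, then opens the mask with a
#' disc to remove specks and thin spurs. All dark cavities (oral, nasal, any
#' dark bone) survive; component selection happens downstream.
#'
#' @param frame A [vt_frame()].
#' @param cfg A [preprocess_config()].
#' @return 0/1 matrix of the frame's shape.
#' @export
extract_cavity_mask <- function(frame, cfg = preprocess_config()) {
  stopifnot(inherits(frame, "vt_frame"))
  px <- frame$pixels
  if (cfg$median_radius > 0) {
    rng <- max(px)
    if (rng == 0) rng <- 1
    px <- EBImage::medianFilter(px / rng, as.integer(cfg$median_radius)) * rng
  }
  th <- cfg$threshold_factor * (max(px) - min(px)) + min(px)
  mask <- (px <= th) * 1
  if (cfg$open_radius > 0 && any(mask > 0))
    mask <- EBImage::opening(mask, disc_kernel(cfg$open_radius))
  unname(mask)
}

#' Label connected components (8-connectivity)
#'
#' @param mask 0/1 matrix.
#' @return A list of class `segment_set` with `labels` (integer matrix,
#'   0 = background) and `sizes` (pixel count per label).
#' @export
label_segments <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask)
  nmax <- max(lab)
  if (nmax > 1) {
    # bwlabel is 4-connected; merge labels touching diagonally
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
    s1 <- a1 > 0 & b1 > 0 & a1 != b1
    a2 <- lab[-1, -nc]; b2 <- lab[-nr, -1]
    s2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2]))
    parent <- seq_len(nmax)
    findroot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
      i <- findroot(pairs[r, 1]); j <- findroot(pairs[r, 2])
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
    root <- vapply(seq_len(nmax), findroot, 1L)
    root <- match(root, sort(unique(root)))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  structure(list(labels = lab, sizes = sizes), class = "segment_set")
}

#' Remove small and jaw-adjacent segments
#'
#' Segments smaller than `cfg$min_size` px, and segments intersecting the jaw
#' mask dilated by a disc of radius `cfg$jaw_radius`, are relabelled to
#' background. Surviving segments keep their pixel sets (labels are
#' renumbered consecutively).
#'
#' @param segs A `segment_set` from [label_segments()].
#' @param jaw_mask 0/1 matrix of the jaw region, same shape as the labels, or
#'   `NULL` to skip the proximity rule.
#' @param cfg A [preprocess_config()].
#' @return A filtered `segment_set`.
#' @export
filter_segments <- function(segs, jaw_mask = NULL, cfg = preprocess_config()) {
  stopifnot(inherits(segs, "segment_set"))
  lab <- segs$labels
  if (!is.null(jaw_mask)) {
    if (!identical(dim(jaw_mask), dim(lab)))
      stop("jaw mask shape does not match segment labels", call. = FALSE)
    dil <- jaw_mask
    if (cfg$jaw_radius > 0 && any(jaw_mask > 0))
      dil <- EBImage::dilate(jaw_mask * 1, disc_kernel(cfg$jaw_radius))
  } else dil <- NULL
  keep <- which(segs$sizes >= cfg$min_size)
  if (!is.null(dil) && length(keep)) {
    touching <- unique(lab[dil > 0 & lab > 0])
    keep <- setdiff(keep, touching)
  }
  new <- integer(length(segs$sizes))
  new[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- new[lab[lab > 0]]
  structure(list(labels = out, sizes = segs$sizes[keep]), class = "segment_set")
}

#' Morphological-gradient contours of a mask
#'
#' Dilation minus erosion with a 3x3 structuring element: a one-to-two pixel
#' ring around every segment.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix of contour pixels.
#' @export
segment_contours <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) return(mask * 0)
  k <- matrix(1, 3, 3)
  d <- EBImage::dilate(mask * 1, k)
  e <- EBImage::erode(mask * 1, k)
  unname((d - e > 0) * 1)
}

#' Select the oral-cavity component
#'
#' Among labelled cavity segments, picks the largest one that does not touch
#' the image border (outside air) and whose centroid lies below the palatal
#' plane (the nasal cavity lies above it). Falls back to the largest
#' non-border component when no plane is supplied.
#'
#' @param segs A `segment_set`.
#' @param plane Optional [palatal_plane()] used to reject the nasal cavity.
#' @param below_limit Maximum distance (px) the centroid may lie below the
#'   plane; guards against picking dark structures near the neck.
#' @return 0/1 matrix of the chosen component.
#' @export
select_cavity_component <- function(segs, plane = NULL, below_limit = 80) {
  stopifnot(inherits(segs, "segment_set"))
  lab <- segs$labels
  if (length(segs$sizes) == 0 || all(segs$sizes == 0))
    stop("no cavity segments to select from", call. = FALSE)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  best <- 0L; best_size <- -1
  for (id in seq_along(segs$sizes)) {
    if (id %in% border) next
    if (!is.null(plane)) {
      rows <- row(lab)[lab == id]
      cols <- col(lab)[lab == id]
      # signed vertical offset of centroid below the ANS-PNS line
      cy <- mean(rows); cx <- mean(cols)
      ly <- plane$ans[2] + (plane$pns[2] - plane$ans[2]) *
        (cx - plane$ans[1]) / (plane$pns[1] - plane$ans[1] + 1e-12)
      off <- cy - ly
      if (off <= 0 || off > below_limit) next
    }
    if (segs$sizes[id] > best_size) { best <- id; best_size <- segs$sizes[id] }
  }
  if (best == 0L) stop("no component qualifies as the oral cavity", call. = FALSE)
  unname((lab == best) * 1)
}

#' Sample the snake's initial points from a cavity component
#'
#' The component boundary is split into an upper trace (smallest row index in
#' each occupied column) and a lower trace (largest row index). Each trace is
#' resampled at approximately equal arc length: `n_upper` movable points on
#' the upper trace and `n_lower` fixed points on the lower trace, both ordered
#' anterior (small x) to posterior.
#'
#' @param cavity 0/1 matrix containing exactly one connected component,
#'   typically the closed output of [select_cavity_component()].
#' @param n_upper,n_lower Point counts (>= 3 each).
#' @param close_radius Disc radius of the closing applied before boundary
#'   extraction (fills pinholes); 0 to skip.
#' @return A list of class `initial_points` with `upper` and `lower`
#'   two-column `(x, y)` matrices.
#' @export
select_initial_points <- function(cavity, n_upper = 30, n_lower = 15,
                                  close_radius = 3) {
  stopifnot(is.matrix(cavity), n_upper >= 3, n_lower >= 3)
  if (!any(cavity > 0)) stop("cavity mask is empty", call. = FALSE)
  if (close_radius > 0)
    cavity <- EBImage::closing(cavity * 1, disc_kernel(close_radius))
  segs <- label_segments(cavity)
  if (length(segs$sizes) != 1)
    stop("cavity mask must contain exactly one component (got ",
         length(segs$sizes), ")", call. = FALSE)
  cols <- which(colSums(cavity) > 0)
  upper <- vapply(cols, function(x) min(which(cavity[, x] > 0)), 1L)
  lower <- vapply(cols, function(x) max(which(cavity[, x] > 0)), 1L)
  resample_trace <- function(xs, ys, k) {
    if (length(xs) < 2) stop("cavity too thin to trace", call. = FALSE)
    seg <- sqrt(diff(xs)^2 + diff(ys)^2)
    s <- c(0, cumsum(seg))
    target <- seq(0, s[length(s)], length.out = k)
    idx <- vapply(target, function(t) which.min(abs(s - t)), 1L)
    cbind(x = xs[idx], y = ys[idx])
  }
  structure(list(upper = resample_trace(cols, upper, n_upper),
                 lower = resample_trace(cols, lower, n_lower)),
            class = "initial_points")
}

#' @export
print.initial_points <- function(x, ...) {
  cat(sprintf("<initial_points> %d movable (upper) + %d fixed (lower)\n",
              nrow(x$upper), nrow(x$lower)))
  invisible(x)
}

#' Write a point set to CSV
#'
#' Columns: `frame_index, point_index, row, col` (1-based).
#'
#' @param points Two-column `(x, y)` matrix.
#' @param path Output CSV path.
#' @param frame_index Frame identifier written in the first column.
#' @export
write_points_csv <- function(points, path, frame_index = 0L) {
  df <- data.frame(frame_index = frame_index,
                   point_index = seq_len(nrow(points)),
                   row = points[, 2], col = points[, 1])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
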