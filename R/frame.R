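#' Midsagittal image frame
#'
#' A frame is a grayscale intensity matrix together with its spatial
#' resolution. Rows run top to bottom (anatomically superior to inferior in a
#' standard midsagittal view) and columns run anterior to posterior, so the
#' pixel at `pixels[y, x]` sits at image coordinate `(x, y)`. Intensities are
#' stored as doubles on whatever scale the source image uses (0--255 for
#' 8-bit input).
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param resolution Pixels per millimetre. The scanner protocol this package
#'   targets acquires 256 x 256 frames at 1.057 px/mm, the default.
#' @param frame_index Non-negative integer identifying the frame within a
#'   sequence.
#' @return An object of class `vt_frame`.
#' @examples
#' fr <- vt_frame(matrix(runif(64, 0, 255), 8, 8))
#' dim(fr$pixels)
#' @export
vt_frame <- function(pixels, resolution = 1.057, frame_index = 0L) {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("'pixels' must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("frame intensities must be finite numbers", call. = FALSE)
  if (any(pixels < 0))
    stop("frame intensities must be non-negative", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("'resolution' must be a positive scalar (pixels per mm)", call. = FALSE)
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0)
    stop("'frame_index' must be a non-negative integer", call. = FALSE)
  structure(list(pixels = unname(pixels), resolution = resolution,
                 frame_index = frame_index),
            class = "vt_frame")
}

#' @export
print.vt_frame <- function(x, ...) {
  cat(sprintf("<vt_frame> %d x %d px, %.3f px/mm, frame %d, intensity [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$resolution, x$frame_index,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
plot.vt_frame <- function(x, ...) {
  px <- x$pixels
  graphics::image(t(px[nrow(px):1, ]), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(px) / ncol(px), ...)
  invisible(x)
}

#' Read a grayscale frame from a PNG or TIFF file
#'
#' Intensities are rescaled to 0--255 regardless of the on-disk bit depth.
#' Multi-channel images are converted to grayscale by averaging channels.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams vt_frame
#' @return A [vt_frame()].
#' @export
read_frame <- function(path, resolution = 1.057, frame_index = 0L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE], c(1, 2), mean)
  vt_frame(arr * 255, resolution = resolution, frame_index = frame_index)
}

#' Write a frame (or binary mask) to a PNG file
#'
#' @param x A [vt_frame()] or a 0/1 matrix.
#' @param path Output path.
#' @export
write_frame_png <- function(x, path) {
  px <- if (inherits(x, "vt_frame")) x$pixels / 255 else x / max(1, max(x))
  png::writePNG(pmin(pmax(px, 0), 1), path)
  invisible(path)
}

#' Read an ordered frame sequence
#'
#' @param paths Character vector of image paths (ordered), or a single
#'   directory whose PNG/TIFF files are taken in lexical order.
#' @inheritParams vt_frame
#' @return List of [vt_frame()] objects with consecutive `frame_index`.
#' @export
read_frame_sequence <- function(paths, resolution = 1.057) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0) stop("no frames found", call. = FALSE)
  lapply(seq_along(paths), function(i)
    read_frame(paths[i], resolution = resolution, frame_index = i - 1L))
}

# --- shared numeric helpers -------------------------------------------------

#' Discrete disc structuring element
#'
#' Binary (2*floor(r)+1)-square kernel marking pixels within Euclidean
#' distance `r` of the centre (centre always included).
#'
#' @param r Radius in pixels (>= 0).
#' @return 0/1 numeric matrix with odd dimensions.
#' @export
disc_kernel <- function(r) {
  if (r < 0) stop("radius must be >= 0", call. = FALSE)
  d <- 2L * as.integer(floor(r)) + 1L
  cc <- as.integer(floor(r)) + 1L
  k <- outer(seq_len(d), seq_len(d),
             function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
  matrix(as.numeric(k), d, d)
}

gaussian_kernel_2d <- function(sigma) {
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

#' Gaussian-blur a matrix (replicated boundary)
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns `m`.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_2d(sigma)
  half <- (nrow(k) - 1L) / 2
  # replicate-pad by the kernel half-width, filter, crop: boundary output
  # then equals true edge replication and the kernel always fits
  ri <- c(rep(1L, half), seq_len(nrow(m)), rep(nrow(m), half))
  ci <- c(rep(1L, half), seq_len(ncol(m)), rep(ncol(m), half))
  out <- EBImage::filter2(m[ri, ci], k)
  out[half + seq_len(nrow(m)), half + seq_len(ncol(m))]
}
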