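#' Subtract a constant background from an image
#'
#' Pixelwise `max(intensity - value, 0)`; the clamp at zero follows 8-bit
#' image semantics. Background subtraction is applied before correlation.
#'
#' @param image Intensity matrix.
#' @param value Background level to subtract (>= 0, default 16).
#' @return Matrix of the same shape.
#' @export
subtract_background <- function(image, value = 16) {
  stopifnot(is.matrix(image) || is.numeric(image))
  stop_if_not_scalar_number(value, "value")
  if (value < 0) stop("background value must be >= 0", call. = FALSE)
  pmax(image - value, 0)
}

#' Pearson colocalization coefficient over an ROI
#'
#' Product-moment correlation of pixel intensities between two channels,
#' restricted to the pixels of a region of interest. No thresholding is
#' applied beyond the optional prior background subtraction.
#'
#' @param ch_a,ch_b Congruent intensity matrices.
#' @param mask Optional logical matrix of the same shape selecting ROI
#'   pixels (default: full frame). At least 10 pixels are required.
#' @param background Optional background value subtracted (with clamping)
#'   from both channels before correlating; `NULL` leaves intensities raw.
#' @return List with `r` and `n_pixels`.
#' @export
pearson_coloc <- function(ch_a, ch_b, mask = NULL, background = NULL) {
  if (!all(dim(ch_a) == dim(ch_b))) {
    stop("channel images must have identical dimensions", call. = FALSE)
  }
  if (!is.null(background)) {
    ch_a <- subtract_background(ch_a, background)
    ch_b <- subtract_background(ch_b, background)
  }
  if (is.null(mask)) {
    a <- as.numeric(ch_a); b <- as.numeric(ch_b)
  } else {
    if (!all(dim(mask) == dim(ch_a))) {
      stop("mask must be congruent with the images", call. = FALSE)
    }
    a <- ch_a[mask]; b <- ch_b[mask]
  }
  if (length(a) < 10) {
    stop("need at least 10 ROI pixels for correlation", call. = FALSE)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero variance within the ROI; correlation undefined", call. = FALSE)
  }
  list(r = cor(a, b), n_pixels = length(a))
}

#' Line-scan intensity profile
#'
#' Samples pixel intensities at equally spaced points along a straight
#' segment by bilinear interpolation, emulating a line-plot profile. Pixel
#' centers are at integer coordinates `(row, col)` starting at 1.
#'
#' @param image Intensity matrix.
#' @param from,to Numeric pairs `c(row, col)` of the segment endpoints; both
#'   must lie inside the image.
#' @param n_samples Number of sample points (>= 2).
#' @param length_um Optional physical segment length; when given, the output
#'   positions are in micrometres instead of pixels.
#' @return data.frame with `position` and `intensity`.
#' @export
line_profile <- function(image, from, to, n_samples = 100, length_um = NULL) {
  stopifnot(is.matrix(image), length(from) == 2, length(to) == 2)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (all(from == to)) stop("segment must have nonzero length", call. = FALSE)
  nr <- nrow(image); nc <- ncol(image)
  pts_r <- seq(from[1], to[1], length.out = n_samples)
  pts_c <- seq(from[2], to[2], length.out = n_samples)
  if (any(pts_r < 1 | pts_r > nr | pts_c < 1 | pts_c > nc)) {
    stop("segment extends outside the image", call. = FALSE)
  }
  r0 <- pmin(floor(pts_r), nr - 1L); c0 <- pmin(floor(pts_c), nc - 1L)
  fr <- pts_r - r0; fc <- pts_c - c0
  val <- image[cbind(r0, c0)]     * (1 - fr) * (1 - fc) +
         image[cbind(r0 + 1, c0)] * fr       * (1 - fc) +
         image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
         image[cbind(r0 + 1, c0 + 1)] * fr   * fc
  seg_len <- sqrt(sum((to - from)^2))
  pos <- seq(0, seg_len, length.out = n_samples)
  if (!is.null(length_um)) pos <- pos / seg_len * length_um
  data.frame(position = pos, intensity = val)
}

#' Ratio of mean ROI intensities
#'
#' Mean intensity in one region divided by the mean in another, e.g.
#' presynaptic terminal over background, or soma over terminal.
#'
#' @param image Intensity matrix.
#' @param roi_a,roi_b Logical masks congruent with the image; non-empty.
#' @return `mean(image[roi_a]) / mean(image[roi_b])`.
#' @export
roi_mean_ratio <- function(image, roi_a, roi_b) {
  if (!all(dim(roi_a) == dim(image)) || !all(dim(roi_b) == dim(image))) {
    stop("ROI masks must be congruent with the image", call. = FALSE)
  }
  if (!any(roi_a) || !any(roi_b)) stop("empty ROI", call. = FALSE)
  denom <- mean(image[roi_b])
  if (denom <= 0) stop("denominator ROI has non-positive mean", call. = FALSE)
  mean(image[roi_a]) / denom
}
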