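#' Construct an image time series
#'
#' @param frames list of frames, one per time point: numeric matrices
#'   (grey) or `H x W x 3` arrays (RGB); all the same spatial size.
#' @param times acquisition times in hours, strictly increasing; the first
#'   is the reference t0.
#' @param sample_id,blend_label metadata.
#' @param well optional boolean matrix marking in-well pixels; white-pixel
#'   counts are restricted to it.
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, times, sample_id = "sample",
                         blend_label = NA_character_, well = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop_phb("frames must be a non-empty list")
  times <- as.numeric(times)
  if (length(times) != length(frames)) stop_phb("one time per frame required")
  if (any(diff(times) <= 0)) stop_phb("times must be strictly increasing")
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_phb("all frames must have the same shape")
  if (!is.null(well) && !identical(dim(well), dims[[1]]))
    stop_phb("well mask must match the frame shape")
  structure(list(frames = frames, times = times, sample_id = sample_id,
                 blend_label = blend_label, well = well),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_series> %s (%s): %d frames of %dx%d, t = %g..%g h\n",
              x$sample_id, x$blend_label, length(x$frames), d[1], d[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Convert a frame to grey levels in [0, 1]
#'
#' RGB frames are collapsed with the luma weights 0.299/0.587/0.114.
#' Grey input is passed through; integer-scaled input (maximum above 1) is
#' normalized by its bit depth (255 for 8-bit, 65535 otherwise).
#'
#' @param frame a 2-D matrix or an array with a third dimension of 1 or 3
#'   channels.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
to_grey <- function(frame) {
  if (is.array(frame) && length(dim(frame)) == 3L) {
    k <- dim(frame)[3]
    if (k > 3L) stop_phb("frames with more than 3 channels are not supported")
    if (k == 2L) stop_phb("2-channel frames are not supported")
    g <- if (k == 1L) frame[, , 1]
    else 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  } else if (is.matrix(frame)) {
    g <- frame
  } else {
    stop_phb("frame must be a matrix or an HxWx{1,3} array")
  }
  storage.mode(g) <- "double"
  mx <- max(g)
  if (!is.finite(mx) || min(g) < 0) stop_phb("frame values must be finite and >= 0")
  if (mx > 1) g <- g / if (mx <= 255) 255 else 65535
  g
}

#' Grey-level threshold interval
#'
#' One closed interval `[low, high]` in `[0, 1]`, shared by every frame of
#' a series: a pixel is white iff `low <= grey <= high`.
#'
#' @param low,high interval bounds, `0 <= low <= high <= 1`.
#' @return An object of class `threshold_range`.
#' @export
threshold_range <- function(low, high = 1) {
  if (!is_scalar_num(low) || !is_scalar_num(high))
    stop_phb("low and high must be finite scalars")
  if (low < 0 || high > 1 || low > high)
    stop_phb("threshold range must satisfy 0 <= low <= high <= 1")
  structure(list(low = low, high = high), class = "threshold_range")
}

#' @export
print.threshold_range <- function(x, ...) {
  cat(sprintf("<threshold_range> [%.4f, %.4f]\n", x$low, x$high))
  invisible(x)
}

#' Binarize an image series with one shared threshold interval
#'
#' Every frame is converted to grey and thresholded with the *same* closed
#' interval, so white-pixel counts are comparable across the whole kinetic
#' series. When the series has a well mask, pixels outside it are never
#' white.
#'
#' @param series an [image_series()].
#' @param thr a [threshold_range()].
#' @return An object of class `binary_series`: boolean `masks`, integer
#'   `white_counts` (one per frame) and `times`.
#' @export
binarize_series <- function(series, thr) {
  if (!inherits(series, "image_series")) stop_phb("series must be an image_series")
  if (!inherits(thr, "threshold_range")) stop_phb("thr must be a threshold_range")
  masks <- lapply(series$frames, function(f) {
    g <- to_grey(f)
    m <- g >= thr$low & g <= thr$high
    if (!is.null(series$well)) m <- m & series$well
    m
  })
  structure(list(
    masks = masks,
    white_counts = vapply(masks, function(m) as.integer(sum(m)), integer(1)),
    times = series$times, sample_id = series$sample_id,
    blend_label = series$blend_label, threshold = thr
  ), class = "binary_series")
}

# Otsu's threshold on [0,1] grey values; returns the midpoint of the
# argmax plateau of the between-class variance over 256 bin edges.
otsu_threshold <- function(x, nbins = 256L) {
  if (diff(range(x)) < 1e-8) stop_phb("degenerate histogram")
  breaks <- seq(0, 1, length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)[-nbins]
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  w1 <- 1 - w0
  num <- (muT * w0 - mu[-nbins])^2
  sb <- ifelse(w0 > 0 & w1 > 0, num / (w0 * w1), 0)
  edges <- breaks[2:nbins]
  best <- which(sb >= max(sb) - 1e-15)
  mean(range(edges[best]))
}

#' Suggest a threshold interval for a series
#'
#' Automated default for the manual "compromise" threshold: Otsu's cut is
#' computed on the reference (t0) frame, restricted to the well when a mask
#' is present, then raised to the midpoint between the cut and the mean of
#' the bright class. The raised bound rejects intermediate grey levels
#' (mycelium appearing in later frames) while keeping the bright polymer
#' grains. The result is a suggestion; callers may override it and should
#' record the value they use.
#'
#' @param series an [image_series()].
#' @return A [threshold_range()] `[t*, 1]`.
#' @export
suggest_threshold <- function(series) {
  if (!inherits(series, "image_series")) stop_phb("series must be an image_series")
  g <- to_grey(series$frames[[1]])
  x <- if (!is.null(series$well)) g[series$well] else as.vector(g)
  t_otsu <- otsu_threshold(x)
  hi <- x[x > t_otsu]
  if (!length(hi)) stop_phb("degenerate histogram")
  threshold_range((t_otsu + mean(hi)) / 2, 1)
}

#' Remaining-percentage degradation curve from a binary series
#'
#' The image-analysis degradation statistic: the white-pixel count of each
#' frame as a percentage of the first frame,
#' `value(t) = 100 * WPt / WPt0`, which is exactly 100 at t0 and falls as
#' grains are consumed. Values above 100 (apparent growth, e.g. specular
#' noise) are kept, not clipped.
#'
#' @param binary a [binarize_series()] result.
#' @param replicate optional replicate label carried into the curve.
#' @return A [kinetic_curve()] of remaining-%.
#' @export
degradation_curve <- function(binary, replicate = NA_integer_) {
  if (!inherits(binary, "binary_series")) stop_phb("binary must be a binary_series")
  wp0 <- binary$white_counts[1]
  if (wp0 <= 0L) stop_phb("empty reference frame")
  kinetic_curve(binary$times, 100 * binary$white_counts / wp0,
                sample_id = binary$sample_id,
                blend_label = binary$blend_label, replicate = replicate)
}

#' Kinetic curve container
#'
#' A per-replicate degradation time course. Remaining-% curves (the image
#' statistic) start at exactly 100 by construction; degraded-% curves (the
#' NMR statistic) start near 0 and may contain missing points.
#'
#' @param times hours, strictly increasing.
#' @param values remaining-% or degraded-% values.
#' @param sample_id,blend_label,replicate metadata.
#' @param kind `"remaining"` (default) or `"degraded"`.
#' @return An object of class `kinetic_curve`.
#' @export
kinetic_curve <- function(times, values, sample_id = "sample",
                          blend_label = NA_character_,
                          replicate = NA_integer_,
                          kind = c("remaining", "degraded")) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) == 0L)
    stop_phb("times and values must be non-empty, equal length")
  if (any(diff(times) <= 0)) stop_phb("times must be strictly increasing")
  if (kind == "remaining") {
    if (any(!is.finite(values))) stop_phb("remaining-% values must be finite")
    if (abs(values[1] - 100) > 1e-8)
      stop_phb("a remaining-%% curve must start at exactly 100 (got %g)", values[1])
  }
  structure(list(times = times, values = values, sample_id = sample_id,
                 blend_label = blend_label, replicate = replicate,
                 kind = kind),
            class = "kinetic_curve")
}

#' @export
print.kinetic_curve <- function(x, ...) {
  cat(sprintf("<kinetic_curve:%s> %s (%s, rep %s): %d points, t = %g..%g h\n",
              x$kind, x$sample_id, x$blend_label, as.character(x$replicate),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.kinetic_curve <- function(x, ...) {
  data.frame(sample_id = x$sample_id, blend_label = x$blend_label,
             replicate = x$replicate, time_h = x$times, value = x$values,
             kind = x$kind)
}

#' @export
plot.kinetic_curve <- function(x, ...) {
  ylab <- if (x$kind == "remaining") "remaining polymer area (%)"
  else "degradation degree (%)"
  graphics::plot(x$times, x$values, xlab = "time (h)", ylab = ylab,
                 type = "b", pch = 16, ...)
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}
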