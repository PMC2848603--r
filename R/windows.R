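# Windowed statistics via summed-area tables. Windows are cropped at the
# image border (statistics over the intersection of window and image).

.check_window <- function(m, window_px) {
  if (window_px %% 2 != 1 || window_px < 1)
    stop("window size must be an odd positive integer", call. = FALSE)
  if (window_px > nrow(m) || window_px > ncol(m))
    stop(sprintf("window (%d px) larger than image (%d x %d)",
                 window_px, nrow(m), ncol(m)), call. = FALSE)
}

.sat <- function(m) {
  s <- apply(m, 2, cumsum)
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(m))
  s <- t(apply(s, 1, cumsum))
  if (is.null(dim(s))) s <- matrix(s, ncol = ncol(m))
  rbind(0, cbind(0, s))  # S[i+1, j+1] = sum m[1:i, 1:j]
}

# Sum of m over the cropped window of half-width r centred at each pixel.
.window_sum <- function(m, window_px) {
  r <- (window_px - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  S <- .sat(m)
  i1 <- pmax(1L, seq_len(nr) - r); i2 <- pmin(nr, seq_len(nr) + r)
  j1 <- pmax(1L, seq_len(nc) - r); j2 <- pmin(nc, seq_len(nc) + r)
  S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
    S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
}

# Number of in-image pixels in each cropped window.
.window_count <- function(dims, window_px) {
  r <- (window_px - 1L) %/% 2L
  nr <- dims[1]; nc <- dims[2]
  rows <- pmin(nr, seq_len(nr) + r) - pmax(1L, seq_len(nr) - r) + 1L
  cols <- pmin(nc, seq_len(nc) + r) - pmax(1L, seq_len(nc) - r) + 1L
  outer(rows, cols)
}

.window_mean <- function(m, window_px) {
  .window_sum(m, window_px) / .window_count(dim(m), window_px)
}

# Per-pixel sample SD over cropped windows. The image is centred on its
# global mean first to curb cancellation in the sum-of-squares identity.
.window_sd <- function(m, window_px) {
  m0 <- m - mean(m)
  n <- .window_count(dim(m), window_px)
  s <- .window_sum(m0, window_px)
  ss <- .window_sum(m0 * m0, window_px)
  v <- (ss - s * s / n) / (n - 1)
  v[v < 0] <- 0
  sqrt(v)
}

# Comparison tolerance guarding against summed-area-table round-off: a pixel
# counts as above threshold only if it clears it by a sliver proportional to
# the image scale, so exactly-flat regions never threshold as foreground.
.threshold_tol <- function(m) 1e-9 * max(1, max(abs(m)))

#' Adaptive local-mean thresholding
#'
#' Classifies a pixel as foreground when its intensity strictly exceeds the
#' mean intensity of the window centred on it; windows are cropped at the
#' image border. This is the nuclear segmentation rule: with bright compact
#' nuclei the windowed mean hugs the local background, so the threshold
#' adapts to non-uniform illumination.
#'
#' @param image A [channel_image()] or numeric matrix.
#' @param window_px Odd window size in pixels (default 41).
#' @return Logical foreground matrix.
#' @export
local_mean_threshold <- function(image, window_px = 41L) {
  m <- .as_pixels(image)
  .check_window(m, window_px)
  m - .window_mean(m, window_px) > .threshold_tol(m)
}

#' Global background SD from the mode of local SDs
#'
#' Computes the sample SD over a small window (default 5x5) at every pixel
#' and returns the mode of the histogram of those values. Because windows
#' covering bright objects contribute a long right tail but only a minority
#' of pixels, the histogram mode tracks the background noise level even with
#' objects present, where a mean or median would be biased upward.
#'
#' @param image A [channel_image()] or numeric matrix, at least
#'   `sd_window_px` on each side.
#' @param sd_window_px Odd window size for the local SD (default 5).
#' @return Scalar background SD estimate; 0 (with a warning) for a constant
#'   image.
#' @export
estimate_global_background_sd <- function(image, sd_window_px = 5L) {
  m <- .as_pixels(image)
  .check_window(m, sd_window_px)
  sds <- .window_sd(m, sd_window_px)
  if (diff(range(sds)) < .threshold_tol(m)) {
    warning("constant image: background SD estimated as 0; ",
            "thresholds reduce to the local mean", call. = FALSE)
    return(0)
  }
  .histogram_mode(as.vector(sds))
}

# Mode of a histogram with Freedman-Diaconis bin widths (falling back to
# Sturges when the IQR degenerates); ties resolve to the lowest bin.
.histogram_mode <- function(x) {
  stopifnot(length(x) > 0)
  rng <- range(x)
  if (diff(rng) == 0) return(x[1])
  bw <- 2 * IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(rng) / (1 + ceiling(log2(length(x))))
  nbin <- max(1L, ceiling(diff(rng) / bw))
  breaks <- seq(rng[1], rng[2], length.out = nbin + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = nbin)
  k <- which.max(counts)
  (breaks[k] + breaks[k + 1L]) / 2
}
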