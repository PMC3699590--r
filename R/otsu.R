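#' Otsu threshold brain mask
#'
#' Computes the threshold maximizing the between-class variance of a 256-bin
#' histogram over `[min, max]` of the image, and returns the foreground mask.
#' By default foreground means values greater than or equal to the threshold
#' (tissue brighter than background); set `foreground = "below"` to invert.
#' Ties between equally good thresholds are broken toward the lower one.
#'
#' @param v A [volume()] with at least two distinct values.
#' @param bins Number of histogram bins (default 256).
#' @param foreground `"above"` (default) or `"below"`.
#' @return List with `threshold` (the lower edge intensity of the first
#'   foreground bin) and `mask` (logical 3-D array, non-empty).
#' @export
otsu_mask <- function(v, bins = 256L, foreground = c("above", "below")) {
  stopifnot(is_volume(v))
  foreground <- match.arg(foreground)
  x <- as.vector(v$data)
  lo <- min(x); hi <- max(x)
  if (hi <= lo)
    stop("constant image: no foreground/background separation possible")
  # bin index 0..bins-1; top value mapped into last bin
  idx <- pmin(as.integer((x - lo) / (hi - lo) * bins), bins - 1L)
  h <- tabulate(idx + 1L, nbins = bins)
  p <- h / sum(h)
  # candidate thresholds: classes {bins < t} vs {bins >= t}, t = 1..bins-1
  omega <- cumsum(p)                      # P(class0) for t = k+1
  mids <- (seq_len(bins) - 0.5)           # bin centers in bin units
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  w0 <- omega[-bins]
  m0 <- mu[-bins]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_bin <- which.max(sigma_b)             # first max = lower threshold
  threshold <- lo + t_bin * (hi - lo) / bins
  mask <- if (foreground == "above") v$data >= threshold else v$data < threshold
  if (!any(mask)) stop("Otsu mask is empty")
  list(threshold = threshold, mask = mask)
}
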