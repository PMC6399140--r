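#' Global field power
#'
#' The spatial standard deviation of the average-referenced scalp map at each
#' sample: `GFP(t) = sqrt(mean_c (v_c(t) - vbar(t))^2)` with the
#' divide-by-C (population) convention. Re-referencing is applied internally,
#' so GFP is invariant to any per-sample constant added to all channels.
#'
#' @param rec an [eeg_recording].
#' @return An object of class `gfp_series`: list with `values` (one
#'   non-negative scalar per sample), `sampling_rate`, and a `smoothed` flag.
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  centered <- sweep(rec$data, 2, colMeans(rec$data))
  structure(list(values = sqrt(colMeans(centered^2)),
                 sampling_rate = rec$sampling_rate, smoothed = FALSE),
            class = "gfp_series")
}

gaussian_kernel <- function(window, sigma = 1) {
  h <- (window - 1) / 2
  w <- exp(-0.5 * ((-h:h) / sigma)^2)
  w / sum(w)
}

#' Smooth a GFP series
#'
#' Gaussian-weighted moving average (default 5 taps, kernel sigma of one
#' sample) with reflected edges; a constant series is left unchanged.
#'
#' @param g a `gfp_series` from [compute_gfp()].
#' @param window odd kernel length in samples.
#' @param sigma kernel standard deviation in samples.
#' @return The smoothed `gfp_series`.
#' @export
smooth_gfp <- function(g, window = 5, sigma = 1) {
  stopifnot(inherits(g, "gfp_series"))
  if (window < 1 || window %% 2 == 0)
    stop("smoothing window must be odd and >= 1")
  if (window > 1) {
    w <- gaussian_kernel(window, sigma)
    h <- (window - 1) / 2
    v <- g$values
    n <- length(v)
    if (n <= h + 1) stop("series too short for the smoothing window")
    vp <- c(rev(v[2:(h + 1)]), v, rev(v[(n - h):(n - 1)]))
    sm <- stats::filter(vp, w, method = "convolution", sides = 2)
    g$values <- as.numeric(sm[(h + 1):(h + n)])
  }
  g$smoothed <- TRUE
  g
}

#' Locate GFP local maxima
#'
#' A peak is a sample strictly greater than its left neighbour and at least
#' as large as its right neighbour, so a flat plateau contributes its first
#' sample; the series endpoints are never peaks.
#'
#' @param g a `gfp_series` (normally smoothed first).
#' @return Integer vector of 1-based peak sample indices, strictly increasing.
#' @export
find_gfp_peaks <- function(g) {
  stopifnot(inherits(g, "gfp_series"))
  v <- g$values
  n <- length(v)
  if (n < 3) stop("need at least 3 samples to locate peaks")
  i <- 2:(n - 1)
  i[v[i - 1] < v[i] & v[i] >= v[i + 1]]
}

#' Randomly subsample peak indices
#'
#' Uniform sampling without replacement down to at most `max_n` peaks
#' (the clustering stage caps at 10,000), returned in ascending order and
#' deterministic for a fixed seed.
#'
#' @param peaks integer vector of peak indices.
#' @param max_n maximum number to retain.
#' @param seed RNG seed for the draw.
#' @return Sorted integer vector of at most `max_n` indices.
#' @export
subsample_peaks <- function(peaks, max_n = 10000, seed = 1) {
  peaks <- as.integer(peaks)
  if (length(peaks) <= max_n) return(sort(peaks))
  sort(with_seed(seed, sample(peaks, max_n)))
}
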