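#' Back-fit templates onto every EEG sample
#'
#' Assigns each sample the template with the highest absolute spatial
#' correlation (polarity-free); exact ties go to the lowest state index.
#' Samples whose best correlation falls below `min_corr`, or with zero spatial
#' variance, are left unassigned (`NA`).
#'
#' When `peaks` is supplied, only the GFP-peak samples are correlated against
#' the templates and every other sample inherits the label of its nearest
#' peak (the classical peak-interpolation scheme). This is the
#' duration-faithful mode: sample-wise labeling is noise-dominated wherever
#' the instantaneous signal amplitude passes through zero, which fragments
#' dwell segments; peak interpolation labels only high-SNR moments.
#'
#' @param rec an [eeg_recording], already filtered; re-referenced internally.
#' @param templates an [ms_templates] with matching channel count.
#' @param min_corr correlation floor in `[0, 1]`; 0 labels every sample.
#' @param peaks optional integer vector of GFP-peak sample indices enabling
#'   peak-interpolated labeling.
#' @return An [ms_labels] with one state per sample.
#' @export
backfit <- function(rec, templates, min_corr = 0, peaks = NULL) {
  if (!is.null(peaks)) return(backfit_peaks(rec, templates, min_corr, peaks))
  backfit_samples(rec, templates, min_corr)
}

backfit_samples <- function(rec, templates, min_corr) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(templates, "ms_templates"))
  if (ncol(templates$maps) != nrow(rec$data))
    stop("channel counts of recording and templates differ")
  V <- sweep(rec$data, 2, colMeans(rec$data))
  nrm <- sqrt(colSums(V^2))
  corr <- abs(templates$maps %*% V)                 # k x n, un-normalized
  ok <- nrm > 1e-12
  corr[, ok] <- sweep(corr[, ok, drop = FALSE], 2, nrm[ok], "/")
  labels <- max.col(t(corr), ties.method = "first")
  best <- corr[cbind(labels, seq_along(labels))]
  labels[!ok | best < min_corr] <- NA_integer_
  ms_labels(labels, rec$sampling_rate, state_names = templates$labels)
}

#' Majority-vote temporal smoothing of a label sequence
#'
#' Replaces each sample's label by the most frequent label inside a centred
#' window (ties keep the lowest state index; `NA` votes are ignored). Heals
#' isolated misassignments at instants of low signal amplitude, where
#' sample-wise back-fitting is noise-dominated. Off by default in the
#' pipeline.
#'
#' @param seq an [ms_labels].
#' @param window_ms full window length in milliseconds.
#' @return The smoothed [ms_labels].
#' @export
smooth_labels <- function(seq, window_ms) {
  stopifnot(inherits(seq, "ms_labels"))
  h <- floor(window_ms * seq$sampling_rate / 1000 / 2)
  if (h < 1) return(seq)
  x <- seq$labels
  n <- length(x)
  # votes per state over a sliding window via cumulative sums
  votes <- matrix(0L, n, seq$k)
  for (s in seq_len(seq$k)) {
    cs <- cumsum(c(0L, as.integer(!is.na(x) & x == s)))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    votes[, s] <- cs[hi + 1L] - cs[lo]
  }
  out <- max.col(votes, ties.method = "first")
  out[rowSums(votes) == 0] <- NA_integer_
  ms_labels(out, seq$sampling_rate, state_names = seq$state_names)
}

backfit_peaks <- function(rec, templates, min_corr, peaks) {
  peaks <- sort(as.integer(peaks))
  n <- ncol(rec$data)
  if (length(peaks) < 1 || peaks[1] < 1 || peaks[length(peaks)] > n)
    stop("peak indices out of range")
  sub <- rec
  sub$data <- rec$data[, peaks, drop = FALSE]
  at_peaks <- backfit_samples(sub, templates, min_corr)$labels
  # nearest-peak interpolation; midpoints tie to the earlier peak
  cuts <- c(-Inf, (peaks[-length(peaks)] + peaks[-1]) / 2, Inf)
  owner <- findInterval(seq_len(n), cuts, left.open = TRUE)
  ms_labels(at_peaks[owner], rec$sampling_rate,
            state_names = templates$labels)
}

#' Run-length segments of a label sequence
#'
#' Maximal runs of equal labels as `(state, start, length)` with 1-based,
#' half-open sample intervals; unassigned stretches appear with `state = NA`.
#'
#' @param seq an [ms_labels].
#' @return A data.frame with columns `state`, `start`, `length`.
#' @export
segments <- function(seq) {
  stopifnot(inherits(seq, "ms_labels"))
  r <- rle(ifelse(is.na(seq$labels), -1L, seq$labels))
  data.frame(state = ifelse(r$values < 0, NA_integer_, r$values),
             start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
             length = r$lengths)
}

# interior segments: first and last runs are truncated by the recording edges
interior_segments <- function(seq) {
  sg <- segments(seq)
  if (nrow(sg) < 3) stop("need at least 3 segments for duration statistics")
  sg <- sg[-c(1, nrow(sg)), , drop = FALSE]
  sg[!is.na(sg$state), , drop = FALSE]
}

#' Mean microstate durations
#'
#' Mean length of the interior segments of each state (boundary segments are
#' discarded as truncated), in milliseconds. States absent from the interior
#' are reported as `NA`, not zero.
#'
#' @param seq an [ms_labels].
#' @return Named numeric vector (ms), one entry per state.
#' @export
mean_durations <- function(seq) {
  sg <- interior_segments(seq)
  out <- rep(NA_real_, seq$k)
  names(out) <- seq$state_names
  agg <- tapply(sg$length, factor(sg$state, levels = seq_len(seq$k)), mean)
  out[] <- as.numeric(agg) * 1000 / seq$sampling_rate
  out
}

#' Microstate occurrence rates
#'
#' Number of interior segment onsets of each state divided by the analyzed
#' duration (the total interior assigned time), in events per second. Absent
#' states are 0.
#'
#' @param seq an [ms_labels].
#' @return Named numeric vector (events/s), one entry per state.
#' @export
occurrence_rates <- function(seq) {
  sg <- interior_segments(seq)
  secs <- sum(sg$length) / seq$sampling_rate
  cnt <- table(factor(sg$state, levels = seq_len(seq$k)))
  out <- as.numeric(cnt) / secs
  names(out) <- seq$state_names
  out
}

#' Microstate coverage
#'
#' Fraction of assigned samples spent in each state; sums to 1.
#'
#' @param seq an [ms_labels].
#' @return Named numeric vector of fractions.
#' @export
coverage <- function(seq) {
  lb <- seq$labels[!is.na(seq$labels)]
  cnt <- tabulate(lb, nbins = seq$k)
  out <- cnt / sum(cnt)
  names(out) <- seq$state_names
  out
}

#' Temporal properties of a microstate sequence
#'
#' @param seq an [ms_labels].
#' @return A data.frame with one row per state: `state`, `mean_duration_ms`,
#'   `occurrence_per_s`, `coverage`.
#' @export
microstate_properties <- function(seq) {
  data.frame(state = seq$state_names,
             mean_duration_ms = unname(mean_durations(seq)),
             occurrence_per_s = unname(occurrence_rates(seq)),
             coverage = unname(coverage(seq)))
}

#' Transition matrix of a label sequence
#'
#' `per_sample` counts every ordered pair of consecutive assigned samples
#' (self-transitions included); `segment` counts consecutive pairs of
#' distinct segments (zero diagonal). Unassigned samples break pairs. Rows
#' with zero counts are left as zeros and flagged in `empty_rows`.
#'
#' @param seq an [ms_labels].
#' @param mode `"per_sample"` or `"segment"`.
#' @return An object of class `ms_transitions`: `probs`, `counts`, `mode`,
#'   `state_names`, `empty_rows`.
#' @export
transition_matrix <- function(seq, mode = c("per_sample", "segment")) {
  mode <- match.arg(mode)
  K <- seq$k
  if (mode == "per_sample") {
    a <- seq$labels[-length(seq$labels)]
    b <- seq$labels[-1]
  } else {
    sg <- segments(seq)
    a <- sg$state[-nrow(sg)]
    b <- sg$state[-1]
  }
  ok <- !is.na(a) & !is.na(b)
  counts <- matrix(tabulate((a[ok] - 1) * K + b[ok], nbins = K * K),
                   K, K, byrow = TRUE)
  if (sum(counts) == 0)
    stop("no valid consecutive pairs to count")
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- 0
  dimnames(probs) <- dimnames(counts) <-
    list(seq$state_names, seq$state_names)
  structure(list(probs = probs, counts = counts, mode = mode,
                 state_names = seq$state_names, empty_rows = which(rs == 0)),
            class = "ms_transitions")
}

#' @export
print.ms_transitions <- function(x, ...) {
  cat(sprintf("<ms_transitions> mode = %s, %d pairs\n", x$mode, sum(x$counts)))
  print(round(x$probs, 4))
  invisible(x)
}
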