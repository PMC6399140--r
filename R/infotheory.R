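# Information-theoretic characterization of microstate label sequences:
# likelihood-ratio (G) tests of low-order Markovianity, stationarity and
# symmetry of the transition matrix, and the autoinformation function.

markov_test_result <- function(test, g, df, alpha) {
  p <- stats::pchisq(g, df, lower.tail = FALSE)
  structure(list(test = test, g_statistic = g, df = df, p_value = p,
                 alpha = alpha, significant = p < alpha),
            class = "markov_test")
}

#' @export
print.markov_test <- function(x, ...) {
  cat(sprintf("<markov_test> %s: G = %.3f, df = %d, p = %.3g (alpha = %g)%s\n",
              x$test, x$g_statistic, x$df, x$p_value, x$alpha,
              if (x$significant) " *" else ""))
  invisible(x)
}

# counts of m-tuples of consecutive assigned samples, as an array of dim K^m
tuple_counts <- function(seq, m) {
  x <- seq$labels
  K <- seq$k
  n <- length(x)
  if (n < m) stop("sequence shorter than the tuple length")
  idx <- rep(0, n - m + 1)
  ok <- rep(TRUE, n - m + 1)
  for (j in seq_len(m)) {
    xi <- x[j:(n - m + j)]
    ok <- ok & !is.na(xi)
    idx <- idx * K + (ifelse(is.na(xi), 1L, xi) - 1L)
  }
  array(tabulate(idx[ok] + 1L, nbins = K^m), dim = rep(K, m))
}

check_seq_for_test <- function(seq) {
  present <- unique(seq$labels[!is.na(seq$labels)])
  if (length(present) < 2)
    stop("test undefined for a sequence with fewer than 2 observed states")
}

# Williams' small-sample correction factor for a likelihood-ratio test of
# independence in one r x c table (Williams 1976): the G statistic is
# divided by q, which tends to 1 as n grows. Margins of zero are skipped.
williams_q <- function(tab, df) {
  n <- sum(tab)
  if (n == 0 || df <= 0) return(1)
  ri <- rowSums(tab); cj <- colSums(tab)
  a <- n * sum(1 / ri[ri > 0]) - 1
  b <- n * sum(1 / cj[cj > 0]) - 1
  max(1, 1 + a * b / (6 * n * df))
}

# G and Williams-corrected G for an independence table
g_independence <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  g <- 2 * xlogratio(tab, tab, expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  g / williams_q(tab, df)
}

#' Test of order-0 Markovianity (independence of consecutive samples)
#'
#' G-test of `P(X_{t+1}) = P(X_{t+1} | X_t)` from the pair counts:
#' `G = 2 sum_ij n_ij ln(n_ij n / (n_i. n_.j))`, df `(K-1)^2`, p-value from
#' the chi-squared tail. Zero-count cells contribute 0. Williams'
#' small-sample correction is applied (it vanishes as n grows but keeps the
#' chi-squared reference honest at moderate sequence lengths).
#'
#' @param seq an [ms_labels].
#' @param alpha significance level.
#' @return A `markov_test` result.
#' @export
markov_order0_test <- function(seq, alpha = 0.01) {
  check_seq_for_test(seq)
  K <- seq$k
  nij <- tuple_counts(seq, 2)
  g <- g_independence(nij)
  markov_test_result("markov_order0", g, (K - 1)^2, alpha)
}

#' Test of order-1 Markovianity
#'
#' G-test of `P(X_{t+1} | X_t, X_{t-1}) = P(X_{t+1} | X_t)` from triple
#' counts: `G = 2 sum_ijk n_ijk ln(n_ijk n_.j. / (n_ij. n_.jk))`, df
#' `K (K-1)^2`. Computed as a sum of per-stratum (one stratum per
#' conditioning state `X_t = j`) independence G statistics, each with
#' Williams' small-sample correction.
#'
#' @inheritParams markov_order0_test
#' @return A `markov_test` result.
#' @export
markov_order1_test <- function(seq, alpha = 0.01) {
  check_seq_for_test(seq)
  K <- seq$k
  nijk <- tuple_counts(seq, 3)
  g <- sum(vapply(seq_len(K), function(j)
    g_independence(nijk[, j, ]), numeric(1)))
  markov_test_result("markov_order1", g, K * (K - 1)^2, alpha)
}

#' Test of order-2 Markovianity
#'
#' G-test of `P(X_{t+1} | X_t, X_{t-1}, X_{t-2}) = P(X_{t+1} | X_t, X_{t-1})`
#' from quadruple counts, df `K^2 (K-1)^2`; one Williams-corrected
#' independence stratum per conditioning pair `(X_{t-1}, X_t)`.
#'
#' @inheritParams markov_order0_test
#' @return A `markov_test` result.
#' @export
markov_order2_test <- function(seq, alpha = 0.01) {
  check_seq_for_test(seq)
  K <- seq$k
  nijkl <- tuple_counts(seq, 4)
  g <- 0
  for (j in seq_len(K)) for (k in seq_len(K))
    g <- g + g_independence(nijkl[, j, k, ])
  markov_test_result("markov_order2", g, K^2 * (K - 1)^2, alpha)
}

#' Stationarity test of the transition matrix over time blocks
#'
#' Splits the sequence into B blocks of `block_length` seconds and tests each
#' block's transition counts against the pooled matrix:
#' `G = 2 sum_b sum_ij n^b_ij ln(n^b_ij n_i. / (n_ij n^b_i.))`, df
#' `(B-1) K (K-1)`, with Williams' correction per conditioning state.
#' Non-overlapping blocks by default; `overlap = TRUE` uses
#' half-block steps (the literal reading of overlapping blocks, at the cost of
#' the chi-squared independence assumption).
#'
#' @param seq an [ms_labels].
#' @param block_length block length in seconds.
#' @param alpha significance level.
#' @param overlap use 50%-overlapping blocks.
#' @return A `markov_test` result (test name `stationarity`).
#' @export
stationarity_test <- function(seq, block_length, alpha = 0.01,
                              overlap = FALSE) {
  check_seq_for_test(seq)
  K <- seq$k
  L <- round(block_length * seq$sampling_rate)
  if (L < 2) stop("block length must cover at least 2 samples")
  n <- length(seq$labels)
  step <- if (overlap) max(1L, L %/% 2L) else L
  if (L + step > n) stop("need at least 2 blocks")
  starts <- seq(1L, n - L + 1L, by = step)
  if (length(starts) < 2) stop("need at least 2 blocks")
  block_counts <- lapply(starts, function(s) {
    sub <- ms_labels(seq$labels[s:(s + L - 1L)], seq$sampling_rate,
                     state_names = seq$state_names)
    tuple_counts(sub, 2)
  })
  B <- length(block_counts)
  # one stratum per current state i: a B x K table of block-wise next-state
  # counts, tested for homogeneity across blocks
  g <- sum(vapply(seq_len(K), function(i) {
    tab <- do.call(rbind, lapply(block_counts, function(bc) bc[i, ]))
    g_independence(tab)
  }, numeric(1)))
  markov_test_result("stationarity", g, (B - 1) * K * (K - 1), alpha)
}

#' Ratio of subjects with non-stationary transitions per block length
#'
#' Evaluates [stationarity_test()] on every subject over a grid of block
#' lengths and reports the fraction significant at each length.
#'
#' @param seqs list of [ms_labels], one per subject.
#' @param block_grid block lengths in seconds (default 2-40 s, step 2).
#' @param alpha significance level (the cohort figure uses `p < 0.05`).
#' @param overlap passed to [stationarity_test()].
#' @return data.frame with `block_length_s` and `ratio_significant`.
#' @export
stationarity_profile <- function(seqs, block_grid = seq(2, 40, by = 2),
                                 alpha = 0.05, overlap = FALSE) {
  ratio <- vapply(block_grid, function(L) {
    mean(vapply(seqs, function(s)
      stationarity_test(s, L, alpha = alpha, overlap = overlap)$significant,
      logical(1)))
  }, numeric(1))
  data.frame(block_length_s = block_grid, ratio_significant = ratio)
}

#' Symmetry test of the transition matrix
#'
#' Tests `P(X_{t+1}=j | X_t=i) = P(X_{t+1}=i | X_t=j)` via
#' `G = 2 sum_{i != j} n_ij ln(2 n_ij / (n_ij + n_ji))`. Along a single
#' trajectory the forward and backward counts of every state are tied
#' (in-degree equals out-degree up to the endpoints), which removes `K - 1`
#' of the `K(K-1)/2` antisymmetric degrees of freedom; the chi-squared
#' reference therefore uses the cycle-space dimension
#' `df = (K-1)(K-2)/2`, under which the statistic is calibrated (checked by
#' simulation against reversible-chain nulls). Requires at least 3 observed
#' states.
#'
#' @inheritParams markov_order0_test
#' @return A `markov_test` result (test name `symmetry`).
#' @export
symmetry_test <- function(seq, alpha = 0.01) {
  check_seq_for_test(seq)
  K <- seq$k
  nij <- tuple_counts(seq, 2)
  if (K < 3)
    stop("symmetry test degenerate below 3 states (counts are tied)")
  off <- nij; diag(off) <- 0
  if (sum(off) == 0) stop("symmetry test undefined without off-diagonal pairs")
  num <- 2 * off
  den <- off + t(off)
  g <- 2 * xlogratio(off, num, den)
  markov_test_result("symmetry", g, (K - 1) * (K - 2) / 2, alpha)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_at_lag <- function(x, K, lag) {
  n <- length(x)
  if (lag == 0) {
    a <- b <- x
  } else {
    a <- x[1:(n - lag)]
    b <- x[(1 + lag):n]
  }
  ok <- !is.na(a) & !is.na(b)
  joint <- matrix(tabulate((a[ok] - 1) * K + b[ok], nbins = K * K),
                  K, K, byrow = TRUE) / sum(ok)
  entropy_bits(rowSums(joint)) + entropy_bits(colSums(joint)) -
    entropy_bits(joint)
}

#' Autoinformation function of a label sequence
#'
#' Plug-in time-lagged mutual information
#' `I(tau) = H(X_t) + H(X_{t+tau}) - H(X_t, X_{t+tau})` in bits, over lags
#' 0..`max_lag_ms`. `I(0)` equals the marginal entropy. Lags that do not fit
#' into the sequence are dropped with a warning.
#'
#' @param seq an [ms_labels].
#' @param max_lag_ms largest lag in milliseconds (default 4000).
#' @return An `aif_curve` data.frame with columns `lag`, `lag_ms`, `mi_bits`.
#' @export
aif <- function(seq, max_lag_ms = 4000) {
  stopifnot(inherits(seq, "ms_labels"))
  max_lag <- floor(max_lag_ms * seq$sampling_rate / 1000)
  n <- length(seq$labels)
  if (max_lag >= n) {
    warning("lag grid truncated to the sequence length")
    max_lag <- n - 1L
  }
  lags <- 0:max_lag
  mi <- vapply(lags, function(L) mi_at_lag(seq$labels, seq$k, L), numeric(1))
  structure(data.frame(lag = lags, lag_ms = lags * 1000 / seq$sampling_rate,
                       mi_bits = mi),
            class = c("aif_curve", "data.frame"), scope = "global")
}

#' Per-state autoinformation
#'
#' AIF of the binary indicator sequence `1{X_t = state}`; at lag 0 this is the
#' binary entropy of the state's coverage.
#'
#' @param seq an [ms_labels].
#' @param state state index or name.
#' @param max_lag_ms largest lag in milliseconds.
#' @return An `aif_curve` data.frame with attribute `scope = "state:<name>"`.
#' @export
partial_aif <- function(seq, state, max_lag_ms = 4000) {
  if (is.character(state)) state <- match(state, seq$state_names)
  if (is.na(state) || state < 1 || state > seq$k)
    stop("unknown state")
  if (!any(seq$labels == state, na.rm = TRUE))
    stop("state absent from the sequence")
  ind <- ifelse(is.na(seq$labels), NA_integer_,
                1L + (seq$labels == state))
  bin <- ms_labels(ind, seq$sampling_rate,
                   state_names = c("other", seq$state_names[state]))
  out <- aif(bin, max_lag_ms)
  attr(out, "scope") <- paste0("state:", seq$state_names[state])
  out
}

#' Stationary distribution of a transition matrix
#'
#' Leading left eigenvector of `T`, normalized to a probability vector.
#'
#' @param T row-stochastic matrix (must be irreducible).
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(T) {
  check_transition_matrix(T)
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (max(abs(Im(e$vectors[, i]))) > 1e-8 || all(abs(v) < 1e-12))
    stop("no real stationary distribution found")
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("transition matrix appears reducible: no positive stationary vector")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Closed-form AIF of a first-order Markov chain
#'
#' For a stationary chain with transition matrix `T` and stationary
#' distribution `pi`, the lag-`tau` joint distribution is `diag(pi) T^tau`,
#' giving `I(tau) = 2 H(pi) - H(joint)` in bits. Serves as the independent
#' reference for the plug-in estimator.
#'
#' @param T irreducible row-stochastic matrix.
#' @param lag non-negative integer lag.
#' @return Mutual information in bits.
#' @export
markov_aif_closed_form <- function(T, lag) {
  p <- stationary_distribution(T)
  Tp <- diag(nrow(T))
  Tl <- T
  lag <- as.integer(lag)
  while (lag > 0) {           # exponentiation by squaring
    if (lag %% 2L == 1L) Tp <- Tp %*% Tl
    Tl <- Tl %*% Tl
    lag <- lag %/% 2L
  }
  joint <- diag(p) %*% Tp
  2 * entropy_bits(p) - entropy_bits(joint)
}

#' Fraction of significant results in a cohort
#'
#' @param results list of `markov_test` results of the same test type.
#' @return Fraction of subjects flagged significant.
#' @export
cohort_summary <- function(results) {
  if (length(results) == 0) stop("empty result list")
  mean(vapply(results, function(r) isTRUE(r$significant), logical(1)))
}
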