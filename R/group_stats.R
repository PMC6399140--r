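# Cohort comparison of microstate features: pooled-variance t-tests,
# Bonferroni-Holm step-down correction, Cohen's d, normality diagnostics.

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled variance estimator and `df = n1 + n2 - 2`
#' (the convention matching printed `t_(111)` statistics for cohorts of 52
#' and 61). Degenerate inputs with zero pooled variance give `t = 0, p = 1`
#' when the means agree and an error otherwise.
#'
#' @param x,y numeric samples (each of size >= 2, finite).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
student_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2 || any(!is.finite(c(x, y))))
    stop("each sample must hold at least 2 finite values")
  df <- length(x) + length(y) - 2
  pooled <- ((length(x) - 1) * stats::var(x) +
             (length(y) - 1) * stats::var(y)) / df
  if (pooled < 1e-24) {
    if (abs(mean(x) - mean(y)) < 1e-12) return(list(t = 0, df = df, p = 1))
    stop("t-test undefined: zero pooled variance with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param p raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled` with `n - 1` weights. Sign convention:
#' `x` is the reference (control) cohort, so a positive d means the reference
#' group is larger.
#'
#' @param x,y numeric samples.
#' @return Scalar effect size.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2 || any(!is.finite(c(x, y))))
    stop("each sample must hold at least 2 finite values")
  df <- length(x) + length(y) - 2
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) / df)
  if (sp < 1e-12) stop("effect size undefined: zero pooled SD")
  (mean(x) - mean(y)) / sp
}

#' Compare two cohorts feature by feature
#'
#' Per-feature pooled t-test and Cohen's d (`group1 - group2` convention),
#' with Bonferroni-Holm correction applied within each feature family (for
#' K = 4: the 12 off-diagonal transitions as one family, the 4 durations as
#' another, the 4 occurrence rates as a third).
#'
#' @param feature_table_1,feature_table_2 data.frames, one row per subject,
#'   one column per feature; both must share the feature columns.
#' @param families named list mapping family name to the character vector of
#'   its feature columns. Defaults to one family holding all features.
#' @param alpha significance level on the adjusted p-values.
#' @return data.frame with one row per feature: `feature`, `family`, `t`,
#'   `df`, `p_raw`, `p_holm`, `cohens_d`, `significant`.
#' @export
compare_cohorts <- function(feature_table_1, feature_table_2,
                            families = NULL, alpha = 0.05) {
  feats <- colnames(feature_table_1)
  if (!identical(sort(feats), sort(colnames(feature_table_2))))
    stop("the two cohorts must share the same feature set")
  families <- families %||% list(all = feats)
  unknown <- setdiff(unlist(families), feats)
  if (length(unknown))
    stop("unknown features in families: ", paste(unknown, collapse = ", "))
  rows <- lapply(names(families), function(fam) {
    fam_feats <- families[[fam]]
    res <- lapply(fam_feats, function(f) {
      x <- feature_table_1[[f]]; y <- feature_table_2[[f]]
      tt <- student_t_test(x, y)
      data.frame(feature = f, family = fam, t = tt$t, df = tt$df,
                 p_raw = tt$p, cohens_d = cohens_d(x, y))
    })
    res <- do.call(rbind, res)
    res$p_holm <- holm_adjust(res$p_raw)
    res
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_holm < alpha
  out[, c("feature", "family", "t", "df", "p_raw", "p_holm", "cohens_d",
          "significant")]
}

#' Numeric normality diagnostics
#'
#' Skewness, excess kurtosis (population moments) and the Shapiro-Wilk
#' p-value, replacing a visual Q-Q inspection.
#'
#' @param x numeric sample of size >= 8.
#' @return List with `skewness`, `excess_kurtosis`, `shapiro_p`.
#' @export
normality_diagnostics <- function(x) {
  if (length(x) < 8) stop("need at least 8 observations")
  if (stats::sd(x) < 1e-12) stop("diagnostics undefined for a constant sample")
  z <- (x - mean(x))
  s <- sqrt(mean(z^2))
  sw <- stats::shapiro.test(if (length(x) > 5000) x[seq_len(5000)] else x)
  list(skewness = mean(z^3) / s^3,
       excess_kurtosis = mean(z^4) / s^4 - 3,
       shapiro_p = sw$p.value)
}
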