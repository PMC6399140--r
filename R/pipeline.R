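#' Pipeline configuration
#'
#' Defaults encode the analysis conventions used throughout: 2-20 Hz band,
#' 5-point Gaussian GFP smoothing, up to 10,000 clustered peaks, k = 4
#' microstates, a 2-40 s stationarity grid, a 4000 ms AIF horizon, alpha 0.01
#' for the sequence tests and 0.05 for cohort comparisons.
#'
#' @param low,high filter band edges (Hz).
#' @param smooth_window GFP smoothing window (samples, odd).
#' @param max_peaks cap on clustered GFP peaks per subject.
#' @param k number of microstate classes.
#' @param min_corr back-fitting correlation floor (0 = label everything).
#' @param label_smooth_ms majority-vote label smoothing window (ms); 0
#'   disables it (the default). See [smooth_labels()].
#' @param block_grid stationarity block lengths (seconds).
#' @param max_lag_ms AIF lag horizon (ms).
#' @param alpha_markov level for the sequence tests.
#' @param alpha_group level for cohort comparisons (on Holm-adjusted p).
#' @param compute_aif include AIF curves in the bundle (costly).
#' @param seed master seed (peak subsampling).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(low = 2, high = 20, smooth_window = 5,
                            max_peaks = 10000, k = 4, min_corr = 0,
                            label_smooth_ms = 0,
                            block_grid = seq(2, 40, by = 2),
                            max_lag_ms = 4000, alpha_markov = 0.01,
                            alpha_group = 0.05, compute_aif = FALSE,
                            seed = 1) {
  structure(list(low = low, high = high, smooth_window = smooth_window,
                 max_peaks = max_peaks, k = k, min_corr = min_corr,
                 label_smooth_ms = label_smooth_ms,
                 block_grid = block_grid, max_lag_ms = max_lag_ms,
                 alpha_markov = alpha_markov, alpha_group = alpha_group,
                 compute_aif = compute_aif, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Segment one subject: filter, GFP peaks, AAHC
#'
#' The per-subject first half of the pipeline: average reference, band-pass,
#' GFP, smoothing, peak picking, random subsampling, and AAHC clustering of
#' the peak maps (maps are taken from the filtered, unsmoothed recording at
#' the peak indices of the smoothed GFP).
#'
#' @param rec an [eeg_recording].
#' @param config a [pipeline_config()].
#' @return List with `templates`, `solution` (the [aahc] fit), `peaks`,
#'   `filtered` (the filtered recording), `gfp`.
#' @export
segment_subject <- function(rec, config = pipeline_config()) {
  rec <- average_reference(rec)
  rec <- bandpass_filter(rec, config$low, config$high)
  g <- compute_gfp(rec)
  gs <- smooth_gfp(g, config$smooth_window)
  peaks <- find_gfp_peaks(gs)
  peaks <- subsample_peaks(peaks, config$max_peaks, seed = config$seed)
  maps <- t(rec$data[, peaks, drop = FALSE])
  sol <- aahc(maps, g$values[peaks], k = config$k)
  list(templates = sol$templates, solution = sol, peaks = peaks,
       filtered = rec, gfp = g)
}

transition_feature_names <- function(state_names) {
  K <- length(state_names)
  idx <- which(diag(K) == 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sprintf("Tr(%s->%s)", state_names[idx[, 1]], state_names[idx[, 2]])
}

#' Feature table for a cohort of label sequences
#'
#' One row per subject: per-state mean durations and occurrence rates plus
#' the 12 off-diagonal segment-mode transition probabilities, the features
#' entering [compare_cohorts()].
#'
#' @param seqs list of [ms_labels].
#' @param mode transition counting mode for the transition features.
#' @return data.frame of features.
#' @export
feature_table <- function(seqs, mode = "segment") {
  stopifnot(length(seqs) > 0)
  sn <- seqs[[1]]$state_names
  K <- length(sn)
  off <- which(diag(K) == 0, arr.ind = TRUE)
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  rows <- lapply(seqs, function(s) {
    tm <- transition_matrix(s, mode = mode)
    vals <- c(mean_durations(s), occurrence_rates(s), tm$probs[off])
    names(vals) <- c(paste0("duration:", sn), paste0("occurrence:", sn),
                     transition_feature_names(sn))
    as.data.frame(as.list(vals), check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Default feature families for Holm correction
#'
#' The 12 transitions corrected together, the 4 durations together, and the
#' 4 occurrence rates together.
#'
#' @param state_names state names (default A-D).
#' @return Named list of feature-name vectors.
#' @export
default_families <- function(state_names = LETTERS[1:4]) {
  list(durations = paste0("duration:", state_names),
       occurrences = paste0("occurrence:", state_names),
       transitions = transition_feature_names(state_names))
}

#' Run the full two-cohort pipeline
#'
#' Executes segmentation (per subject), group-template construction and
#' canonical ordering (per cohort), back-fitting, temporal properties,
#' the sequence tests (Markov orders 0-2, symmetry, stationarity profile,
#' optionally AIF), and the cohort comparison. Deterministic for a fixed
#' config.
#'
#' @param group1,group2 lists of [eeg_recording] (group 1 is the reference
#'   cohort in all effect-size sign conventions).
#' @param config a [pipeline_config()].
#' @param canonical template set used for ordering; `NULL` skips canonical
#'   reordering when channel counts do not match the packaged montage.
#' @return A result bundle: per-group `templates`, `labels`, `features`,
#'   `sequence_tests`, `stationarity`, optional `aif`, plus `comparison`
#'   and the `config`.
#' @export
run_pipeline <- function(group1, group2, config = pipeline_config(),
                         canonical = NULL) {
  stopifnot(length(group1) >= 1, length(group2) >= 1)
  groups <- list(group1 = group1, group2 = group2)
  out <- list(config = config)
  for (gname in names(groups)) {
    recs <- groups[[gname]]
    message(sprintf("[%s] segmenting %d subjects", gname, length(recs)))
    segs <- lapply(recs, segment_subject, config = config)
    gt <- group_templates(lapply(segs, `[[`, "templates"))
    if (is.null(canonical) && ncol(gt$maps) == 31)
      canonical <- canonical_templates()
    if (!is.null(canonical) && ncol(canonical$maps) == ncol(gt$maps))
      gt <- order_canonical(gt, canonical)
    message(sprintf("[%s] back-fitting group templates", gname))
    labels <- lapply(segs, function(s) {
      sq <- backfit(s$filtered, gt, min_corr = config$min_corr)
      if (config$label_smooth_ms > 0)
        sq <- smooth_labels(sq, config$label_smooth_ms)
      sq
    })
    tests <- lapply(labels, function(sq) list(
      markov0 = markov_order0_test(sq, config$alpha_markov),
      markov1 = markov_order1_test(sq, config$alpha_markov),
      markov2 = markov_order2_test(sq, config$alpha_markov),
      symmetry = symmetry_test(sq, config$alpha_markov)))
    stat_prof <- stationarity_profile(labels, config$block_grid,
                                      alpha = config$alpha_group)
    res <- list(templates = gt, labels = labels,
                gev = vapply(segs, function(s) s$solution$gev, numeric(1)),
                features = feature_table(labels),
                sequence_tests = tests, stationarity = stat_prof)
    if (config$compute_aif)
      res$aif <- lapply(labels, aif, max_lag_ms = config$max_lag_ms)
    out[[gname]] <- res
  }
  message("comparing cohorts")
  out$comparison <- compare_cohorts(out$group1$features, out$group2$features,
                                    families = default_families(
                                      out$group1$templates$labels),
                                    alpha = config$alpha_group)
  out
}
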