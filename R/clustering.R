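#' Atomize-and-agglomerate hierarchical clustering (AAHC) of peak maps
#'
#' Polarity-invariant AAHC: every map starts as its own cluster; the cluster
#' contributing least to the global explained variance (GEV) is dissolved and
#' each orphaned map is reassigned to the surviving cluster with the highest
#' squared spatial correlation; affected cluster templates are recomputed as
#' the dominant eigenvector of their members' outer-product sum (a
#' polarity-free mean). Iteration stops at `k` clusters. Deterministic for a
#' fixed input order; exact correlation ties go to the lowest cluster index.
#'
#' @param maps numeric N x C matrix of peak topographies (rows are maps).
#' @param gfp_at_peaks GFP value at each peak (length N), used as map weight.
#' @param k number of clusters (microstate classes), conventionally 4.
#' @return An object of class `aahc_solution`: `templates` (an
#'   [ms_templates]), `assignment` (length-N integer, 1..k), `gev`, and the
#'   per-cluster GEV `contributions`.
#' @export
aahc <- function(maps, gfp_at_peaks, k = 4) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n <= k) stop("need more maps than clusters")
  if (length(gfp_at_peaks) != n) stop("one GFP value per map required")
  M <- normalize_maps(maps)
  g <- as.numeric(gfp_at_peaks)
  g2tot <- sum(g^2)
  if (g2tot <= 0) stop("GEV undefined when all GFP values are zero")

  templates <- M                      # row i = template of cluster i
  members <- as.list(seq_len(n))
  contrib <- g^2 / g2tot              # singleton: |corr| = 1 with itself
  alive <- rep(TRUE, n)
  n_alive <- n

  recompute <- function(idx) {
    mm <- M[idx, , drop = FALSE]
    tmpl <- eigen(crossprod(mm), symmetric = TRUE)$vectors[, 1]
    proj <- abs(mm %*% tmpl)
    list(template = tmpl, contrib = sum((g[idx] * proj)^2) / g2tot)
  }

  while (n_alive > k) {
    surv <- which(alive)
    worst <- surv[which.min(contrib[surv])]
    orphans <- members[[worst]]
    alive[worst] <- FALSE
    members[worst] <- list(NULL)
    n_alive <- n_alive - 1
    surv <- which(alive)
    corr <- abs(M[orphans, , drop = FALSE] %*% t(templates[surv, , drop = FALSE]))
    dest <- surv[max.col(corr, ties.method = "first")]
    for (d in unique(dest)) {
      members[[d]] <- c(members[[d]], orphans[dest == d])
      upd <- recompute(members[[d]])
      templates[d, ] <- upd$template
      contrib[d] <- upd$contrib
    }
  }

  surv <- which(alive)
  assignment <- integer(n)
  for (i in seq_along(surv)) assignment[members[[surv[i]]]] <- i
  structure(list(
    templates = ms_templates(templates[surv, , drop = FALSE]),
    assignment = assignment,
    gev = sum(contrib[surv]),
    contributions = unname(contrib[surv])
  ), class = "aahc_solution")
}

#' Global explained variance of a segmentation
#'
#' GFP-weighted squared spatial correlation between each map and its assigned
#' template, normalized by the total squared GFP:
#' `sum_t (GFP_t * corr_t)^2 / sum_t GFP_t^2`.
#'
#' @param maps N x C matrix of topographies.
#' @param gfp_at_peaks length-N GFP values.
#' @param templates an [ms_templates].
#' @param assignment length-N integer cluster labels (1..k).
#' @return A fraction in `[0, 1]`.
#' @export
gev <- function(maps, gfp_at_peaks, templates, assignment) {
  M <- normalize_maps(as.matrix(maps))
  g <- as.numeric(gfp_at_peaks)
  if (length(g) != nrow(M) || length(assignment) != nrow(M))
    stop("maps, GFP values and assignment must have matching lengths")
  g2tot <- sum(g^2)
  if (g2tot <= 0) stop("GEV undefined when all GFP values are zero")
  corr <- abs(rowSums(M * templates$maps[assignment, , drop = FALSE]))
  sum((g * corr)^2) / g2tot
}

# best permutation (and per-map signs) aligning `maps` to `ref`; both K x C,
# rows unit-norm zero-mean. Exhaustive over K! permutations.
align_to_reference <- function(maps, ref) {
  k <- nrow(ref)
  perms <- permutations(k)
  dots <- maps %*% t(ref)                 # dots[i, j] = <map_i, ref_j>
  scores <- apply(perms, 1, function(p) sum(abs(dots[cbind(p, seq_len(k))])))
  best <- perms[which.max(scores), ]
  signs <- sign(dots[cbind(best, seq_len(k))])
  signs[signs == 0] <- 1
  list(perm = best, signs = signs, score = max(scores))
}

#' Group-mean templates by iterative permutation alignment
#'
#' Builds the common topographies of a cohort: starting from the first
#' subject's template set as reference, each subject's maps are matched to the
#' reference by the state permutation and per-map signs maximizing total
#' spatial correlation (exhaustive over K! permutations), the reference is
#' recomputed as the aligned row-wise mean (renormalized), and the loop
#' repeats until the matching stabilizes.
#'
#' @param individual list of [ms_templates], one per subject, sharing K and
#'   channel count.
#' @return The converged reference as an `ms_templates`.
#' @export
group_templates <- function(individual) {
  if (length(individual) == 0) stop("need at least one template set")
  k <- individual[[1]]$k
  C <- ncol(individual[[1]]$maps)
  for (ts in individual)
    if (ts$k != k || ncol(ts$maps) != C)
      stop("all template sets must share K and the channel count")
  if (length(individual) == 1) return(individual[[1]])

  ref <- individual[[1]]$maps
  prev_perms <- NULL
  for (iter in 1:100) {
    aligned <- vector("list", length(individual))
    perms <- matrix(0L, length(individual), k)
    for (s in seq_along(individual)) {
      al <- align_to_reference(individual[[s]]$maps, ref)
      perms[s, ] <- al$perm
      aligned[[s]] <- individual[[s]]$maps[al$perm, , drop = FALSE] * al$signs
    }
    ref <- normalize_maps(Reduce(`+`, aligned) / length(aligned))
    if (!is.null(prev_perms) && identical(perms, prev_perms)) break
    prev_perms <- perms
  }
  ms_templates(ref, labels = individual[[1]]$labels,
               channel_labels = individual[[1]]$channel_labels)
}

#' Relabel a template set against canonical maps
#'
#' Finds the state permutation maximizing total spatial correlation with a
#' canonical reference set (exhaustive over K! permutations) and reorders the
#' rows so that labels A-D carry their conventional meaning. Purely a
#' relabeling: no map is altered.
#'
#' @param ts an [ms_templates] to relabel.
#' @param canonical reference [ms_templates]; defaults to
#'   [canonical_templates()] when the channel count matches its montage.
#' @return The reordered `ms_templates` with canonical labels.
#' @export
order_canonical <- function(ts, canonical = NULL) {
  if (is.null(canonical)) canonical <- canonical_templates()
  if (ts$k != canonical$k || ncol(ts$maps) != ncol(canonical$maps))
    stop("template set and canonical set must share K and the channel count")
  al <- align_to_reference(ts$maps, canonical$maps)
  # al$perm[j] = row of ts matched to canonical row j
  ms_templates(ts$maps[al$perm, , drop = FALSE], labels = canonical$labels,
               channel_labels = ts$channel_labels)
}
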