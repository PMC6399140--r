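#' Microstate template set
#'
#' K unit-norm, zero-mean (average-referenced) topographies. Polarity is
#' meaningless: a template set is equivalent to its row-wise negation, and all
#' comparisons go through the absolute spatial correlation.
#'
#' @param maps numeric K x C matrix, one topography per row. Rows are centred
#'   and scaled to unit norm on construction.
#' @param labels state names; defaults to `A`, `B`, ... in row order.
#' @param channel_labels optional channel names (length C).
#' @return An object of class `ms_templates`.
#' @export
ms_templates <- function(maps, labels = NULL, channel_labels = NULL) {
  maps <- as.matrix(maps)
  if (!is.numeric(maps) || any(!is.finite(maps)))
    stop("template maps must be finite and numeric")
  maps <- normalize_maps(maps)
  k <- nrow(maps)
  labels <- labels %||% LETTERS[seq_len(k)]
  if (length(labels) != k) stop("one label per template required")
  if (!is.null(channel_labels) && length(channel_labels) != ncol(maps))
    stop("channel_labels length must match channel count")
  structure(list(maps = maps, labels = as.character(labels), k = k,
                 channel_labels = channel_labels),
            class = "ms_templates")
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> %d maps x %d channels (%s)\n",
              x$k, ncol(x$maps), paste(x$labels, collapse = ", ")))
  invisible(x)
}

# centre each row and scale to unit norm; zero-variance rows are an error
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm < 1e-12)) stop("zero-variance topography cannot be normalized")
  maps / nrm
}

#' Polarity-free spatial correlation between two topographies
#'
#' Absolute Pearson correlation across channels, the similarity measure of
#' all microstate operations (clustering, alignment, back-fitting).
#'
#' @param u,v numeric vectors over the same channels.
#' @return A scalar in `[0, 1]`.
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("topographies must share the channel count")
  u <- u - mean(u); v <- v - mean(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    stop("spatial correlation undefined for a zero-variance map")
  abs(sum(u * v)) / (nu * nv)
}

# Idealized 31-channel 10-20 montage (approximate head-circle coordinates).
# Used only to synthesize canonical ordering templates and for default labels.
montage_1020_31 <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1",
              "FC2", "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
              "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1",
              "O2"),
    x = c(-0.31, 0.31, -0.81, -0.43, 0, 0.43, 0.81, -0.95, -0.64, -0.22,
          0.22, 0.64, 0.95, -1, -0.5, 0, 0.5, 1, -0.95, -0.64,
          -0.22, 0.22, 0.64, 0.95, -0.81, -0.43, 0, 0.43, 0.81, -0.31,
          0.31),
    y = c(0.95, 0.95, 0.59, 0.58, 0.6, 0.58, 0.59, 0.31, 0.3, 0.28,
          0.28, 0.3, 0.31, 0, 0, 0, 0, 0, -0.31, -0.3,
          -0.28, -0.28, -0.3, -0.31, -0.59, -0.58, -0.6, -0.58, -0.59, -0.95,
          -0.95)
  )
}

#' Canonical ordering templates (synthetic)
#'
#' Synthetic stand-ins for the four literature microstate classes on the
#' packaged 31-channel 10-20 montage: A (left-posterior to right-anterior
#' gradient), B (right-posterior to left-anterior), C (occipital, symmetric),
#' D (fronto-central). They fix label names via [order_canonical()] and never
#' enter any numeric result.
#'
#' @return An `ms_templates` with labels A-D.
#' @export
canonical_templates <- function() {
  m <- montage_1020_31()
  a <- cos(pi / 4) * m$x - sin(pi / 4) * m$y    # LP (-) to RA (+) axis
  b <- -cos(pi / 4) * m$x - sin(pi / 4) * m$y   # RP to LA axis
  cc <- exp(-((m$x)^2 + (m$y + 0.8)^2) / 0.8)   # occipital blob
  d <- exp(-((m$x)^2 + (m$y - 0.2)^2) / 0.6)    # fronto-central blob
  ms_templates(rbind(a, b, cc, d), labels = c("A", "B", "C", "D"),
               channel_labels = m$label)
}
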