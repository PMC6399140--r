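#' Microstate label sequence
#'
#' The categorical stochastic process produced by back-fitting (or planted by
#' the simulator): one state per sample, `NA` where no state was assigned.
#'
#' @param labels integer vector of state indices in `1..K`, `NA` = unassigned.
#' @param sampling_rate sampling rate in Hz.
#' @param state_names names of the K states (defaults to `A`, `B`, ...).
#' @param k number of states; defaults to `length(state_names)` or, absent
#'   both, the largest observed label.
#' @return An object of class `ms_labels`.
#' @export
ms_labels <- function(labels, sampling_rate, state_names = NULL, k = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 2) stop("a label sequence needs at least 2 samples")
  k <- k %||% (if (!is.null(state_names)) length(state_names)
               else max(labels, na.rm = TRUE))
  if (any(!is.na(labels) & (labels < 1 | labels > k)))
    stop("labels must lie in 1..k (NA = unassigned)")
  state_names <- state_names %||% LETTERS[seq_len(k)]
  if (length(state_names) != k) stop("state_names must have length k")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  structure(list(labels = labels, sampling_rate = sampling_rate,
                 state_names = as.character(state_names), k = as.integer(k)),
            class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d samples @ %g Hz, %d states (%s), %d unassigned\n",
              length(x$labels), x$sampling_rate, x$k,
              paste(x$state_names, collapse = ","), sum(is.na(x$labels))))
  invisible(x)
}
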