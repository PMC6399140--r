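# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

check_transition_matrix <- function(T, zero_diag = FALSE, tol = 1e-12) {
  if (!is.matrix(T) || nrow(T) != ncol(T) || !is.numeric(T))
    stop("transition matrix must be a square numeric matrix")
  if (any(!is.finite(T)) || any(T < -tol))
    stop("transition matrix entries must be finite and non-negative")
  rs <- rowSums(T)
  if (any(abs(rs - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  if (zero_diag && any(abs(diag(T)) > tol))
    stop("jump matrix must have a zero diagonal")
  invisible(T)
}

# x * log(x/y) with the 0 * log 0 -> 0 convention; used by all G statistics
xlogratio <- function(n, num, den) {
  keep <- n > 0
  sum(n[keep] * log(num[keep] / den[keep]))
}

# all permutations of 1..k (k small; used for template alignment, k = 4 -> 24)
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
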