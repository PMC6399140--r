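#' Simulation configuration
#'
#' Conditions of the synthetic resting-state recordings used as the pipeline's
#' test bed: a 31-channel 10-20 montage sampled at 250 Hz for 8 minutes, four
#' planted states driven by a semi-Markov sequence (zero-diagonal jump matrix,
#' configurable dwell-time distribution), an alpha-band amplitude carrier
#' creating GFP peaks, and additive Gaussian noise at a configurable SNR.
#'
#' @param n_channels electrode count.
#' @param n_states number of planted microstate classes K.
#' @param sampling_rate Hz.
#' @param duration seconds; `duration * sampling_rate` must be integral.
#' @param transition_matrix K x K jump probabilities (zero diagonal, rows sum
#'   to 1). Default: uniform over the other states.
#' @param dwell_mean mean state dwell time in ms.
#' @param dwell_dist `"geometric"` (memoryless; sample-level first-order
#'   Markov) or `"gamma"` (shape 2; non-Markovian dwell).
#' @param carrier_freq amplitude-modulation frequency in Hz; GFP maxima occur
#'   at twice this rate (rectified sinusoid).
#' @param snr signal-RMS over noise-RMS ratio.
#' @param seed RNG seed.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_channels = 31, n_states = 4,
                              sampling_rate = 250, duration = 480,
                              transition_matrix = NULL, dwell_mean = 80,
                              dwell_dist = c("geometric", "gamma"),
                              carrier_freq = 10, snr = 4, seed = 1) {
  dwell_dist <- match.arg(dwell_dist)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (n_states - 1), n_states, n_states)
    diag(transition_matrix) <- 0
    if (n_states == 1) transition_matrix <- matrix(1, 1, 1)
  }
  if (n_states > 1) check_transition_matrix(transition_matrix, zero_diag = TRUE)
  if (dwell_mean <= 0) stop("dwell_mean must be positive (ms)")
  if (snr <= 0) stop("snr must be positive")
  n <- duration * sampling_rate
  if (abs(n - round(n)) > 1e-9)
    stop("duration * sampling_rate must be an integer sample count")
  structure(list(n_channels = n_channels, n_states = n_states,
                 sampling_rate = sampling_rate, duration = duration,
                 transition_matrix = transition_matrix,
                 dwell_mean = dwell_mean, dwell_dist = dwell_dist,
                 carrier_freq = carrier_freq, snr = snr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted microstate topographies
#'
#' Draws K random zero-mean, unit-norm maps with every pairwise absolute
#' spatial correlation below 0.5 (maps violating the bound are redrawn), the
#' planted analogues of the four canonical classes. Deterministic given seed.
#'
#' @param n_channels electrode count C (must exceed `n_states`).
#' @param n_states number of maps K.
#' @param seed RNG seed.
#' @return An [ms_templates] with K rows.
#' @export
make_templates <- function(n_channels = 31, n_states = 4, seed = 1) {
  if (n_states < 2) stop("need at least 2 states")
  if (n_states >= n_channels) stop("need more channels than states")
  with_seed(seed, {
    maps <- matrix(NA_real_, n_states, n_channels)
    for (i in seq_len(n_states)) {
      for (try in 1:1000) {
        m <- stats::rnorm(n_channels)
        m <- m - mean(m)
        m <- m / sqrt(sum(m^2))
        ok <- i == 1 ||
          all(abs(maps[seq_len(i - 1), , drop = FALSE] %*% m) < 0.5)
        if (ok) { maps[i, ] <- m; break }
      }
      if (anyNA(maps[i, ])) stop("failed to draw sufficiently distinct maps")
    }
    ms_templates(maps)
  })
}

# dwell duration draws in samples (>= 1), mean dwell_mean ms
draw_dwells <- function(n, dwell_mean, dwell_dist, sampling_rate) {
  m <- dwell_mean * sampling_rate / 1000   # mean dwell in samples
  if (dwell_dist == "geometric") {
    if (m <= 1) rep(1L, n) else stats::rgeom(n, prob = 1 / m) + 1L
  } else {
    pmax(1L, as.integer(round(stats::rgamma(n, shape = 2, scale = m / 2))))
  }
}

#' Sample a planted semi-Markov state sequence
#'
#' Successive distinct states follow the configured jump matrix; dwell
#' durations are i.i.d. draws from the configured dwell distribution.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return An [ms_labels] of length `duration * sampling_rate`.
#' @export
sample_state_sequence <- function(config, seed = config$seed) {
  n <- round(config$duration * config$sampling_rate)
  K <- config$n_states
  if (K == 1)
    return(ms_labels(rep(1L, n), config$sampling_rate, state_names = "A"))
  with_seed(seed, {
    m <- config$dwell_mean * config$sampling_rate / 1000
    n_seg <- max(16L, ceiling(1.5 * n / max(m, 1)) + 16L)
    repeat {
      states <- integer(n_seg)
      cum <- t(apply(config$transition_matrix, 1, cumsum))
      states[1] <- sample.int(K, 1)
      u <- stats::runif(n_seg)
      for (s in 2:n_seg)
        states[s] <- sum(u[s] > cum[states[s - 1], ]) + 1L
      dw <- draw_dwells(n_seg, config$dwell_mean, config$dwell_dist,
                        config$sampling_rate)
      if (sum(dw) >= n) break
      n_seg <- n_seg * 2L
    }
    labels <- rep(states, dw)[seq_len(n)]
    ms_labels(labels, config$sampling_rate, k = K)
  })
}

#' Sample a plain Markov (or i.i.d.) sequence
#'
#' Test harness for the sequence statistics: order 1 draws a first-order chain
#' with transition matrix `T` (diagonal allowed, start at the stationary
#' distribution); order 0 draws i.i.d. from the stationary distribution of `T`.
#'
#' @param T row-stochastic K x K matrix.
#' @param n sequence length in samples.
#' @param seed RNG seed.
#' @param order 0 (i.i.d.) or 1 (first-order chain).
#' @param sampling_rate carried on the returned labels (default 250).
#' @return An [ms_labels].
#' @export
sample_markov_sequence <- function(T, n, seed = 1, order = 1,
                                   sampling_rate = 250) {
  check_transition_matrix(T)
  if (!order %in% c(0, 1)) stop("order must be 0 or 1")
  K <- nrow(T)
  pi0 <- stationary_distribution(T)
  with_seed(seed, {
    if (order == 0) {
      labels <- sample.int(K, n, replace = TRUE, prob = pi0)
    } else {
      cum <- t(apply(T, 1, cumsum))
      labels <- integer(n)
      labels[1] <- sample.int(K, 1, prob = pi0)
      u <- stats::runif(n)
      for (t in 2:n) labels[t] <- sum(u[t] > cum[labels[t - 1], ]) + 1L
    }
    ms_labels(labels, sampling_rate, k = K)
  })
}

#' Render multichannel EEG from a planted label sequence
#'
#' Forward model `v(t) = a(t) * template[x(t)] + noise(t)` with a sinusoidal
#' carrier `a(t) = sin(2 pi f t)` scaled to unit RMS magnitude, and zero-mean
#' Gaussian channel noise scaled so that signal-RMS / noise-RMS equals `snr`.
#' The carrier magnitude `|a(t)|` is a rectified sinusoid, so GFP maxima occur
#' twice per carrier cycle (the empirical peak rate tied to the alpha rhythm);
#' the carrier's sign is irrelevant downstream because every microstate
#' operation is polarity-free, and keeping the oscillation at `carrier_freq`
#' leaves the signal inside the 2-20 Hz analysis band. Noiseless samples are
#' average-reference consistent because templates are zero-mean.
#'
#' @param labels an [ms_labels] with K states.
#' @param templates an [ms_templates] with the same K.
#' @param config a [simulation_config()]; `snr = Inf` disables noise.
#' @param seed RNG seed for the noise; defaults to `config$seed`.
#' @param subject_id carried on the recording.
#' @return An [eeg_recording] (channels x samples).
#' @export
render_eeg <- function(labels, templates, config, seed = config$seed,
                       subject_id = "sim") {
  if (templates$k < labels$k)
    stop("templates and labels disagree on the number of states")
  n <- length(labels$labels)
  fs <- config$sampling_rate
  t_sec <- (seq_len(n) - 1) / fs
  a <- sin(2 * pi * config$carrier_freq * t_sec)
  a <- a / sqrt(mean(a^2))
  V <- t(templates$maps)[, labels$labels, drop = FALSE] *
    rep(a, each = ncol(templates$maps))
  if (is.finite(config$snr)) {
    sig_rms <- sqrt(mean(V^2))
    sigma <- sig_rms / config$snr
    V <- V + with_seed(seed, matrix(stats::rnorm(length(V), sd = sigma),
                                    nrow(V), ncol(V)))
  }
  eeg_recording(V, fs, subject_id = subject_id)
}

#' Simulate one subject
#'
#' Convenience wrapper: planted templates + semi-Markov labels + rendered EEG.
#'
#' @param config a [simulation_config()].
#' @param templates optional shared [ms_templates]; drawn from `config$seed`
#'   when omitted.
#' @param subject_id identifier.
#' @return List with `recording` ([eeg_recording]) and `truth` (list of
#'   `templates`, `labels`, `jump_matrix`, `config`).
#' @export
simulate_recording <- function(config = simulation_config(),
                               templates = NULL, subject_id = "sim") {
  templates <- templates %||%
    make_templates(config$n_channels, config$n_states, seed = config$seed)
  labels <- sample_state_sequence(config)
  rec <- render_eeg(labels, templates, config, subject_id = subject_id)
  list(recording = rec,
       truth = list(templates = templates, labels = labels,
                    jump_matrix = config$transition_matrix, config = config))
}

#' Generate two synthetic cohorts
#'
#' Group 1 follows the base jump matrix; group 2 follows base + `effect`
#' (entrywise deltas), renormalized per row. Per-subject seeds are derived
#' deterministically from the master seed, so cohorts are reproducible.
#'
#' @param n_per_group integer vector of length 2 (or a scalar used for both).
#' @param base_config a [simulation_config()].
#' @param effect K x K matrix of probability deltas added to group 2's jump
#'   matrix (diagonal must stay zero; perturbed entries must stay in `[0,1]`).
#' @param seed master RNG seed.
#' @param templates shared planted topographies; drawn from `seed` if omitted.
#' @param render if `FALSE`, skip EEG rendering and return label sequences
#'   only (fast path for sequence-level studies).
#' @return List with elements `group1` and `group2`, each a list of subjects
#'   (`recording` is `NULL` when `render = FALSE`; `truth` always present).
#' @export
generate_cohorts <- function(n_per_group, base_config = simulation_config(),
                             effect = NULL, seed = 1, templates = NULL,
                             render = TRUE) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  K <- base_config$n_states
  effect <- effect %||% matrix(0, K, K)
  T2 <- base_config$transition_matrix + effect
  if (any(T2 < -1e-12 | T2 > 1 + 1e-12))
    stop("effect drives a jump probability outside [0, 1]")
  if (any(abs(diag(T2)) > 1e-12))
    stop("effect must leave the jump-matrix diagonal at zero")
  T2 <- T2 / rowSums(T2)
  templates <- templates %||%
    make_templates(base_config$n_channels, K, seed = seed)
  total <- sum(n_per_group)
  subj_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, total))
  make_group <- function(cfg_T, idx, tag) {
    lapply(seq_along(idx), function(i) {
      cfg <- base_config
      cfg$transition_matrix <- cfg_T
      cfg$seed <- subj_seeds[idx[i]]
      id <- sprintf("%s%03d", tag, i)
      labels <- sample_state_sequence(cfg)
      rec <- if (render) render_eeg(labels, templates, cfg, subject_id = id)
      list(recording = rec,
           truth = list(templates = templates, labels = labels,
                        jump_matrix = cfg_T, config = cfg, subject_id = id))
    })
  }
  list(group1 = make_group(base_config$transition_matrix,
                           seq_len(n_per_group[1]), "g1_"),
       group2 = make_group(T2, n_per_group[1] + seq_len(n_per_group[2]),
                           "g2_"))
}
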