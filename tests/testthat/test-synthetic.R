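test_that("planted templates are deterministic, normalized and distinct", {
  a <- make_templates(31, 4, seed = 1)
  b <- make_templates(31, 4, seed = 1)
  expect_identical(a$maps, b$maps)
  expect_equal(rowMeans(a$maps), rep(0, 4), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(a$maps^2)), rep(1, 4), tolerance = 1e-12)
  # brute-force pairwise correlations under the 0.5 bound
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(spatial_correlation(a$maps[i, ], a$maps[j, ]), 0.5)
  expect_error(make_templates(4, 4), "more channels")
  expect_error(make_templates(31, 1), "at least 2")
})

test_that("semi-Markov sequences follow the jump matrix and dwell law", {
  # deterministic cycle A->B->C->D->A
  Tc <- matrix(0, 4, 4)
  Tc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cfg <- simulation_config(duration = 20, transition_matrix = Tc,
                           dwell_mean = 40, seed = 3)
  sq <- sample_state_sequence(cfg)
  sg <- segments(sq)
  jumps <- cbind(sg$state[-nrow(sg)], sg$state[-1])
  expect_true(all(Tc[jumps] == 1))

  # empirical mean dwell within its Monte-Carlo interval (interior segments)
  cfg <- simulation_config(duration = 480, dwell_mean = 80, seed = 7)
  sg <- segments(sample_state_sequence(cfg))
  d <- sg$length[-c(1, nrow(sg))] * 1000 / 250
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 80), 2.6 * se + 1)  # +1 ms discretization slack

  # segment-jump frequencies converge to the jump matrix
  cfg <- simulation_config(duration = 480, dwell_mean = 20, seed = 11)
  sq <- sample_state_sequence(cfg)
  tm <- transition_matrix(sq, mode = "segment")
  expect_lt(max(abs(tm$probs - cfg$transition_matrix)), 0.02)
})

test_that("plain Markov sampler honours order and transition structure", {
  expect_error(sample_markov_sequence(matrix(c(.5, .2, .6, .8), 2), 10),
               "sum to 1")
  Tid <- diag(4)
  sq <- sample_markov_sequence(Tid, 500, seed = 2)
  expect_equal(length(unique(sq$labels)), 1L)

  sq0 <- sample_markov_sequence(matrix(0.25, 4, 4), 10000, seed = 5, order = 0)
  freq <- tabulate(sq0$labels, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 10000)))

  T2 <- matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE)
  sq1 <- sample_markov_sequence(T2, 100000, seed = 6)
  emp <- transition_matrix(sq1, "per_sample")$probs
  expect_lt(max(abs(emp - T2)), 0.01)
})

test_that("rendered EEG is identifiable and calibrated to the requested SNR", {
  tp <- make_templates(31, 4, seed = 2)
  cfg <- simulation_config(duration = 10, snr = Inf, seed = 4)
  lab <- sample_state_sequence(cfg)
  rec <- render_eeg(lab, tp, cfg)
  expect_equal(colMeans(rec$data), rep(0, ncol(rec$data)), tolerance = 1e-10)
  amp <- abs(sin(2 * pi * 10 * (seq_len(2500) - 1) / 250))
  bf <- backfit(rec, tp)
  nz <- amp > 1e-6
  expect_true(all(bf$labels[nz] == lab$labels[nz]))

  # constant labels, no noise: every non-zero sample proportional to one map
  labc <- ms_labels(rep(2L, 2500), 250, k = 4)
  recc <- render_eeg(labc, tp, cfg)
  corr <- apply(recc$data[, amp > 0.1], 2, spatial_correlation, tp$maps[2, ])
  expect_equal(corr, rep(1, length(corr)), tolerance = 1e-9)

  # measured SNR within 1% of the configured ratio
  cfgN <- simulation_config(duration = 60, snr = 4, seed = 5)
  labN <- sample_state_sequence(cfgN)
  clean <- render_eeg(labN, tp, simulation_config(duration = 60, snr = Inf,
                                                  seed = 5))
  noisy <- render_eeg(labN, tp, cfgN)
  noise <- noisy$data - clean$data
  snr_hat <- sqrt(mean(clean$data^2)) / sqrt(mean(noise^2))
  expect_lt(abs(snr_hat / 4 - 1), 0.01)
})

test_that("GFP maxima track the carrier amplitude maxima", {
  tp <- make_templates(31, 4, seed = 2)
  cfg <- simulation_config(duration = 60, snr = 4, seed = 11)
  sim <- simulate_recording(cfg, templates = tp)
  g <- smooth_gfp(compute_gfp(bandpass_filter(average_reference(sim$recording))))
  pk <- find_gfp_peaks(g)
  amp <- abs(sin(2 * pi * 10 * (seq_len(15000) - 1) / 250))
  cmax <- which(diff(sign(diff(amp))) < 0) + 1
  hit <- vapply(pk, function(p) min(abs(p - cmax)) <= 1, logical(1))
  expect_gte(mean(hit), 0.95)
  expect_lt(abs(length(pk) - 2 * 10 * 60) / (2 * 10 * 60), 0.1)
})

test_that("cohort generation applies the planted effect deterministically", {
  eff <- matrix(0, 4, 4); eff[2, 4] <- -0.1
  co <- generate_cohorts(c(52, 61), simulation_config(duration = 60, seed = 1),
                         effect = eff, seed = 9, render = FALSE)
  expect_length(co$group1, 52)
  expect_length(co$group2, 61)
  T1 <- co$group1[[1]]$truth$jump_matrix
  T2 <- co$group2[[1]]$truth$jump_matrix
  expect_equal(rowSums(T2), rep(1, 4))
  expect_lt(T2[2, 4], T1[2, 4])
  # null effect: both groups share the base process
  co0 <- generate_cohorts(c(2, 2), simulation_config(duration = 10, seed = 1),
                          seed = 9, render = FALSE)
  expect_identical(co0$group1[[1]]$truth$jump_matrix,
                   co0$group2[[1]]$truth$jump_matrix)
  # reproducibility under the master seed
  co2 <- generate_cohorts(c(2, 2), simulation_config(duration = 10, seed = 1),
                          seed = 9, render = FALSE)
  expect_identical(co0$group1[[2]]$truth$labels$labels,
                   co2$group1[[2]]$truth$labels$labels)
  expect_error(generate_cohorts(2, simulation_config(), effect = eff * 20,
                                seed = 1), "outside")
})
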