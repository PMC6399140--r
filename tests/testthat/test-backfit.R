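test_that("back-fitting recovers exact template samples and honours min_corr", {
  tp <- make_templates(16, 4, seed = 1)
  planted <- c(1, 3, 2, 4, 4, 1)
  scale <- c(2, -1, 0.5, 3, -2, 1)
  rec <- eeg_recording(t(tp$maps[planted, ] * scale), 250)
  bf <- backfit(rec, tp)
  expect_equal(bf$labels, as.integer(planted))
  noisy <- eeg_recording(rec$data + matrix(rnorm(96, sd = 0.2), 16, 6), 250)
  expect_true(all(is.na(backfit(noisy, tp, min_corr = 1)$labels)))
  expect_error(backfit(eeg_recording(matrix(rnorm(20), 4, 5), 250), tp),
               "channel")
})

test_that("segments round-trip the label sequence", {
  sq <- ms_labels(c(1L, 1L, 2L), 250, k = 2)
  sg <- segments(sq)
  expect_equal(sg$state, c(1L, 2L))
  expect_equal(sg$start, c(1L, 3L))
  expect_equal(sg$length, c(2L, 1L))
  expect_equal(nrow(segments(ms_labels(rep(2L, 10), 250, k = 3))), 1L)
  set.seed(4)
  lab <- sample(c(1:3, NA), 20, replace = TRUE)
  lab[1] <- 1L
  sq <- ms_labels(lab, 100, k = 3)
  sg <- segments(sq)
  expect_equal(rep(sg$state, sg$length), lab)
  expect_equal(sum(sg$length), 20L)
})

test_that("durations and occurrence use interior segments only", {
  sq <- ms_labels(c(3, 1, 1, 2, 2, 2, 3), 250, state_names = c("A", "B", "C"))
  d <- mean_durations(sq)
  expect_equal(unname(d[c("A", "B")]), c(8, 12))
  expect_true(is.na(d["C"]))            # only boundary occurrences
  # constant interior dwell of 25 samples at 250 Hz -> 100 ms
  lab <- c(2L, rep(rep(c(1L, 2L), 10), each = 25)[1:500], 2L)
  lab[length(lab)] <- 3L
  sq <- ms_labels(lab, 250, k = 3)
  expect_equal(unname(mean_durations(sq)["A"]), 100)
  # 4 B-segments in exactly 2 s of interior -> 2 per second
  lab <- c(3L, rep(rep(c(2L, 1L), 4), times = rep(c(50L, 75L), 4)), 3L)
  sq <- ms_labels(lab, 250, k = 3)
  expect_equal(unname(occurrence_rates(sq)["B"]), 2)
  expect_equal(unname(occurrence_rates(sq)["C"]), 0)
})

test_that("planted cycle with fixed dwell gives the closed-form rate", {
  Tc <- matrix(0, 4, 4); Tc[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cfg <- simulation_config(duration = 240, transition_matrix = Tc,
                           dwell_mean = 62.5, seed = 5)
  sq <- sample_state_sequence(cfg)
  rate <- occurrence_rates(sq)
  expect_equal(unname(rate), rep(1 / (4 * 0.0625), 4), tolerance = 0.1)
})

test_that("coverage conserves the assigned sample count", {
  set.seed(9)
  lab <- sample(c(1:4, NA), 500, replace = TRUE, prob = c(rep(0.22, 4), 0.12))
  sq <- ms_labels(lab, 250, k = 4)
  cv <- coverage(sq)
  expect_equal(sum(cv), 1)
  expect_equal(unname(cv * sum(!is.na(lab))),
               as.numeric(table(factor(lab, levels = 1:4))))
})

test_that("transition matrices match hand counts in both modes", {
  sq <- ms_labels(c(1L, 1L, 2L), 250, k = 2)
  expect_equal(transition_matrix(sq, "per_sample")$probs[1, ], c(A = 0.5, B = 0.5))
  sq2 <- ms_labels(c(1L, 1L, 2L, 2L, 3L, 1L), 250, k = 3)
  tm <- transition_matrix(sq2, "segment")
  expect_equal(unname(tm$probs[1, ]), c(0, 1, 0))
  expect_equal(unname(tm$probs[2, ]), c(0, 0, 1))
  expect_equal(unname(tm$probs[3, ]), c(1, 0, 0))
  expect_true(all(diag(tm$probs) == 0))
  const <- ms_labels(rep(2L, 10), 250, k = 3)
  tmc <- transition_matrix(const, "per_sample")
  expect_equal(unname(tmc$probs[2, ]), c(0, 1, 0))
  expect_equal(tmc$empty_rows, c(1L, 3L))
  # rows with positive counts are stochastic; NA breaks pairs
  lab <- c(1L, 2L, NA, 3L, 1L, 1L)
  tmn <- transition_matrix(ms_labels(lab, 250, k = 3), "per_sample")
  expect_equal(sum(tmn$counts), 3)
  rs <- rowSums(tmn$probs)
  expect_true(all(abs(rs[rowSums(tmn$counts) > 0] - 1) < 1e-12))
})

test_that("per-sample diagonal reflects the geometric dwell hazard", {
  cfg <- simulation_config(duration = 480, dwell_mean = 80, seed = 13)
  sq <- sample_state_sequence(cfg)
  tm <- transition_matrix(sq, "per_sample")
  expect_lt(max(abs(diag(tm$probs) - (1 - 1 / 20))), 0.02)
})

test_that("noisy back-fit recovers planted labels at high-amplitude samples", {
  tp <- make_templates(31, 4, seed = 2)
  accs <- vapply(1:5, function(s) {
    cfg <- simulation_config(duration = 40, snr = 4, seed = 100 + s)
    lab <- sample_state_sequence(cfg)
    rec <- render_eeg(lab, tp, cfg)
    bf <- backfit(bandpass_filter(average_reference(rec)), tp)
    amp <- abs(sin(2 * pi * 10 * (seq_along(lab$labels) - 1) / 250))
    mean(bf$labels[amp > 0.3] == lab$labels[amp > 0.3])
  }, numeric(1))
  expect_gte(mean(accs), 0.8)
})

test_that("majority smoothing heals isolated misassignments only", {
  lab <- rep(c(1L, 2L), each = 20)
  lab[c(5, 25)] <- 3L                     # isolated one-sample errors
  sm <- smooth_labels(ms_labels(lab, 250, k = 3), window_ms = 16)
  expect_equal(sm$labels, rep(c(1L, 2L), each = 20))
  # a genuine segment longer than the window survives
  lab2 <- c(rep(1L, 20), rep(2L, 8), rep(1L, 20))
  sm2 <- smooth_labels(ms_labels(lab2, 250, k = 2), window_ms = 16)
  expect_true(any(sm2$labels == 2L))
})

test_that("peak-interpolated back-fit propagates peak labels between peaks", {
  tp <- make_templates(8, 2, seed = 3)
  # samples: template 1 at peaks 3 and 11, template 2 at peak 7; junk between
  planted <- c(1L, 1L, 2L)
  V <- matrix(rnorm(8 * 14, sd = 0.01), 8, 14)
  V[, c(3, 7, 11)] <- t(tp$maps[c(1, 2, 1), ] * 5)
  rec <- eeg_recording(V, 250)
  bf <- backfit(rec, tp, peaks = c(3, 7, 11))
  expect_equal(bf$labels[1:5], rep(1L, 5))
  expect_equal(bf$labels[6:9], rep(2L, 4))
  expect_equal(bf$labels[10:14], rep(1L, 5))
})

test_that("smoothed back-fit recovers the planted mean dwell at snr 8", {
  tp <- make_templates(31, 4, seed = 2)
  devs <- vapply(1:8, function(s) {
    cfg <- simulation_config(duration = 120, snr = 8, dwell_dist = "gamma",
                             seed = 500 + s)
    lab <- sample_state_sequence(cfg)
    rec <- bandpass_filter(average_reference(render_eeg(lab, tp, cfg)))
    bf <- smooth_labels(backfit(rec, tp), window_ms = 16)
    mean(mean_durations(bf)) - mean(mean_durations(lab))
  }, numeric(1))
  expect_lt(max(abs(devs)), 10)
})
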