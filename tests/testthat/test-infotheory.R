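test_that("G statistics vanish exactly when the null factorization holds", {
  # pair counts factorize exactly for the closed repeating block AABB + A
  sq <- ms_labels(c(rep(c(1L, 1L, 2L, 2L), 100), 1L), 250, k = 2)
  r0 <- markov_order0_test(sq)
  expect_lt(r0$g_statistic, 1e-8)
  expect_equal(r0$df, 1L)
  # deterministic cycle is perfectly first- and second-order predictable
  cyc <- ms_labels(rep(1:4, 100), 250)
  expect_lt(markov_order1_test(cyc)$g_statistic, 1e-10)
  expect_lt(markov_order2_test(cyc)$g_statistic, 1e-10)
  expect_equal(markov_order1_test(cyc)$df, 4 * 9)
  expect_equal(markov_order2_test(cyc)$df, 16 * 9)
  # pairwise-balanced sequence is exactly symmetric
  sym <- ms_labels(c(rep(c(1L, 2L, 1L, 3L, 2L, 3L), 50), 1L), 250, k = 3)
  rs <- symmetry_test(sym)
  expect_lt(rs$g_statistic, 1e-8)
  expect_gt(rs$p_value, 0.999)
  expect_error(markov_order0_test(ms_labels(rep(1L, 50), 250, k = 4)),
               "2 observed states")
})

test_that("sequence tests reject their alternatives with high power", {
  # gamma (non-geometric) dwell: non-Markovian at every low order
  cfg <- simulation_config(duration = 480, dwell_mean = 80,
                           dwell_dist = "gamma", seed = 2)
  sq <- sample_state_sequence(cfg)
  expect_true(markov_order0_test(sq)$significant)
  expect_true(markov_order1_test(sq)$significant)
  expect_true(markov_order2_test(sq)$significant)
  # strongly cyclic chain violates symmetry
  Tc <- matrix(0.04, 4, 4); diag(Tc) <- 0
  Tc[cbind(1:4, c(2, 3, 4, 1))] <- 0.88
  Tc <- Tc / rowSums(Tc)
  sqc <- sample_markov_sequence(Tc, 10000, seed = 3)
  expect_true(symmetry_test(sqc)$significant)
  # geometric dwell is sample-level first-order Markov: order-1 not rejected
  cfg_g <- simulation_config(duration = 480, dwell_mean = 80, seed = 4)
  expect_false(markov_order1_test(sample_state_sequence(cfg_g),
                                  alpha = 0.01)$significant)
})

test_that("stationarity test separates homogeneous from switching chains", {
  T1 <- matrix(0.7 / 3, 4, 4); diag(T1) <- 0.3
  T2 <- matrix(0.1, 4, 4); diag(T2) <- 0.7
  hom <- sample_markov_sequence(T1, 20000, seed = 5)
  expect_false(stationarity_test(hom, 10, alpha = 0.01)$significant)
  half1 <- sample_markov_sequence(T1, 10000, seed = 6)
  half2 <- sample_markov_sequence(T2, 10000, seed = 7)
  mixed <- ms_labels(c(half1$labels, half2$labels), 250, k = 4)
  expect_true(stationarity_test(mixed, 20, alpha = 0.01)$significant)
  expect_error(stationarity_test(hom, 200), "2 blocks")
  prof <- stationarity_profile(list(hom, mixed), block_grid = c(10, 20))
  expect_equal(dim(prof), c(2L, 2L))
  expect_true(all(prof$ratio_significant >= 0 & prof$ratio_significant <= 1))
})

test_that("AIF matches closed-form values and marginal identities", {
  # uniform 4-state marginal -> I(0) = 2 bits exactly
  sq <- ms_labels(rep(1:4, 250), 250)
  a <- aif(sq, max_lag_ms = 40)
  expect_equal(a$mi_bits[a$lag == 0], 2)
  # strict alternation: 1 bit at every lag
  alt <- ms_labels(rep(c(1L, 2L), 500), 250, k = 2)
  aa <- aif(alt, max_lag_ms = 60)
  expect_equal(aa$mi_bits, rep(1, nrow(aa)), tolerance = 1e-5)
  # plug-in estimate converges to the analytic Markov-chain AIF
  T2 <- matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE)
  sqm <- sample_markov_sequence(T2, 100000, seed = 3)
  am <- aif(sqm, max_lag_ms = 20 * 1000 / 250)
  cf <- vapply(0:20, function(l) markov_aif_closed_form(T2, l), numeric(1))
  expect_lt(max(abs(am$mi_bits - cf)), 0.01)
  expect_equal(markov_aif_closed_form(T2, 1), 0.531, tolerance = 1e-3)
  expect_equal(markov_aif_closed_form(T2, 0), 1, tolerance = 1e-12)
  expect_equal(markov_aif_closed_form(matrix(0.25, 4, 4), 3), 0,
               tolerance = 1e-12)
})

test_that("AIF is invariant under state relabeling and warns on truncation", {
  set.seed(8)
  lab <- sample.int(3, 3000, replace = TRUE, prob = c(.5, .3, .2))
  a1 <- aif(ms_labels(lab, 250, k = 3), max_lag_ms = 40)
  relab <- c(3L, 1L, 2L)[lab]
  a2 <- aif(ms_labels(relab, 250, k = 3), max_lag_ms = 40)
  expect_equal(a1$mi_bits, a2$mi_bits, tolerance = 1e-12)
  short <- ms_labels(rep(1:2, 10), 250, k = 2)
  expect_warning(aif(short, max_lag_ms = 4000), "truncated")
})

test_that("per-state AIF reduces to the indicator-sequence information", {
  alt <- ms_labels(rep(c(1L, 2L), 500), 250, k = 2)
  pa <- partial_aif(alt, 1, max_lag_ms = 40)
  expect_equal(pa$mi_bits, rep(1, nrow(pa)), tolerance = 1e-5)
  # I(0) equals the binary entropy of the state's coverage
  set.seed(2)
  lab <- sample.int(4, 5000, replace = TRUE, prob = c(.4, .3, .2, .1))
  sq <- ms_labels(lab, 250, k = 4)
  for (s in 1:4) {
    p <- mean(lab == s)
    h <- -p * log2(p) - (1 - p) * log2(1 - p)
    expect_equal(partial_aif(sq, s, max_lag_ms = 8)$mi_bits[1], h,
                 tolerance = 1e-12)
  }
  # i.i.d. sequence: lagged information within the plug-in bias bound
  expect_lt(max(partial_aif(sq, 1, max_lag_ms = 40)$mi_bits[-1]),
            20 / (2 * 5000 * log(2)))
  expect_error(partial_aif(sq, 9), "unknown state")
})

test_that("time reversal preserves the symmetry test exactly", {
  set.seed(11)
  Tc <- matrix(0.04, 4, 4); diag(Tc) <- 0
  Tc[cbind(1:4, c(2, 3, 4, 1))] <- 0.88
  Tc <- Tc / rowSums(Tc)
  sq <- sample_markov_sequence(Tc, 5000, seed = 12)
  rev_sq <- ms_labels(rev(sq$labels), 250, k = 4)
  expect_equal(symmetry_test(rev_sq)$g_statistic,
               symmetry_test(sq)$g_statistic, tolerance = 1e-10)
})

test_that("cohort summary counts significant subjects", {
  mk <- function(sig) structure(list(significant = sig), class = "markov_test")
  expect_equal(cohort_summary(lapply(c(TRUE, FALSE, TRUE, TRUE), mk)), 0.75)
  expect_equal(cohort_summary(lapply(rep(FALSE, 5), mk)), 0)
  expect_error(cohort_summary(list()), "empty")
})
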