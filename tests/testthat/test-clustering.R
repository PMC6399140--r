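test_that("spatial correlation is polarity-free and matches hand arithmetic", {
  u <- c(1, -1, 0); v <- c(1, 0, -1)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), 1)
  expect_equal(spatial_correlation(u, v), 0.5)
  expect_error(spatial_correlation(u, c(0, 0, 0)), "zero-variance")
  expect_error(spatial_correlation(u, c(1, 2)), "channel count")
})

test_that("AAHC recovers planted maps exactly in the noiseless case", {
  tp <- make_templates(31, 4, seed = 1)
  maps <- tp$maps[rep(1:4, each = 25), ]
  sol <- aahc(maps, rep(1, 100), k = 4)
  expect_equal(sol$templates$k, 4L)
  expect_equal(recovery_corrs(sol$templates, tp), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(sol$gev, 1, tolerance = 1e-9)
  expect_error(aahc(maps[1:4, ], rep(1, 4), k = 4), "more maps")
})

test_that("AAHC attains the exhaustive-partition optimum on separable input", {
  tp <- make_templates(12, 2, seed = 9)
  maps <- noisy_peak_maps(tp, copies = 4, noise_sd = 0.15, seed = 5)
  set.seed(5)
  gfp <- runif(8, 0.5, 1.5)
  sol <- aahc(maps, gfp, k = 2)
  best <- best_two_partition_gev(maps, gfp)
  expect_gte(sol$gev, best - 1e-9)
})

test_that("AAHC and GEV are invariant to input polarity flips", {
  tp <- make_templates(16, 3, seed = 4)
  maps <- noisy_peak_maps(tp, copies = 6, noise_sd = 0.1, seed = 7)
  set.seed(7)
  gfp <- runif(18, 0.5, 2)
  sol <- aahc(maps, gfp, k = 3)
  flip <- rep(c(1, -1), length.out = 18)
  sol_f <- aahc(maps * flip, gfp, k = 3)
  expect_equal(sol_f$gev, sol$gev, tolerance = 1e-9)
  for (j in 1:3)
    expect_equal(max(vapply(1:3, function(i)
      spatial_correlation(sol_f$templates$maps[i, ], sol$templates$maps[j, ]),
      numeric(1))), 1, tolerance = 1e-9)
})

test_that("GEV matches its defining formula on constructed cases", {
  tp <- make_templates(10, 2, seed = 2)
  # perfect fit up to scale and sign
  maps <- rbind(3 * tp$maps[1, ], -2 * tp$maps[2, ], tp$maps[1, ])
  expect_equal(gev(maps, c(1, 2, 3), tp, c(1, 2, 1)), 1, tolerance = 1e-12)
  # orthogonal maps explain nothing (project out the full template span)
  set.seed(6)
  ortho <- matrix(rnorm(30), 3, 10)
  ortho <- ortho - rowMeans(ortho)
  M <- tp$maps
  proj <- t(M) %*% solve(M %*% t(M)) %*% M
  ortho <- ortho - ortho %*% proj
  expect_equal(gev(ortho, c(1, 1, 1), tp, c(1, 2, 1)), 0, tolerance = 1e-12)
  # correlations {1, 0.5, 0} with equal GFP -> (1 + 0.25 + 0) / 3
  a <- tp$maps[1, ]
  b <- ortho[1, ] / sqrt(sum(ortho[1, ]^2))
  mid <- a * 0.5 + b * sqrt(0.75)          # corr 0.5 with a
  expect_equal(gev(rbind(a, mid, b), c(1, 1, 1), tp, c(1, 1, 1)),
               (1 + 0.25 + 0) / 3, tolerance = 1e-9)
})

test_that("group templates align subjects over permutations and signs", {
  tp <- make_templates(31, 4, seed = 3)
  # subjects identical up to row order and sign
  subs <- lapply(1:5, function(s) {
    p <- sample(4)
    ms_templates(tp$maps[p, ] * c(1, -1, 1, -1))
  })
  set.seed(10)
  gt <- group_templates(subs)
  expect_equal(recovery_corrs(gt, tp), rep(1, 4), tolerance = 1e-9)
  # single subject passes through
  expect_equal(group_templates(subs[1])$maps, subs[[1]]$maps)
  # noisy subjects: the consensus beats the average individual
  set.seed(21)
  gains <- replicate(10, {
    noisy <- lapply(1:10, function(s)
      ms_templates(tp$maps[sample(4), ] +
                     matrix(rnorm(4 * 31, sd = 0.12), 4, 31)))
    gcorr <- mean(recovery_corrs(group_templates(noisy), tp))
    icorr <- mean(vapply(noisy, function(x) mean(recovery_corrs(x, tp)),
                         numeric(1)))
    gcorr - icorr
  })
  expect_gt(mean(gains), 0)
})

test_that("canonical ordering finds the best of all 24 permutations", {
  can <- canonical_templates()
  expect_equal(order_canonical(can)$maps, can$maps, tolerance = 1e-12)
  rev_ts <- ms_templates(can$maps[4:1, ])
  expect_equal(order_canonical(rev_ts)$maps, can$maps, tolerance = 1e-12)
  # random valid set: chosen permutation beats the other 23 exhaustively
  ts <- make_templates(31, 4, seed = 8)
  ord <- order_canonical(ts)
  total <- function(maps) sum(vapply(1:4, function(i)
    spatial_correlation(maps[i, ], can$maps[i, ]), numeric(1)))
  perms <- microdyn:::permutations(4)
  scores <- apply(perms, 1, function(p) total(ts$maps[p, ]))
  expect_equal(total(ord$maps), max(scores), tolerance = 1e-12)
})
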