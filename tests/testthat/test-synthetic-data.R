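test_that("trajectories honour forced initial states and determinism", {
  times <- seq(0, by = 30, length.out = 12)
  # no colonization from a forced absent start: all-zero trajectories
  ps <- simulate_presence(S = 10, c = 0, e = 0.1, times = times,
                          init = "absent", seed = 2)
  expect_true(all(ps$sites[[1]]$detections == 0))
  # identical seeds give identical output
  a <- simulate_presence(S = 20, c = 0.01, e = 0.005, times = times,
                         seed = 7)
  b <- simulate_presence(S = 20, c = 0.01, e = 0.005, times = times,
                         seed = 7)
  expect_identical(a$sites[[1]]$detections, b$sites[[1]]$detections)
  # per-taxon substreams: growing the pool never reshuffles early taxa
  big <- simulate_presence(S = 40, c = 0.01, e = 0.005, times = times,
                           seed = 7)
  expect_identical(a$sites[[1]]$detections[1:20, , ],
                   big$sites[[1]]$detections[1:20, , ])
})

test_that("mean occupancy approaches the stationary value", {
  ps <- simulate_presence(S = 1000, c = 0.2, e = 0.1,
                          times = seq(0, by = 30, length.out = 50),
                          seed = 33)
  occ <- mean(ps$sites[[1]]$detections)
  mc_se <- sqrt((2 / 3) * (1 / 3) / (1000 * 50))
  expect_lt(abs(occ - 2 / 3), 3 * mc_se)
})

test_that("equalized communities satisfy c * p = k exactly", {
  ps <- simulate_equalized(S = 100, k = 2, seed = 4)
  tr <- true_rates(ps)
  expect_equal(tr$c * tr$persistence, rep(2, 100), tolerance = 1e-12)
  expect_equal(tr$pi_star, rep(2 / 3, 100), tolerance = 1e-12)
  # empirical mean occupancy near k/(1+k); trajectories autocorrelate,
  # so allow 3 conservative (independent-Bernoulli) standard errors
  occ <- rowMeans(ps$sites[[1]]$detections[, , 1])
  expect_lt(abs(mean(occ) - 2 / 3), 3 * sqrt(2 / 9 / 100))
  expect_warning(simulate_equalized(S = 5, k = 2, c_range = c(0.01, 0.01),
                                    seed = 1), "degenerate")
  # a fixed rate_seed pins the community while seeds vary its sampling
  a <- simulate_equalized(S = 30, k = 2, seed = 10, rate_seed = 1)
  b <- simulate_equalized(S = 30, k = 2, seed = 11, rate_seed = 1)
  expect_identical(true_rates(a)$c, true_rates(b)$c)
  expect_false(identical(a$sites[[1]]$detections,
                         b$sites[[1]]$detections))
})

test_that("log-series deviates match the distribution's moments", {
  set.seed(6)
  x <- 0.9
  draws <- rlogseries(20000, x)
  expect_true(all(draws >= 1))
  expect_equal(mean(draws), -x / ((1 - x) * log(1 - x)), tolerance = 0.05)
  expect_equal(mean(draws == 1), -x / log(1 - x), tolerance = 0.02)
})

test_that("depth-limited sampling creates apparent turnover", {
  times <- seq(0, by = 30, length.out = 24)
  # saturating depth: everything always detected, no apparent events
  sat <- simulate_sad_detection(S = 50, times = times, depth = 1e7,
                                seed = 3)
  expect_true(all(sat$sites[[1]]$detections == 1))
  # realistic depth: apparent colonizations/extinctions appear
  ps <- simulate_sad_detection(S = 300, times = times, depth = 2000,
                               seed = 3)
  det <- ps$sites[[1]]$detections[, , 1]
  flips <- sum(abs(det[, -1] - det[, -24]))
  expect_gt(flips, 0)
  # rarer taxa lose detection more often: apparent persistence grows
  # with abundance while every true trajectory is static
  tr <- true_rates(ps)
  losses <- rowSums(det[, -1] == 0 & det[, -24] == 1)
  pres <- rowSums(det[, -24] == 1)
  seen <- pres > 0 & rowSums(det[, -24] == 0) > 0
  app_ext <- losses[seen] / pres[seen]
  expect_lt(cor(tr$rel_abundance[seen], app_ext, method = "spearman"), 0)
  # counts and detections stay aligned
  expect_identical(unname(ps$sites[[1]]$counts > 0),
                   unname(ps$sites[[1]]$detections == 1))
})

test_that("bundled fixtures are deterministic and carry their truth", {
  d1 <- tempfile("fx1")
  d2 <- tempfile("fx2")
  p1 <- make_fixtures(d1)
  p2 <- make_fixtures(d2)
  expect_equal(basename(p1), basename(p2))
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  truth <- read.csv(file.path(d1, "two_regime_truth.csv"))
  expect_equal(truth$true_break_occupancy, 0.5)
  lik <- read.csv(file.path(d1, "likelihood_counts.csv"),
                  check.names = FALSE)
  expect_equal(nrow(lik), 3)      # small enough for path enumeration
  expect_equal(ncol(lik) - 1, 4)
})
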