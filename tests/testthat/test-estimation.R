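fixture_series <- function() {
  det <- rbind(a = c(1, 1, 0, 1), b = c(0, 1, 1, 1), c = c(1, 0, 0, 0))
  presence_series(det, times = c(0, 30, 45, 120))
}

test_that("the transitions-only likelihood matches direct products", {
  # one taxon, two samples both present: exactly -log P(1->1)
  ps <- presence_series(matrix(c(1, 1), 1), times = c(0, 12))
  m <- transition_probabilities(0.05, 0.02, 12)
  expect_equal(negative_log_likelihood(ps, 0.05, 0.02),
               -log(m["present", "present"]), tolerance = 1e-12)
  # impossible event under c = 0 gives +Inf, not an error
  ps01 <- presence_series(matrix(c(0, 1), 1), times = c(0, 12))
  expect_identical(negative_log_likelihood(ps01, 0, 0.1), Inf)
  # 3-taxon, 4-time fixture with irregular gaps: product oracle
  ps <- fixture_series()
  det <- rbind(c(1, 1, 0, 1), c(0, 1, 1, 1), c(1, 0, 0, 0))
  for (rates in list(c(0.01, 0.005), c(0.2, 0.02), c(0.004, 0.09))) {
    expect_equal(
      negative_log_likelihood(ps, rates[1], rates[2]),
      product_nll_oracle(det, c(0, 30, 45, 120), rates[1], rates[2]),
      tolerance = 1e-10)
  }
})

test_that("transition counts aggregate per interval length", {
  cnts <- transition_counts(fixture_series())
  expect_equal(cnts$dt, c(15, 30, 75))
  expect_equal(sum(cnts[, -1]), 9)     # 3 taxa x 3 pairs
  # dt = 30: a 1->1, b 0->1, c 1->0
  r <- cnts[cnts$dt == 30, ]
  expect_equal(unlist(r[c("n00", "n01", "n10", "n11")], use.names = FALSE),
               c(0, 1, 1, 1))
})

test_that("the MLE agrees with an exhaustive grid search", {
  ps <- simulate_presence(S = 2, c = c(0.02, 0.005), e = c(0.01, 0.02),
                          times = seq(0, by = 30, length.out = 24),
                          seed = 5)
  fit <- fit_rates(ps)
  grid <- 10^seq(-4, 1, length.out = 200)
  step <- diff(log10(grid))[1]
  for (i in 1:2) {
    cnts <- transition_counts(ps, fit$group[i])
    nll <- outer(grid, grid, function(a, b)
      mapply(function(x, y) negative_log_likelihood(cnts, x, y), a, b))
    ix <- which(nll == min(nll), arr.ind = TRUE)[1, ]
    expect_lt(abs(log10(fit$c[i]) - log10(grid[ix[1]])), 1.5 * step)
    expect_lt(abs(log10(fit$e[i]) - log10(grid[ix[2]])), 1.5 * step)
  }
})

test_that("community-wide rates are recovered from simulated data", {
  ps <- simulate_presence(S = 500, c = 0.2 / 30, e = 0.1 / 30,
                          times = seq(0, by = 30, length.out = 24),
                          seed = 3)
  fit <- fit_rates(ps, grouping = "community")
  expect_true(fit$converged)
  expect_false(fit$boundary)
  expect_lt(abs(fit$c - 0.2 / 30) / (0.2 / 30), 0.1)
  expect_lt(abs(fit$e - 0.1 / 30) / (0.1 / 30), 0.1)
  expect_lte(fit$loglik, 0)
})

test_that("irregularly spaced samplings are handled without bias", {
  times <- cumsum(c(0, rep(c(30, 15, 75, 30), 12)))
  ps <- simulate_presence(S = 400, c = 0.01, e = 0.005, times = times,
                          seed = 9)
  fit <- fit_rates(ps, grouping = "community")
  expect_lt(abs(fit$c - 0.01) / 0.01, 0.1)
  expect_lt(abs(fit$e - 0.005) / 0.005, 0.1)
})

test_that("degenerate series yield errors or boundary flags", {
  all0 <- presence_series(matrix(0, 2, 5), times = 1:5)
  expect_error(fit_rates(all0, grouping = "g"), "never observed")
  all1 <- presence_series(matrix(1, 2, 5), times = 1:5)
  fit <- fit_rates(all1, grouping = "g")
  expect_true(fit$boundary)
  expect_equal(fit$e, 1e-6)   # pinned at the lower bound
})

test_that("estimates are invariant to taxon relabelling and order", {
  ps <- simulate_presence(S = 30, c = 0.01, e = 0.004,
                          times = seq(0, by = 30, length.out = 18),
                          seed = 21)
  fit1 <- fit_rates(ps, grouping = "g")
  perm <- rev(ps$taxa)
  fit2 <- fit_rates(subset_series(ps, taxa = perm), grouping = "g")
  expect_equal(fit1$c, fit2$c, tolerance = 1e-12)
  expect_equal(fit1$e, fit2$e, tolerance = 1e-12)
})

test_that("labile taxa are excluded below a quarter of the interval", {
  fits <- data.frame(group = c("a", "b", "c"), c = 1, e = c(1 / 7.4, 1 / 7.6, 1 / 500),
                     persistence = c(7.4, 7.6, 500), boundary = FALSE)
  flt <- filter_labile(fits, min_interval = 30)
  expect_equal(flt$threshold, 7.5)
  expect_equal(flt$excluded$group, "a")
  expect_equal(flt$kept$group, c("b", "c"))
  expect_equal(flt$excluded_fraction, 1 / 3)
  # nothing excluded when every persistence is long
  none <- filter_labile(fits[fits$persistence > 100, , drop = FALSE], 30)
  expect_equal(nrow(none$excluded), 0)
  expect_equal(none$excluded_fraction, 0)
})

test_that("forward-algorithm likelihood equals full path enumeration", {
  set.seed(13)
  times <- c(0, 20, 50, 60)
  ps <- simulate_presence(S = 3, c = 0.03, e = 0.02, times = times,
                          r = 3, d = 0.7, seed = 13)
  y <- apply(ps$sites[[1]]$detections, c(1, 2), sum)
  for (par in list(c(0.03, 0.02, 0.7), c(0.1, 0.01, 0.4))) {
    fwd <- occdyn:::nll_detect(par[1], par[2], par[3],
                               occdyn:::detect_site_stats(ps, ps$taxa))
    oracle <- enumeration_nll_oracle(y, times, r = 3, c = par[1],
                                     e = par[2], d = par[3])
    expect_equal(fwd, oracle, tolerance = 1e-10)
  }
})

test_that("perfect detection reduces to the collapsed-series likelihood", {
  ps <- simulate_presence(S = 40, c = 0.01, e = 0.005,
                          times = seq(0, by = 30, length.out = 16),
                          r = 2, d = 1, seed = 31)
  cnts <- transition_counts(ps)
  st <- occdyn:::detect_site_stats(ps, ps$taxa)
  pi1 <- function(c, e) c / (c + e)
  first <- ps$sites[[1]]$detections[, 1, 1]
  for (rates in list(c(0.01, 0.005), c(0.03, 0.001))) {
    # d = 1: forward likelihood = transitions-only likelihood plus the
    # stationary log-probabilities of the initial latent states
    init_ll <- sum(log(ifelse(first == 1, pi1(rates[1], rates[2]),
                              1 - pi1(rates[1], rates[2]))))
    expect_equal(occdyn:::nll_detect(rates[1], rates[2], 1, st),
                 negative_log_likelihood(cnts, rates[1], rates[2]) - init_ll,
                 tolerance = 1e-9)
  }
  # and the d-fixed estimates stay close to the collapsed-data estimates
  fitd <- fit_rates_detectability(ps, grouping = "g", fixed_d = 1)
  fitp <- fit_rates(collapse_replicates(ps), grouping = "g")
  expect_equal(fitd$c, fitp$c, tolerance = 0.05)
  expect_equal(fitd$e, fitp$e, tolerance = 0.05)
})

test_that("replicated surveys identify the detection probability", {
  ps <- simulate_presence(S = 300, c = 0.2 / 30, e = 0.1 / 30,
                          times = seq(0, by = 30, length.out = 24),
                          r = 3, d = 0.8, seed = 17)
  fit <- fit_rates_detectability(ps, grouping = "community")
  expect_lt(abs(fit$d - 0.8), 0.1)
  expect_lt(abs(fit$c - 0.2 / 30) / (0.2 / 30), 0.2)
  # single-replicate data are rejected with a pointer to fit_rates
  ps1 <- simulate_presence(S = 5, c = 0.01, e = 0.01, times = c(0, 30, 60),
                           seed = 1)
  expect_error(fit_rates_detectability(ps1, grouping = "g"), "fit_rates")
})
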