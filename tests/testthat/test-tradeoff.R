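test_that("points on p = k/c give slope -1, intercept log k, rho -1", {
  cs <- exp(seq(log(0.001), log(1), length.out = 50))
  fit <- loglog_tradeoff_fit(cs, 2 / cs)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  expect_equal(fit$intercept, log(2), tolerance = 1e-10)
  expect_equal(fit$rho, -1)
  expect_true(fit$ci[1] <= fit$slope && fit$slope <= fit$ci[2])
  expect_error(loglog_tradeoff_fit(c(-1, 1, 2), c(1, 2, 3)),
               "non-positive")
  expect_error(loglog_tradeoff_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("the slope CI covers a known generating slope", {
  set.seed(77)
  logc <- runif(200, log(1e-3), log(1e-1))
  logp <- 1.5 - 0.7 * logc + rnorm(200, 0, 0.4)
  fit <- loglog_tradeoff_fit(exp(logc), exp(logp))
  expect_true(fit$ci[1] <= -0.7 && -0.7 <= fit$ci[2])
  expect_lt(fit$rho_p, 1e-10)
})

test_that("slopes are invariant to log base and time units", {
  set.seed(5)
  cs <- 10^runif(60, -3, -1)
  ps <- 2 / cs * exp(rnorm(60, 0, 0.3))
  f_days <- loglog_tradeoff_fit(cs, ps)
  f_months <- loglog_tradeoff_fit(cs * 30, ps / 30)   # rates per month
  expect_equal(f_days$slope, f_months$slope, tolerance = 1e-10)
  # intercept shifts by (1 + slope) * log 30 under the unit change
  expect_equal(f_months$intercept,
               f_days$intercept - (1 + f_days$slope) * log(30),
               tolerance = 1e-9)
  expect_equal(f_days$rho, f_months$rho)
})

test_that("the slope = -1 test behaves at both extremes", {
  cs <- exp(seq(log(0.01), log(1), length.out = 50))
  # noiseless trade-off: degenerate SE, exact agreement
  exact <- test_slope_equals(loglog_tradeoff_fit(cs, 2 / cs), -1)
  expect_true(exact$degenerate)
  expect_equal(exact$p, 1)
  # noiseless slope -2 curve: certain rejection
  steep <- test_slope_equals(loglog_tradeoff_fit(cs, 2 / cs^2), -1)
  expect_equal(steep$p, 0)
  # self-test identity on noisy data
  set.seed(8)
  fit <- loglog_tradeoff_fit(cs, 2 / cs * exp(rnorm(50, 0, 0.3)))
  self <- test_slope_equals(fit, fit$slope)
  expect_equal(self$t, 0, tolerance = 1e-12)
  expect_equal(self$p, 1, tolerance = 1e-12)
  expect_equal(self$df, 48)
})

test_that("slope-equality rejections track real differences", {
  set.seed(31)
  mk <- function(slope, n) {
    x <- runif(n, log(1e-3), log(1e-1))
    loglog_tradeoff_fit(exp(x), exp(1 + slope * x + rnorm(n, 0, 0.3)))
  }
  # duplicated data cannot differ from themselves
  f <- mk(-1, 60)
  same <- compare_slopes(f, f, allow_overlap = TRUE)
  expect_equal(same$t, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)
  expect_error(compare_slopes(f, f), "overlap")
  # strongly different generating slopes: rejected in every replicate
  rej <- vapply(1:20, function(i) {
    cmp <- compare_slopes(mk(-1, 100), mk(-0.3, 100))
    expect_equal(cmp$df, 196)
    cmp$p < 0.01
  }, TRUE)
  expect_gte(mean(rej), 0.95)
  # the welch variant agrees in direction
  cmp <- compare_slopes(mk(-1, 100), mk(-0.3, 100), method = "welch")
  expect_lt(cmp$t, 0)
  expect_lt(cmp$p, 0.01)
})

test_that("taxonomic coherence separates clustered from null strategies", {
  set.seed(12)
  # well-separated per-group clusters in (log c, log p)
  g <- rep(c("A", "B", "C"), each = 8)
  centers <- cbind(A = c(-3, 3), B = c(-2, 2), C = c(-1, 1))
  lc <- centers[1, g] + rnorm(24, 0, 0.05)
  lp <- centers[2, g] + rnorm(24, 0, 0.05)
  strong <- taxonomic_coherence(10^lc, 10^lp, g)
  expect_lt(strong$p, 0.01)
  expect_equal(strong$n_intra + strong$n_inter, choose(24, 2))
  # labels unrelated to position: p should not be systematically small
  ps <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    lc <- rnorm(24, -2, 1)
    lp <- rnorm(24, 2, 1)
    taxonomic_coherence(10^lc, 10^lp, g)$p
  }, 1)
  expect_gt(median(ps), 0.2)
  expect_lt(median(ps), 0.8)
  expect_error(taxonomic_coherence(c(1, 2), c(1, 2), c("A", "B")),
               "2 members")
})

test_that("exclusion reanalysis reports before/after correlations", {
  cs <- 10^seq(-3, -1, length.out = 40)
  ps <- 2 / cs
  taxa <- sprintf("t%02d", 1:40)
  none <- exclude_taxa_and_correlate(cs, ps, taxa, character())
  expect_equal(none$rho_before, none$rho_after)
  # diluting a clean backbone with noise points, then excluding them
  set.seed(3)
  noise_c <- 10^runif(15, -3, -1)
  noise_p <- 10^runif(15, 0, 3)
  all_c <- c(cs, noise_c)
  all_p <- c(ps, noise_p)
  all_t <- c(taxa, sprintf("n%02d", 1:15))
  res <- exclude_taxa_and_correlate(all_c, all_p, all_t,
                                    exclude = sprintf("n%02d", 1:15))
  expect_gt(abs(res$rho_after), abs(res$rho_before))
  expect_equal(res$n_after, 40)
  expect_error(exclude_taxa_and_correlate(cs, ps, taxa,
                                          exclude = taxa[-1]), "fewer than 3")
})
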