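test_that("occupancy and maximum abundance are tallied per taxon", {
  cnt <- rbind(a = c(0, 3, 17, 0, 1, 2, 5, 0, 0, 0, 4, 9),
               b = c(rep(1, 6), rep(0, 6)),
               z = rep(0, 12))
  ps <- presence_series((cnt > 0) * 1, times = 1:12, counts = cnt)
  expect_warning(tab <- occupancy_abundance(ps), "never-detected")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$occupancy[tab$taxon == "b"], 0.5)
  expect_equal(tab$max_abundance[tab$taxon == "a"], 17)
  # permuting sample order changes nothing
  perm <- sample(12)
  ps2 <- presence_series((cnt[, perm] > 0) * 1, times = 1:12,
                         counts = cnt[, perm])
  expect_warning(tab2 <- occupancy_abundance(ps2), "never-detected")
  expect_equal(tab2, tab)
})

test_that("the Chow statistic matches direct RSS arithmetic", {
  # one global noiseless line: F = 0
  x <- seq(0, 1, length.out = 20)
  expect_equal(chow_statistic(x, 2 + 3 * x, 10), 0, tolerance = 1e-9)
  # independent hand computation on noisy data
  set.seed(99)
  y <- 2 + 3 * x + c(rep(0, 10), rep(1.5, 10)) + rnorm(20, 0, 0.2)
  rss <- function(ix) sum(resid(lm(y[ix] ~ x[ix]))^2)
  f_manual <- ((rss(1:20) - rss(1:10) - rss(11:20)) / 2) /
    ((rss(1:10) + rss(11:20)) / 16)
  expect_equal(chow_statistic(x, y, 10), f_manual, tolerance = 1e-10)
  expect_error(chow_statistic(x, y, 2), "3 points")
  expect_error(chow_statistic(rev(x), y, 10), "sorted")
  expect_error(chow_statistic(rep(1, 10), rnorm(10), 5), "degenerate")
})

test_that("the scan maximizes F at a noiseless two-slope kink", {
  occ <- seq(0.05, 0.95, length.out = 30)
  y <- ifelse(occ <= 0.5, occ, 0.5 + 4 * (occ - 0.5))
  Fs <- vapply(5:25, function(i) chow_statistic(occ, y, i), 1)
  best <- (5:25)[which.max(Fs)]
  expect_equal(occ[best], max(occ[occ <= 0.5]))
})

test_that("core/satellite splitting recovers a two-regime structure", {
  ok_thr <- ok_acc <- logical(5)
  for (s in 1:5) {
    tab <- two_regime_table(s)
    scan <- split_core_satellite(tab)
    expect_true(scan$significant)
    # threshold strictly inside the occupancy range
    expect_gt(scan$occupancy_threshold, min(tab$occupancy))
    expect_lt(scan$occupancy_threshold, max(tab$occupancy))
    ok_thr[s] <- abs(scan$occupancy_threshold - 0.5) < 0.1
    ok_acc[s] <- mean(scan$labels[tab$taxon] == tab$regime) >= 0.9
    # labels follow the strict-greater threshold rule
    expect_equal(unname(scan$labels),
                 unname(ifelse(tab$occupancy > scan$occupancy_threshold,
                               "core", "satellite")))
  }
  expect_true(all(ok_thr))
  expect_true(all(ok_acc))
})

test_that("splitting is deterministic and honours its edge rules", {
  tab <- two_regime_table(3)
  s1 <- split_core_satellite(tab)
  s2 <- split_core_satellite(tab[sample(nrow(tab)), ])
  expect_equal(s1$occupancy_threshold, s2$occupancy_threshold)
  expect_equal(s1$labels[sort(names(s1$labels))],
               s2$labels[sort(names(s2$labels))])
  # single-line data: no significant break, no labels
  set.seed(2)
  n <- 40
  occ <- seq(0.05, 0.95, length.out = n)
  line <- data.frame(taxon = sprintf("t%02d", 1:n), occupancy = occ,
                     max_abundance = pmax(1, round(10^(1 + occ))),
                     log10_max_abundance = 1 + occ + rnorm(n, 0, 0.05))
  scan <- split_core_satellite(line)
  expect_false(scan$significant)
  expect_null(scan$labels)
  expect_error(split_core_satellite(line[1:8, ]), "at least 10")
  same <- transform(line, occupancy = 0.5)
  expect_error(split_core_satellite(same), "identical")
})

test_that("ties in maximal F resolve to the lowest-occupancy candidate", {
  # symmetric double kink gives identical F at two candidates
  occ <- c(seq(0.1, 0.3, length.out = 5), seq(0.42, 0.58, length.out = 5),
           seq(0.7, 0.9, length.out = 5))
  y <- c(rep(0, 5), occ[6:10], rep(1, 5))
  tab <- data.frame(taxon = sprintf("t%02d", seq_along(occ)),
                    occupancy = occ, max_abundance = round(10^(y + 1)),
                    log10_max_abundance = y)
  scan <- split_core_satellite(tab, trim = 0.2)
  tied <- scan$candidates[abs(scan$F - scan$F_max) < 1e-9]
  expect_gt(length(tied), 1)      # a genuine tie exists
  expect_equal(scan$best_index, min(tied))
})

test_that("lognormal rank-abundance fits recover self-generated data", {
  z <- qnorm((seq_len(40) - 0.5) / 40)
  ab <- round(exp(8 - 1.2 * sort(z, decreasing = TRUE)))
  fit <- lognormal_rad_fit(ab)
  expect_lt(fit$deviance / fit$n, 0.01)
  expect_equal(fit$intercept, 8, tolerance = 0.01)
  expect_equal(fit$scale, 1.2, tolerance = 0.01)
  expect_true(all(diff(fit$fitted) <= 0))
  expect_gte(fit$deviance, 0)
  # scaling abundances shifts the level, not the shape
  fit10 <- lognormal_rad_fit(ab * 10)
  expect_equal(fit10$scale, fit$scale, tolerance = 0.01)
  expect_gt(fit10$intercept, fit$intercept)
  expect_error(lognormal_rad_fit(c(3, 2, 1)), "at least 5")
  expect_error(lognormal_rad_fit(c(3, 2, 1, 0.5, 4)), ">= 1")
})
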