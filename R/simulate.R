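## Synthetic-data generators: presence-absence trajectories of the
## two-state chain, fitness-equalized communities, and detection-only
## "apparent dynamics" driven purely by a species abundance distribution
## sampled at finite sequencing depth.
##
## Each taxon gets its own RNG substream derived from (seed, taxon index,
## stream), so enlarging the pool never reshuffles existing taxa.

taxon_seed <- function(seed, i, stream = 0L) {
  as.integer(((seed %% 1000003) * 1009 + i * 104729 + stream * 7919) %%
               2147483647)
}

#' Simulate presence-absence trajectories of the two-state chain
#'
#' Each taxon starts from its stationary occupancy (or a forced state)
#' and is propagated across the supplied sampling times with the exact
#' interval transition probabilities, so irregular spacing is handled
#' natively. Detection is optionally imperfect: each of \code{r}
#' replicates detects a present taxon with probability \code{d} (absent
#' taxa are never detected).
#'
#' @param S number of taxa.
#' @param c,e colonization/extinction rates (per day), recycled to
#'   length \code{S}.
#' @param times sampling times in days, strictly increasing, irregular
#'   spacing allowed.
#' @param r replicates per sampling time.
#' @param d per-replicate detection probability given presence.
#' @param init \code{"stationary"} (default), \code{"absent"} or
#'   \code{"present"}.
#' @param taxa optional taxon ids.
#' @param site site label.
#' @param seed integer seed; the same seed reproduces the same series,
#'   and taxon i's trajectory does not change when \code{S} grows.
#' @return A \code{\link{presence_series}} with the generator truth
#'   (data frame: taxon, c, e, k, persistence, pi_star) attached as
#'   attribute \code{"truth"}; see \code{\link{true_rates}}.
#' @export
simulate_presence <- function(S, c, e, times, r = 1L, d = 1,
                              init = c("stationary", "absent", "present"),
                              taxa = NULL, site = "site1", seed = 1L) {
  init <- match.arg(init)
  stopifnot(S >= 1, r >= 1, d > 0, d <= 1, length(times) >= 1,
            all(diff(times) > 0))
  c <- rep_len(c, S)
  e <- rep_len(e, S)
  if (any(c < 0) || any(e < 0) || any(c + e == 0))
    stop("rates must be non-negative with c + e > 0")
  if (is.null(taxa)) taxa <- sprintf("t%04d", seq_len(S))
  Tn <- length(times)
  dts <- diff(times)
  det <- array(0L, dim = c(S, Tn, r))
  pi_star <- c / (c + e)
  for (i in seq_len(S)) {
    set.seed(taxon_seed(seed, i))
    z <- integer(Tn)
    z[1] <- switch(init,
                   stationary = stats::rbinom(1L, 1L, pi_star[i]),
                   absent = 0L, present = 1L)
    for (t in seq_len(Tn - 1L)) {
      pr <- if (z[t] == 1L) trans_p11(c[i], e[i], dts[t])
            else trans_p01(c[i], e[i], dts[t])
      z[t + 1L] <- stats::rbinom(1L, 1L, pr)
    }
    det[i, , ] <- if (d >= 1) rep(z, r)
                  else stats::rbinom(Tn * r, 1L, d * rep(z, r))
  }
  ps <- presence_series(det, times, taxa = taxa, site = site)
  attr(ps, "truth") <- data.frame(
    taxon = taxa, c = c, e = e, k = c / e,
    persistence = 1 / e, pi_star = pi_star)
  ps
}

#' Simulate a fitness-equalized community
#'
#' All taxa share the same colonization-to-extinction ratio \code{k}
#' (the fitness-equalization scenario): colonization rates are drawn
#' log-uniformly over \code{c_range} and each extinction rate is
#' \code{e = c/k}, so every true \eqn{(c, p)} pair satisfies
#' \eqn{c \cdot p = k} exactly and all taxa share stationary occupancy
#' \eqn{k/(1+k)}. Trajectories are then generated as in
#' \code{\link{simulate_presence}}.
#'
#' @param S number of taxa.
#' @param k shared colonization-to-extinction ratio (> 0).
#' @param c_range range of colonization rates (per day), sampled
#'   log-uniformly; should span at least two decades for the downstream
#'   slope to be well identified (a degenerate single-value range
#'   triggers a warning).
#' @param rate_seed seed governing the rate draws only (default: same
#'   as \code{seed}). Keeping \code{rate_seed} fixed while varying
#'   \code{seed} yields repeated independent samplings of one and the
#'   same community.
#' @inheritParams simulate_presence
#' @return As \code{\link{simulate_presence}}.
#' @export
simulate_equalized <- function(S, k = 2, c_range = c(0.02, 2) / 30,
                               times = seq(0, by = 30, length.out = 24),
                               r = 1L, d = 1, taxa = NULL, site = "site1",
                               seed = 1L, rate_seed = seed) {
  stopifnot(k > 0, length(c_range) == 2L, all(c_range > 0))
  if (c_range[1] == c_range[2])
    warning("degenerate colonization range: the trade-off slope will be ",
            "unidentifiable downstream")
  cs <- vapply(seq_len(S), function(i) {
    set.seed(taxon_seed(rate_seed, i, stream = 1L))
    exp(stats::runif(1, log(c_range[1]), log(c_range[2])))
  }, 1)
  simulate_presence(S, c = cs, e = cs / k, times = times, r = r, d = d,
                    taxa = taxa, site = site, seed = seed)
}

#' Simulate a community with independent colonization and extinction rates
#'
#' The non-equalized counterpart of \code{\link{simulate_equalized}}:
#' each taxon's colonization and extinction rates are drawn
#' independently log-uniformly, so colonization-to-extinction ratios
#' vary freely across taxa and no trade-off is enforced.
#'
#' @param S number of taxa.
#' @param c_range,e_range log-uniform sampling ranges (per day).
#' @inheritParams simulate_presence
#' @return As \code{\link{simulate_presence}}.
#' @export
simulate_independent <- function(S, c_range = c(0.02, 2) / 30,
                                 e_range = c(0.02, 2) / 30,
                                 times = seq(0, by = 30, length.out = 24),
                                 r = 1L, d = 1, taxa = NULL,
                                 site = "site1", seed = 1L) {
  stopifnot(all(c_range > 0), all(e_range > 0))
  draw <- function(i, stream, range) {
    set.seed(taxon_seed(seed, i, stream = stream))
    exp(stats::runif(1, log(range[1]), log(range[2])))
  }
  cs <- vapply(seq_len(S), draw, 1, stream = 1L, range = c_range)
  es <- vapply(seq_len(S), draw, 1, stream = 3L, range = e_range)
  simulate_presence(S, c = cs, e = es, times = times, r = r, d = d,
                    taxa = taxa, site = site, seed = seed)
}

#' Log-series random deviates
#'
#' Samples from the logarithmic (Fisher log-series) distribution
#' \eqn{P(n) = -x^n / (n \log(1-x))}, \eqn{n \ge 1}, by inversion.
#'
#' @param n number of deviates.
#' @param x log-series parameter in (0, 1).
#' @return Positive integers.
#' @export
rlogseries <- function(n, x) {
  stopifnot(x > 0, x < 1)
  kmax <- 10L
  repeat {
    k <- seq_len(kmax)
    pmf <- -x^k / (k * log(1 - x))
    if (sum(pmf) > 1 - 1e-12 || kmax > 1e7) break
    kmax <- kmax * 10L
  }
  findInterval(stats::runif(n), cumsum(pmf)) + 1L
}

#' Simulate sampling-driven apparent dynamics from a static SAD
#'
#' The null model for the trade-off signal: taxa have fixed latent
#' relative abundances drawn from a species abundance distribution
#' (lognormal for a core fraction, log-series for the rest) and no
#' colonization-extinction dynamics at all. Each sample draws
#' \code{depth} reads multinomially, and detection is \code{count > 0},
#' so all apparent colonizations and extinctions are sequencing-depth
#' artefacts. Rates estimated from such data must not reproduce the
#' slope -1 trade-off; enforcing equalized dynamics
#' (\code{\link{simulate_equalized}}) must.
#'
#' @param S number of taxa.
#' @param times sampling times (days).
#' @param depth reads per sample.
#' @param core_fraction fraction of taxa drawn from the lognormal.
#' @param meanlog,sdlog lognormal parameters of the core abundances.
#' @param ls_x log-series parameter of the satellite abundances.
#' @param jitter_sd optional per-sample lognormal jitter (sd on the log
#'   scale) of the latent abundances, mimicking compositional noise.
#' @param seed integer seed.
#' @return A \code{\link{presence_series}} with counts; attribute
#'   \code{"truth"} holds taxon, SAD class and latent relative
#'   abundance.
#' @export
simulate_sad_detection <- function(S = 300L,
                                   times = seq(0, by = 30, length.out = 24),
                                   depth = 2000L, core_fraction = 0.2,
                                   meanlog = 3, sdlog = 1, ls_x = 0.95,
                                   jitter_sd = 0, seed = 1L) {
  stopifnot(S >= 2, depth >= 1, core_fraction >= 0, core_fraction <= 1)
  set.seed(taxon_seed(seed, 0L, stream = 2L))
  ncore <- round(core_fraction * S)
  ab <- c(stats::rlnorm(ncore, meanlog, sdlog),
          rlogseries(S - ncore, ls_x))
  cls <- rep(c("lognormal_core", "logseries_satellite"),
             c(ncore, S - ncore))
  rel <- ab / sum(ab)
  Tn <- length(times)
  counts <- matrix(0L, S, Tn)
  for (t in seq_len(Tn)) {
    w <- if (jitter_sd > 0) rel * stats::rlnorm(S, 0, jitter_sd) else rel
    counts[, t] <- stats::rmultinom(1L, depth, w)[, 1L]
  }
  taxa <- sprintf("t%04d", seq_len(S))
  ps <- presence_series((counts > 0) * 1L, times, taxa = taxa,
                        counts = counts, site = "site1")
  attr(ps, "truth") <- data.frame(taxon = taxa, sad_class = cls,
                                  rel_abundance = rel)
  ps
}

#' Attach a synthetic taxonomy to a taxon set
#'
#' Round-robin assignment of genera to families and families to higher
#' ranks; purely for exercising rank aggregation and coherence tests on
#' simulated data.
#'
#' @param taxa character vector of taxon ids (treated as genera).
#' @param n_families,n_phyla numbers of synthetic higher-rank groups.
#' @return A taxonomy data frame (taxon, phylum, class, order, family,
#'   genus).
#' @export
synthetic_taxonomy <- function(taxa, n_families = 10L, n_phyla = 3L) {
  fam <- sprintf("fam%02d", (seq_along(taxa) - 1L) %% n_families + 1L)
  phy <- sprintf("phy%02d",
                 (match(fam, sort(unique(fam))) - 1L) %% n_phyla + 1L)
  data.frame(taxon = taxa, phylum = phy, class = phy, order = fam,
             family = fam, genus = taxa)
}

#' Write the bundled deterministic test fixtures
#'
#' Generates the small fixtures used across the test-suite: a 3-taxon,
#' 4-time likelihood fixture (small enough for exhaustive latent-path
#' enumeration), a two-regime occupancy-abundance table with its true
#' break occupancy recorded in a sidecar, and a duplicated-site dataset
#' for the partition-model comparison. All files are deterministic
#' (byte-identical across runs).
#'
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  ## 1. likelihood fixture: irregular times, hand-chosen states
  det <- rbind(a = c(1, 1, 0, 1), b = c(0, 1, 1, 1), c = c(1, 0, 0, 0))
  cnt <- det * rbind(c(5, 2, 0, 9), c(0, 1, 3, 2), c(7, 0, 0, 0))
  ps <- presence_series(det, times = c(0, 30, 45, 120), counts = cnt)
  paths <- c(paths, write_dataset(ps, dir, prefix = "likelihood",
                                  taxonomy = synthetic_taxonomy(ps$taxa,
                                                                2L, 2L)))

  ## 2. two-regime occupancy-abundance fixture, true break at 0.5
  occ <- seq(0.04, 0.96, length.out = 40)
  slope_lo <- 0.5
  slope_hi <- 4
  y <- ifelse(occ <= 0.5, 0.5 + slope_lo * occ,
              0.5 + slope_lo * 0.5 + slope_hi * (occ - 0.5))
  tworeg <- data.frame(taxon = sprintf("g%02d", seq_along(occ)),
                       occupancy = occ,
                       max_abundance = round(10^y),
                       log10_max_abundance = y)
  f <- file.path(dir, "two_regime_occupancy.csv")
  utils::write.csv(tworeg, f, row.names = FALSE)
  truth <- data.frame(true_break_occupancy = 0.5,
                      left_slope = slope_lo, right_slope = slope_hi)
  ft <- file.path(dir, "two_regime_truth.csv")
  utils::write.csv(truth, ft, row.names = FALSE)
  paths <- c(paths, f, ft)

  ## 3. duplicated-site fixture for partition comparison
  a <- simulate_presence(S = 20, c = 0.02, e = 0.01,
                         times = seq(0, by = 30, length.out = 12),
                         site = "siteA", seed = 20L)
  b <- a
  names(b$sites) <- "siteB"
  two <- combine_sites(a, b)
  paths <- c(paths, write_dataset(two, dir, prefix = "dupsite",
                                  taxonomy = synthetic_taxonomy(two$taxa)))
  invisible(paths)
}
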