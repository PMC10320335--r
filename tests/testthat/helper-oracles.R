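## Independent oracles and small generators shared across the suite.

## Product oracle: likelihood of observed binary sequences as the direct
## product of per-interval transition probabilities, computed without the
## package's sufficient-statistic reduction.
product_nll_oracle <- function(det, times, c, e) {
  ll <- 0
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(ncol(det) - 1L)) {
      m <- transition_probabilities(c, e, times[j + 1L] - times[j])
      ll <- ll + log(m[det[i, j] + 1L, det[i, j + 1L] + 1L])
    }
  }
  -ll
}

## Path-enumeration oracle for the imperfect-detection likelihood: sums
## the joint probability over every latent presence path (2^T per taxon).
## y: taxa x times detection counts; r replicates; initial latent state
## from the stationary distribution of (c, e).
enumeration_nll_oracle <- function(y, times, r, c, e, d) {
  Tn <- ncol(y)
  pi1 <- c / (c + e)
  paths <- as.matrix(expand.grid(rep(list(0:1), Tn)))
  total <- 0
  for (i in seq_len(nrow(y))) {
    lik <- 0
    for (p in seq_len(nrow(paths))) {
      z <- paths[p, ]
      pr <- if (z[1] == 1) pi1 else 1 - pi1
      for (t in seq_len(Tn - 1L)) {
        m <- transition_probabilities(c, e, times[t + 1L] - times[t])
        pr <- pr * m[z[t] + 1L, z[t + 1L] + 1L]
      }
      for (t in seq_len(Tn)) {
        pr <- pr * if (z[t] == 1) dbinom(y[i, t], r, d)
                   else as.numeric(y[i, t] == 0)
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  -unname(total)
}

## Two-regime occupancy-abundance generator: nearly flat satellite
## segment, steep core segment, lognormal scatter of maximum abundances
## around the piecewise relation (sd 0.1 on the log10 scale), regime
## change at occupancy 0.5.
two_regime_table <- function(seed, n = 150, break_occ = 0.5,
                             slope_lo = 0.5, slope_hi = 4, noise_sd = 0.1) {
  set.seed(seed)
  occ <- runif(n, 0.02, 0.98)
  y <- ifelse(occ <= break_occ, 0.3 + slope_lo * occ,
              0.3 + slope_lo * break_occ + slope_hi * (occ - break_occ)) +
    rnorm(n, 0, noise_sd)
  y <- pmax(y, 0)
  data.frame(taxon = sprintf("g%03d", seq_len(n)), occupancy = occ,
             max_abundance = pmax(1, round(10^y)),
             log10_max_abundance = y,
             regime = ifelse(occ > break_occ, "core", "satellite"))
}

## Drop taxa never observed present (fit_rates errors on them when
## fitted one group per taxon).
drop_undetected <- function(ps) {
  det <- Reduce(`+`, lapply(ps$sites, function(s)
    apply(s$detections, 1L, sum)))
  subset_series(ps, taxa = ps$taxa[det > 0])
}

## The per-taxon estimation pipeline shared by the trade-off recovery
## checks: fit each taxon, drop boundary fits, apply the labile filter.
estimate_filtered <- function(ps, min_interval = 30) {
  fits <- fit_rates(drop_undetected(ps))
  filter_labile(fits[!fits$boundary, , drop = FALSE], min_interval)$kept
}
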