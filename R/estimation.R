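## Maximum-likelihood estimation of colonization/extinction rates from
## irregular presence-absence samplings.
##
## The workhorse is a sufficient-statistic reduction: for a set of taxa the
## transitions-only likelihood depends on the data only through the counts
## of (absent/present -> absent/present) pairs at each distinct inter-sample
## interval, so the per-evaluation cost is O(#distinct intervals).

#' Transition counts at each distinct inter-sample interval
#'
#' Tabulates, over all selected taxa, sites and consecutive sample pairs,
#' the number of observed 0->0, 0->1, 1->0 and 1->1 pairs per distinct
#' interval length. Replicates are collapsed to any-replicate detection.
#'
#' @param series a \code{\link{presence_series}}.
#' @param taxa optional character vector restricting to a taxon subset.
#' @return A data frame with columns \code{dt, n00, n01, n10, n11}, one
#'   row per distinct interval length.
#' @export
transition_counts <- function(series, taxa = NULL) {
  stopifnot(inherits(series, "presence_series"))
  if (!is.null(taxa)) series <- subset_series(series, taxa = taxa)
  rows <- list()
  for (s in series$sites) {
    Tn <- length(s$times)
    if (Tn < 2L) next
    det <- collapse_detections(s)
    dts <- diff(s$times)
    for (j in seq_len(Tn - 1L)) {
      code <- det[, j] * 2L + det[, j + 1L]
      rows[[length(rows) + 1L]] <-
        c(dts[j], tabulate(code + 1L, nbins = 4L))
    }
  }
  if (!length(rows))
    stop("series has no consecutive sample pair to estimate from")
  m <- do.call(rbind, rows)
  agg <- rowsum(m[, 2:5, drop = FALSE], group = m[, 1])
  data.frame(dt = as.numeric(rownames(agg)), n00 = agg[, 1],
             n01 = agg[, 2], n10 = agg[, 3], n11 = agg[, 4],
             row.names = NULL)
}

## n * log(p) with the convention 0 * log(0) = 0; n > 0, p = 0 -> -Inf.
xlogp <- function(n, p) ifelse(n == 0, 0, n * log(p))

nll_from_counts <- function(c, e, counts) {
  p01 <- trans_p01(c, e, counts$dt)
  p11 <- trans_p11(c, e, counts$dt)
  ll <- sum(xlogp(counts$n00, 1 - p01) + xlogp(counts$n01, p01) +
              xlogp(counts$n10, 1 - p11) + xlogp(counts$n11, p11))
  if (is.nan(ll)) return(Inf)
  -ll
}

#' Transitions-only negative log-likelihood
#'
#' Negative log-probability of the observed presence-absence sequences
#' under a two-state chain with rates \code{(c, e)}: the sum over taxa,
#' sites and consecutive sample pairs of \eqn{-\log P(s_t \to
#' s_{t+\Delta t})}, each pair evaluated at its own interval. The first
#' observation of every sequence is conditioned on, not modelled.
#' Impossible data under boundary rates (e.g. an observed colonization
#' with \code{c = 0}) yield \code{Inf}, not an error.
#'
#' @param series a \code{\link{presence_series}} (or a data frame of
#'   transition counts from \code{\link{transition_counts}}).
#' @param c,e colonization and extinction rates (per day).
#' @param taxa optional taxon subset.
#' @return A non-negative scalar (possibly \code{Inf}).
#' @export
negative_log_likelihood <- function(series, c, e, taxa = NULL) {
  if (any(c < 0) || any(e < 0)) stop("rates must be non-negative")
  counts <- if (is.data.frame(series)) series
            else transition_counts(series, taxa)
  nll_from_counts(c, e, counts)
}

## Grouping helpers -----------------------------------------------------

resolve_grouping <- function(series, grouping) {
  if (is.null(grouping)) {
    split(series$taxa, factor(series$taxa, levels = series$taxa))
  } else if (length(grouping) == 1L && is.null(names(grouping))) {
    stats::setNames(list(series$taxa), grouping)
  } else {
    if (is.null(names(grouping)) || !all(series$taxa %in% names(grouping)))
      stop("'grouping' must be named by taxon id and cover all taxa")
    g <- grouping[series$taxa]
    split(names(g), factor(g, levels = unique(g)))
  }
}

## Fixed multi-start grid in log-rate space (per day).
rate_starts <- function() {
  g <- log(10^c(-3, -1.5, 0))
  as.matrix(expand.grid(logc = g, loge = g))
}

## Multi-start Nelder-Mead with box constraints enforced by penalty;
## 'lo'/'up' are bounds in the transformed (log/logit) parameter space.
optimize_nll <- function(fn, starts, lo, up, reltol = 1e-8) {
  pen <- function(par) {
    if (any(par < lo) || any(par > up))
      return(1e10 + sum(pmax(lo - par, 0)) + sum(pmax(par - up, 0)))
    fn(par)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], pen, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par <- pmin(pmax(best$par, lo), up)
  best
}

#' Fit colonization/extinction rates by maximum likelihood
#'
#' Estimates a single \code{(c, e)} pair per group of taxa by maximizing
#' the transitions-only likelihood jointly over the group's members,
#' sites and consecutive sample pairs (each with its own interval
#' length). Optimization is a derivative-free Nelder-Mead search in
#' log-rate space, multi-started from a fixed 3 x 3 log grid, so the
#' result is deterministic given the data.
#'
#' A group whose members are never detected cannot be fitted and raises
#' an error. A group observed present at every sample has no information
#' about extinction: its \code{e} is pinned at the lower bound and the
#' fit is flagged as a boundary fit (its \code{c} is not identified).
#'
#' @param series a \code{\link{presence_series}}.
#' @param grouping \code{NULL} (one group per taxon), a single unnamed
#'   label (all taxa in one group), or a character vector mapping taxon
#'   id -> group label (named by taxon).
#' @param lower,upper rate bounds, per day.
#' @param reltol convergence tolerance for the simplex search.
#' @return A data frame of class \code{"group_rates"}: one row per group
#'   with columns \code{group, c, e, k, persistence, loglik,
#'   n_transitions, converged, boundary}.
#' @examples
#' set.seed(1)
#' ps <- simulate_presence(S = 50, c = 0.02, e = 0.01,
#'                         times = seq(0, 690, by = 30), seed = 1)
#' fit_rates(ps, grouping = "community")
#' @export
fit_rates <- function(series, grouping = NULL, lower = 1e-6, upper = 1e3,
                      reltol = 1e-8) {
  stopifnot(inherits(series, "presence_series"))
  groups <- resolve_grouping(series, grouping)
  starts <- rate_starts()
  out <- lapply(names(groups), function(g) {
    counts <- transition_counts(series, groups[[g]])
    n_pairs <- sum(counts[, c("n00", "n01", "n10", "n11")])
    ever_present <- sum(counts$n01, counts$n10, counts$n11) > 0 ||
      any_first_detection(series, groups[[g]])
    if (!ever_present)
      stop("group '", g, "' is never observed present; cannot fit rates")
    all_present <- sum(counts$n00, counts$n01, counts$n10) == 0
    ## an interior maximum needs every transition type observed at
    ## least once; a missing type drives the MLE to a rate bound
    structural <- any(colSums(counts[, c("n00", "n01", "n10", "n11")]) == 0)
    o <- optimize_nll(function(par)
      nll_from_counts(exp(par[1]), exp(par[2]), counts),
      starts, lo = log(c(lower, lower)), up = log(c(upper, upper)),
      reltol = reltol)
    cc <- exp(o$par[1])
    ee <- exp(o$par[2])
    if (all_present) ee <- lower
    near <- function(x) x <= lower * 1.05 || x >= upper / 1.05
    boundary <- all_present || structural || near(cc) || near(ee)
    data.frame(group = g, c = cc, e = ee,
               k = cc / ee, persistence = 1 / ee,
               loglik = -nll_from_counts(cc, ee, counts),
               n_transitions = n_pairs,
               converged = o$convergence == 0,
               boundary = boundary)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("group_rates", class(out))
  out
}

## TRUE if any member taxon is ever detected (including first samples,
## which contribute no transition pair).
any_first_detection <- function(series, taxa) {
  for (s in series$sites) {
    det <- collapse_detections(s)
    if (any(det[taxa, , drop = FALSE] > 0)) return(TRUE)
  }
  FALSE
}

#' Exclude labile taxa whose persistence is too short to estimate
#'
#' Rate estimates are unreliable for taxa that turn over much faster than
#' the sampling: a taxon whose expected residence time is shorter than a
#' quarter of the minimal inter-sample interval can appear and vanish
#' between samples, biasing its rates. This filter drops groups with
#' persistence \code{1/e < min_interval/4}.
#'
#' @param fits a \code{\link{fit_rates}} result.
#' @param min_interval the dataset's minimal inter-sample interval (days);
#'   see \code{\link{min_sampling_interval}}.
#' @return A list with elements \code{kept} and \code{excluded} (the two
#'   halves of \code{fits}), \code{threshold} (days) and
#'   \code{excluded_fraction}.
#' @export
filter_labile <- function(fits, min_interval) {
  stopifnot(is.data.frame(fits), min_interval > 0)
  threshold <- min_interval / 4
  drop <- !is.na(fits$persistence) & fits$persistence < threshold
  list(kept = fits[!drop, , drop = FALSE],
       excluded = fits[drop, , drop = FALSE],
       threshold = threshold,
       excluded_fraction = if (nrow(fits)) mean(drop) else NaN)
}

## Imperfect detectability -----------------------------------------------

## Forward-algorithm negative log-likelihood over the latent presence
## chain, vectorized across taxa. Emissions: a present taxon is detected
## independently in each of r replicates with probability d; an absent
## taxon is never detected (no false positives). Initial latent
## distribution: stationary occupancy of the candidate rates.
nll_detect <- function(c, e, d, site_stats) {
  s <- c + e
  if (s <= 0 || d < 0 || d > 1) return(Inf)
  pi1 <- c / s
  total <- 0
  for (st in site_stats) {
    y <- st$y                      # taxa x times detection counts
    r <- st$r
    Tn <- ncol(y)
    e1 <- stats::dbinom(y, r, d)   # emission given present
    e0 <- (y == 0) * 1             # emission given absent
    a0 <- (1 - pi1) * e0[, 1L]
    a1 <- pi1 * e1[, 1L]
    sc <- a0 + a1
    if (any(sc == 0)) return(Inf)
    total <- total + sum(log(sc))
    a0 <- a0 / sc
    a1 <- a1 / sc
    for (t in seq_len(Tn - 1L)) {
      p01 <- trans_p01(c, e, st$dts[t])
      p11 <- trans_p11(c, e, st$dts[t])
      b0 <- a0 * (1 - p01) + a1 * (1 - p11)
      b1 <- a0 * p01 + a1 * p11
      a0 <- b0 * e0[, t + 1L]
      a1 <- b1 * e1[, t + 1L]
      sc <- a0 + a1
      if (any(sc == 0)) return(Inf)
      total <- total + sum(log(sc))
      a0 <- a0 / sc
      a1 <- a1 / sc
    }
  }
  -total
}

detect_site_stats <- function(series, taxa) {
  lapply(series$sites, function(s) {
    d <- s$detections[taxa, , , drop = FALSE]
    y <- apply(d, c(1, 2), sum)
    if (!is.matrix(y)) y <- matrix(y, nrow = length(taxa))
    list(y = y, r = dim(d)[3L], dts = diff(s$times))
  })
}

#' Fit rates with imperfect detection from replicated surveys
#'
#' Dynamic-occupancy variant of \code{\link{fit_rates}} for series with
#' replicated samplings: the latent presence state follows the two-state
#' chain, and given presence each replicate detects independently with a
#' probability \code{d} shared across surveys and taxa (absent taxa are
#' never detected). The likelihood is evaluated by the forward algorithm
#' over time, with the latent initial state integrated over the
#' stationary distribution of the candidate rates.
#'
#' @param series a \code{\link{presence_series}} with at least 2
#'   replicates at some survey. Single-replicate data are rejected
#'   (\code{d} is then unidentifiable; use \code{\link{fit_rates}}).
#' @param grouping as in \code{\link{fit_rates}}.
#' @param fixed_d optionally fix the detection probability instead of
#'   estimating it (e.g. \code{fixed_d = 1} reduces to perfect
#'   detection).
#' @param lower,upper rate bounds, per day.
#' @param reltol simplex convergence tolerance.
#' @return A \code{"group_rates"} data frame with an additional column
#'   \code{d}.
#' @export
fit_rates_detectability <- function(series, grouping = NULL, fixed_d = NULL,
                                    lower = 1e-6, upper = 1e3,
                                    reltol = 1e-8) {
  stopifnot(inherits(series, "presence_series"))
  if (max_replicates(series) < 2L)
    stop("detection probability is unidentifiable without replicates ",
         "(r = 1 everywhere); use fit_rates() instead")
  groups <- resolve_grouping(series, grouping)
  rs <- rate_starts()
  out <- lapply(names(groups), function(g) {
    st <- detect_site_stats(series, groups[[g]])
    n_pairs <- sum(vapply(st, function(x)
      length(x$dts) * nrow(x$y), 1))
    if (is.null(fixed_d)) {
      starts <- rbind(cbind(rs, logitd = stats::qlogis(0.5)),
                      cbind(rs, logitd = stats::qlogis(0.9)))
      o <- optimize_nll(function(par)
        nll_detect(exp(par[1]), exp(par[2]), stats::plogis(par[3]), st),
        starts, lo = c(log(lower), log(lower), stats::qlogis(1e-6)),
        up = c(log(upper), log(upper), stats::qlogis(1 - 1e-9)),
        reltol = reltol)
      dd <- stats::plogis(o$par[3])
    } else {
      stopifnot(fixed_d > 0, fixed_d <= 1)
      o <- optimize_nll(function(par)
        nll_detect(exp(par[1]), exp(par[2]), fixed_d, st),
        rs, lo = log(c(lower, lower)), up = log(c(upper, upper)),
        reltol = reltol)
      dd <- fixed_d
    }
    cc <- exp(o$par[1])
    ee <- exp(o$par[2])
    near <- function(x) x <= lower[1] * (1 + 1e-6) ||
      x >= upper[1] * (1 - 1e-6)
    data.frame(group = g, c = cc, e = ee, k = cc / ee,
               persistence = 1 / ee, d = dd,
               loglik = -nll_detect(cc, ee, dd, st),
               n_transitions = n_pairs,
               converged = o$convergence == 0,
               boundary = near(cc) || near(ee))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("group_rates", class(out))
  out
}
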