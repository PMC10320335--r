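## Core/satellite partitioning of a community via a structural break
## (Chow test) in the occupancy vs log10 maximum-abundance relation,
## plus a lognormal rank-abundance fit for the core.

#' Per-taxon occupancy and maximum abundance
#'
#' Occupancy is the fraction of samples (pooled over sites and
#' replicates) in which a taxon was detected — the empirical probability
#' that the taxon appears in the community over time. Maximum abundance
#' is the largest observed count. Taxa never detected are dropped with a
#' warning.
#'
#' @param series a \code{\link{presence_series}} carrying counts.
#' @return A data frame with columns \code{taxon, occupancy,
#'   max_abundance, log10_max_abundance}.
#' @export
occupancy_abundance <- function(series) {
  stopifnot(inherits(series, "presence_series"))
  if (any(vapply(series$sites, function(s) is.null(s$counts), TRUE)))
    stop("all sites must carry counts to compute maximum abundances")
  det_n <- 0
  det_tot <- 0
  maxab <- rep(0, length(series$taxa))
  for (s in series$sites) {
    d <- s$detections
    det_n <- det_n + apply(d, 1L, sum)
    det_tot <- det_tot + prod(dim(d)[2:3])
    maxab <- pmax(maxab, apply(s$counts, 1L, max))
  }
  occ <- det_n / det_tot
  keep <- occ > 0
  if (any(!keep))
    warning(sum(!keep), " never-detected taxa dropped from the ",
            "occupancy-abundance table")
  data.frame(taxon = series$taxa[keep], occupancy = occ[keep],
             max_abundance = maxab[keep],
             log10_max_abundance = log10(maxab[keep]),
             row.names = NULL)
}

segment_rss <- function(x, y) {
  if (diff(range(x)) == 0)
    stop("degenerate segment: constant predictor")
  sum(stats::resid(stats::lm(y ~ x))^2)
}

#' Chow F statistic for a structural break in a linear relation
#'
#' Tests whether the simple linear regressions on the two sides of a
#' candidate breakpoint differ from a single pooled regression:
#' \deqn{F = \frac{(RSS_{pooled} - RSS_1 - RSS_2)/2}
#'            {(RSS_1 + RSS_2)/(n_1 + n_2 - 4)}.}
#'
#' @param x predictor, sorted ascending.
#' @param y response, aligned with \code{x}.
#' @param break_index last index of the left segment (the break lies
#'   between \code{break_index} and \code{break_index + 1}). Both
#'   segments need at least 3 points.
#' @return The F statistic (possibly \code{Inf} when both segments fit
#'   exactly), with 2 and \eqn{n - 4} degrees of freedom.
#' @export
chow_statistic <- function(x, y, break_index) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.unsorted(x)) stop("'x' must be sorted ascending")
  if (break_index < 3L || break_index > n - 3L)
    stop("both segments need at least 3 points")
  i1 <- seq_len(break_index)
  i2 <- (break_index + 1L):n
  rss1 <- segment_rss(x[i1], y[i1])
  rss2 <- segment_rss(x[i2], y[i2])
  rssp <- segment_rss(x, y)
  num <- (rssp - rss1 - rss2) / 2
  den <- (rss1 + rss2) / (n - 4)
  ## numerically exact fits: a perfect single line means no break (F = 0);
  ## perfect segments around a real kink mean unbounded evidence
  eps <- 1e-12 * max(sum((y - mean(y))^2), 1)
  if (den <= eps) return(if (num <= eps) 0 else Inf)
  max(num / den, 0)
}

#' Split a community into core and satellite taxa
#'
#' Scans all intermediate breakpoints of the occupancy vs log10 maximum
#' abundance relation (points ordered by occupancy, a trimming margin
#' excluded at both ends), computes the Chow F statistic at each, and
#' takes the break with the largest statistic. The occupancy threshold
#' is the mean occupancy of the two points flanking the chosen break
#' (optionally of the two fitted regression-line ends), and taxa with
#' occupancy strictly above the threshold are labelled core, the rest
#' satellite. If no candidate exceeds the F critical value at
#' \code{alpha}, the scan is returned flagged "no significant break"
#' and no labels are assigned.
#'
#' @param table an \code{\link{occupancy_abundance}} data frame (>= 10
#'   taxa, >= 2 distinct occupancy values).
#' @param trim fraction of points (minimum 3) excluded at each end of
#'   the ordering when proposing breakpoints.
#' @param alpha significance level for the break (F with 2 and n - 4 df).
#' @param order_by ordering/predictor variable of the scan:
#'   \code{"occupancy"} (default) or \code{"abundance"} (log10 maximum
#'   abundance).
#' @param threshold_from \code{"observed"} (default): mean occupancy of
#'   the two flanking data points; \code{"fitted"}: mean of the two
#'   segment regression lines evaluated at their facing ends.
#' @return An object of class \code{"chow_scan"}: list with the ordered
#'   \code{data}, \code{candidates} and their \code{F} values,
#'   \code{best_index}, \code{F_max}, \code{F_crit}, \code{significant},
#'   \code{occupancy_threshold} and \code{labels} (named character
#'   vector, or NULL when no significant break).
#' @export
split_core_satellite <- function(table, trim = 0.1, alpha = 0.05,
                                 order_by = c("occupancy", "abundance"),
                                 threshold_from = c("observed", "fitted")) {
  order_by <- match.arg(order_by)
  threshold_from <- match.arg(threshold_from)
  stopifnot(is.data.frame(table),
            all(c("taxon", "occupancy", "log10_max_abundance") %in%
                  names(table)))
  n <- nrow(table)
  if (n < 10L) stop("need at least 10 taxa to scan for a break")
  if (length(unique(table$occupancy)) < 2L)
    stop("all occupancies identical; no break to find")
  xvar <- if (order_by == "occupancy") "occupancy" else
    "log10_max_abundance"
  yvar <- if (order_by == "occupancy") "log10_max_abundance" else
    "occupancy"
  ## stable ordering: ties in the predictor broken by taxon id
  ord <- order(table[[xvar]], table$taxon)
  tab <- table[ord, , drop = FALSE]
  rownames(tab) <- NULL
  x <- tab[[xvar]]
  y <- tab[[yvar]]
  margin <- max(3L, ceiling(trim * n))
  cand <- seq.int(margin, n - margin)
  if (!length(cand)) stop("too few points left after trimming")
  Fs <- vapply(cand, function(i)
    tryCatch(chow_statistic(x, y, i), error = function(e) NA_real_),
    1)
  if (all(is.na(Fs))) stop("no admissible breakpoint (degenerate segments)")
  F_max <- max(Fs, na.rm = TRUE)
  ## near-ties resolve to the lowest-occupancy candidate
  tied <- if (is.infinite(F_max)) which(is.infinite(Fs) & Fs > 0)
          else which(!is.na(Fs) & Fs >= F_max - 1e-9 * max(1, abs(F_max)))
  best <- tied[1]
  i <- cand[best]
  F_crit <- stats::qf(1 - alpha, 2, n - 4)
  significant <- is.finite(F_crit) && F_max >= F_crit
  threshold <- NA_real_
  labels <- NULL
  if (significant) {
    if (threshold_from == "observed") {
      threshold <- mean(tab$occupancy[c(i, i + 1L)])
    } else {
      ## mean of the two regression lines evaluated at their facing
      ## ends, on the occupancy axis. When occupancy is the predictor
      ## the line ends sit at the observed occupancies, so the fitted
      ## and observed interpretations coincide.
      if (order_by == "occupancy") {
        threshold <- mean(tab$occupancy[c(i, i + 1L)])
      } else {
        fit_end <- function(ix, at) unname(stats::predict(
          stats::lm(occ ~ xx, data = data.frame(occ = tab$occupancy[ix],
                                                xx = x[ix])),
          newdata = data.frame(xx = at)))
        threshold <- mean(c(fit_end(seq_len(i), x[i]),
                            fit_end((i + 1L):n, x[i + 1L])))
      }
    }
    labels <- ifelse(table$occupancy > threshold, "core", "satellite")
    names(labels) <- table$taxon
  }
  structure(list(data = tab, order_by = order_by,
                 candidates = cand, F = Fs, best_index = i,
                 F_max = F_max, F_crit = F_crit,
                 significant = significant,
                 occupancy_threshold = threshold, labels = labels),
            class = "chow_scan")
}

#' @export
print.chow_scan <- function(x, ...) {
  cat(sprintf(
    "Chow structural-break scan (ordered by %s): %d points, %d candidates\n",
    x$order_by, nrow(x$data), length(x$candidates)))
  cat(sprintf("  max F = %.3f at index %d (critical value %.3f)\n",
              x$F_max, x$best_index, x$F_crit))
  if (x$significant) {
    cat(sprintf("  occupancy threshold = %.4f; %d core / %d satellite\n",
                x$occupancy_threshold, sum(x$labels == "core"),
                sum(x$labels == "satellite")))
  } else {
    cat("  no significant break\n")
  }
  invisible(x)
}

#' Lognormal rank-abundance fit for the community core
#'
#' Fits the lognormal rank-abundance model of Preston type, as
#' implemented by \code{vegan::rad.lognormal}: expected abundance
#' \eqn{\exp(a + b\,z_r)} with \eqn{z_r} the standard normal quantile of
#' the scaled rank, estimated by a Poisson log-link generalized linear
#' model. The residual deviance measures how closely the core follows a
#' lognormal abundance distribution.
#'
#' @param abundances positive abundances (>= 5 taxa, all >= 1).
#' @return A list of class \code{"lognormal_rad_fit"}: \code{intercept}
#'   (log.mu), \code{scale} (log.sigma), \code{deviance}, \code{n},
#'   \code{fitted} (decreasing in rank) and the underlying vegan
#'   \code{rad} object.
#' @export
lognormal_rad_fit <- function(abundances) {
  abundances <- as.numeric(abundances)
  if (length(abundances) < 5L)
    stop("need at least 5 taxa for a rank-abundance fit")
  if (any(abundances < 1)) stop("all abundances must be >= 1")
  fit <- vegan::rad.lognormal(abundances)
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf["log.mu"]),
                 scale = unname(cf["log.sigma"]),
                 deviance = stats::deviance(fit),
                 n = length(abundances),
                 fitted = sort(unname(stats::fitted(fit)),
                               decreasing = TRUE),
                 rad = fit),
            class = "lognormal_rad_fit")
}

#' @export
print.lognormal_rad_fit <- function(x, ...) {
  cat(sprintf(
    "Lognormal rank-abundance fit: n = %d, log.mu = %.3f, log.sigma = %.3f\n",
    x$n, x$intercept, x$scale))
  cat(sprintf("  residual deviance = %.4g\n", x$deviance))
  invisible(x)
}
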