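## Quantifying the colonization-persistence relationship: log-log
## regression, Spearman correlation, the slope = -1 fitness-equalization
## test, core-vs-satellite slope equality, and taxonomic coherence.

#' Log-log regression of persistence on colonization
#'
#' Ordinary least squares of \eqn{\log p} on \eqn{\log c} (natural logs;
#' the slope is base- and time-unit-invariant), with the t-based 95%
#' confidence interval of the slope and the Spearman rank correlation of
#' \eqn{(c, p)}. Under fitness equalization the expected slope is -1 and
#' the intercept is \eqn{K = \log k}.
#'
#' @param c colonization rates (> 0).
#' @param p persistence values (> 0), aligned with \code{c}.
#' @param component label for the point set (e.g. "all", "core",
#'   "satellite").
#' @param level optional taxonomic level label.
#' @param conf confidence level for the slope interval.
#' @return An object of class \code{"tradeoff_fit"}: slope, intercept,
#'   slope SE, CI, Spearman rho and p-value, n, and the log-scale data.
#' @examples
#' cc <- exp(seq(log(0.01), log(1), length.out = 50))
#' loglog_tradeoff_fit(cc, 2 / cc)$slope   # exactly -1
#' @export
loglog_tradeoff_fit <- function(c, p, component = "all", level = NA_character_,
                                conf = 0.95) {
  bad <- !is.finite(c) | !is.finite(p) | c <= 0 | p <= 0
  if (any(bad))
    stop("non-positive or non-finite rate pairs at positions: ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  n <- length(c)
  if (length(p) != n) stop("'c' and 'p' must have equal length")
  if (n < 3L) stop("need at least 3 points")
  x <- log(c)
  y <- log(p)
  fit <- stats::lm(y ~ x)
  ## exactly collinear input is legitimate here (noiseless trade-off
  ## curves); the degenerate SE = 0 case is handled downstream
  suppressWarnings({
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit, "x", level = conf)
  })
  suppressWarnings(ct <- stats::cor.test(c, p, method = "spearman",
                                         exact = n < 10))
  structure(list(component = component, level = level, n = n,
                 slope = unname(sm["x", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 slope_se = unname(sm["x", "Std. Error"]),
                 ci = unname(ci[1, ]), conf = conf,
                 rho = unname(ct$estimate), rho_p = ct$p.value,
                 logc = x, logp = y, lm = fit),
            class = "tradeoff_fit")
}

#' @export
print.tradeoff_fit <- function(x, ...) {
  cat(sprintf(
    "Colonization-persistence trade-off (%s%s): n = %d\n",
    x$component,
    if (is.na(x$level)) "" else paste0(", ", x$level), x$n))
  cat(sprintf("  log-log slope = %.4f  (%d%% CI %.4f, %.4f; SE %.4f)\n",
              x$slope, round(100 * x$conf), x$ci[1], x$ci[2], x$slope_se))
  cat(sprintf("  intercept K = %.4f (k = %.4g under slope -1)\n",
              x$intercept, exp(x$intercept)))
  cat(sprintf("  Spearman rho = %.4f (p = %.3g)\n", x$rho, x$rho_p))
  invisible(x)
}

#' @export
as.data.frame.tradeoff_fit <- function(x, ...) {
  data.frame(component = x$component, level = x$level, n = x$n,
             slope = x$slope, lower_ci = x$ci[1], upper_ci = x$ci[2],
             slope_se = x$slope_se, intercept = x$intercept,
             rho = x$rho, rho_p = x$rho_p)
}

#' Test whether a trade-off slope equals a hypothesized value
#'
#' Student t-test of the fitted log-log slope against a reference value
#' (default -1, the fitness-equalization prediction):
#' \eqn{t = (\hat\beta - \beta_0)/SE}, df \eqn{= n - 2}, two-sided p.
#'
#' @param fit a \code{\link{loglog_tradeoff_fit}} result with n >= 4.
#' @param value hypothesized slope.
#' @return A list with \code{t}, \code{df}, \code{p} and
#'   \code{degenerate} (TRUE when the points are perfectly collinear so
#'   SE = 0; p is then 1 or 0 by exact equality).
#' @export
test_slope_equals <- function(fit, value = -1) {
  stopifnot(inherits(fit, "tradeoff_fit"))
  if (fit$n < 4L) stop("need at least 4 points to test the slope")
  df <- fit$n - 2L
  if (fit$slope_se <= .Machine$double.eps * max(1, abs(fit$slope))) {
    equal <- isTRUE(all.equal(fit$slope, value, tolerance = 1e-12))
    return(list(t = if (equal) 0 else sign(fit$slope - value) * Inf,
                df = df, p = as.numeric(equal), degenerate = TRUE))
  }
  t <- (fit$slope - value) / fit$slope_se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Compare the trade-off slopes of two components
#'
#' Tests slope equality between two point sets (e.g. core vs satellite)
#' with a Student t-test. The default pools both sets in a dummy-variable
#' regression \code{log p ~ log c * component} and tests the interaction
#' coefficient (df = n1 + n2 - 4); \code{method = "welch"} instead
#' combines the two separate standard errors with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param fit_a,fit_b \code{\link{loglog_tradeoff_fit}} results on
#'   disjoint point sets, each with n >= 4.
#' @param method \code{"pooled"} (default) or \code{"welch"}.
#' @param allow_overlap set TRUE to skip the disjointness check (e.g.
#'   for sanity checks on duplicated data).
#' @return An object of class \code{"slope_comparison"}: \code{t}
#'   (sign = sign of slope_a - slope_b), \code{df}, \code{p}, and the
#'   two fits.
#' @export
compare_slopes <- function(fit_a, fit_b, method = c("pooled", "welch"),
                           allow_overlap = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(fit_a, "tradeoff_fit"), inherits(fit_b, "tradeoff_fit"))
  if (fit_a$n < 4L || fit_b$n < 4L)
    stop("each component needs at least 4 points")
  if (!allow_overlap &&
      length(intersect(paste(fit_a$logc, fit_a$logp),
                       paste(fit_b$logc, fit_b$logp))))
    stop("the two point sets overlap; components must be disjoint")
  if (method == "pooled") {
    dat <- data.frame(
      x = c(fit_a$logc, fit_b$logc),
      y = c(fit_a$logp, fit_b$logp),
      g = rep(c(0, 1), c(fit_a$n, fit_b$n)))
    fit <- stats::lm(y ~ x * g, data = dat)
    sm <- summary(fit)$coefficients
    ## interaction = slope_b - slope_a; flip so sign(t) = sign(a - b)
    t <- -unname(sm["x:g", "t value"])
    df <- fit_a$n + fit_b$n - 4L
  } else {
    se <- sqrt(fit_a$slope_se^2 + fit_b$slope_se^2)
    t <- (fit_a$slope - fit_b$slope) / se
    df <- se^4 / (fit_a$slope_se^4 / (fit_a$n - 2) +
                    fit_b$slope_se^4 / (fit_b$n - 2))
  }
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 method = method, fit_a = fit_a, fit_b = fit_b),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "Slope equality test (%s vs %s, %s): t = %.3f, df = %.1f, p = %.3g\n",
    x$fit_a$component, x$fit_b$component, x$method, x$t, x$df, x$p))
  invisible(x)
}

#' Taxonomic coherence of colonization-extinction strategies
#'
#' Asks whether taxa in the same higher-rank group sit closer together in
#' the \eqn{(\log_{10} c, \log_{10} p)} plane than taxa from different
#' groups: Euclidean pairwise distances are classified as intra- or
#' inter-group and the two distance samples are compared by a
#' Kruskal-Wallis test.
#'
#' @param c,p rate/persistence vectors (> 0), one entry per taxon.
#' @param groups higher-rank group labels aligned with \code{c}; at
#'   least 2 groups with >= 2 members each.
#' @return A list with \code{H} (the Kruskal-Wallis statistic),
#'   \code{p}, \code{n_intra}, \code{n_inter} and the two distance
#'   vectors.
#' @export
taxonomic_coherence <- function(c, p, groups) {
  stopifnot(length(c) == length(p), length(groups) == length(c))
  if (any(c <= 0 | p <= 0)) stop("rates must be strictly positive")
  groups <- as.character(groups)
  sizes <- table(groups)
  if (sum(sizes >= 2) < 2)
    stop("need at least 2 higher-rank groups with at least 2 members each")
  D <- as.matrix(stats::dist(cbind(log10(c), log10(p))))
  same <- outer(groups, groups, "==")
  ut <- upper.tri(D)
  intra <- D[ut & same]
  inter <- D[ut & !same]
  kw <- stats::kruskal.test(list(intra = intra, inter = inter))
  list(H = unname(kw$statistic), p = kw$p.value,
       n_intra = length(intra), n_inter = length(inter),
       intra = intra, inter = inter)
}

#' Spearman correlation before and after excluding taxa
#'
#' Supports exclusion re-analyses (e.g. dropping classes suspected to
#' contribute dormant spore-bank DNA): reports the Spearman correlation
#' of colonization and persistence on the full set and on the set with
#' the listed taxa removed.
#'
#' @param c,p rate/persistence vectors (> 0), named or accompanied by
#'   \code{taxa}.
#' @param taxa taxon ids aligned with \code{c}.
#' @param exclude character vector of taxon ids to drop (may be empty).
#' @return A list with \code{rho_before}, \code{rho_after},
#'   \code{p_after}, \code{n_before}, \code{n_after}.
#' @export
exclude_taxa_and_correlate <- function(c, p, taxa, exclude = character()) {
  stopifnot(length(c) == length(p), length(taxa) == length(c))
  keep <- !(taxa %in% exclude)
  if (sum(keep) < 3L) stop("fewer than 3 taxa left after exclusion")
  suppressWarnings({
    before <- stats::cor.test(c, p, method = "spearman",
                              exact = length(c) < 10)
    after <- stats::cor.test(c[keep], p[keep], method = "spearman",
                             exact = sum(keep) < 10)
  })
  list(rho_before = unname(before$estimate),
       rho_after = unname(after$estimate),
       p_after = after$p.value,
       n_before = length(c), n_after = sum(keep))
}
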