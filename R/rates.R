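#' Colonization/extinction rate pair
#'
#' Bundles a colonization rate and an extinction rate (both per day) with
#' the derived quantities used throughout the package: the
#' colonization-to-extinction ratio \eqn{k = c/e} (a dimensionless fitness
#' measure: the expected number of colonization events during one residence
#' time), the persistence \eqn{p = 1/e} (expected residence time in days)
#' and the stationary occupancy \eqn{\pi^* = c/(c+e) = k/(1+k)}.
#'
#' When \code{e = 0} the taxon never goes extinct; \code{k} and
#' \code{persistence} are then \code{Inf}.
#'
#' @param c colonization rate (per day, >= 0). May be a vector.
#' @param e extinction rate (per day, >= 0). Recycled against \code{c}.
#' @return An object of class \code{"rate_pair"}: a list with elements
#'   \code{c}, \code{e}, \code{k}, \code{persistence} and \code{pi_star}.
#' @examples
#' rp <- rate_pair(c = 0.2, e = 0.1)
#' rp$k          # 2
#' rp$pi_star    # 2/3
#' @export
rate_pair <- function(c, e) {
  if (any(c < 0) || any(e < 0))
    stop("rates must be non-negative")
  n <- max(length(c), length(e))
  c <- rep_len(as.numeric(c), n)
  e <- rep_len(as.numeric(e), n)
  k <- ifelse(e > 0, c / e, ifelse(c > 0, Inf, NaN))
  structure(
    list(
      c = c, e = e, k = k,
      persistence = ifelse(e > 0, 1 / e, Inf),
      pi_star = ifelse(c + e > 0, c / (c + e), NaN)
    ),
    class = "rate_pair"
  )
}

#' @export
print.rate_pair <- function(x, ...) {
  df <- data.frame(c = x$c, e = x$e, k = x$k,
                   persistence = x$persistence, pi_star = x$pi_star)
  cat("Colonization/extinction rate pair(s) [per day]:\n")
  print(df, ...)
  invisible(x)
}

#' Stationary occupancy of the two-state colonization-extinction model
#'
#' Probability that a taxon is present at equilibrium,
#' \eqn{\pi^* = c/(c+e) = k/(1+k)}.
#'
#' @param c colonization rate (per day), or a \code{\link{rate_pair}}.
#' @param e extinction rate (per day); ignored when \code{c} is a
#'   \code{rate_pair}.
#' @return Numeric vector of stationary occupancies in \[0, 1\].
#' @examples
#' stationary_occupancy(0.1, 0.1)  # 0.5
#' stationary_occupancy(0.2, 0.1)  # 2/3
#' @export
stationary_occupancy <- function(c, e) {
  if (inherits(c, "rate_pair")) {
    e <- c$e
    c <- c$c
  }
  if (any(c < 0) || any(e < 0)) stop("rates must be non-negative")
  if (any(c + e == 0))
    stop("stationary occupancy undefined when c = e = 0")
  c / (c + e)
}

## Vectorized transition probabilities, used in likelihoods; recycle
## over any of (c, e, dt). 1 - exp(-s dt) via expm1 for accuracy at
## small s*dt. The 0/0 case (c = e = 0) is the frozen chain: no
## colonization, certain persistence of the current state.
trans_p01 <- function(c, e, dt) {
  p <- -(c / (c + e)) * expm1(-(c + e) * dt)
  p[is.nan(p)] <- 0
  p
}

trans_p11 <- function(c, e, dt) {
  p <- (c + e * exp(-(c + e) * dt)) / (c + e)
  p[is.nan(p)] <- 1
  p
}

#' Transition probabilities over an arbitrary interval
#'
#' Closed-form solution of the two-state master equation
#' \eqn{d\pi/dt = c(1-\pi) - e\pi} over an interval of length \code{dt}:
#' \deqn{P(0 \to 1) = \frac{c}{c+e}\left(1 - e^{-(c+e)\Delta t}\right),
#'   \quad P(1 \to 1) = \frac{c + e\,e^{-(c+e)\Delta t}}{c+e}.}
#' Irregular sampling designs are handled by evaluating this matrix at each
#' observed inter-sample interval.
#'
#' @param c colonization rate (per day), or a \code{\link{rate_pair}}.
#' @param e extinction rate (per day).
#' @param dt interval length in days (scalar, >= 0). \code{dt = 0} gives
#'   the identity matrix.
#' @return A 2 x 2 row-stochastic matrix of class
#'   \code{"transition_matrix"} with dimnames
#'   \code{c("absent", "present")} and attribute \code{dt}.
#' @examples
#' transition_probabilities(1, 1, log(2))["absent", "present"]  # 0.375
#' @export
transition_probabilities <- function(c, e, dt) {
  if (inherits(c, "rate_pair")) {
    dt <- e
    e <- c$e
    c <- c$c
  }
  if (length(c) != 1L || length(e) != 1L || length(dt) != 1L)
    stop("'c', 'e' and 'dt' must be scalars")
  if (any(c < 0) || any(e < 0)) stop("rates must be non-negative")
  if (is.na(dt) || dt < 0) stop("'dt' must be a non-negative number of days")
  if (dt > 0 && c + e == 0)
    stop("c + e must be positive when dt > 0")
  if (dt == 0) {
    p01 <- 0
    p11 <- 1
  } else {
    p01 <- trans_p01(c, e, dt)
    p11 <- trans_p11(c, e, dt)
  }
  m <- matrix(c(1 - p01, 1 - p11, p01, p11), nrow = 2,
              dimnames = list(from = c("absent", "present"),
                              to = c("absent", "present")))
  structure(m, dt = dt, class = c("transition_matrix", class(m)))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition probabilities over dt = %g days:\n",
              attr(x, "dt")))
  print(unclass(x), ...)
  invisible(x)
}

#' Colonization-persistence trade-off curve
#'
#' A generic trade-off \eqn{p = k\,c^{\alpha}} with exponent
#' \eqn{\alpha < 0}. Fitness equalization (all taxa sharing the same
#' colonization-to-extinction ratio \eqn{k}) corresponds to
#' \eqn{\alpha = -1}, for which \eqn{p \cdot c = k} everywhere on the
#' curve and \eqn{\log p = K - \log c} with intercept \eqn{K = \log k}.
#'
#' @param k equalized fitness constant (> 0).
#' @param alpha trade-off exponent (default -1).
#' @return An object of class \code{"tradeoff_curve"} with elements
#'   \code{k}, \code{alpha} and \code{K} (\eqn{= \log k}, natural log).
#' @seealso \code{\link{tradeoff_persistence}}
#' @export
tradeoff_curve <- function(k, alpha = -1) {
  if (length(k) != 1L || k <= 0) stop("'k' must be a positive scalar")
  if (length(alpha) != 1L || !is.finite(alpha))
    stop("'alpha' must be a finite scalar")
  structure(list(k = k, alpha = alpha, K = log(k)),
            class = "tradeoff_curve")
}

#' Persistence implied by a trade-off curve
#'
#' Evaluates \eqn{p = k\,c^{\alpha}} at colonization rate(s) \code{c}.
#'
#' @param curve a \code{\link{tradeoff_curve}}.
#' @param c colonization rate(s), strictly positive.
#' @return Persistence value(s) in days.
#' @examples
#' tradeoff_persistence(tradeoff_curve(k = 2), c = 0.5)  # 4
#' @export
tradeoff_persistence <- function(curve, c) {
  if (!inherits(curve, "tradeoff_curve"))
    stop("'curve' must be a tradeoff_curve")
  if (any(c <= 0)) stop("colonization rates must be strictly positive")
  curve$k * c^curve$alpha
}
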