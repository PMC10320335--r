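## AIC-based comparison of site-partition models: which sites share a
## single colonization/extinction pair?

#' Enumerate all set partitions of a site list
#'
#' Generates every way of grouping the sites into non-empty blocks, in
#' canonical order (blocks ordered by their smallest member; partitions
#' in restricted-growth order). Guarded against combinatorial explosion
#' at n > 12 sites (Bell(12) = 4,213,597).
#'
#' @param sites character vector of site labels (1 to 12, unique).
#' @return A list of partitions; each partition is a list of character
#'   vectors (the blocks).
#' @examples
#' length(enumerate_partitions(c("a", "b", "c")))   # Bell(3) = 5
#' @export
enumerate_partitions <- function(sites) {
  n <- length(sites)
  if (n < 1L) stop("need at least one site")
  if (anyDuplicated(sites)) stop("site labels must be unique")
  if (n > 12L)
    stop("refusing to enumerate all partitions of more than 12 sites ",
         "(Bell number too large); supply an explicit model set instead")
  parts <- list(list(1L))
  if (n > 1L) {
    for (i in 2:n) {
      nxt <- list()
      for (p in parts) {
        for (b in seq_along(p)) {
          q <- p
          q[[b]] <- c(q[[b]], i)
          nxt[[length(nxt) + 1L]] <- q
        }
        nxt[[length(nxt) + 1L]] <- c(p, list(i))
      }
      parts <- nxt
    }
  }
  lapply(parts, function(p) lapply(p, function(ix) sites[ix]))
}

#' Format a partition as a compact string
#'
#' @param partition a list of character vectors (blocks).
#' @return A string like \code{"\{a,b\}|\{c\}"}.
#' @export
format_partition <- function(partition) {
  paste(vapply(partition, function(b)
    paste0("{", paste(b, collapse = ","), "}"), ""), collapse = "|")
}

#' Akaike weights for a set of models
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min_j AIC_j}.
#'
#' @param aic numeric vector of AIC values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit every site-partition model and compare by AIC
#'
#' For each candidate partition of the sites, each block is fitted as a
#' single community-wide colonization/extinction pair (jointly over all
#' taxa and the block's sites), giving a model with 2 parameters per
#' block. Models are compared by AIC (optionally AICc) and Akaike
#' weights over the supplied model set.
#'
#' @param series a multi-site \code{\link{presence_series}}.
#' @param partitions an explicit list of partitions (as produced by
#'   \code{\link{enumerate_partitions}}); default: all partitions of the
#'   series' sites.
#' @param criterion \code{"AIC"} (default) or \code{"AICc"} (small-sample
#'   correction using the total number of transition pairs).
#' @param ... passed to \code{\link{fit_rates}}.
#' @return An object of class \code{"partition_fits"}: a list with
#'   \code{table} (one row per model: partition, n_blocks, loglik,
#'   n_params, AIC, dAIC, weight), \code{models} (per-model list of the
#'   partition and its per-block \code{group_rates}) and
#'   \code{criterion}.
#' @export
fit_partition_models <- function(series, partitions = NULL,
                                 criterion = c("AIC", "AICc"), ...) {
  stopifnot(inherits(series, "presence_series"))
  criterion <- match.arg(criterion)
  if (is.null(partitions))
    partitions <- enumerate_partitions(names(series$sites))
  models <- lapply(partitions, function(p) {
    blocks <- lapply(p, function(block) {
      sub <- subset_series(series, sites = block)
      fit <- tryCatch(
        fit_rates(sub, grouping = format_partition(list(block)), ...),
        error = function(err) stop(
          "partition ", format_partition(p), ", block ",
          format_partition(list(block)), ": ", conditionMessage(err),
          call. = FALSE))
      fit
    })
    blocks <- do.call(rbind, blocks)
    loglik <- sum(blocks$loglik)
    npar <- 2L * length(p)
    ntr <- sum(blocks$n_transitions)
    aic <- 2 * npar - 2 * loglik
    if (criterion == "AICc")
      aic <- aic + 2 * npar * (npar + 1) / (ntr - npar - 1)
    list(partition = p, blocks = blocks, loglik = loglik,
         n_params = npar, aic = aic)
  })
  tab <- data.frame(
    partition = vapply(models, function(m) format_partition(m$partition), ""),
    n_blocks = vapply(models, function(m) length(m$partition), 1L),
    loglik = vapply(models, `[[`, 1, "loglik"),
    n_params = vapply(models, `[[`, 1L, "n_params"),
    AIC = vapply(models, `[[`, 1, "aic"))
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$weight <- akaike_weights(tab$AIC)
  structure(list(table = tab, models = models, criterion = criterion),
            class = "partition_fits")
}

#' @export
print.partition_fits <- function(x, ...) {
  cat(sprintf("Site-partition model comparison (%s), %d models:\n",
              x$criterion, nrow(x$table)))
  tab <- x$table[order(x$table$AIC), ]
  print(tab, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Summed weight of evidence for a class of partitions
#'
#' Adds up the Akaike weights of every model whose partition satisfies a
#' predicate, e.g. "groups at least two of the three same-basin lakes".
#'
#' @param fits a \code{\link{fit_partition_models}} result.
#' @param predicate a function taking one partition (list of character
#'   blocks) and returning TRUE/FALSE.
#' @return The summed weight, in \[0, 1\].
#' @examples
#' \dontrun{
#' evidence_for(fits, function(p)
#'   any(vapply(p, function(b) sum(b %in% basin_lakes) >= 2, TRUE)))
#' }
#' @export
evidence_for <- function(fits, predicate) {
  stopifnot(inherits(fits, "partition_fits"), is.function(predicate))
  if (!length(fits$models)) stop("empty model set")
  sel <- vapply(fits$models, function(m)
    isTRUE(predicate(m$partition)), TRUE)
  sum(fits$table$weight[sel])
}
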