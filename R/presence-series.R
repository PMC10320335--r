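#' Presence-absence time series for a set of taxa
#'
#' The central data container: binary detections of taxa at ordered,
#' possibly irregularly spaced sampling times, optionally with replicated
#' surveys per time point and with the underlying counts. A series may
#' span several sites (datasets); all sites share the taxon set but each
#' has its own sampling times and replicate structure.
#'
#' @param detections a taxa x times binary matrix, or a taxa x times x
#'   replicates binary array. Row names, if present, are taxon ids.
#' @param times numeric vector of sampling times in days, strictly
#'   increasing, one per column of \code{detections}.
#' @param taxa optional character vector of taxon ids (defaults to row
#'   names or \code{"t1"..."tS"}).
#' @param counts optional non-negative integer matrix/array of the same
#'   shape as \code{detections}; where supplied, detection must equal
#'   \code{counts > 0}.
#' @param site site label for this block of samples.
#' @return An object of class \code{"presence_series"}.
#' @examples
#' det <- rbind(a = c(1, 1, 0, 1), b = c(0, 1, 1, 1))
#' ps <- presence_series(det, times = c(0, 30, 45, 120))
#' ps
#' @export
presence_series <- function(detections, times, taxa = NULL, counts = NULL,
                            site = "site1") {
  if (is.matrix(detections))
    detections <- array(detections, dim = c(dim(detections), 1L),
                        dimnames = c(dimnames(detections), list(NULL)))
  if (!is.array(detections) || length(dim(detections)) != 3L)
    stop("'detections' must be a matrix or a 3-d array")
  S <- dim(detections)[1L]
  Tn <- dim(detections)[2L]
  if (is.null(taxa)) taxa <- dimnames(detections)[[1L]]
  if (is.null(taxa)) taxa <- paste0("t", seq_len(S))
  if (anyDuplicated(taxa)) stop("taxon ids must be unique")
  if (length(taxa) != S) stop("length of 'taxa' does not match 'detections'")
  if (length(times) != Tn)
    stop("length of 'times' does not match the number of sample columns")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing within a site")
  if (!all(detections %in% c(0, 1)))
    stop("'detections' must be binary (0/1)")
  if (!is.null(counts)) {
    if (is.matrix(counts))
      counts <- array(counts, dim = c(dim(counts), 1L))
    if (!identical(dim(counts), dim(detections)))
      stop("'counts' must have the same shape as 'detections'")
    if (any(counts < 0) || any(counts != round(counts)))
      stop("'counts' must be non-negative integers")
    if (!all((counts > 0) == (detections == 1)))
      stop("detection must be 1 exactly where the aligned count is > 0")
  }
  dimnames(detections) <- list(taxa, NULL, NULL)
  sites <- list(list(times = as.numeric(times), detections = detections,
                     counts = counts))
  names(sites) <- site
  structure(list(taxa = taxa, sites = sites), class = "presence_series")
}

#' Combine single-site series into a multi-site series
#'
#' @param ... \code{presence_series} objects sharing the same taxon set,
#'   each with distinct site names.
#' @return A multi-site \code{presence_series}.
#' @export
combine_sites <- function(...) {
  pieces <- list(...)
  if (length(pieces) == 1L && is.list(pieces[[1L]]) &&
      !inherits(pieces[[1L]], "presence_series"))
    pieces <- pieces[[1L]]
  stopifnot(length(pieces) >= 1L,
            all(vapply(pieces, inherits, TRUE, "presence_series")))
  taxa <- pieces[[1L]]$taxa
  for (p in pieces)
    if (!identical(p$taxa, taxa))
      stop("all series must share an identical taxon set")
  sites <- do.call(c, lapply(pieces, `[[`, "sites"))
  if (anyDuplicated(names(sites))) stop("duplicated site names")
  structure(list(taxa = taxa, sites = sites), class = "presence_series")
}

#' @export
print.presence_series <- function(x, ...) {
  nrep <- vapply(x$sites, function(s) dim(s$detections)[3L], 1L)
  cat(sprintf(
    "presence_series: %d taxa, %d site(s)\n", length(x$taxa),
    length(x$sites)))
  for (nm in names(x$sites)) {
    s <- x$sites[[nm]]
    cat(sprintf(
      "  %s: %d samples over days %g-%g, %d replicate(s)%s\n", nm,
      length(s$times), min(s$times), max(s$times),
      dim(s$detections)[3L],
      if (is.null(s$counts)) "" else ", with counts"))
  }
  invisible(x)
}

#' Subset a presence series by taxa or sites
#'
#' @param x a \code{presence_series}.
#' @param taxa,sites character vectors of ids to keep (NULL = keep all).
#' @return A \code{presence_series}.
#' @export
subset_series <- function(x, taxa = NULL, sites = NULL) {
  stopifnot(inherits(x, "presence_series"))
  if (!is.null(sites)) {
    if (!all(sites %in% names(x$sites)))
      stop("unknown site(s): ",
           paste(setdiff(sites, names(x$sites)), collapse = ", "))
    x$sites <- x$sites[sites]
  }
  if (!is.null(taxa)) {
    if (!all(taxa %in% x$taxa))
      stop("unknown taxon id(s): ",
           paste(utils::head(setdiff(taxa, x$taxa), 5), collapse = ", "))
    idx <- match(taxa, x$taxa)
    x$taxa <- x$taxa[idx]
    x$sites <- lapply(x$sites, function(s) {
      s$detections <- s$detections[idx, , , drop = FALSE]
      if (!is.null(s$counts)) s$counts <- s$counts[idx, , , drop = FALSE]
      s
    })
  }
  x
}

## Any-replicate detection as a taxa x times binary matrix.
collapse_detections <- function(site_entry) {
  d <- site_entry$detections
  if (dim(d)[3L] == 1L) {
    out <- d[, , 1L, drop = FALSE]
    dim(out) <- dim(d)[1:2]
  } else {
    out <- apply(d, c(1, 2), max)
  }
  rownames(out) <- dimnames(d)[[1L]]
  out
}

#' Collapse replicated surveys to any-replicate detection
#'
#' Replicates at a time point are merged: a taxon is detected if any
#' replicate detected it; counts, if present, are summed.
#'
#' @param x a \code{presence_series}.
#' @return A \code{presence_series} with one replicate everywhere.
#' @export
collapse_replicates <- function(x) {
  stopifnot(inherits(x, "presence_series"))
  x$sites <- lapply(x$sites, function(s) {
    det <- collapse_detections(s)
    if (!is.null(s$counts)) {
      cnt <- apply(s$counts, c(1, 2), sum)
      s$counts <- array(cnt, dim = c(dim(cnt), 1L))
    }
    s$detections <- array(det, dim = c(dim(det), 1L),
                          dimnames = list(rownames(det), NULL, NULL))
    s
  })
  x
}

#' Minimal inter-sample interval of a series
#'
#' The smallest time gap between consecutive samples across all sites, in
#' days. Used as the reference interval for the labile-taxon filter.
#'
#' @param x a \code{presence_series}.
#' @return A positive scalar (days).
#' @export
min_sampling_interval <- function(x) {
  stopifnot(inherits(x, "presence_series"))
  min(vapply(x$sites, function(s)
    if (length(s$times) > 1L) min(diff(s$times)) else Inf, 1))
}

#' True rates attached to a simulated series
#'
#' @param x a simulated \code{presence_series}.
#' @return The generator's truth table (data frame), or NULL.
#' @export
true_rates <- function(x) attr(x, "truth")

max_replicates <- function(x)
  max(vapply(x$sites, function(s) dim(s$detections)[3L], 1L))
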