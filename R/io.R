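## Readers/writers and validation for the TSV/CSV dataset trio:
## counts (taxa x samples), sample metadata (sample, time, site,
## replicate) and taxonomy (taxon, phylum ... genus).

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

TAX_RANKS <- c("phylum", "class", "order", "family", "genus")

#' Read and validate a community dataset
#'
#' Loads the three tables the pipeline consumes — a counts table, a
#' sample-metadata table and a taxonomy table — cross-validates them and
#' returns a \code{"community_dataset"}. The counts table's first column
#' holds taxon ids (or sample ids with \code{taxa_as_rows = FALSE});
#' metadata needs columns \code{sample}, \code{time} (days, numeric) and
#' \code{site}, with an optional \code{replicate}.
#'
#' @param counts_file,metadata_file,taxonomy_file paths; \code{.tsv} is
#'   read tab-separated, anything else comma-separated.
#' @param taxa_as_rows orientation of the counts table (no guessing).
#' @return A list of class \code{"community_dataset"}: \code{counts}
#'   (taxa x samples integer matrix), \code{metadata}, \code{taxonomy},
#'   \code{validation} (flags, e.g. taxa without a taxonomy row).
#' @export
read_dataset <- function(counts_file, metadata_file, taxonomy_file,
                         taxa_as_rows = TRUE) {
  counts <- read_table_auto(counts_file)
  metadata <- read_table_auto(metadata_file)
  taxonomy <- read_table_auto(taxonomy_file)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- as.character(counts[[1]])
  if (!taxa_as_rows) m <- t(m)
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers with no missing values")
  community_dataset(m, metadata, taxonomy)
}

#' Assemble a community dataset from in-memory tables
#'
#' @param counts taxa x samples matrix with dimnames.
#' @param metadata data frame with columns sample, time, site and
#'   optionally replicate.
#' @param taxonomy data frame with a \code{taxon} column and taxonomic
#'   rank columns (phylum ... genus).
#' @return A \code{"community_dataset"}.
#' @export
community_dataset <- function(counts, metadata, taxonomy) {
  need <- setdiff(c("sample", "time", "site"), names(metadata))
  if (length(need))
    stop("metadata is missing column(s): ", paste(need, collapse = ", "))
  if (!"replicate" %in% names(metadata)) metadata$replicate <- 1L
  metadata$sample <- as.character(metadata$sample)
  if (!is.numeric(metadata$time))
    stop("metadata 'time' must be numeric (days)")
  missing_meta <- setdiff(colnames(counts), metadata$sample)
  if (length(missing_meta))
    stop("samples present in counts but missing from metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  dup <- duplicated(metadata[c("site", "time", "replicate")])
  if (any(dup))
    stop("duplicate (site, time, replicate) metadata rows: ",
         paste(utils::head(metadata$sample[dup], 5), collapse = ", "))
  if (!"taxon" %in% names(taxonomy))
    stop("taxonomy needs a 'taxon' column")
  metadata <- metadata[match(colnames(counts), metadata$sample), ,
                       drop = FALSE]
  untaxed <- setdiff(rownames(counts), as.character(taxonomy$taxon))
  structure(list(counts = counts, metadata = metadata,
                 taxonomy = taxonomy,
                 validation = list(taxa_without_taxonomy = untaxed)),
            class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat(sprintf(
    "community_dataset: %d taxa x %d samples, %d site(s)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$metadata$site))))
  if (length(x$validation$taxa_without_taxonomy))
    cat(sprintf("  %d taxa lack a taxonomy row\n",
                length(x$validation$taxa_without_taxonomy)))
  invisible(x)
}

#' Aggregate a dataset to a taxonomic rank
#'
#' Sums counts over all taxa sharing the same value of the chosen rank.
#' Taxa with no taxonomy row or an empty rank value are dropped (listed
#' in the validation report).
#'
#' @param dataset a \code{\link{community_dataset}}.
#' @param rank one of \code{"phylum", "class", "order", "family",
#'   "genus"}, or \code{"taxon"} for no aggregation.
#' @return An aggregated \code{"community_dataset"}.
#' @export
aggregate_rank <- function(dataset, rank = "genus") {
  stopifnot(inherits(dataset, "community_dataset"))
  if (rank == "taxon") return(dataset)
  if (!rank %in% names(dataset$taxonomy))
    stop("unknown taxonomic rank: ", rank)
  tax <- dataset$taxonomy
  key <- as.character(tax[[rank]])[match(rownames(dataset$counts),
                                         as.character(tax$taxon))]
  ok <- !is.na(key) & key != ""
  m <- rowsum(dataset$counts[ok, , drop = FALSE], group = key[ok])
  keep_cols <- intersect(TAX_RANKS[seq_len(match(rank, TAX_RANKS))],
                         names(tax))
  rows <- match(rownames(dataset$counts)[ok], as.character(tax$taxon))
  agg_tax <- data.frame(taxon = key[ok],
                        tax[rows, keep_cols, drop = FALSE],
                        row.names = NULL, check.names = FALSE)
  agg_tax <- agg_tax[!duplicated(agg_tax$taxon), , drop = FALSE]
  agg_tax <- agg_tax[match(rownames(m), agg_tax$taxon), , drop = FALSE]
  out <- community_dataset(m, dataset$metadata, agg_tax)
  out$validation$dropped_unclassified <-
    rownames(dataset$counts)[!ok]
  out
}

#' Build a presence series from a community dataset
#'
#' Orders samples by time within each site, stacks replicates, and
#' derives binary detections as \code{count > 0}. Each site must have
#' the same replicate set at every time point.
#'
#' @param dataset a \code{\link{community_dataset}}.
#' @param rank optional taxonomic rank to aggregate to first.
#' @return A \code{\link{presence_series}} with counts.
#' @export
as_presence_series <- function(dataset, rank = NULL) {
  stopifnot(inherits(dataset, "community_dataset"))
  if (!is.null(rank)) dataset <- aggregate_rank(dataset, rank)
  md <- dataset$metadata
  taxa <- rownames(dataset$counts)
  pieces <- lapply(split(seq_len(nrow(md)), md$site), function(ix) {
    sub <- md[ix, , drop = FALSE]
    times <- sort(unique(sub$time))
    reps <- sort(unique(sub$replicate))
    cnt <- array(NA_real_,
                 dim = c(length(taxa), length(times), length(reps)))
    for (j in seq_len(nrow(sub))) {
      ti <- match(sub$time[j], times)
      ri <- match(sub$replicate[j], reps)
      cnt[, ti, ri] <- dataset$counts[, sub$sample[j]]
    }
    if (any(is.na(cnt)))
      stop("site '", sub$site[1], "': unbalanced replicates ",
           "(a (time, replicate) combination has no sample)")
    presence_series((cnt > 0) * 1L, times, taxa = taxa, counts = cnt,
                    site = as.character(sub$site[1]))
  })
  combine_sites(pieces)
}

#' Write a presence series as the dataset trio
#'
#' Emits \code{<prefix>_counts.csv}, \code{<prefix>_metadata.csv} and
#' \code{<prefix>_taxonomy.csv} (plus \code{<prefix>_truth.csv} when
#' the series carries generator truth), in the schema
#' \code{\link{read_dataset}} expects. Series without counts are written
#' with detections (0/1) as counts.
#'
#' @param series a \code{\link{presence_series}}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param taxonomy optional taxonomy data frame (default: a synthetic
#'   one).
#' @return Invisibly, the written paths.
#' @export
write_dataset <- function(series, dir = ".", prefix = "community",
                          taxonomy = NULL) {
  stopifnot(inherits(series, "presence_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- list()
  meta <- list()
  for (nm in names(series$sites)) {
    s <- series$sites[[nm]]
    cnt <- if (is.null(s$counts)) s$detections else s$counts
    for (ri in seq_len(dim(cnt)[3L])) {
      for (ti in seq_along(s$times)) {
        id <- sprintf("%s_d%g_r%d", nm, s$times[ti], ri)
        cols[[id]] <- cnt[, ti, ri]
        meta[[id]] <- data.frame(sample = id, time = s$times[ti],
                                 site = nm, replicate = ri)
      }
    }
  }
  counts <- data.frame(taxon = series$taxa, do.call(cbind, cols),
                       check.names = FALSE)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  if (is.null(taxonomy)) taxonomy <- synthetic_taxonomy(series$taxa)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("counts", "metadata", "taxonomy"),
                                 ".csv"))
  utils::write.csv(counts, paths[1], row.names = FALSE)
  utils::write.csv(metadata, paths[2], row.names = FALSE)
  utils::write.csv(taxonomy, paths[3], row.names = FALSE)
  truth <- attr(series, "truth")
  if (!is.null(truth)) {
    tp <- file.path(dir, paste0(prefix, "_truth.csv"))
    utils::write.csv(truth, tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}
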