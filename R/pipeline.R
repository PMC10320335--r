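## End-to-end pipeline and the command-line entry point.

#' Run the full colonization-persistence analysis
#'
#' Chains the stages on one dataset: aggregate counts to a taxonomic
#' rank, estimate a colonization/extinction pair per taxon by maximum
#' likelihood, drop boundary fits and labile taxa (persistence below a
#' quarter of the minimal inter-sample interval), locate the
#' core/satellite occupancy threshold by the Chow structural-break scan,
#' fit the log-log persistence-colonization regression per component,
#' test each slope against -1, compare the core and satellite slopes,
#' and fit the lognormal rank-abundance model to the core.
#'
#' @param dataset a \code{\link{community_dataset}} (see
#'   \code{\link{read_dataset}}).
#' @param rank taxonomic rank to analyse at (default "genus").
#' @param min_interval labile-filter reference interval in days
#'   (default: the dataset's minimal inter-sample gap).
#' @param trim,alpha passed to \code{\link{split_core_satellite}}.
#' @param out_dir optional directory; when set, writes
#'   \code{rates.csv}, \code{core_satellite.csv}, \code{tradeoff.csv}
#'   and \code{run.log}.
#' @return A list with elements \code{rates} (all fits),
#'   \code{kept} (fits surviving the filters), \code{filter},
#'   \code{scan}, \code{tradeoff} (data frame over components),
#'   \code{slope_tests}, \code{comparison} (core vs satellite, or NULL)
#'   and \code{core_rad} (lognormal fit, or NULL).
#' @export
run_pipeline <- function(dataset, rank = "genus", min_interval = NULL,
                         trim = 0.1, alpha = 0.05, out_dir = NULL) {
  stopifnot(inherits(dataset, "community_dataset"))
  series <- as_presence_series(dataset, rank = rank)
  detected <- series$taxa[vapply(series$taxa, function(tx)
    any_first_detection(series, tx), TRUE)]
  series <- subset_series(series, taxa = detected)
  fits <- fit_rates(series)
  if (is.null(min_interval)) min_interval <- min_sampling_interval(series)
  flt <- filter_labile(fits[!fits$boundary, , drop = FALSE], min_interval)
  kept <- flt$kept
  tab <- occupancy_abundance(series)
  scan <- tryCatch(split_core_satellite(tab, trim = trim, alpha = alpha),
                   error = function(e) NULL)
  comp_of <- function(g) {
    if (is.null(scan) || !scan$significant) return("all")
    unname(scan$labels[g])
  }
  kept$component <- vapply(kept$group, comp_of, "")
  fit_one <- function(rows, label) {
    if (nrow(rows) < 4L) return(NULL)
    loglog_tradeoff_fit(rows$c, rows$persistence, component = label,
                        level = rank)
  }
  fits_by_comp <- list(all = fit_one(kept, "all"))
  if (!is.null(scan) && scan$significant) {
    fits_by_comp$core <- fit_one(kept[kept$component == "core", ], "core")
    fits_by_comp$satellite <-
      fit_one(kept[kept$component == "satellite", ], "satellite")
  }
  fits_by_comp <- Filter(Negate(is.null), fits_by_comp)
  slope_tests <- lapply(fits_by_comp, test_slope_equals, value = -1)
  comparison <- NULL
  if (!is.null(fits_by_comp$core) && !is.null(fits_by_comp$satellite))
    comparison <- compare_slopes(fits_by_comp$core, fits_by_comp$satellite)
  core_rad <- NULL
  if (!is.null(scan) && scan$significant) {
    core_ab <- tab$max_abundance[scan$labels[tab$taxon] == "core"]
    if (length(core_ab) >= 5L) core_rad <- lognormal_rad_fit(core_ab)
  }
  tradeoff <- do.call(rbind, lapply(fits_by_comp, as.data.frame))
  if (!is.null(tradeoff)) {
    tradeoff$t_vs_minus1 <-
      vapply(slope_tests[rownames(tradeoff)], `[[`, 1, "t")
    tradeoff$p_vs_minus1 <-
      vapply(slope_tests[rownames(tradeoff)], `[[`, 1, "p")
    rownames(tradeoff) <- NULL
  }
  res <- list(rates = fits, kept = kept, filter = flt, scan = scan,
              tradeoff = tradeoff, slope_tests = slope_tests,
              fits_by_component = fits_by_comp,
              comparison = comparison, core_rad = core_rad,
              rank = rank, min_interval = min_interval)
  if (!is.null(out_dir)) write_pipeline_outputs(res, tab, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, tab, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$rates, file.path(out_dir, "rates.csv"),
                   row.names = FALSE)
  if (!is.null(res$scan) && res$scan$significant)
    tab$component <- unname(res$scan$labels[tab$taxon])
  utils::write.csv(tab, file.path(out_dir, "core_satellite.csv"),
                   row.names = FALSE)
  if (!is.null(res$tradeoff))
    utils::write.csv(res$tradeoff, file.path(out_dir, "tradeoff.csv"),
                     row.names = FALSE)
  log_lines <- c(
    paste("rank:", res$rank),
    paste("min_interval_days:", res$min_interval),
    paste("labile_threshold_days:", res$filter$threshold),
    paste("excluded_fraction:",
          format(res$filter$excluded_fraction, digits = 4)),
    paste("occdyn_version:",
          as.character(utils::packageVersion("occdyn"))),
    R.version.string)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(NULL)
}

## ---- command line ----------------------------------------------------

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

need_flags <- function(flags, keys, usage) {
  miss <- setdiff(keys, names(flags))
  if (length(miss))
    stop("missing required flag(s): ",
         paste(paste0("--", miss), collapse = ", "), "\nusage: ", usage,
         call. = FALSE)
}

num_or <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

load_cli_dataset <- function(flags, usage) {
  need_flags(flags, c("counts", "metadata", "taxonomy"), usage)
  read_dataset(flags$counts, flags$metadata, flags$taxonomy)
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{simulate}, \code{estimate},
#' \code{select-partitions}, \code{core-satellite}, \code{tradeoff} and
#' \code{pipeline}. Flags may also be supplied through a YAML config
#' file (\code{--config}); explicit flags override config values. A
#' thin executable wrapper is installed under \code{exec/occdyn}.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly 0 on success; signals an error otherwise.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "occdyn <simulate|estimate|select-partitions|core-satellite|",
    "tradeoff|pipeline> [--flags]", sep = "")
  if (!length(args)) stop("no subcommand given\nusage: ", usage,
                          call. = FALSE)
  sub <- args[1]
  flags <- parse_flags(args[-1])
  if (!is.null(flags$config)) {
    cfg <- yaml::read_yaml(flags$config)
    for (k in setdiff(names(cfg), names(flags))) flags[[k]] <- cfg[[k]]
  }
  switch(
    sub,
    simulate = cli_simulate(flags),
    estimate = cli_estimate(flags),
    `select-partitions` = cli_partitions(flags),
    `core-satellite` = cli_core_satellite(flags),
    tradeoff = cli_tradeoff(flags),
    pipeline = cli_pipeline(flags),
    stop("unknown subcommand '", sub, "'\nusage: ", usage, call. = FALSE))
  invisible(0L)
}

cli_simulate <- function(flags) {
  need_flags(flags, "out", "occdyn simulate --out DIR [--mode ...]")
  mode <- if (is.null(flags$mode)) "equalized" else flags$mode
  S <- as.integer(num_or(flags, "s", 300))
  seed <- as.integer(num_or(flags, "seed", 1))
  dt <- num_or(flags, "dt", 30)
  nt <- as.integer(num_or(flags, "samples", 24))
  times <- seq(0, by = dt, length.out = nt)
  ps <- switch(
    mode,
    equalized = simulate_equalized(S, k = num_or(flags, "k", 2),
                                   times = times, seed = seed,
                                   r = as.integer(num_or(flags, "replicates", 1)),
                                   d = num_or(flags, "d", 1)),
    independent = simulate_independent(S, times = times, seed = seed),
    sad = simulate_sad_detection(S, times = times,
                                 depth = as.integer(num_or(flags, "depth", 2000)),
                                 seed = seed),
    stop("unknown --mode '", mode, "'"))
  paths <- write_dataset(ps, flags$out, prefix = mode)
  message("wrote: ", paste(basename(paths), collapse = ", "))
}

cli_estimate <- function(flags) {
  ds <- load_cli_dataset(flags,
    "occdyn estimate --counts F --metadata F --taxonomy F [--rank R] [--out F]")
  rank <- if (is.null(flags$rank)) "taxon" else flags$rank
  fits <- fit_rates(as_presence_series(ds, rank = rank))
  out <- if (is.null(flags$out)) stdout() else flags$out
  utils::write.csv(fits, out, row.names = FALSE)
}

cli_partitions <- function(flags) {
  ds <- load_cli_dataset(flags,
    "occdyn select-partitions --counts F --metadata F --taxonomy F [--out F]")
  fits <- fit_partition_models(as_presence_series(ds))
  out <- if (is.null(flags$out)) stdout() else flags$out
  utils::write.csv(fits$table, out, row.names = FALSE)
}

cli_core_satellite <- function(flags) {
  ds <- load_cli_dataset(flags,
    "occdyn core-satellite --counts F --metadata F --taxonomy F [--rank R] [--out F]")
  rank <- if (is.null(flags$rank)) "genus" else flags$rank
  tab <- occupancy_abundance(as_presence_series(ds, rank = rank))
  scan <- split_core_satellite(tab, trim = num_or(flags, "trim", 0.1))
  if (scan$significant)
    tab$component <- unname(scan$labels[tab$taxon])
  out <- if (is.null(flags$out)) stdout() else flags$out
  utils::write.csv(tab, out, row.names = FALSE)
}

cli_tradeoff <- function(flags) {
  ds <- load_cli_dataset(flags,
    "occdyn tradeoff --counts F --metadata F --taxonomy F [--rank R] [--out F]")
  rank <- if (is.null(flags$rank)) "genus" else flags$rank
  res <- run_pipeline(ds, rank = rank)
  out <- if (is.null(flags$out)) stdout() else flags$out
  utils::write.csv(res$tradeoff, out, row.names = FALSE)
}

cli_pipeline <- function(flags) {
  usage <- paste("occdyn pipeline --counts F --metadata F --taxonomy F",
                 "--out DIR [--rank R]")
  need_flags(flags, c("counts", "metadata", "taxonomy", "out"), usage)
  ds <- read_dataset(flags$counts, flags$metadata, flags$taxonomy)
  rank <- if (is.null(flags$rank)) "genus" else flags$rank
  run_pipeline(ds, rank = rank, trim = num_or(flags, "trim", 0.1),
               out_dir = flags$out)
  message("pipeline outputs written to ", flags$out)
}
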