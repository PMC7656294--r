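#' @title Tables, configuration and the pipeline driver
#' @description TSV readers/writers for isotopomer time courses, the
#'   end-to-end pipeline (simulate or load, enrich, filter, fit, aggregate,
#'   summarize), YAML configuration, and the command-line entry point.
#' @name io_pipeline
NULL

#' Read an isotopomer time-course table
#'
#' Tab-separated, UTF-8, header row, `.` decimal.  Required columns:
#' `group`, `animal_id`, `accession`, `peptide`, `time_h` (or `time_d`,
#' converted to hours), and `m0`, `m1`, ...  Validation failures name the
#' offending column or row.
#'
#' @param path Path to the TSV.
#' @return data.frame, one row per (animal, peptide, time point).
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("time_d" %in% names(tab) && !"time_h" %in% names(tab)) {
    tab$time_h <- tab$time_d * 24
    tab$time_d <- NULL
  }
  need <- c("group", "animal_id", "accession", "peptide", "time_h",
            "m0", "m1")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("time-course table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  mcols <- grep("^m[0-9]+$", names(tab), value = TRUE)
  for (cl in c("time_h", mcols)) {
    if (!is.numeric(tab[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[cl]]))))[1]
      stop("non-numeric value in column '", cl, "' at row ", bad)
    }
  }
  mm <- as.matrix(tab[, mcols])
  if (any(mm < 0, na.rm = TRUE) || anyNA(mm)) {
    bad <- which(apply(mm, 1, function(r) anyNA(r) || any(r < 0)))[1]
    stop("negative or missing intensity at row ", bad)
  }
  key <- paste(tab$animal_id, tab$peptide, tab$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (animal, peptide, time) at row ", which(duplicated(key))[1])
  }
  if (!"total_intensity" %in% names(tab)) {
    tab$total_intensity <- rowSums(mm)
  }
  tab
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its documented default.
#' `input` may be `NULL`, in which case the synthetic cohort described by
#' `simulation` is generated first.
#'
#' @param input Optional path to an isotopomer time-course TSV.
#' @param out_dir Output directory (created if absent); `NULL` disables
#'   file output.
#' @param seed Integer seed; the single source of randomness.
#' @param n_iso Isotopomers per peptide.
#' @param min_points,intensity_window Quantifiability filter settings, see
#'   [filter_series()].
#' @param k_bounds,plateau_max,fix_plateau,outlier_threshold,max_removals
#'   Fit settings, see [fit_exponential()] and [remove_outliers()].
#' @param min_peptides Converged peptide fits required per protein.
#' @param variant,var_equal,alpha Statistics settings, see
#'   [cohort_summary()].
#' @param simulation A [cohort_config()] or list of arguments for it
#'   (the `seed` defaults to the pipeline seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, out_dir = NULL, seed = 1L,
                            n_iso = 6L, min_points = 5L,
                            intensity_window = c(1e6, 1e8),
                            k_bounds = c(1e-5, 2), plateau_max = 0.995,
                            fix_plateau = NULL, outlier_threshold = 3,
                            max_removals = 1L, min_peptides = 3L,
                            variant = "student", var_equal = TRUE,
                            alpha = 0.05, simulation = list()) {
  if (!inherits(simulation, "cohort_config")) {
    if (is.null(simulation$seed)) simulation$seed <- seed
    simulation <- do.call(cohort_config, simulation)
  }
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 n_iso = n_iso, min_points = min_points,
                 intensity_window = intensity_window, k_bounds = k_bounds,
                 plateau_max = plateau_max, fix_plateau = fix_plateau,
                 outlier_threshold = outlier_threshold,
                 max_removals = max_removals, min_peptides = min_peptides,
                 variant = variant, var_equal = var_equal, alpha = alpha,
                 simulation = simulation),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every field of [pipeline_config()] can appear in the file; the
#' `simulation` block mirrors [cohort_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

log_msg <- function(...) message("[proturn] ", sprintf(...))

#' Fit every peptide series of a cohort time course
#'
#' Splits the time-course table by (group, animal, protein, peptide),
#' builds the enrichment series, applies the quantifiability filter and
#' fits the exponential-rise model with outlier screening.  Records that
#' fail a stage land in the exclusion table with the stage and reason, so
#' every input series appears exactly once in either output.
#'
#' @param timecourse Table as from [generate_cohort()] or
#'   [read_timecourse()].
#' @param config A [pipeline_config()].
#' @return list with `enrichment` (per-point table), `fits` (per-peptide
#'   table), `exclusions` (series-level rejects).
#' @export
fit_cohort <- function(timecourse, config = pipeline_config()) {
  key <- paste(timecourse$group, timecourse$animal_id, timecourse$accession,
               timecourse$peptide, sep = "\r")
  pieces <- split(seq_len(nrow(timecourse)), key)
  enr_list <- vector("list", length(pieces))
  fit_rows <- vector("list", length(pieces))
  excl_rows <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    idx <- pieces[[i]]
    d <- timecourse[idx, , drop = FALSE]
    id <- d[1, c("group", "animal_id", "accession", "peptide")]
    ser <- tryCatch(enrichment_series(d), error = function(e) e)
    if (inherits(ser, "error")) {
      excl_rows[[i]] <- cbind(id, stage = "enrichment",
                              reason = conditionMessage(ser))
      next
    }
    enr_list[[i]] <- cbind(id, ser, row.names = NULL)
    flt <- filter_series(ser, min_points = config$min_points,
                         intensity_window = config$intensity_window)
    if (!flt$accepted) {
      excl_rows[[i]] <- cbind(id, stage = "filter", reason = flt$reason)
      next
    }
    ser_ok <- ser[flt$in_window, , drop = FALSE]
    if (!any(ser_ok$time_h == 0)) {
      excl_rows[[i]] <- cbind(id, stage = "filter",
                              reason = "baseline outside intensity window")
      next
    }
    fit <- tryCatch(
      fit_peptide(ser_ok, threshold = config$outlier_threshold,
                  max_removals = config$max_removals,
                  k_bounds = config$k_bounds,
                  plateau_max = config$plateau_max,
                  fix_plateau = config$fix_plateau),
      error = function(e) e)
    if (inherits(fit, "error")) {
      excl_rows[[i]] <- cbind(id, stage = "fit",
                              reason = conditionMessage(fit))
      next
    }
    fit_rows[[i]] <- cbind(
      id,
      data.frame(k = fit$k, k_se = fit$k_se, I0 = fit$I0,
                 Iplateau = fit$Iplateau, t_half = fit$t_half,
                 rse = fit$rse, n_points = fit$n_points,
                 outliers_removed = length(fit$removed),
                 converged = fit$converged))
  }
  compact <- function(l) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (length(l)) do.call(rbind, l) else NULL
  }
  list(enrichment = compact(enr_list), fits = compact(fit_rows),
       exclusions = compact(excl_rows))
}

#' Aggregate peptide fits to per-animal protein turnover
#'
#' @param fits `fits` table from [fit_cohort()].
#' @param min_peptides Converged fits required per (protein, animal).
#' @return list with `proteins` (group, animal_id, accession, mean_k, sd_k,
#'   t_half, n_peptides) and `exclusions`.
#' @export
aggregate_cohort <- function(fits, min_peptides = 3L) {
  key <- paste(fits$group, fits$animal_id, fits$accession, sep = "\r")
  pieces <- split(seq_len(nrow(fits)), key)
  rows <- vector("list", length(pieces))
  excl <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    d <- fits[pieces[[i]], , drop = FALSE]
    id <- d[1, c("group", "animal_id", "accession")]
    id$peptide <- NA_character_  # aligns with series-level exclusion rows
    pseudo <- lapply(seq_len(nrow(d)), function(j) {
      structure(list(k = d$k[j], converged = d$converged[j]),
                class = "kinetic_fit")
    })
    agg <- aggregate_protein(pseudo, min_peptides = min_peptides)
    if (agg$excluded) {
      excl[[i]] <- cbind(id, stage = "aggregate", reason = agg$reason)
    } else {
      rows[[i]] <- cbind(id, data.frame(
        mean_k = agg$mean_k, sd_k = agg$sd_k, t_half = agg$t_half,
        n_peptides = agg$n_peptides))
    }
  }
  compact <- function(l) {
    l <- l[!vapply(l, is.null, logical(1))]
    if (length(l)) do.call(rbind, l) else NULL
  }
  list(proteins = compact(rows), exclusions = compact(excl))
}

#' Run the full pipeline
#'
#' Simulate (or load) an isotopomer cohort, compute enrichment series,
#' filter, fit, aggregate to protein turnover per animal, and summarize the
#' two-group comparison.  Deterministic for a fixed config: all randomness
#' flows from the config seed.  When `out_dir` is set, writes
#' `timecourse.tsv`, `enrichment.tsv`, `fits.tsv`, `proteins.tsv`,
#' `exclusions.tsv`, `cohort_proteins.csv`, `cohort_summary.json` and, for
#' simulated input, `truth.tsv`.
#'
#' @param config A [pipeline_config()].
#' @return list with `timecourse`, `truth` (NULL for file input),
#'   `enrichment`, `fits`, `proteins`, `exclusions`, `cohort`
#'   (a [cohort_summary()] result).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(config$input)) {
    log_msg("simulating cohort (seed %d)", config$simulation$seed)
    sim <- generate_cohort(config$simulation)
    tc <- sim$timecourse
    truth <- sim$truth
  } else {
    log_msg("reading %s", config$input)
    tc <- read_timecourse(config$input)
  }
  n_series <- length(unique(paste(tc$animal_id, tc$peptide)))
  log_msg("%d rows, %d peptide series", nrow(tc), n_series)

  fc <- fit_cohort(tc, config)
  n_fit <- if (is.null(fc$fits)) 0L else nrow(fc$fits)
  n_excl <- if (is.null(fc$exclusions)) 0L else nrow(fc$exclusions)
  log_msg("fitted %d series, excluded %d", n_fit, n_excl)
  if (n_fit == 0L) stop("pipeline stage 'fit': no peptide series survived")

  ag <- aggregate_cohort(fc$fits, min_peptides = config$min_peptides)
  exclusions <- rbind(fc$exclusions, ag$exclusions)
  if (is.null(ag$proteins)) {
    stop("pipeline stage 'aggregate': no protein reached ",
         config$min_peptides, " peptides")
  }
  log_msg("%d (protein, animal) turnover values; %d exclusions total",
          nrow(ag$proteins), if (is.null(exclusions)) 0L else nrow(exclusions))

  cohort <- cohort_summary(ag$proteins, var_equal = config$var_equal,
                           alpha = config$alpha)
  log_msg("cohort: %d proteins, %.1f%% mean half-life reduction",
          cohort$summary$n_proteins, cohort$summary$pct_reduction)

  out <- list(timecourse = tc, truth = truth, enrichment = fc$enrichment,
              fits = fc$fits, proteins = ag$proteins,
              exclusions = exclusions, cohort = cohort)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$out_dir, f)
    write_tsv(tc, pth("timecourse.tsv"))
    if (!is.null(truth)) write_tsv(truth, pth("truth.tsv"))
    write_tsv(fc$enrichment, pth("enrichment.tsv"))
    write_tsv(fc$fits, pth("fits.tsv"))
    write_tsv(ag$proteins, pth("proteins.tsv"))
    if (!is.null(exclusions)) write_tsv(exclusions, pth("exclusions.tsv"))
    utils::write.csv(cohort$proteins, pth("cohort_proteins.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cohort$summary, pth("cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_msg("outputs written to %s", config$out_dir)
  }
  invisible(out)
}

#' Summary-statistic reanalysis of the packaged half-life catalog
#'
#' Runs [cohort_summary()] in summary-statistic mode on
#' [hdl_halflife_catalog()]: through-origin regression slope and r-squared,
#' percent mean half-life reduction, and the fraction of proteins whose
#' recomputed two-tailed t-test is significant with a reduced half-life.
#' Because only printed group sizes "6-7 per group" are known, the result
#' carries a `qc_group_sizes` attribute with the summary under each
#' plausible (n_control, n_hfd) combination.
#'
#' @param n_control,n_hfd Group sizes for the main analysis (defaults 7, 6).
#' @param variant,alpha Passed to [cohort_summary()].
#' @return A `cohort_result`; attribute `qc_group_sizes` is a data.frame of
#'   key statistics at (7,6), (6,7), (7,7), (6,6).
#' @export
reproduce_catalog <- function(n_control = 7L, n_hfd = 6L,
                              variant = "student", alpha = 0.05) {
  cat <- hdl_halflife_catalog()
  res <- cohort_summary(cat, n_control = n_control, n_hfd = n_hfd,
                        variant = variant, alpha = alpha)
  combos <- rbind(c(7, 6), c(6, 7), c(7, 7), c(6, 6))
  qc <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    s <- cohort_summary(cat, n_control = combos[i, 1], n_hfd = combos[i, 2],
                        variant = variant, alpha = alpha)$summary
    data.frame(n_control = combos[i, 1], n_hfd = combos[i, 2],
               n_significant_reduced = s$n_significant_reduced,
               pct_significant_reduced = s$pct_significant_reduced)
  }))
  attr(res, "qc_group_sizes") <- qc
  res
}

cli_usage <- function() {
  cat("usage: proturn <command> [--config FILE] [--input FILE]",
      "[--out DIR] [--seed N]\n\n",
      "commands:\n",
      "  simulate          generate a synthetic cohort and write its tables\n",
      "  enrich            compute enrichment series from a time-course TSV\n",
      "  fit               enrich + fit peptide kinetics\n",
      "  summarize         full statistics on fitted protein turnover\n",
      "  run               all stages end to end\n",
      "  reproduce-table2  summary-stat reanalysis of the packaged catalog\n",
      sep = "")
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args)) stop("missing value for --", key)
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `enrich`, `fit`, `summarize`,
#' `run` and `reproduce-table2`.  Flags: `--config FILE` (YAML mirroring
#' [pipeline_config()]), `--input FILE`, `--out DIR`, `--seed N`.  Returns
#' 0 on success; errors carry the failing stage in their message.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, invisibly.
#' @export
proturn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    cli_usage()
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  config <- if (!is.null(opts$config)) read_config(opts$config) else
    pipeline_config()
  if (!is.null(opts$seed)) {
    config <- pipeline_config(input = config$input, out_dir = config$out_dir,
                              seed = as.integer(opts$seed))
  }
  if (!is.null(opts$input)) config$input <- opts$input
  if (!is.null(opts$out)) config$out_dir <- opts$out
  od <- config$out_dir
  if (is.null(od) && cmd != "reproduce-table2") od <- "."
  pth <- function(f) file.path(od, f)
  if (!is.null(od)) dir.create(od, recursive = TRUE, showWarnings = FALSE)

  switch(cmd,
    simulate = {
      sim <- generate_cohort(config$simulation)
      write_tsv(sim$timecourse, pth("timecourse.tsv"))
      write_tsv(sim$truth, pth("truth.tsv"))
      write_tsv(sim$peptides, pth("peptides.tsv"))
      log_msg("wrote %d time-course rows", nrow(sim$timecourse))
    },
    enrich = ,
    fit = {
      if (is.null(config$input)) stop("stage 'input': --input is required")
      tc <- read_timecourse(config$input)
      fc <- fit_cohort(tc, config)
      write_tsv(fc$enrichment, pth("enrichment.tsv"))
      if (cmd == "fit") {
        write_tsv(fc$fits, pth("fits.tsv"))
        if (!is.null(fc$exclusions)) {
          write_tsv(fc$exclusions, pth("exclusions.tsv"))
        }
      }
    },
    summarize = ,
    run = {
      config$out_dir <- od
      run_pipeline(config)
    },
    `reproduce-table2` = {
      res <- reproduce_catalog(alpha = config$alpha)
      print(res)
      if (!is.null(od)) {
        utils::write.csv(res$proteins, pth("catalog_reanalysis.csv"),
                         row.names = FALSE)
        jsonlite::write_json(res$summary, pth("catalog_summary.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    },
    {
      cli_usage()
      stop("unknown command: ", cmd)
    })
  invisible(0L)
}
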