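# End-to-end orchestration: simulate (or load) -> filter -> richness ->
# assess -> evaluate, writing all artifacts as delimited text / GeoJSON
# plus a machine-readable run manifest.

#' Pipeline configuration
#'
#' @param out_dir artifact directory (created if needed).
#' @param seed integer seed; recorded in the manifest and used for the
#'   simulation stage.
#' @param sim_spec a [simulation_spec()], or `NULL` to read occurrences from
#'   `occurrences_path` instead of simulating.
#' @param occurrences_path,reference_path input files used when `sim_spec`
#'   is `NULL` (occurrences; optional reference categories).
#' @param filter_cfg a [filter_config()]; when `NULL`, one is built with
#'   default thresholds and, for a simulated run, the simulation's group
#'   realms.
#' @param thresholds a [criterion_b_thresholds()].
#' @param richness_cell_km richness grid cell side (default 100 km).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim_spec = simulation_spec(),
                            occurrences_path = NULL, reference_path = NULL,
                            filter_cfg = NULL,
                            thresholds = criterion_b_thresholds(),
                            richness_cell_km = 100) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 sim_spec = sim_spec, occurrences_path = occurrences_path,
                 reference_path = reference_path, filter_cfg = filter_cfg,
                 thresholds = thresholds,
                 richness_cell_km = richness_cell_km),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate the toy world and occurrence data (or load supplied
#' files), (2) run every quality test and split the data into raw and
#' filtered sets, (3) grid species richness for both sets and their
#' difference, (4) assess every species under Criterion B on both sets,
#' (5) compare the automated assessments with the reference categories and
#' summarize range change. All artifacts are plain text; a manifest records
#' seed, configuration hash and package version. Outputs are a pure function
#' of the inputs and configuration (byte-identical on re-run apart from the
#' manifest timestamp).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  out <- function(f) file.path(config$out_dir, f)

  # stage 1: data
  if (!is.null(config$sim_spec)) {
    gaz <- make_toy_gazetteer()
    sim <- simulate_occurrences(config$sim_spec, gaz, seed = config$seed)
    records <- sim$records
    truth <- sim$truth
    reference <- make_reference_assessments(records, truth,
                                            config$thresholds)
    paths$gazetteer <- write_gazetteer(gaz, out("gazetteer"))
    paths$occurrences_raw <- write_occurrences(records,
                                               out("occurrences_raw.csv"))
    paths$truth <- write_tsv(sim$truth, out("truth_synthetic.tsv"))
    paths$ranges <- write_tsv(sim$ranges, out("ranges_synthetic.tsv"))
    paths$reference <- write_tsv(reference,
                                 out("reference_synthetic.tsv"))
    realms <- stats::setNames(config$sim_spec$realms,
                              sprintf("group%02d",
                                      seq_len(config$sim_spec$n_groups)))
  } else {
    stopifnot(!is.null(config$occurrences_path))
    records <- read_occurrences(config$occurrences_path)
    gaz <- make_toy_gazetteer()
    truth <- NULL
    reference <- if (!is.null(config$reference_path))
      read_reference_assessments(config$reference_path) else NULL
    realms <- character()
  }

  # stage 2: quality tests and filtering
  fc <- config$filter_cfg
  if (is.null(fc)) fc <- filter_config(realms = realms)
  report <- run_filters(records, fc, gaz)
  clean <- filtered_dataset(records, report)
  flag_cols <- report
  for (tk in filter_test_tokens) flag_cols[[tk]] <- as.integer(report[[tk]])
  flag_cols$erroneous <- as.integer(report$erroneous)
  flag_cols$unfit <- as.integer(report$unfit)
  flag_cols$clean <- as.integer(report$clean)
  paths$flags <- write_tsv(as.data.frame(flag_cols), out("flags.tsv"))
  paths$occurrences_clean <- write_occurrences(clean,
                                               out("occurrences_clean.csv"))
  summary_tbl <- summarize_flags(report, records)
  paths$flag_summary <- write_tsv(round_df(summary_tbl, 4),
                                  out("flag_summary.tsv"))

  # stage 3: richness grids
  r_raw <- richness(records, config$richness_cell_km)
  r_filt <- richness(clean, config$richness_cell_km)
  paths$richness_raw <- write_tsv(round_df(as.data.frame(r_raw), 6),
                                  out("richness_raw.tsv"))
  paths$richness_filtered <- write_tsv(round_df(as.data.frame(r_filt), 6),
                                       out("richness_filtered.tsv"))
  paths$richness_difference <- write_tsv(
    round_df(richness_difference(r_raw, r_filt), 6),
    out("richness_difference.tsv"))

  # stage 4: conservation assessment
  a_raw <- assess_all(records, config$thresholds)
  a_filt <- assess_all(clean, config$thresholds)
  paths$assessments_raw <- write_tsv(round_df(a_raw, 4),
                                     out("assessments_raw.tsv"))
  paths$assessments_filtered <- write_tsv(round_df(a_filt, 4),
                                          out("assessments_filtered.tsv"))

  # stage 5: evaluation
  groups <- stats::setNames(records$group_id, records$species)
  groups <- groups[!duplicated(names(groups))]
  chg <- range_change(a_raw, a_filt, groups)
  paths$range_change <- write_tsv(round_df(chg, 4), out("range_change.tsv"))
  eval_rows <- data.frame(metric = character(), value = numeric(),
                          stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    cmp_filt <- compare_with_reference(a_filt, reference)
    cmp_raw <- compare_with_reference(a_raw, reference)
    eval_rows <- data.frame(
      metric = c("match_pct_filtered", "match_pct_raw",
                 "n_compared_filtered", "n_compared_raw",
                 "median_eoo_change_pct", "median_aoo_change_pct"),
      value = round(c(cmp_filt$match_pct, cmp_raw$match_pct,
                      cmp_filt$n_compared, cmp_raw$n_compared,
                      stats::median(chg$median_eoo_change_pct, na.rm = TRUE),
                      stats::median(chg$median_aoo_change_pct,
                                    na.rm = TRUE)), 4),
      stringsAsFactors = FALSE)
  }
  paths$evaluation <- write_tsv(eval_rows, out("evaluation.tsv"))

  # manifest
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package = "occfiltr",
    version = as.character(utils::packageVersion("occfiltr")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tf)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_records = nrow(records), n_clean = nrow(clean),
    artifacts = vapply(paths, function(p) paste(basename(unlist(p)),
                                                collapse = ";"),
                       character(1)))
  unlink(tf)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$manifest <- out("manifest.json")
  invisible(paths)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Summarize a pipeline artifact directory
#'
#' Reads the artifacts written by [run_pipeline()] and prints the headline
#' numbers: overall flagged / erroneous / unfit percentages, the per-group
#' flag table, and (when present) the evaluation metrics.
#'
#' @param dir artifact directory.
#' @return invisibly, a list with `flag_summary`, `evaluation`,
#'   `range_change` data frames.
#' @export
pipeline_report <- function(dir) {
  if (!dir.exists(dir)) stop("no such artifact directory: ", dir,
                             call. = FALSE)
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p))
      utils::read.table(p, header = TRUE, sep = "\t", check.names = FALSE,
                        stringsAsFactors = FALSE)
    else NULL
  }
  fs <- rd("flag_summary.tsv")
  ev <- rd("evaluation.tsv")
  ch <- rd("range_change.tsv")
  if (!is.null(fs)) {
    tot <- fs[fs$group == "Total", , drop = FALSE]
    if (nrow(tot) == 1L) {
      cat(sprintf("%d records: %.1f%% flagged (%.1f%% erroneous, %.1f%% unfit)\n",
                  tot$n_records, tot$pct_flagged, tot$pct_erroneous,
                  tot$pct_unfit))
    }
    cat("\nPer-group flag summary (%):\n")
    print(fs, row.names = FALSE)
  }
  if (!is.null(ch) && nrow(ch)) {
    cat("\nMedian range change after filtering (%):\n")
    print(ch, row.names = FALSE)
  }
  if (!is.null(ev) && nrow(ev)) {
    cat("\nEvaluation against reference assessments:\n")
    print(ev, row.names = FALSE)
  }
  invisible(list(flag_summary = fs, evaluation = ev, range_change = ch))
}
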