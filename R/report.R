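# Evaluation-report assembly: ties the stratification/evaluation protocol
# together and persists metrics, curves and a run record.

#' Run the full stratification evaluation on a scored cohort
#'
#' Applies the complete evaluation protocol to per-subject risk scores:
#' median (below/above) and (0.5, 0.75) quantile stratifications,
#' Kaplan-Meier curves per stratum, k-group and pairwise log-rank tests,
#' Harrell's C-index overall and truncated at each horizon, the
#' threshold-sweep ROC per horizon, the all-time ROC (classification
#' disregarding censoring), the three-segment stratified ROC, and the
#' subgroup hazard-ratio forest when a subgroup column is named.
#'
#' @param data Tibble with `subject_id`, `score`, `time_days`, `event`,
#'   optionally a subgroup column.
#' @param horizons_days Evaluation horizons in days.
#' @param subgroup Optional name of a subgroup label column for the forest.
#' @param tie_policy Passed to [stratify_by_quantiles()].
#' @param out_dir Optional output directory; when given, KM/ROC TSVs, the
#'   forest TSV, a metrics JSON and a run-record JSON are written there.
#' @param seed Seed recorded in the run record (the evaluation itself is
#'   deterministic).
#' @return An `evaluation_report` list: `strata`, `km`, `logrank`,
#'   `c_index`, `rocs`, `forest`, `metrics`, `files`.
#' @export
run_evaluate <- function(data, horizons_days = c(1000, 2000, 3000),
                         subgroup = NULL, tie_policy = "strict",
                         out_dir = NULL, seed = NA_integer_) {
  assert_cols(data, c("subject_id", "score", "time_days", "event"))
  assert_outcomes(data)

  two <- stratify_by_quantiles(data, 0.5, tie_policy = tie_policy)
  three <- stratify_by_quantiles(data, c(0.5, 0.75), tie_policy = tie_policy)

  strata <- dplyr::left_join(
    dplyr::select(two, "subject_id", median_stratum = "stratum"),
    dplyr::select(three, "subject_id", quartile_stratum = "stratum"),
    by = "subject_id"
  )

  km <- list(
    median = km_by_group(two, .data$stratum),
    quartile = km_by_group(three, .data$stratum)
  )

  safe_logrank <- function(data, comparison) {
    res <- tryCatch(
      logrank_test(data, .data$stratum),
      error = function(e) tibble(chi_square = NA_real_, df = NA_integer_,
                                 p_value = NA_real_)
    )
    dplyr::mutate(res, comparison = comparison)
  }
  lr <- list(
    median = safe_logrank(two, "below_median vs above_median"),
    quartile_all = safe_logrank(three, "low vs intermediate vs high")
  )
  pairs <- utils::combn(levels(three$stratum), 2, simplify = FALSE)
  lr_pairs <- purrr::map_dfr(pairs, function(p) {
    safe_logrank(three[three$stratum %in% p, ], paste(p, collapse = " vs "))
  })
  logrank <- dplyr::bind_rows(c(lr, list(pairs = lr_pairs)))

  ci_overall <- concordance_index(data)
  ci_h <- purrr::map_dfr(horizons_days, function(h) {
    tibble(horizon_days = h,
           c_index = tryCatch(concordance_index(data, horizon_days = h),
                              error = function(e) NA_real_))
  })

  rocs <- list()
  all_time <- horizon_labels(data, max(data$time_days),
                             policy = "censored_as_negative")
  rocs$all_time <- tryCatch(roc_curve(all_time), error = function(e) NULL)
  for (h in horizons_days) {
    hl <- horizon_labels(data, h)
    rocs[[paste0("horizon_", h)]] <- tryCatch(roc_curve(hl),
                                              error = function(e) NULL)
  }
  strat_labels <- dplyr::left_join(
    dplyr::select(all_time, "subject_id", "label"),
    dplyr::select(three, "subject_id", "stratum"),
    by = "subject_id"
  )
  rocs$stratified <- tryCatch(stratified_roc(strat_labels),
                              error = function(e) NULL)

  forest <- if (!is.null(subgroup)) {
    subgroup_forest(data, !!rlang::sym(subgroup))
  }

  metrics <- list(
    n_subjects = nrow(data),
    n_events = sum(data$event),
    strata_sizes = list(
      median = as.list(table(two$stratum)),
      quartile = as.list(table(three$stratum))
    ),
    c_index = ci_overall,
    c_index_by_horizon = stats::setNames(
      as.list(ci_h$c_index), paste0("d", ci_h$horizon_days)
    ),
    logrank = lapply(split(logrank, logrank$comparison), function(r) {
      list(chi2 = r$chi_square, df = r$df, p = r$p_value)
    }),
    auc = lapply(rocs, function(r) if (!is.null(r)) roc_auc(r))
  )

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_report_files(out_dir, km, rocs, forest, metrics)
    write_run_record(out_dir, files, metrics, seed)
    files <- c(files, file.path(out_dir, "run_record.json"))
  }

  structure(list(
    strata = strata, km = km, logrank = logrank,
    c_index = list(overall = ci_overall, by_horizon = ci_h),
    rocs = rocs, forest = forest, metrics = metrics, files = files
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d (%d events); C-index %.3f; median-split log-rank p = %.3g\n",
    x$metrics$n_subjects, x$metrics$n_events, x$c_index$overall,
    x$logrank$p_value[x$logrank$comparison == "below_median vs above_median"]
  ))
  invisible(x)
}

write_report_files <- function(out_dir, km, rocs, forest, metrics) {
  files <- character()
  for (nm in names(km)) {
    p <- file.path(out_dir, sprintf("km_%s.tsv", nm))
    readr::write_tsv(as_tibble(km[[nm]]), p)
    files <- c(files, p)
  }
  for (nm in names(rocs)) {
    if (is.null(rocs[[nm]])) next
    p <- file.path(out_dir, sprintf("roc_%s.tsv", nm))
    readr::write_tsv(as_tibble(rocs[[nm]]), p)
    files <- c(files, p)
  }
  if (!is.null(forest)) {
    p <- file.path(out_dir, "forest.tsv")
    readr::write_tsv(forest, p)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, p)
}

# The run record is written atomically (temp file + rename) at run end.
write_run_record <- function(out_dir, files, headline, seed) {
  record <- list(
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files),
    headline = list(
      c_index = headline$c_index,
      n_subjects = headline$n_subjects,
      n_events = headline$n_events
    )
  )
  tmp <- tempfile(tmpdir = out_dir, fileext = ".json")
  jsonlite::write_json(record, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "run_record.json"))
  invisible(record)
}
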