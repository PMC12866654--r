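#' Study configuration
#'
#' Configuration of the end-to-end synthetic method-comparison study:
#' cohort, automated-segmenter error model, ABC/2 reader noise, the method
#' pairs and stratifiers to analyse, and the clinical acceptability limit.
#' Defaults reproduce the study conditions (300 cases, calibrated error
#' model, three pairwise comparisons, 10% rule, a ~10% subsample read by
#' 3 ABC/2 readers for the inter-observer ICC).
#'
#' @param cohort a [cohort_config()]; defaults to the study cohort with the
#'   given `seed`.
#' @param error_model an [auto_seg_error_model()].
#' @param reader_sd ABC/2 reader noise (log-scale SD of diameter readings).
#' @param pairs list of `c(method1, method2)` character pairs; the second
#'   method is the reference of each comparison.
#' @param stratifiers subset of `c("ivh", "location", "volume_40")`.
#' @param acceptance_limit_pct clinical acceptability bound (percent).
#' @param repeat_fraction fraction of cases read by additional ABC/2
#'   readers (inter-observer design).
#' @param n_repeat_readers total readers on the repeat subsample.
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @param seed master seed; all randomness derives from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohort = NULL,
                         error_model = auto_seg_error_model(),
                         reader_sd = 0.05,
                         pairs = list(c("auto_sim", "reference_voxel"),
                                      c("auto_sim", "abc2"),
                                      c("abc2", "reference_voxel")),
                         stratifiers = c("ivh", "location", "volume_40"),
                         acceptance_limit_pct = 10,
                         repeat_fraction = 0.1,
                         n_repeat_readers = 3L,
                         out_dir = NULL,
                         seed = 1L) {
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  if (acceptance_limit_pct <= 0) stop("`acceptance_limit_pct` must be positive")
  methods <- c("reference_voxel", "abc2", "auto_sim")
  for (p in pairs) {
    if (!all(p %in% methods)) {
      stop("pairs must reference reference_voxel, abc2 or auto_sim")
    }
  }
  structure(list(cohort = cohort, error_model = error_model,
                 reader_sd = reader_sd, pairs = pairs,
                 stratifiers = match.arg(stratifiers,
                                         c("ivh", "location", "volume_40"),
                                         several.ok = TRUE),
                 acceptance_limit_pct = acceptance_limit_pct,
                 repeat_fraction = repeat_fraction,
                 n_repeat_readers = as.integer(n_repeat_readers),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

# measure one case with all three methods; masks are discarded afterwards so
# memory stays flat across large cohorts
measure_case <- function(vol, par, config, is_repeat, ref_mL = NULL) {
  if (is.null(ref_mL)) ref_mL <- voxel_volume_mL(vol, 1L)
  recs <- list(measurement_record(par$case_id, "reference_voxel",
                                  volume_mL = ref_mL))
  ideal <- abc2_measure(vol)
  n_readers <- if (is_repeat) config$n_repeat_readers else 1L
  for (r in seq_len(n_readers)) {
    recs <- c(recs, list(simulate_abc2_reader(
      ideal, config$reader_sd, seed = par$case_seed + 10L + r,
      case_id = par$case_id, reader_id = sprintf("reader_%d", r))))
  }
  recs <- c(recs, list(simulate_auto_segmentation(
    NULL, par, config$error_model, seed = par$case_seed + 3L)))
  do.call(rbind, recs)
}

#' Run the full synthetic agreement study
#'
#' End-to-end pipeline: sample the phantom cohort; measure every case with
#' the voxel-count reference, the ABC/2 estimator (with reader noise; a
#' configurable subsample is read by several readers), and the simulated
#' automated segmenter; then run the complete agreement analysis for every
#' requested method pair: absolute and percent Bland-Altman limits with
#' heteroscedasticity-adaptive log back-transformation, subgroup analyses,
#' paired t-tests, Shapiro-Wilk normality checks, the inter-observer ICC,
#' and the clinical acceptability verdicts. Fully reproducible from the
#' seed.
#'
#' @param config a [study_config()].
#' @param keep_masks if `TRUE`, return the phantom masks (memory-heavy for
#'   large cohorts).
#' @return A list with `truth` (ground-truth table), `records` (long
#'   measurement table), `report` (the agreement report, see
#'   [write_agreement_report()]), and optionally `volumes`. If
#'   `config$out_dir` is set, `truth.csv`, `measurements.csv` and
#'   `report.json` are written there.
#' @export
run_study <- function(config, keep_masks = FALSE) {
  if (!inherits(config, "study_config")) stop("expected a `study_config`")
  params <- sample_cohort_params(config$cohort)
  n <- nrow(params)
  repeat_ids <- with_seed(config$seed + 1L, {
    k <- max(0L, round(config$repeat_fraction * n))
    sample(params$case_id, k)
  })
  rec_list <- vector("list", n)
  vols <- if (keep_masks) stats::setNames(vector("list", n), params$case_id)
  for (i in seq_len(n)) {
    par <- params[i, ]
    # distractor voxels influence no measurement (the automated method's
    # distractor inclusion is parametric), so masks are built without them
    vol <- tryCatch(build_phantom(par, distractors = FALSE), error = function(e) {
      stop(sprintf("case %s: %s", par$case_id, conditionMessage(e)),
           call. = FALSE)
    })
    lv <- label_volumes_mL(vol)
    params$true_ich_volume_mL[i] <- lv[["1"]]
    params$true_ivh_volume_mL[i] <- lv[["2"]]
    rec_list[[i]] <- measure_case(vol, params[i, ], config,
                                  par$case_id %in% repeat_ids,
                                  ref_mL = lv[["1"]])
    if (keep_masks) vols[[i]] <- vol
  }
  records <- do.call(rbind, rec_list)
  truth <- params[c("case_id", "true_ich_volume_mL", "true_ivh_volume_mL",
                    "location", "ivh_present", "irregularity",
                    "slice_thickness_mm")]
  report <- agreement_report(records, truth, config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_truth(truth, file.path(config$out_dir, "truth.csv"))
    write_measurements(records, file.path(config$out_dir, "measurements.csv"))
    write_agreement_report(report, file.path(config$out_dir, "report.json"))
  }
  out <- list(truth = truth, records = records, report = report)
  if (keep_masks) out$volumes <- vols
  out
}

ba_result_fields <- function(res) {
  if (identical(res, "not estimable")) {
    return(list(estimable = FALSE))
  }
  out <- list(estimable = TRUE, n = res$n, mode = res$mode,
              mean_diff = res$mean_diff, sd_diff = res$sd_diff,
              loa_low = res$loa_low, loa_high = res$loa_high,
              tau_raw = res$tau_raw, heteroscedastic = res$heteroscedastic)
  if (!is.null(res$log_branch)) out$log_branch <- res$log_branch
  out
}

#' Assemble the full agreement report
#'
#' Runs every analysis of the study on an existing measurement table and
#' ground-truth table: per-pair absolute and percent Bland-Altman results
#' (overall and per stratum, with the heteroscedasticity-adaptive log
#' branch), paired t and Shapiro-Wilk tests, the ABC/2 inter-observer ICC,
#' event counts, the Table-2-style cohort summary, and the clinical
#' acceptability verdicts. [run_study()] calls this on the cohort it
#' simulates; it can equally be applied to tables read back from CSV.
#'
#' @param records long-format measurement table (see [write_measurements()]).
#' @param truth cohort ground-truth table (see [write_cohort_truth()]).
#' @param config a [study_config()]; only its `pairs`, `stratifiers` and
#'   `acceptance_limit_pct` (and `seed`, echoed) are used here.
#' @return The report list; serialise with [write_agreement_report()].
#' @export
agreement_report <- function(records, truth, config = study_config()) {
  entries <- list()
  tests <- list()
  acceptance <- list()
  for (pair in config$pairs) {
    key <- paste(pair[1], "vs", pair[2])
    paired <- tryCatch(paired_complete_cases(records, pair[1], pair[2]),
                       error = function(e) NULL)
    for (mode in c("absolute", "percent")) {
      entries[[length(entries) + 1L]] <- c(
        list(pair = key, mode = mode, stratifier = "overall",
             stratum = "overall"),
        ba_result_fields(if (is.null(paired)) "not estimable" else
          adaptive_log_loa(paired, mode = mode)))
      for (strat in config$stratifiers) {
        by_stratum <- subgroup_agreement(records, truth, strat,
                                         pair[1], pair[2], mode = mode)
        for (nm in names(by_stratum)) {
          entries[[length(entries) + 1L]] <- c(
            list(pair = key, mode = mode, stratifier = strat, stratum = nm),
            ba_result_fields(by_stratum[[nm]]))
        }
      }
    }
    if (!is.null(paired)) {
      d_abs <- differences(paired, "absolute")$d
      # degenerate pairs (zero-variance differences) make these tests
      # undefined; the report notes that instead of failing
      tests[[key]] <- list(
        paired_t = tryCatch({
          tt <- paired_t_test(d_abs)
          list(statistic = tt$statistic, p_value = tt$p_value, df = tt$df)
        }, error = function(e) list(note = conditionMessage(e))),
        shapiro_wilk = tryCatch({
          sw <- shapiro_wilk(d_abs)
          list(statistic = sw$statistic, p_value = sw$p_value)
        }, error = function(e) list(note = conditionMessage(e))))
      pct <- adaptive_log_loa(paired, mode = "percent")
      acceptance[[key]] <- list(
        limit_pct = config$acceptance_limit_pct,
        loa_low = pct$loa_low, loa_high = pct$loa_high,
        acceptable = acceptance_check(pct, config$acceptance_limit_pct))
    } else {
      tests[[key]] <- list(note = "not estimable")
      acceptance[[key]] <- list(note = "not estimable")
    }
  }
  abc2_rows <- records[records$method == "abc2" & !is.na(records$volume_mL), ]
  icc <- tryCatch({
    r <- icc_oneway(abc2_rows)
    list(icc = r$icc, ms_between = r$ms_between, ms_within = r$ms_within,
         n_subjects = r$n_subjects, k_bar = r$k_bar)
  }, error = function(e) list(note = conditionMessage(e)))
  missed_ids <- unique(records$case_id[records$missed])
  list(
    n_cases = nrow(truth),
    n_missed = length(missed_ids),
    n_complete = length(setdiff(truth$case_id, missed_ids)),
    event_counts = list(
      missed = sum(records$missed),
      partial = sum(records$partial),
      ivh_included = sum(records$ivh_included),
      distractor_included = sum(records$distractor_included)),
    cohort_summary = summarize_cohort(records, truth),
    agreement = entries,
    tests = tests,
    icc_abc2 = icc,
    acceptance = acceptance,
    seed = config$seed)
}

#' Measure an existing phantom cohort
#'
#' Applies the three volumetry methods to masks that already exist (e.g.
#' read back from NIfTI): the voxel-count reference, noisy ABC/2 readings
#' (with a repeat-read subsample for the inter-observer ICC), and the
#' parametric automated-segmentation simulator driven by the ground truth.
#' [run_study()] performs the same measurements inline; this entry point
#' serves the file-based workflow.
#'
#' @param volumes named list of [labeled_volume()] masks, names matching
#'   `truth$case_id`.
#' @param truth cohort ground-truth table.
#' @param error_model an [auto_seg_error_model()].
#' @param reader_sd ABC/2 reader noise (log-scale SD).
#' @param repeat_fraction fraction of cases read by the additional readers.
#' @param n_repeat_readers readers on the repeat subsample.
#' @param seed integer seed for all measurement randomness.
#' @return Long-format measurement data frame.
#' @export
measure_cohort <- function(volumes, truth,
                           error_model = auto_seg_error_model(),
                           reader_sd = 0.05,
                           repeat_fraction = 0.1,
                           n_repeat_readers = 3L,
                           seed = 1L) {
  if (!all(truth$case_id %in% names(volumes))) {
    stop("every truth case_id needs a mask in `volumes`")
  }
  n <- nrow(truth)
  plan <- with_seed(seed, {
    list(repeat_ids = sample(truth$case_id, max(0L, round(repeat_fraction * n))),
         case_seed = sample.int(.Machine$integer.max - 1L, n))
  })
  cfg <- list(error_model = error_model, reader_sd = reader_sd,
              n_repeat_readers = as.integer(n_repeat_readers))
  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    par <- truth[i, ]
    par$case_seed <- plan$case_seed[i]
    rec_list[[i]] <- measure_case(volumes[[par$case_id]], par, cfg,
                                  par$case_id %in% plan$repeat_ids)
  }
  do.call(rbind, rec_list)
}

#' Summarise measured volumes per method
#'
#' The per-method descriptive table of the study report: mean, median and
#' IQR of the measured volumes for all cases, for complete cases (cases
#' measured by every method), and for the cases missed by the automated
#' method, plus the same summaries restricted to cases without IVH.
#' Quantiles use R's default type-7 linear interpolation. An empty subset
#' yields `NA` summaries, not zeros.
#'
#' @param records long-format measurement table (first readings are used).
#' @param truth cohort ground-truth table.
#' @return A data frame with columns `subset`, `method`, `n`, `mean`,
#'   `median`, `q25`, `q75`.
#' @export
summarize_cohort <- function(records, truth) {
  if (!nrow(records)) stop("`records` is empty")
  first <- records[order(records$case_id, records$method, records$reader_id), ]
  first <- first[!duplicated(first[c("case_id", "method")]), ]
  methods <- sort(unique(first$method))
  measured <- function(meth) {
    sub <- first[first$method == meth & !is.na(first$volume_mL), ]
    stats::setNames(sub$volume_mL, sub$case_id)
  }
  missed_ids <- unique(first$case_id[first$missed])
  complete_ids <- setdiff(truth$case_id, missed_ids)
  no_ivh_ids <- truth$case_id[!truth$ivh_present]
  subsets <- list(
    all = truth$case_id,
    complete = complete_ids,
    missed = missed_ids,
    no_ivh_all = no_ivh_ids,
    no_ivh_complete = intersect(no_ivh_ids, complete_ids))
  rows <- list()
  for (sub_name in names(subsets)) {
    for (meth in methods) {
      v <- measured(meth)
      v <- v[names(v) %in% subsets[[sub_name]]]
      q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                          type = 7) else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = sub_name, method = meth, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        median = q[2], q25 = q[1], q75 = q[3],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write an agreement report as JSON
#'
#' The report is serialised deterministically (no environment-dependent
#' ordering), so identical configurations and seeds produce byte-identical
#' files. The shipped schema (`inst/schema/agreement_report_schema.json`)
#' describes the structure; see [validate_report()].
#'
#' @param report report list from [run_study()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_agreement_report
#' @export
read_agreement_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Validate an agreement report against the shipped schema
#'
#' Structural validation: checks the required properties listed in the
#' package's JSON schema file, including the per-entry fields of the
#' agreement list.
#'
#' @param report report list (as returned by [run_study()] or
#'   [read_agreement_report()]).
#' @return `TRUE`, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "agreement_report_schema.json",
                             package = "ichagree")
  schema <- jsonlite::read_json(schema_path)
  for (key in unlist(schema$required)) {
    if (is.null(report[[key]])) stop(sprintf("report lacks required field '%s'", key))
  }
  entry_req <- unlist(schema$properties$agreement$items$required)
  for (i in seq_along(report$agreement)) {
    e <- report$agreement[[i]]
    for (key in entry_req) {
      if (is.null(e[[key]])) {
        stop(sprintf("agreement entry %d lacks required field '%s'", i, key))
      }
    }
    if (isTRUE(e$estimable)) {
      for (key in unlist(schema$properties$agreement$items$estimable_required)) {
        if (is.null(e[[key]])) {
          stop(sprintf("estimable agreement entry %d lacks field '%s'", i, key))
        }
      }
    }
  }
  TRUE
}
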