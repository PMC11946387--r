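#' Pipeline configuration
#'
#' Everything one run needs: the input mode, the cohort source, modeling
#' and threshold settings, and a single seed from which all randomness
#' flows.
#'
#' @param mode `"synthetic"` (generate a cohort), `"cohort_csv"` (read one),
#'   or `"images"` (NIfTI exams to an FTV table only).
#' @param cohort_csv Path to the cohort CSV (`cohort_csv` mode).
#' @param image_manifest data.frame for `images` mode: columns
#'   `patient_id`, `timepoint`, `s0`, `s1`, `s2` (NIfTI paths), `config`
#'   (per-patient VOI/threshold JSON).
#' @param cohort A [cohort_spec()] for synthetic mode; its seed is
#'   overridden by `seed`.
#' @param k_folds Stratified CV folds for predictor selection.
#' @param ppv_levels Minimum PPV levels in percent, each in (0, 100].
#' @param decision_ppv_level Level whose threshold drives per-patient
#'   recommendations (default 50).
#' @param min_class_count Minimum records per outcome class for a subtype
#'   model; smaller strata are flagged, not fit.
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "cohort_csv", "images"),
                            cohort_csv = NULL, image_manifest = NULL,
                            cohort = cohort_spec(),
                            k_folds = 5L, ppv_levels = c(50, 70, 90),
                            decision_ppv_level = 50,
                            min_class_count = 10L,
                            seed = 1L, out_dir = "results") {
  mode <- match.arg(mode)
  if (any(ppv_levels <= 0 | ppv_levels > 100))
    stop("ppv_levels must lie in (0, 100]", call. = FALSE)
  if (!decision_ppv_level %in% ppv_levels)
    stop("decision_ppv_level must be one of ppv_levels", call. = FALSE)
  if (mode == "cohort_csv" && (is.null(cohort_csv) || !file.exists(cohort_csv)))
    stop("cohort_csv mode requires an existing cohort CSV path", call. = FALSE)
  if (mode == "images" && is.null(image_manifest))
    stop("images mode requires an image manifest", call. = FALSE)
  structure(list(mode = mode, cohort_csv = cohort_csv,
                 image_manifest = image_manifest, cohort = cohort,
                 k_folds = as.integer(k_folds), ppv_levels = ppv_levels,
                 decision_ppv_level = decision_ppv_level,
                 min_class_count = as.integer(min_class_count),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

ftv_from_manifest <- function(manifest) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    cfg <- read_patient_config(m$config)
    exam <- read_dce_exam(m$patient_id, m$timepoint, m$s0, m$s1, m$s2)
    res <- compute_ftv(exam, cfg$voi, cfg$thresholds)
    data.frame(patient_id = m$patient_id, timepoint = m$timepoint,
               ftv_cc = res$ftv_cc, voxel_count = res$voxel_count,
               pe_min = cfg$thresholds$pe_min,
               ser_min = cfg$thresholds$ser_min,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

fit_scope <- function(records, scope, cfg) {
  counts <- table(factor(records$pcr, levels = 0:1))
  if (nrow(records) == 0L || any(counts < cfg$min_class_count))
    return(NULL)
  select_model(records, k_folds = cfg$k_folds, seed = cfg$seed,
               scope = scope)
}

#' Run the full response-modeling pipeline
#'
#' Stages: obtain the cohort (synthetic, CSV, or — in `images` mode — stop
#' after the FTV table), audit exclusions, fit the full-cohort and
#' per-subtype logistic models with cross-validated predictor selection,
#' build PPV-sensitivity curves and select thresholds at every configured
#' PPV level, and emit per-patient recommendations at the decision level.
#' Subtypes with too few records per outcome class are reported as
#' `"insufficient data"` rather than aborting the run. Artifacts written
#' to `out_dir`: `cohort.csv` (synthetic mode), `ftv.csv` (images mode),
#' `models.json`, `threshold_report.csv`, `implications.csv`,
#' `decisions.csv`, `run_log.json`. Idempotent for a fixed config + seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the cohort, audit, fitted `models`,
#'   `selections`, `report`, `implications` and `decisions`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  log <- list(seed = cfg$seed, mode = cfg$mode,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("ftvresponse")),
              stages = list())

  if (cfg$mode == "images") {
    ftv <- ftv_from_manifest(cfg$image_manifest)
    utils::write.csv(ftv, file.path(cfg$out_dir, "ftv.csv"),
                     row.names = FALSE)
    log$stages$ftv <- list(n_rows = nrow(ftv))
    jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(ftv = ftv, log = log)))
  }

  cohort <- if (cfg$mode == "synthetic") {
    spec <- cfg$cohort
    spec$seed <- cfg$seed
    co <- generate_cohort(spec)
    write_cohort_csv(co, file.path(cfg$out_dir, "cohort.csv"))
    co
  } else read_cohort_csv(cfg$cohort_csv)
  log$stages$cohort <- list(n = nrow(cohort))

  audit <- exclusion_audit(cohort)
  records <- audit$records
  log$stages$exclusions <- audit[c("n_input",
                                   "n_missing_outcome_or_receptor",
                                   "n_missing_ftv", "n_analysis")]
  if (nrow(records) == 0L)
    stop("pipeline stage 'exclusions': no analyzable records remain",
         call. = FALSE)
  if (length(unique(records$pcr)) < 2L)
    stop("pipeline stage 'models': a single outcome class remains after ",
         "exclusions", call. = FALSE)

  scopes <- c("full", sort(unique(records$subtype)))
  models <- list()
  selections <- list()
  for (scope in scopes) {
    sub <- if (scope == "full") records
           else records[records$subtype == scope, , drop = FALSE]
    model <- fit_scope(sub, scope, cfg)
    models[[scope]] <- model
    if (is.null(model)) { selections[[scope]] <- NULL; next }
    curve <- ppv_sensitivity_curve(predict(model, sub), sub$pcr)
    selections[[scope]] <- lapply(cfg$ppv_levels,
                                  function(l) select_threshold(curve, l))
    names(selections[[scope]]) <- as.character(cfg$ppv_levels)
  }
  log$stages$models <- lapply(models, function(m)
    if (is.null(m)) "insufficient data"
    else list(predictors = m$predictors, cv_auc = m$cv_auc))

  fitted <- !vapply(models, is.null, TRUE)
  report <- threshold_report(selections[names(selections)[
    !vapply(selections, is.null, TRUE)]])
  for (scope in scopes[!fitted]) {
    report <- rbind(report, data.frame(
      cohort = scope, ppv_level = cfg$ppv_levels,
      threshold = "insufficient data", sensitivity = NA_real_,
      ci_lo = NA_real_, ci_hi = NA_real_, stringsAsFactors = FALSE))
  }
  utils::write.csv(report, file.path(cfg$out_dir, "threshold_report.csv"),
                   row.names = FALSE)

  lev <- as.character(cfg$decision_ppv_level)
  imp_in <- lapply(selections[setdiff(names(selections), "full")],
                   function(s) s[[lev]])
  imp_in <- imp_in[!vapply(imp_in, is.null, TRUE)]
  implications <- implication_report(imp_in)
  utils::write.csv(implications, file.path(cfg$out_dir, "implications.csv"),
                   row.names = FALSE)

  decisions <- data.frame(patient_id = cohort$patient_id,
                          subtype = cohort$subtype,
                          probability = NA_real_,
                          decision = "insufficient data",
                          stringsAsFactors = FALSE)
  for (scope in setdiff(scopes, "full")) {
    if (is.null(models[[scope]])) next
    idx <- which(decisions$subtype == scope &
                   cohort$patient_id %in% records$patient_id)
    rows <- cohort[idx, , drop = FALSE]
    pr <- predict(models[[scope]], rows)
    sel <- selections[[scope]][[lev]]
    decisions$probability[idx] <- pr
    decisions$decision[idx] <- vapply(pr, recommend, "", selection = sel)
  }
  utils::write.csv(decisions, file.path(cfg$out_dir, "decisions.csv"),
                   row.names = FALSE)
  log$stages$decisions <- list(n = nrow(decisions))

  model_json <- lapply(models[fitted], function(m)
    list(scope = m$scope, predictors = m$predictors,
         intercept = m$intercept, coefficients = as.list(m$coefficients),
         cv_auc = m$cv_auc, k_folds = m$k_folds, seed = m$seed))
  jsonlite::write_json(model_json, file.path(cfg$out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, audit = audit, models = models,
                 selections = selections, report = report,
                 implications = implications, decisions = decisions,
                 log = log))
}
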