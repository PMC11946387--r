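#' Candidate FTV predictor sets
#'
#' The seven non-empty subsets of `{ftv_t0_cc, dftv_t1_pct, dftv_t2_pct}`,
#' ordered by size then lexicographically — the order used to break
#' cross-validated-AUC ties toward parsimony.
#'
#' @return List of character vectors.
#' @export
candidate_predictor_sets <- function() {
  vars <- c("dftv_t1_pct", "dftv_t2_pct", "ftv_t0_cc")
  sets <- list()
  for (k in 1:3)
    sets <- c(sets, utils::combn(vars, k, simplify = FALSE))
  sets
}

# drop records unusable for fitting: missing outcome or any predictor
# (undefined percent change from ftv_t0 = 0 arrives here as NA)
complete_records <- function(records, predictors) {
  keep <- !is.na(records$pcr)
  for (p in predictors) keep <- keep & !is.na(records[[p]])
  records[keep, , drop = FALSE]
}

#' Fit a logistic pCR model for one predictor set
#'
#' Maximum-likelihood logistic regression of pCR on the given FTV
#' variables, untransformed: percent changes in percent units, baseline FTV
#' in cc, so predicted-probability thresholds stay on the clinical scale.
#' Complete separation is detected and flagged (fit returned with a
#' warning; predicted probabilities remain defined).
#'
#' @param records data.frame with columns `pcr` (0/1) and the predictors.
#' @param predictors Character vector of predictor column names.
#' @return Object of class `ftv_model`: `predictors`, `intercept`,
#'   `coefficients` (named, log-odds per unit), `separation` flag, and the
#'   underlying `glm` fit.
#' @export
fit_logistic <- function(records, predictors) {
  records <- complete_records(records, predictors)
  tab <- table(factor(records$pcr, levels = 0:1))
  if (any(tab == 0))
    stop("both outcome classes must be present to fit", call. = FALSE)
  if (any(tab < 2))
    stop("need at least 2 records per outcome class", call. = FALSE)
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("pcr ~", rhs))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # complete separation: the fitted score splits the classes perfectly
  # (glm can converge on such data without warning)
  if (!fit$converged) sep <- TRUE
  if (length(predictors)) {
    mu <- stats::fitted(fit)
    if (min(mu[records$pcr == 1]) > max(mu[records$pcr == 0])) sep <- TRUE
  }
  if (sep)
    warning("possible complete separation: coefficients unreliable, ",
            "predicted probabilities still defined", call. = FALSE)
  cf <- stats::coef(fit)
  structure(list(predictors = predictors,
                 intercept = unname(cf["(Intercept)"]),
                 coefficients = cf[setdiff(names(cf), "(Intercept)")],
                 separation = sep, glm = fit),
            class = "ftv_model")
}

#' Predicted pCR probabilities
#'
#' @param object An `ftv_model`.
#' @param newdata data.frame containing the model's predictors; defaults to
#'   the training records.
#' @param ... Unused.
#' @return Numeric vector of probabilities (inverse-logit of the linear
#'   predictor).
#' @export
predict.ftv_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(unname(stats::predict(object$glm, type = "response")))
  unname(stats::predict(object$glm, newdata = newdata, type = "response"))
}

#' @export
print.ftv_model <- function(x, ...) {
  cat(sprintf("<ftv_model> pCR ~ %s\n",
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  intercept %.4f; %s%s\n", x$intercept,
              paste(sprintf("%s %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              if (isTRUE(x$separation)) "  [separation flagged]" else ""))
  if (!is.null(x$cv_auc))
    cat(sprintf("  cv AUC %.3f (scope %s)\n", x$cv_auc,
                x$scope %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) form: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted half.
#'
#' @param scores Numeric vector of scores or probabilities.
#' @param labels Logical/0-1 vector of true outcomes, same length.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)              # midranks handle ties exactly
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment: positives and negatives are each split
# round-robin after shuffling, so every fold keeps both classes whenever
# counts allow
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Select the FTV predictor set by cross-validated AUC
#'
#' For each candidate predictor set, fits the logistic model on k-1
#' stratified folds and scores the held-out fold; the mean held-out AUC
#' over folds ranks the candidates. Candidates within `tie_tol` of the best
#' mean AUC are treated as tied, and the tie is broken toward fewer
#' predictors, then lexicographic order — without a tolerance, a pure-noise
#' predictor riding sampling error would win roughly half of near-ties,
#' which contradicts the parsimony the selection is meant to enforce. The
#' winner is refit on all records. Folds with a single outcome class
#' trigger a bounded number of reseeded refolds before erroring.
#'
#' @param records data.frame with `pcr` and the candidate predictors.
#' @param candidates List of predictor sets; default all seven subsets of
#'   the three FTV variables.
#' @param k_folds Number of stratified folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param scope Label stored on the model (subtype name or `"full"`).
#' @param tie_tol Mean-AUC margin within which candidates count as tied
#'   (default 0.01).
#' @param max_refolds Retries when a fold degenerates to one class.
#' @return An `ftv_model` refit on all records, with `cv_auc` (winning
#'   mean held-out AUC), `cv_auc_table` (per-candidate), `scope`,
#'   `k_folds`, `seed` attached.
#' @export
select_model <- function(records, candidates = candidate_predictor_sets(),
                         k_folds = 5L, seed = 1L, scope = "full",
                         tie_tol = 0.01, max_refolds = 10L) {
  stopifnot(length(candidates) >= 1L)
  all_pred <- unique(unlist(candidates))
  records <- complete_records(records, all_pred)
  labels <- records$pcr
  if (length(unique(labels)) < 2L)
    stop("both outcome classes required for model selection", call. = FALSE)
  if (min(table(labels)) < k_folds)
    stop("too few records in the minority class for ", k_folds,
         "-fold stratified CV", call. = FALSE)

  fold <- NULL
  for (attempt in 0:max_refolds) {
    f <- stratified_folds(labels, k_folds, seed + attempt)
    ok <- all(vapply(seq_len(k_folds), function(j)
      length(unique(labels[f != j])) == 2L && any(f == j), TRUE))
    if (ok) { fold <- f; break }
  }
  if (is.null(fold))
    stop("could not build folds with both classes after ",
         max_refolds, " refolds", call. = FALSE)

  cv_auc <- vapply(candidates, function(preds) {
    aucs <- vapply(seq_len(k_folds), function(j) {
      train <- records[fold != j, , drop = FALSE]
      test <- records[fold == j, , drop = FALSE]
      if (length(unique(test$pcr)) < 2L) return(NA_real_)
      m <- suppressWarnings(fit_logistic(train, preds))
      compute_auc(predict(m, test), test$pcr)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))

  # highest mean held-out AUC; near-ties (within tie_tol) -> fewer
  # predictors, then the candidates' lexicographic order
  # (candidate_predictor_sets() is sorted)
  sizes <- lengths(candidates)
  tied <- which(cv_auc >= max(cv_auc) - tie_tol)
  best <- tied[order(sizes[tied], tied)][1]
  model <- fit_logistic(records, candidates[[best]])
  model$cv_auc <- cv_auc[best]
  model$cv_auc_table <- data.frame(
    predictors = vapply(candidates, paste, "", collapse = "+"),
    n_predictors = sizes, cv_auc = cv_auc, stringsAsFactors = FALSE)
  model$scope <- scope
  model$k_folds <- as.integer(k_folds)
  model$seed <- as.integer(seed)
  model
}

#' Serialize a fitted model to JSON
#'
#' @param model An `ftv_model` from [select_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "ftv_model"))
  jsonlite::write_json(
    list(scope = model$scope %||% NA, predictors = model$predictors,
         intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         cv_auc = model$cv_auc %||% NA,
         cv_auc_table = model$cv_auc_table %||% NULL,
         k_folds = model$k_folds %||% NA, seed = model$seed %||% NA,
         separation = model$separation),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
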