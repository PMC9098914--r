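#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end experiment: split fraction and
#' seed, region-growing tolerance (gray levels), peritumoral ring radius
#' (mm; 20 mm = 2 cm by default), original-ROI box margin (mm), gray
#' quantization levels, the selection-frequency cutoff (0.5 = features kept
#' in at least half of the leave-one-out rounds), GA and SVM parameters, and
#' the bootstrap/permutation round counts. All randomness derives from
#' `seed`.
#'
#' @param fraction Training fraction of the stratified hold-out split.
#' @param tolerance Region-growing gray-level tolerance.
#' @param ring_mm Peritumoral dilation radius in mm.
#' @param box_margin_mm Original-ROI bounding-box margin in mm.
#' @param levels Gray quantization levels for the texture matrices.
#' @param cutoff Leave-one-out selection-frequency cutoff.
#' @param ga A [ga_params()] (its seed is overridden by `seed`).
#' @param cost,gamma SVM hyperparameters (see [train_svm()]).
#' @param bootstrap_rounds Bootstrap rounds for the 95% CIs.
#' @param perm_rounds Permutation rounds for AUC significance.
#' @param include_concat Also fit the direct clinical+radiomic(original)
#'   concatenation model (reported as a 12th row).
#' @param seed Master seed for the whole run.
#' @return An object of class `sln_config`.
#' @export
sln_config <- function(fraction = 0.8, tolerance = 25, ring_mm = 20,
                       box_margin_mm = 5, levels = 32L, cutoff = 0.5,
                       ga = ga_params(), cost = 1, gamma = NULL,
                       bootstrap_rounds = 200L, perm_rounds = 1000L,
                       include_concat = FALSE, seed = 1L) {
  ga$seed <- as.integer(seed)
  structure(list(fraction = fraction, tolerance = tolerance, ring_mm = ring_mm,
                 box_margin_mm = box_margin_mm, levels = as.integer(levels),
                 cutoff = cutoff, ga = ga, cost = cost, gamma = gamma,
                 bootstrap_rounds = as.integer(bootstrap_rounds),
                 perm_rounds = as.integer(perm_rounds),
                 include_concat = include_concat, seed = as.integer(seed)),
            class = "sln_config")
}

# internal: per-ROI-type feature matrices for a cohort (patients x features,
# feature names prefixed by ROI type); uses precomputed cohort$features when
# present, otherwise runs inpainting, region growing, ROI construction and
# the 134-feature extraction per patient.
cohort_feature_tables <- function(cohort, config) {
  if (!is.null(cohort$features)) {
    tabs <- cohort$features
  } else {
    if (is.null(cohort$images))
      stop("cohort has neither images nor precomputed features")
    man <- feature_manifest()
    n <- length(cohort$images)
    tabs <- list(original = NULL, intra = NULL, peri = NULL, combined = NULL)
    rows <- lapply(seq_len(n), function(i) {
      img <- cohort$images[[i]]
      if (!is.null(img$marker_mask) && any(img$marker_mask))
        img <- inpaint(img)
      lesion <- region_grow(img, cohort$seeds[[i]], config$tolerance)
      rs <- build_roi_set(img, lesion, config$ring_mm, config$box_margin_mm)
      extract_roi_features(img, rs, config$levels, manifest = man)
    })
    for (ty in names(tabs))
      tabs[[ty]] <- do.call(rbind, lapply(rows, `[[`, ty))
  }
  for (ty in names(tabs))
    colnames(tabs[[ty]]) <- paste(ty, colnames(tabs[[ty]]), sep = ".")
  if (is.null(tabs$intra_peri))
    tabs$intra_peri <- cbind(tabs$intra, tabs$peri)
  tabs
}

# internal: fit on selected features, score the test set
fit_and_score <- function(x, y, split, feats, config) {
  fit <- train_svm(x[split$train_ids, feats, drop = FALSE], y[split$train_ids],
                   cost = config$cost, gamma = config$gamma,
                   seed = config$seed)
  list(fit = fit,
       scores = stats::predict(fit, x[split$test_ids, feats, drop = FALSE]))
}

# internal: metrics + CIs + significance for one model's test scores
report_row <- function(name, scores, y_test, threshold, n_features, config) {
  m <- evaluate_scores(scores, y_test, threshold)
  ci <- lapply(c(auc = "auc", accuracy = "accuracy",
                 sensitivity = "sensitivity", specificity = "specificity"),
               function(mt) bootstrap_ci(scores, y_test, mt,
                                         rounds = config$bootstrap_rounds,
                                         seed = config$seed,
                                         threshold = threshold))
  p <- auc_significance(scores, y_test, rounds = config$perm_rounds,
                        seed = config$seed)
  data.frame(model = name, n_features = n_features,
             auc = m$auc, auc_lo = ci$auc[1], auc_hi = ci$auc[2],
             accuracy = m$accuracy, acc_lo = ci$accuracy[1],
             acc_hi = ci$accuracy[2],
             sensitivity = m$sensitivity, sens_lo = ci$sensitivity[1],
             sens_hi = ci$sensitivity[2],
             specificity = m$specificity, spec_lo = ci$specificity[1],
             spec_hi = ci$specificity[2],
             auc_p = p, significant = p < 0.05,
             stringsAsFactors = FALSE)
}

#' Run the eleven-model experiment
#'
#' The full pipeline on one cohort: proximity imputation and encoding of the
#' clinical table; radiomic feature extraction for the four ROI types (plus
#' the intra+peri concatenation); one stratified hold-out split shared by
#' all models; the clinical RBF-SVM (no feature selection); five radiomic
#' RBF-SVMs, each trained on the features whose GA selection frequency over
#' the leave-one-out rounds reaches the cutoff; and the five soft-voting
#' ensembles of the clinical model with each radiomic model. Every model is
#' evaluated on the same hold-out test set at a threshold equal to the
#' training-set positive prevalence, with percentile-bootstrap 95% CIs and a
#' permutation p-value for AUC.
#'
#' @param cohort A [gen_cohort()] result, or any list with `clinical`
#'   (a [clinical_table()]), `labels`, and either `images` + `seeds` or
#'   precomputed `features` (named list of per-ROI feature matrices).
#' @param config A [sln_config()].
#' @return An object of class `sln_experiment`: the Table-2-shaped `report`
#'   (one row per model), per-model test `scores`, `profiles` (selection
#'   profiles of the radiomic models), the `split`, decision `threshold`
#'   and `config`.
#' @export
sln_experiment <- function(cohort, config = sln_config()) {
  stopifnot(inherits(config, "sln_config"))
  y <- as.integer(cohort$labels)

  clin <- impute_proximity(clinical_table(cohort$clinical))
  enc <- encode_clinical(clin)
  if (any(is.na(enc$x))) stop("clinical encoding left missing values")

  tabs <- cohort_feature_tables(cohort, config)
  split <- stratified_split(y, config$fraction, seed = config$seed)
  threshold <- mean(y[split$train_ids])
  y_test <- y[split$test_ids]

  scores <- list(); profiles <- list(); rows <- list()

  cl <- fit_and_score(enc$x, y, split, colnames(enc$x), config)
  scores[["Clinical"]] <- cl$scores
  rows[["Clinical"]] <- report_row("Clinical", cl$scores, y_test, threshold,
                                   ncol(enc$x), config)

  roi_names <- c(original = "original", intra = "intra", peri = "peri",
                 comb = "combined", `intra+peri` = "intra_peri")
  for (k in seq_along(roi_names)) {
    lab <- names(roi_names)[k]; ty <- roi_names[[k]]
    x <- tabs[[ty]]
    prof <- loocv_frequency(x[split$train_ids, , drop = FALSE],
                            y[split$train_ids], config$ga, config$cutoff)
    feats <- attr(prof, "selected_set")
    if (!length(feats))  # degenerate profile: fall back to the modal features
      feats <- select_at(prof, max(prof$frequency))
    profiles[[lab]] <- prof
    rad <- fit_and_score(x, y, split, feats, config)
    rname <- paste("Radiomic", lab)
    scores[[rname]] <- rad$scores
    rows[[rname]] <- report_row(rname, rad$scores, y_test, threshold,
                                length(feats), config)
    sv <- soft_vote(scores[["Clinical"]], rad$scores)
    sname <- sprintf("Clinical/Radiomic %s (SV)", lab)
    scores[[sname]] <- sv
    rows[[sname]] <- report_row(sname, sv, y_test, threshold,
                                length(feats) + ncol(enc$x), config)
  }

  if (isTRUE(config$include_concat)) {
    xc <- cbind(enc$x, tabs$original)
    cc <- fit_and_score(xc, y, split, colnames(xc), config)
    nm <- "Clinical+Radiomic original (concat)"
    scores[[nm]] <- cc$scores
    rows[[nm]] <- report_row(nm, cc$scores, y_test, threshold, ncol(xc), config)
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, scores = scores, profiles = profiles,
                 split = split, threshold = threshold, config = config,
                 labels = y),
            class = "sln_experiment")
}

#' @rdname sln_experiment
#' @export
run_experiment <- sln_experiment

#' @export
print.sln_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("Eleven-model nodal-status experiment: %d train / %d test, threshold %.3f\n\n",
              length(x$split$train_ids), length(x$split$test_ids), x$threshold))
  df <- x$report
  out <- data.frame(model = df$model,
                    AUC = sprintf("%.3f (%.2f-%.2f)%s", df$auc, df$auc_lo,
                                  df$auc_hi, ifelse(df$significant, " *", "")),
                    accuracy = round(df$accuracy, digits),
                    sensitivity = round(df$sensitivity, digits),
                    specificity = round(df$specificity, digits))
  print(out, row.names = FALSE)
  cat("\n* permutation p < 0.05 for AUC vs chance\n")
  invisible(x)
}

#' @export
summary.sln_experiment <- function(object, ...) {
  df <- object$report
  best <- df$model[which.max(df$auc)]
  cat(sprintf("Best model by test AUC: %s (AUC %.3f)\n\n", best, max(df$auc)))
  print.sln_experiment(object, ...)
  invisible(df)
}

#' @export
as.data.frame.sln_experiment <- function(x, ...) x$report

#' @export
plot.sln_experiment <- function(x, ...) {
  df <- x$report
  n <- nrow(df)
  old <- graphics::par(mar = c(4, 14, 2, 1)); on.exit(graphics::par(old))
  graphics::plot(df$auc, seq_len(n), xlim = c(0, 1), yaxt = "n",
                 xlab = "test AUC (95% bootstrap CI)", ylab = "",
                 pch = 19, ...)
  graphics::segments(df$auc_lo, seq_len(n), df$auc_hi, seq_len(n))
  graphics::abline(v = 0.5, lty = 3)
  graphics::axis(2, at = seq_len(n), labels = df$model, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Write an experiment report to CSV and JSON
#'
#' @param x An [sln_experiment()] result.
#' @param path_csv,path_json Output paths (`NULL` to skip either).
#' @return Invisibly, the report data frame.
#' @export
write_report <- function(x, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(x, "sln_experiment"))
  if (!is.null(path_csv)) utils::write.csv(x$report, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(x$report, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(x$report)
}
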