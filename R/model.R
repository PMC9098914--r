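#' Stratified train/test split
#'
#' Samples, per class and without replacement, `round(fraction * n_class)`
#' patients into the training set, so both sets keep the cohort's class
#' proportions. Deterministic given `seed`.
#'
#' @param labels Binary (0/1) vector; both classes must have >= 2 members.
#' @param fraction Training fraction in (0, 1); 0.8 by default.
#' @param seed Integer seed.
#' @return An object of class `split_spec`: list with `train_ids`,
#'   `test_ids` (row indices), `fraction`, `seed`.
#' @examples
#' sp <- stratified_split(rep(c(0, 1), c(115, 27)), 0.8, seed = 7)
#' length(sp$train_ids)  # 114 = 92 negatives + 22 positives
#' @export
stratified_split <- function(labels, fraction = 0.8, seed = 1L) {
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab < 2L)) stop("each class needs >= 2 members")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  with_seed(seed, {
    train <- integer(0)
    for (cl in c(0L, 1L)) {
      ids <- which(labels == cl)
      k <- round(fraction * length(ids))
      if (k < 1L || k >= length(ids))
        stop("fraction leaves a class empty in train or test")
      train <- c(train, sample(ids, k))
    }
    train <- sort(train)
    structure(list(train_ids = train,
                   test_ids = setdiff(seq_along(labels), train),
                   fraction = fraction, seed = as.integer(seed)),
              class = "split_spec")
  })
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$fraction, x$seed))
  invisible(x)
}

# internal: AUC by the rank statistic (midranks for ties);
# NA when labels are single-class
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# internal: stratified fold assignment (vector of fold ids per sample)
stratified_folds <- function(labels, k) {
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- which(labels == cl)
    ids <- ids[sample.int(length(ids))]
    f[ids] <- rep_len(seq_len(k), length(ids))
  }
  f
}

# internal: mean held-out-fold AUC of an RBF-SVM on (pre-standardized) x
svm_cv_auc <- function(x, y, fold_id, cost, gamma) {
  aucs <- c()
  for (k in unique(fold_id)) {
    tr <- fold_id != k
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    dvm <- attr(stats::predict(fit, x[!tr, , drop = FALSE],
                               decision.values = TRUE), "decision.values")
    dv <- if (colnames(dvm)[1] == "0/1") -dvm[, 1] else dvm[, 1]
    aucs <- c(aucs, rank_auc(dv, as.integer(as.character(y[!tr]))))
  }
  if (!length(aucs)) return(0.5)
  mean(aucs, na.rm = TRUE)
}

#' Genetic-algorithm parameters
#'
#' Defaults: population 30, 20 generations, crossover 0.8, per-bit mutation
#' `1/n_features`, elitism 1, fitness = `cv_folds`-fold internal
#' cross-validated AUC of an RBF-SVM on the masked features minus a
#' parsimony penalty of 0.002 per active feature.
#'
#' @param population_size Chromosomes per generation (>= 4).
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Rates in \[0, 1\] (`NULL` mutation =
#'   `1/n_features`).
#' @param elitism Chromosomes copied unchanged to the next generation.
#' @param cv_folds Internal cross-validation folds for the fitness.
#' @param parsimony Fitness penalty per active feature.
#' @param cost,gamma RBF-SVM hyperparameters for the fitness model (`NULL`
#'   gamma = `1/n_active_features`).
#' @param seed Integer seed.
#' @return An object of class `ga_params`.
#' @export
ga_params <- function(population_size = 30L, generations = 20L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      elitism = 1L, cv_folds = 5L, parsimony = 0.002,
                      cost = 1, gamma = NULL, seed = 1L) {
  if (population_size < 4L) stop("population_size must be >= 4")
  if (crossover_rate < 0 || crossover_rate > 1) stop("rates must lie in [0, 1]")
  if (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1))
    stop("rates must lie in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), cv_folds = as.integer(cv_folds),
                 parsimony = parsimony, cost = cost, gamma = gamma,
                 seed = as.integer(seed)), class = "ga_params")
}

#' Genetic-algorithm feature selection
#'
#' Evolves binary feature masks by tournament selection, uniform crossover,
#' bit-flip mutation and elitism; each mask's fitness is the internal
#' cross-validated AUC of an RBF-SVM restricted to the active features,
#' minus a small parsimony penalty. Deterministic given `params$seed`.
#'
#' @param features Numeric matrix (patients x named features), all finite.
#' @param labels Binary (0/1) vector with both classes present.
#' @param params A [ga_params()].
#' @return Character vector of selected feature names, with attributes
#'   `fitness` and `mask`.
#' @export
ga_select <- function(features, labels, params = ga_params()) {
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop("features must be finite")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  p <- ncol(x)
  if (p < 1L) stop("at least one feature required")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  if (p == 1L) return(structure(colnames(x), fitness = NA_real_,
                                mask = TRUE))
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  y <- factor(labels, levels = c(0L, 1L))

  with_seed(params$seed, {
    k <- min(params$cv_folds, min(table(y)))
    fold_id <- if (k >= 2L) stratified_folds(labels, k) else NULL
    cache <- new.env(parent = emptyenv())
    fitness <- function(mask) {
      if (!any(mask)) return(-1)
      key <- paste(which(mask), collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      xa <- x[, mask, drop = FALSE]
      g <- params$gamma %||% (1 / sum(mask))
      auc <- if (is.null(fold_id)) {
        fit <- e1071::svm(xa, y, kernel = "radial", cost = params$cost,
                          gamma = g, scale = FALSE)
        dvm <- attr(stats::predict(fit, xa, decision.values = TRUE),
                    "decision.values")
        rank_auc(if (colnames(dvm)[1] == "0/1") -dvm[, 1] else dvm[, 1],
                 labels)
      } else svm_cv_auc(xa, y, fold_id, params$cost, g)
      val <- auc - params$parsimony * sum(mask)
      cache[[key]] <- val
      val
    }
    mut <- params$mutation_rate %||% (1 / p)
    np <- params$population_size
    pop <- matrix(stats::runif(np * p) < 0.5, np, p)
    pop[rowSums(pop) == 0, sample.int(p, 1)] <- TRUE
    fit <- apply(pop, 1, fitness)
    for (gen in seq_len(params$generations)) {
      ord <- order(fit, decreasing = TRUE)
      nxt <- pop[ord[seq_len(params$elitism)], , drop = FALSE]
      while (nrow(nxt) < np) {
        pick <- function() {
          c2 <- sample.int(np, 2L)
          c2[which.max(fit[c2])]
        }
        pa <- pop[pick(), ]; pb <- pop[pick(), ]
        child <- if (stats::runif(1) < params$crossover_rate) {
          sel <- stats::runif(p) < 0.5
          ifelse(sel, pa, pb)
        } else pa
        flip <- stats::runif(p) < mut
        child[flip] <- !child[flip]
        if (!any(child)) child[sample.int(p, 1)] <- TRUE
        nxt <- rbind(nxt, child)
      }
      pop <- nxt
      fit <- apply(pop, 1, fitness)
    }
    best <- which.max(fit)
    structure(colnames(x)[pop[best, ]], fitness = fit[best],
              mask = pop[best, ])
  })
}

#' Per-feature selection frequency over leave-one-out rounds
#'
#' Repeats [ga_select()] on each leave-one-out training fold (round `i`
#' reseeded as `params$seed + i`) and records, for every feature, the
#' fraction of rounds in which it was selected; the working subset at a
#' cutoff is the set of features selected at least that fraction of the
#' time (50% by default).
#'
#' @param train_features Numeric matrix (patients x named features).
#' @param train_labels Binary labels (training set; >= 5 patients).
#' @param params A [ga_params()].
#' @param cutoff Selection-frequency cutoff in (0, 1\].
#' @return An object of class `selection_profile`: data frame of `feature`,
#'   `frequency` (sorted decreasing), with attributes `cutoff`,
#'   `selected_set`, `n_rounds`.
#' @export
loocv_frequency <- function(train_features, train_labels, params = ga_params(),
                            cutoff = 0.5) {
  x <- as.matrix(train_features)
  n <- nrow(x)
  if (n < 5L) stop("training set must have >= 5 patients")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  counts <- stats::setNames(numeric(ncol(x)), colnames(x))
  rounds <- 0L
  for (i in seq_len(n)) {
    yi <- train_labels[-i]
    if (length(unique(yi)) < 2L) next
    pi <- params; pi$seed <- params$seed + i
    sel <- tryCatch(ga_select(x[-i, , drop = FALSE], yi, pi),
                    error = function(e)
                      stop(sprintf("leave-one-out round %d: %s", i,
                                   conditionMessage(e))))
    counts[sel] <- counts[sel] + 1
    rounds <- rounds + 1L
  }
  freq <- counts / rounds
  ord <- order(freq, decreasing = TRUE)
  prof <- data.frame(feature = names(freq)[ord], frequency = unname(freq)[ord],
                     stringsAsFactors = FALSE)
  class(prof) <- c("selection_profile", "data.frame")
  attr(prof, "cutoff") <- cutoff
  attr(prof, "n_rounds") <- rounds
  attr(prof, "selected_set") <- prof$feature[prof$frequency >= cutoff]
  prof
}

#' Re-threshold a selection profile
#'
#' @param profile A [loocv_frequency()] result.
#' @param cutoff New frequency cutoff.
#' @return Character vector: features with frequency >= cutoff.
#' @export
select_at <- function(profile, cutoff) {
  stopifnot(inherits(profile, "selection_profile"))
  profile$feature[profile$frequency >= cutoff]
}

#' Test AUC as a function of the selection-frequency cutoff
#'
#' For each cutoff, trains an RBF-SVM on the features whose leave-one-out
#' selection frequency reaches it and reports the hold-out test AUC and
#' subset size; cutoffs that leave no feature are flagged, not computed.
#'
#' @param train_x,train_y,test_x,test_y Train/test feature matrices and
#'   binary labels.
#' @param profile A [loocv_frequency()] result.
#' @param cutoffs Numeric vector of cutoffs to scan.
#' @param cost,gamma SVM hyperparameters (see [train_svm()]).
#' @return Data frame with `cutoff`, `n_features`, `auc` (NA when flagged
#'   empty), `empty`.
#' @export
frequency_curve <- function(train_x, train_y, test_x, test_y, profile,
                            cutoffs = seq(0.1, 0.5, by = 0.1),
                            cost = 1, gamma = NULL) {
  rows <- lapply(cutoffs, function(ct) {
    feats <- select_at(profile, ct)
    if (!length(feats))
      return(data.frame(cutoff = ct, n_features = 0L, auc = NA_real_,
                        empty = TRUE))
    fit <- train_svm(train_x[, feats, drop = FALSE], train_y,
                     cost = cost, gamma = gamma)
    sc <- stats::predict(fit, test_x[, feats, drop = FALSE])
    data.frame(cutoff = ct, n_features = length(feats),
               auc = rank_auc(sc, test_y), empty = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit a calibrated RBF-SVM classifier
#'
#' Standardizes the features (scaler fitted on the training data only), fits
#' a radial-basis-function support vector machine, and calibrates its
#' decision values to \[0, 1\] scores with a sigmoid fitted on internal
#' training folds (Platt scaling), so that scores from different models can
#' be averaged and thresholded at the class prevalence.
#'
#' @param x Numeric matrix (patients x features).
#' @param y Binary (0/1) labels; both classes required.
#' @param cost SVM cost parameter (default 1).
#' @param gamma RBF bandwidth; `NULL` = `1 / n_features` on the
#'   standardized inputs.
#' @param seed Seed for the internal calibration folds.
#' @return An object of class `sln_svm`; `predict()` returns positive-class
#'   scores in \[0, 1\].
#' @export
train_svm <- function(x, y, cost = 1, gamma = NULL, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(y)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (any(!is.finite(x))) stop("features must be finite")
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  g <- gamma %||% (1 / ncol(xs))
  fit <- with_seed(seed,
    e1071::svm(xs, factor(labels, levels = c(0L, 1L)), kernel = "radial",
               cost = cost, gamma = g, scale = FALSE, probability = TRUE))
  structure(list(fit = fit, center = ctr, scale = scl,
                 features = colnames(x), cost = cost, gamma = g),
            class = "sln_svm")
}

#' @export
predict.sln_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x)))
    x <- x[, object$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  pr <- stats::predict(object$fit, xs, probability = TRUE)
  p <- attr(pr, "probabilities")[, "1"]
  unname(pmin(pmax(p, 0), 1))
}

#' @export
print.sln_svm <- function(x, ...) {
  cat(sprintf("<sln_svm> RBF SVM, %d features, cost %.3g, gamma %.3g, %d SVs\n",
              length(x$center), x$cost, x$gamma, x$fit$tot.nSV))
  invisible(x)
}

#' Soft voting
#'
#' Element-wise arithmetic mean of two models' class scores (the ensemble
#' score of the clinical/radiomic combination).
#'
#' @param scores_a,scores_b Equal-length score vectors in \[0, 1\].
#' @return Averaged scores.
#' @export
soft_vote <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stop("score lengths differ")
  if (any(scores_a < 0 | scores_a > 1 | scores_b < 0 | scores_b > 1))
    stop("scores must lie in [0, 1]")
  (scores_a + scores_b) / 2
}

#' Classification metrics at a prevalence threshold
#'
#' AUC by the rank statistic (midranks for ties) plus the confusion-matrix
#' metrics at `score >= threshold`: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/n. The conventional threshold is the
#' positive-class prevalence of the training cohort.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary (0/1) labels.
#' @param threshold Decision threshold in (0, 1).
#' @return List with `auc` (NA and `degenerate = TRUE` if labels are
#'   single-class), `accuracy`, `sensitivity`, `specificity`, `threshold`,
#'   `confusion` (2x2 matrix).
#' @export
evaluate_scores <- function(scores, labels, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  auc <- rank_auc(scores, labels)
  list(auc = auc,
       accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       threshold = threshold,
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(pred = c("0", "1"),
                                          truth = c("0", "1"))),
       degenerate = is.na(auc))
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples (score, label) pairs with replacement, stratified by class, and
#' returns the 2.5/97.5 percentiles of the metric over the resamples
#' (200 rounds by default).
#'
#' @inheritParams evaluate_scores
#' @param metric One of `"auc"`, `"accuracy"`, `"sensitivity"`,
#'   `"specificity"`.
#' @param rounds Bootstrap rounds (>= 2).
#' @param seed Integer seed.
#' @param threshold Threshold for the confusion-matrix metrics.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auc", rounds = 200L,
                         seed = 1L, threshold = 0.5) {
  if (rounds < 2L) stop("`rounds` must be >= 2")
  metric <- match.arg(metric, c("auc", "accuracy", "sensitivity", "specificity"))
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  with_seed(seed, {
    vals <- numeric(0)
    for (b in seq_len(rounds)) {
      ids <- NULL
      for (try in seq_len(10L)) {
        ids <- c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
                 neg[sample.int(length(neg), length(neg), replace = TRUE)])
        if (length(unique(labels[ids])) == 2L) break
        ids <- NULL
      }
      if (is.null(ids)) { warning("bootstrap round skipped: one class"); next }
      m <- evaluate_scores(scores[ids], labels[ids], threshold)
      vals <- c(vals, m[[metric]])
    }
    unname(stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE))
  })
}

#' Permutation p-value for AUC against the chance null
#'
#' Permutes the labels and counts how often the permuted AUC reaches the
#' observed one; `p = (1 + #{AUC_perm >= AUC_obs}) / (rounds + 1)`.
#'
#' @inheritParams evaluate_scores
#' @param rounds Permutation rounds (>= 1000 recommended).
#' @param seed Integer seed.
#' @return p-value in (0, 1\].
#' @export
auc_significance <- function(scores, labels, rounds = 1000L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  obs <- rank_auc(scores, labels)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(rounds)) {
      if (rank_auc(scores, sample(labels)) >= obs) hits <- hits + 1L
    }
    (1 + hits) / (rounds + 1)
  })
}
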