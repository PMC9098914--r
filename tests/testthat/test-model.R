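test_that("stratified splitting reproduces per-class rounding on any input", {
  y <- rep(c(0, 1), c(115, 27))
  sp <- stratified_split(y, 0.8, seed = 3)
  expect_length(sp$train_ids, 114)
  expect_length(sp$test_ids, 28)
  expect_equal(sum(y[sp$train_ids]), 22)
  expect_equal(sum(y[sp$test_ids]), 5)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), seq_along(y))
  # two seeds: different membership, identical per-class counts
  sp2 <- stratified_split(y, 0.8, seed = 4)
  expect_false(identical(sp$train_ids, sp2$train_ids))
  expect_equal(sum(y[sp2$train_ids]), 22)
  # property: counts = round(fraction * n_class)
  set.seed(9)
  for (i in 1:10) {
    n0 <- sample(10:60, 1); n1 <- sample(5:30, 1)
    f <- runif(1, 0.5, 0.9)
    yy <- sample(rep(c(0, 1), c(n0, n1)))
    s <- stratified_split(yy, f, seed = i)
    expect_equal(sum(yy[s$train_ids] == 0), round(f * n0))
    expect_equal(sum(yy[s$train_ids] == 1), round(f * n1))
  }
  expect_error(stratified_split(y, 1.0), "\\(0, 1\\)")
  expect_error(stratified_split(c(0, 0, 1), 0.8), ">= 2")
})

test_that("the genetic algorithm recovers a perfectly separating feature", {
  set.seed(2)
  n <- 24
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(0, 1), each = n / 2)
  x[, 1] <- 3 * y + rnorm(n, 0, 0.25)
  hits <- 0
  for (s in 1:5) {
    sel <- ga_select(x, y, ga_params(population_size = 10, generations = 6,
                                     cv_folds = 3, seed = s))
    hits <- hits + ("f1" %in% sel)
  }
  expect_gte(hits, 5)
  # determinism and trivial cases
  p <- ga_params(population_size = 8, generations = 4, cv_folds = 3, seed = 7)
  expect_identical(ga_select(x, y, p), ga_select(x, y, p))
  expect_equal(as.character(ga_select(x[, 1, drop = FALSE], y)), "f1")
  xb <- x; xb[2, 3] <- NA
  expect_error(ga_select(xb, y), "finite")
  expect_error(ga_params(population_size = 2), ">= 4")
})

test_that("leave-one-out selection frequencies obey their contracts", {
  set.seed(4)
  n <- 16
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(0, 1), each = n / 2)
  x[, 1] <- 3 * y + rnorm(n, 0, 0.25)
  prof <- loocv_frequency(x, y, ga_params(population_size = 8, generations = 4,
                                          cv_folds = 3, seed = 5))
  expect_true(all(prof$frequency >= 0 & prof$frequency <= 1))
  expect_equal(attr(prof, "n_rounds"), n)
  expect_gte(prof$frequency[prof$feature == "f1"], 0.9)
  expect_true("f1" %in% attr(prof, "selected_set"))
  # selected set is antitone in the cutoff
  cuts <- seq(0.1, 1, by = 0.1)
  sizes <- vapply(cuts, function(ct) length(select_at(prof, ct)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_identical(select_at(prof, 0.5),
                   prof$feature[prof$frequency >= 0.5])
  expect_error(loocv_frequency(x[1:4, ], y[1:4]), ">= 5")
})

test_that("the frequency curve reports subset sizes and flags empty cutoffs", {
  set.seed(6)
  n <- 20
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(0, 1), each = n / 2)
  x[, 1] <- 2.5 * y + rnorm(n, 0, 0.3)
  sp <- stratified_split(y, 0.7, seed = 1)
  prof <- loocv_frequency(x[sp$train_ids, ], y[sp$train_ids],
                          ga_params(population_size = 8, generations = 3,
                                    cv_folds = 3, seed = 2))
  fc <- frequency_curve(x[sp$train_ids, ], y[sp$train_ids],
                        x[sp$test_ids, ], y[sp$test_ids], prof,
                        cutoffs = c(0.1, 0.3, 0.5, 1.01))
  expect_true(all(diff(fc$n_features) <= 0))
  expect_true(fc$empty[fc$cutoff > 1])
  expect_true(all(is.na(fc$auc[fc$empty])))
  expect_true(all(fc$auc[!fc$empty] >= 0 & fc$auc[!fc$empty] <= 1))
})

test_that("the calibrated SVM separates separable data with scores in [0, 1]", {
  set.seed(8)
  x <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0, 1), each = 15)
  x[, 1] <- x[, 1] + 4 * y
  fit <- train_svm(x, y)
  sc <- predict(fit, x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(mean((sc >= 0.5) == (y == 1)), 1)  # training accuracy 1
  expect_error(train_svm(x, rep(1, 30)), "both classes")
})

test_that("shuffled labels give chance-level internal AUC", {
  set.seed(12)
  aucs <- vapply(1:20, function(s) {
    x <- matrix(rnorm(24 * 4), 24, 4)
    y <- sample(rep(c(0, 1), each = 12))
    fold <- slnradiomics:::stratified_folds(y, 3)
    slnradiomics:::svm_cv_auc(scale(x), factor(y, levels = c(0, 1)), fold,
                              cost = 1, gamma = 0.25)
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("soft voting is the element-wise mean with its convexity bounds", {
  expect_equal(soft_vote(0.2, 0.8), 0.5)
  s <- c(0.1, 0.5, 0.9)
  expect_equal(soft_vote(s, s), s)
  set.seed(3)
  a <- runif(20); b <- runif(20)
  v <- soft_vote(a, b)
  expect_true(all(v >= pmin(a, b) & v <= pmax(a, b)))
  expect_error(soft_vote(a, b[1:5]), "lengths differ")
  expect_error(soft_vote(a, b + 1), "\\[0, 1\\]")
})

test_that("evaluation equals the hand confusion matrix and the all-pairs AUC", {
  ev <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.19)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 0.5)  # 0.2 >= 0.19 counts as positive
  expect_equal(ev$accuracy, 0.75)
  expect_equal(round(27 / 142, 4), 0.1901)  # the prevalence threshold
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    sc <- round(runif(n), 2)         # ties likely
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(evaluate_scores(sc, y, 0.5)$auc, oracle_auc(sc, y))
  }
  # AUC invariant under strictly monotone transforms
  sc <- runif(15); y <- rbinom(15, 1, 0.4); y[1:2] <- c(0, 1)
  expect_equal(slnradiomics:::rank_auc(plogis(5 * sc - 2), y),
               slnradiomics:::rank_auc(sc, y))
  expect_true(evaluate_scores(sc, rep(1, 15), 0.5)$degenerate)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  sc <- runif(40); y <- rbinom(40, 1, 0.3); y[1:2] <- c(0, 1)
  expect_equal(slnradiomics:::rank_auc(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))))
})

test_that("bootstrap intervals are ordered, degenerate-safe, and shrink with n", {
  y <- rep(c(0, 1), each = 10)
  perfect <- c(runif(10, 0, 0.3), runif(10, 0.7, 1))
  ci <- bootstrap_ci(perfect, y, "auc", rounds = 100, seed = 1)
  expect_equal(ci, c(1, 1))
  widths <- function(n, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      yy <- rbinom(n, 1, 0.4); yy[1:2] <- c(0, 1)
      sc <- plogis(rnorm(n, yy))
      d <- bootstrap_ci(sc, yy, "auc", rounds = 100, seed = s)
      expect_lte(d[1], d[2])
      d[2] - d[1]
    }, numeric(1))
  }
  expect_lt(mean(widths(500, 1:20)), mean(widths(50, 1:20)))
  expect_error(bootstrap_ci(perfect, y, rounds = 1), ">= 2")
})

test_that("AUC permutation p-values detect separation and stay calibrated", {
  y <- rep(c(0, 1), c(23, 5))
  sc <- c(runif(23, 0, 0.4), runif(5, 0.6, 1))
  p <- auc_significance(sc, y, rounds = 1000, seed = 2)
  expect_lt(p, 0.05)
  expect_gt(p, 0)
  set.seed(31)
  nulls <- vapply(1:40, function(s) {
    yy <- sample(rep(c(0, 1), c(12, 6)))
    auc_significance(runif(18), yy, rounds = 199, seed = s)
  }, numeric(1))
  expect_gt(mean(nulls), 0.35)
  expect_lt(mean(nulls), 0.65)
  expect_true(all(nulls > 0 & nulls <= 1))
})
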