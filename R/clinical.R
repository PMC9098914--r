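#' The 12 clinical variables
#'
#' Names of the clinical/histopathological variables the pipeline models:
#' age at diagnosis, tumor diameter class (T1a/T1b/T1c/T2), histological
#' grade (1-3), histological type, estrogen and progesterone receptor
#' expression (%), ki67 (%), HER2/neu score (0-3), breast quadrant (8
#' levels), multifocality, angioinvasion and invasiveness.
#'
#' @return Character vector of length 12.
#' @export
clinical_variables <- function() {
  c("age", "diameter", "grading", "histological_type", "er", "pgr", "ki67",
    "her2", "quadrant", "multifocality", "angioinvasion", "invasiveness")
}

clinical_levels <- function() {
  list(diameter = c("T1a", "T1b", "T1c", "T2"),
       grading = c("1", "2", "3"),
       histological_type = c("ductal", "lobular", "other"),
       her2 = c("0", "1", "2", "3"),
       quadrant = c("QSM", "QSE", "QEE", "QIE", "QIM", "QII", "QEI", "QSI"),
       multifocality = c("absent", "present"),
       angioinvasion = c("absent", "present"),
       invasiveness = c("infiltrating", "in_situ"))
}

clinical_continuous <- function() c("age", "er", "pgr", "ki67")

#' Validate a clinical table
#'
#' Checks that a data frame carries the 12 clinical variables with their
#' expected types — percents in \[0, 100\], categorical values within their
#' level sets — and returns it classed as `clinical_table`. Missing entries
#' are `NA`.
#'
#' @param df Data frame with a `patient_id` column and the 12 variables of
#'   [clinical_variables()].
#' @return The validated data frame, classed `c("clinical_table",
#'   "data.frame")`.
#' @export
clinical_table <- function(df) {
  need <- c("patient_id", clinical_variables())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing clinical columns: ", paste(miss, collapse = ", "))
  for (v in clinical_continuous()) {
    if (!is.numeric(df[[v]])) stop(sprintf("`%s` must be numeric", v))
  }
  for (v in c("er", "pgr", "ki67")) {
    bad <- !is.na(df[[v]]) & (df[[v]] < 0 | df[[v]] > 100)
    if (any(bad)) stop(sprintf("`%s` must lie in [0, 100]", v))
  }
  for (v in names(clinical_levels())) {
    lv <- clinical_levels()[[v]]
    x <- as.character(df[[v]])
    if (any(!is.na(x) & !x %in% lv))
      stop(sprintf("`%s` has values outside {%s}", v, paste(lv, collapse = ", ")))
    df[[v]] <- factor(x, levels = lv)
  }
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Encode a clinical table as a numeric matrix
#'
#' Ordinals (diameter, grading, HER2) become integer ranks, binaries 0/1,
#' nominals (histological type, quadrant) one-hot columns, and continuous
#' variables are kept as-is; all columns are then z-scaled (invertible:
#' centers and scales are returned). `NA` cells stay `NA`.
#'
#' @param table A [clinical_table()].
#' @param center,scale Optional precomputed scaling parameters (to encode new
#'   patients on a reference cohort's scale).
#' @return List with `x` (patients x encoded columns), `center`, `scale`,
#'   and `var_of` (the source clinical variable of each column).
#' @export
encode_clinical <- function(table, center = NULL, scale = NULL) {
  stopifnot(inherits(table, "clinical_table"))
  n <- nrow(table)
  cols <- list(); var_of <- character(0)
  add <- function(name, v, values) {
    cols[[name]] <<- values
    var_of <<- c(var_of, v)
  }
  for (v in clinical_variables()) {
    x <- table[[v]]
    if (v %in% clinical_continuous()) {
      add(v, v, as.numeric(x))
    } else if (v %in% c("diameter", "grading", "her2")) {
      add(v, v, as.numeric(x))               # integer rank of ordered levels
    } else if (v %in% c("multifocality", "angioinvasion", "invasiveness")) {
      add(v, v, as.numeric(x) - 1)
    } else {                                  # nominal: one-hot
      for (lv in levels(x))
        add(paste(v, lv, sep = "."), v, as.numeric(x == lv))
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- table$patient_id
  if (is.null(center)) {
    center <- colMeans(x, na.rm = TRUE)
    scale <- apply(x, 2, stats::sd, na.rm = TRUE)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  list(x = xs, center = center, scale = scale, var_of = var_of)
}

#' Proximity imputation of missing clinical values
#'
#' Each patient with missing entries receives, for every missing variable,
#' the value of the complete-case donor minimizing the Euclidean distance
#' over the encoded, z-scaled variables that the incomplete patient did
#' observe. Observed cells are never altered; ties between donors are broken
#' by lowest reference row index. New patients can be scored against a
#' frozen reference cohort by passing it as `reference`.
#'
#' @param table A [clinical_table()] to complete.
#' @param reference A [clinical_table()] providing the complete-case donor
#'   pool and the encoding scale (defaults to `table` itself).
#' @return The completed table, with a `donors` attribute logging each
#'   imputed patient's donor `patient_id`.
#' @export
impute_proximity <- function(table, reference = table) {
  stopifnot(inherits(table, "clinical_table"), inherits(reference, "clinical_table"))
  vars <- clinical_variables()
  ref_complete <- stats::complete.cases(reference[, vars])
  if (!any(ref_complete)) stop("no complete case available as donor")
  enc_ref <- encode_clinical(reference)
  enc_tab <- if (identical(table, reference)) enc_ref
             else encode_clinical(table, enc_ref$center, enc_ref$scale)
  donors <- character(0)
  out <- table
  pool <- which(ref_complete)
  for (i in seq_len(nrow(table))) {
    miss <- vars[vapply(vars, function(v) is.na(table[[v]][i]), logical(1))]
    if (!length(miss)) next
    obs <- !is.na(enc_tab$x[i, ])
    d <- if (any(obs)) {
      diff <- sweep(enc_ref$x[pool, obs, drop = FALSE], 2,
                    enc_tab$x[i, obs], "-")
      sqrt(rowSums(diff^2))
    } else rep(0, length(pool))
    donor <- pool[which.min(d)]
    for (v in miss) out[[v]][i] <- reference[[v]][donor]
    donors[table$patient_id[i]] <- reference$patient_id[donor]
  }
  attr(out, "donors") <- donors
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midranks for ties: exact p for small
#' untied samples (both groups <= 10), normal approximation with tie
#' correction otherwise. Identical degenerate samples give p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  exact <- length(x) <= 10 && length(y) <= 10 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Pearson chi-square test of independence
#'
#' Zero-marginal rows/columns are dropped (with a warning) before computing
#' the Pearson statistic with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param contingency Matrix of nonnegative counts (>= 2 rows and columns
#'   after dropping empty margins).
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("counts must be nonnegative")
  keep_r <- rowSums(m) > 0; keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-marginal rows/columns")
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L)
    return(list(statistic = 0, df = 0, p = 1))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# internal: the appropriate univariate test between two samples of one
# clinical variable; returns p (1 when the variable is degenerate)
univariate_p <- function(xa, xb, continuous) {
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (!length(xa) || !length(xb)) return(1)
  if (length(unique(c(as.character(xa), as.character(xb)))) < 2L) return(1)
  if (continuous) {
    mann_whitney(as.numeric(xa), as.numeric(xb))$p
  } else {
    suppressWarnings(chi_square(rbind(table(xa), table(xb)))$p)
  }
}

#' Per-variable cohort description with univariate tests
#'
#' For each of the 12 clinical variables: median and quartiles (continuous)
#' or level counts (categorical), plus the Mann-Whitney (continuous) or
#' chi-square (categorical) p-value against the binary nodal-status label,
#' flagged significant at p < 0.05 (no multiplicity correction, matching
#' per-variable reporting practice).
#'
#' @param table A [clinical_table()].
#' @param labels Binary (0/1) nodal-status vector, one per patient.
#' @return Data frame with columns `variable`, `type`, `summary`,
#'   `p_value`, `significant`.
#' @export
cohort_summary <- function(table, labels) {
  stopifnot(inherits(table, "clinical_table"),
            length(labels) == nrow(table))
  rows <- lapply(clinical_variables(), function(v) {
    x <- table[[v]]
    if (v %in% clinical_continuous()) {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
      sm <- sprintf("median %.3g [%.3g, %.3g]", q[2], q[1], q[3])
      ty <- "continuous"
    } else {
      tb <- table(x)
      sm <- paste(sprintf("%s:%d", names(tb), tb), collapse = " ")
      ty <- "categorical"
    }
    p <- univariate_p(x[labels == 0], x[labels == 1], ty == "continuous")
    data.frame(variable = v, type = ty, summary = sm, p_value = p,
               significant = p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train/test homogeneity check
#'
#' Applies the same per-variable univariate tests between the training and
#' test partitions of a cohort; a split is homogeneous when most variables
#' show p > 0.05.
#'
#' @param table A [clinical_table()].
#' @param split A [stratified_split()] result, a `list(train_ids, test_ids)`
#'   of row indices, or a logical vector (`TRUE` = train).
#' @return Data frame of per-variable p-values, with attribute
#'   `n_homogeneous` (count of variables with p > 0.05).
#' @export
homogeneity_check <- function(table, split) {
  if (is.logical(split)) {
    stopifnot(length(split) == nrow(table))
    split <- list(train_ids = which(split), test_ids = which(!split))
  }
  a <- table[split$train_ids, , drop = FALSE]
  b <- table[split$test_ids, , drop = FALSE]
  p <- vapply(clinical_variables(), function(v) {
    univariate_p(a[[v]], b[[v]], v %in% clinical_continuous())
  }, numeric(1))
  out <- data.frame(variable = clinical_variables(), p_value = unname(p),
                    stringsAsFactors = FALSE)
  attr(out, "n_homogeneous") <- sum(p > 0.05)
  out
}
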