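test_that("the clinical schema is validated and spans 12 variables", {
  expect_length(clinical_variables(), 12)
  tab <- toy_clinical()
  expect_s3_class(tab, "clinical_table")
  bad <- as.data.frame(tab); bad$er[1] <- 150
  expect_error(clinical_table(bad), "\\[0, 100\\]")
  bad2 <- as.data.frame(tab); bad2$grading <- as.character(bad2$grading)
  bad2$grading[2] <- "4"
  expect_error(clinical_table(bad2), "outside")
  expect_error(clinical_table(data.frame(age = 1)), "missing clinical columns")
})

test_that("encoding is numeric, invertible in scale, and NA-preserving", {
  tab <- toy_clinical()
  enc <- encode_clinical(tab)
  expect_false(any(is.na(enc$x)))
  expect_equal(nrow(enc$x), 5)
  # one-hot blocks for the two nominals, single columns elsewhere
  expect_equal(sum(enc$var_of == "quadrant"), 8)
  expect_equal(sum(enc$var_of == "histological_type"), 3)
  expect_equal(length(unique(enc$var_of)), 12)
  # missing age propagates into the encoded matrix
  tab2 <- tab; tab2$age[3] <- NA
  enc2 <- encode_clinical(clinical_table(as.data.frame(tab2)))
  expect_true(is.na(enc2$x[3, "age"]))
})

test_that("proximity imputation copies from the nearest complete donor", {
  tab <- toy_clinical()
  expect_identical(impute_proximity(tab)[, clinical_variables()],
                   tab[, clinical_variables()])
  # an incomplete row identical to row 2 on every observed field
  inc <- as.data.frame(tab)
  inc[6, ] <- inc[2, ]; inc$patient_id[6] <- "T6"; inc$age[6] <- NA
  inc <- clinical_table(inc)
  out <- impute_proximity(inc)
  expect_equal(out$age[6], tab$age[2])
  expect_equal(unname(attr(out, "donors")["T6"]), "T2")
  # brute-force Euclidean oracle over the encoded complete rows
  inc2 <- as.data.frame(tab); inc2$age[4] <- NA
  inc2 <- clinical_table(inc2)
  out2 <- impute_proximity(inc2)
  enc <- encode_clinical(inc2)
  obs <- !is.na(enc$x[4, ])
  d <- apply(enc$x[c(1, 2, 3, 5), obs, drop = FALSE], 1,
             function(r) sqrt(sum((r - enc$x[4, obs])^2)))
  donor <- c(1, 2, 3, 5)[which.min(d)]
  expect_equal(out2$age[4], tab$age[donor])
  # observed cells never altered; no missing cells remain
  expect_identical(out2[-4, clinical_variables()], tab[-4, clinical_variables()])
  expect_equal(sum(is.na(out2[, clinical_variables()])), 0)
})

test_that("imputation requires a complete donor and supports a frozen reference", {
  tab <- as.data.frame(toy_clinical())
  tab$age <- NA_real_
  expect_error(impute_proximity(clinical_table(tab)), "no complete case")
  # newcomer scored against a reference cohort
  ref <- toy_clinical()
  newc <- as.data.frame(ref[1, ]); newc$patient_id <- "N1"; newc$ki67 <- NA_real_
  out <- impute_proximity(clinical_table(newc), reference = ref)
  expect_equal(out$ki67[1], ref$ki67[1])
})

test_that("Mann-Whitney matches exact enumeration for small untied samples", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6)
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5))$p, 1)  # degenerate
  x <- c(1.2, 3.4, 0.5); y <- c(2.2, 5.1)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)
  set.seed(21)
  for (i in 1:10) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(100, nx + ny)  # untied
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(mann_whitney(x, y)$p, oracle_mw_exact_p(x, y))
  }
})

test_that("chi-square equals the hand formula and is permutation invariant", {
  expect_equal(chi_square(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square(matrix(10, 2, 2))$p, 1)
  cs <- chi_square(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(cs$statistic, 40)
  expect_equal(cs$df, 1)
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(sample(5:30, 4), 2, 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(chi_square(m)$statistic, sum((m - e)^2 / e))
    expect_equal(chi_square(m)$statistic, chi_square(m[2:1, 2:1])$statistic)
  }
  expect_warning(chi_square(matrix(c(5, 0, 0, 0, 3, 9), 2, 3)), "zero-marginal")
})

test_that("cohort summaries flag a strong planted age shift and not a constant", {
  hits <- 0
  for (s in 1:8) {
    co <- gen_cohort(60, prevalence = 0.4, clinical_effects = 1.5,
                     missing_rates = no_missing(), seed = 300 + s,
                     with_images = FALSE)
    cs <- cohort_summary(co$clinical, co$labels)
    hits <- hits + cs$significant[cs$variable == "age"]
  }
  expect_gte(hits, 7)
  # a degenerate variable is never flagged
  co <- gen_cohort(30, missing_rates = no_missing(), seed = 1,
                   with_images = FALSE)
  tab <- as.data.frame(co$clinical)
  tab$ki67 <- 20
  cs <- cohort_summary(clinical_table(tab), co$labels)
  expect_equal(cs$p_value[cs$variable == "ki67"], 1)
  expect_false(cs$significant[cs$variable == "ki67"])
})

test_that("homogeneity checks separate fair from adversarial splits", {
  co <- gen_cohort(80, clinical_effects = 0, missing_rates = no_missing(),
                   seed = 17, with_images = FALSE)
  tab <- co$clinical
  # degenerate: test is a copy of train -> every p is exactly 1
  h0 <- homogeneity_check(tab, list(train_ids = 1:80, test_ids = 1:80))
  expect_true(all(h0$p_value == 1))
  # stratified random split on a null cohort: mostly homogeneous
  sp <- stratified_split(co$labels, 0.8, seed = 2)
  h1 <- homogeneity_check(tab, sp)
  expect_gte(attr(h1, "n_homogeneous"), 9)
  # adversarial split by age: age flagged
  ord <- order(tab$age)
  h2 <- homogeneity_check(tab, list(train_ids = ord[1:40], test_ids = ord[41:80]))
  expect_lt(h2$p_value[h2$variable == "age"], 0.05)
})
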