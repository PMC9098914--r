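# Small fixtures built in code.

no_missing <- function() {
  r <- default_missing_rates()
  r[] <- 0
  r
}

# hand-built 5-row clinical table (complete except where noted)
toy_clinical <- function(age = c(50, 60, 70, 40, 55)) {
  clinical_table(data.frame(
    patient_id = paste0("T", 1:5),
    age = age,
    diameter = factor(c("T1a", "T1b", "T1c", "T2", "T1b"),
                      levels = c("T1a", "T1b", "T1c", "T2")),
    grading = factor(c("1", "2", "3", "2", "1"), levels = c("1", "2", "3")),
    histological_type = factor(c("ductal", "ductal", "lobular", "other", "ductal"),
                               levels = c("ductal", "lobular", "other")),
    er = c(90, 95, 98, 60, 97), pgr = c(40, 10, 80, 5, 60),
    ki67 = c(15, 20, 35, 12, 18),
    her2 = factor(c("0", "1", "2", "3", "0"), levels = c("0", "1", "2", "3")),
    quadrant = factor(c("QSE", "QSM", "QSE", "QII", "QSI"),
                      levels = c("QSM", "QSE", "QEE", "QIE", "QIM", "QII",
                                 "QEI", "QSI")),
    multifocality = factor(c("absent", "present", "absent", "absent", "present"),
                           levels = c("absent", "present")),
    angioinvasion = factor(c("absent", "absent", "present", "absent", "absent"),
                           levels = c("absent", "present")),
    invasiveness = factor(c("infiltrating", "infiltrating", "in_situ",
                            "infiltrating", "infiltrating"),
                          levels = c("infiltrating", "in_situ")),
    stringsAsFactors = FALSE))
}

# cohort with precomputed per-ROI feature tables (fast pipeline fixture):
# feature t1 of every table carries the planted radiomic class signal
make_feature_cohort <- function(n = 40, prevalence = 0.25,
                                clinical_effects = 0, rad_effect = 0,
                                n_feat = 4, seed = 1) {
  co <- gen_cohort(n, prevalence = prevalence,
                   clinical_effects = clinical_effects,
                   missing_rates = no_missing(), seed = seed,
                   with_images = FALSE)
  set.seed(seed + 90000)
  mk <- function() {
    x <- matrix(rnorm(n * n_feat), n, n_feat,
                dimnames = list(NULL, paste0("t", seq_len(n_feat))))
    x[, 1] <- x[, 1] + rad_effect * co$labels
    x
  }
  co$features <- list(original = mk(), intra = mk(), peri = mk(),
                      combined = mk())
  co
}

# lean GA/bootstrap settings for pipeline-shape tests
fast_config <- function(seed = 1, ...) {
  sln_config(ga = ga_params(population_size = 6L, generations = 3L,
                            cv_folds = 3L),
             bootstrap_rounds = 20L, perm_rounds = 99L, seed = seed, ...)
}
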