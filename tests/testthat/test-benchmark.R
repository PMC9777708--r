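test_that("CV partitions cover every patient once per repetition", {
  out <- toy_outcome(rexp(47), rbinom(47, 1, 0.6))
  scheme <- cv_scheme(folds = 5, repetitions = 3, seed = 9)
  splits <- depthsurv:::make_cv_splits(scheme, out)
  expect_length(splits, 15)
  for (r in 1:3) {
    test_ids <- unlist(lapply(splits, function(s) {
      if (s$repetition == r) s$test_idx else integer(0)
    }))
    expect_setequal(test_ids, 1:47)
    expect_length(test_ids, 47)
  }
  # deterministic given the scheme seed
  splits2 <- depthsurv:::make_cv_splits(scheme, out)
  expect_identical(splits, splits2)
  expect_error(cv_scheme(folds = 1), "folds")
})

test_that("repeated CV emits folds x repetitions values per metric", {
  coh <- quick_cohort(seed = 41, n = 60, p = 20, effect = 0.8)
  r <- repeated_cv_evaluate(coh$counts, coh$survival,
                            scheme = cv_scheme(3, 2, seed = 5))
  expect_equal(nrow(r), 3 * 2 * 2)
  expect_equal(sum(r$metric == "cindex"), 6)
  expect_equal(sum(r$metric == "ibs"), 6)
  expect_true(all(r$value[r$metric == "cindex"] >= 0 &
                    r$value[r$metric == "cindex"] <= 1))
  expect_true(all(r$value[r$metric == "ibs"] >= 0 &
                    r$value[r$metric == "ibs"] <= 1))
})

test_that("changing only the thinning seed leaves fold assignments unchanged", {
  coh <- quick_cohort(seed = 42, n = 50, p = 15, effect = 0.5)
  scheme <- cv_scheme(2, 1, seed = 3)
  a <- repeated_cv_evaluate(coh$counts, coh$survival, scheme = scheme,
                            delta = 10, thin_seed = 1)
  b <- repeated_cv_evaluate(coh$counts, coh$survival, scheme = scheme,
                            delta = 10, thin_seed = 2)
  expect_identical(a[, c("repetition", "fold")], b[, c("repetition", "fold")])
  expect_false(identical(a$value, b$value))
})

test_that("training-fraction subsampling keeps the 20% test fold untouched", {
  coh <- quick_cohort(seed = 43, n = 80, p = 15, effect = 0.8, censoring = 0.3)
  scheme <- cv_scheme(5, 1, seed = 7)
  small <- repeated_cv_evaluate(coh$counts, coh$survival, scheme = scheme,
                                train_fraction = 0.4)
  expect_equal(unique(small$train_fraction), 0.4)
  expect_equal(nrow(small), 10)
  expect_error(repeated_cv_evaluate(coh$counts, coh$survival, scheme = scheme,
                                    train_fraction = 0.9), "train_fraction")
})

test_that("Wilcoxon comparisons match exact enumeration and handle zeros", {
  x <- c(1, 2, 3)
  expect_equal(compare_metric_samples(x, x), 1)
  # ten strictly positive paired differences: p = 2^-10
  a <- 1:10 + (1:10) / 100
  b <- 1:10
  expect_equal(compare_metric_samples(a, b, "greater"), 2^-10)
  # n = 5 with one negative difference: brute-force null enumeration
  d <- c(1, 2, 3, 4, -5)
  p_pkg <- compare_metric_samples(d, rep(0, 5), "greater")
  expect_equal(p_pkg, signed_rank_enum(d, "greater"))
  expect_equal(p_pkg, 10 / 32)
  # unpaired rank-sum agrees with wilcox.test
  set.seed(44)
  u <- rnorm(8)
  v <- rnorm(9) + 1
  expect_equal(compare_metric_samples(u, v, "less", paired = FALSE),
               stats::wilcox.test(u, v, alternative = "less", exact = TRUE)$p.value)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(45)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("inclusion rule: uniformly above includes, boundary excludes", {
  expect_true(inclusion_test(rep(0.7, 50)))
  res <- inclusion_test(rep(0.6, 50))
  expect_false(as.logical(res))
  expect_equal(attr(res, "p_value"), 1)
  # p-value agrees with exact signed-rank enumeration on a small sample
  set.seed(46)
  v <- round(rnorm(12, 0.62, 0.05), 6)
  res2 <- inclusion_test(v)
  expect_equal(attr(res2, "p_value"), signed_rank_enum(v - 0.6, "greater"))
})

test_that("max_fold_reduction reads a hand-built grid correctly", {
  set.seed(100)
  base_ci <- rnorm(10, 0.7, 0.02)
  base_ibs <- rnorm(10, 0.15, 0.01)
  build_grid <- function(shift_at) {
    # identical split-paired values unless a delta is designed to degrade,
    # so the paired tests are exactly null (p = 1) off the breakpoints
    do.call(rbind, lapply(c(1, 100, 1000), function(d) {
      ci <- base_ci - if (d %in% shift_at) 0.15 else 0
      data.frame(delta = d, train_fraction = 0.8, model = "cox",
                 data_kind = "omics",
                 repetition = rep(1:2, each = 5), fold = rep(1:5, 2),
                 metric = rep(c("cindex", "ibs"), each = 10),
                 value = c(ci, base_ibs))
    }))
  }
  # no degradation anywhere: delta* is the maximum tested, metric "none"
  flat <- build_grid(shift_at = integer(0))
  dec <- max_fold_reduction(flat)
  expect_equal(dec$max_fold_reduction, 1000)
  expect_equal(dec$metric_degraded_first, "none")
  # C-index collapses at 1000 only: delta* = 100 and C-index fails first
  brk <- build_grid(shift_at = 1000)
  dec2 <- max_fold_reduction(brk)
  expect_equal(dec2$max_fold_reduction, 100)
  expect_equal(dec2$metric_degraded_first, "C-index")
  # failure already at the smallest tested reduction reports "<1"
  early <- build_grid(shift_at = c(100, 1000))
  dec3 <- max_fold_reduction(early)
  expect_equal(dec3$max_fold_reduction, "<1")
  # monotone closure: a dip at 100 with recovery at 1000 still stops at "<1"
  dip <- build_grid(shift_at = 100)
  expect_equal(max_fold_reduction(dip)$max_fold_reduction, "<1")
  expect_error(max_fold_reduction(flat[flat$delta > 1, ]), "reference")
})

test_that("clinical design encodes factors safely", {
  clin <- data.frame(patient_id = paste0("p", 1:6),
                     age = c(50, 60, 70, 55, 65, 75),
                     grade = factor(c("G1", "G2", "G2", "G3", "G1", "G3")),
                     M = factor(rep("M0", 6)))
  expect_warning(des <- depthsurv:::.clinical_design(clin), "single level")
  expect_false(any(grepl("^M", rownames(des$train))))
  clin_te <- data.frame(patient_id = paste0("q", 1:2), age = c(58, 62),
                        grade = factor(c("G2", "G4")), M = factor(c("M0", "M1")))
  expect_warning(
    expect_warning(des2 <- depthsurv:::.clinical_design(clin, clin_te),
                   "single level"),
    "unseen")
  expect_equal(dim(des2$test), c(nrow(des2$train), 2))
})

test_that("clinical integration recovers the orientation of a real omics signal", {
  hits <- 0
  for (s in 1:3) {
    coh <- quick_cohort(seed = 50 + s, n = 80, p = 15, effect = 1,
                        censoring = 0.3)
    rs <- coh$true_linear_predictor + rnorm(80, 0, 0.3)
    tr <- 1:60
    te <- 61:80
    comb <- suppressWarnings(integrate_clinical_risk(
      rs[tr], rs[te], coh$clinical[tr, ], coh$clinical[te, ],
      coh$survival[tr, ]))
    if (comb$model$beta["risk_score"] > 0) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("clinical and combined data kinds run end to end", {
  coh <- quick_cohort(seed = 61, n = 70, p = 15, effect = 0.8, censoring = 0.4)
  scheme <- cv_scheme(2, 1, seed = 11)
  r_clin <- suppressWarnings(
    repeated_cv_evaluate(coh$counts, coh$survival, coh$clinical,
                         scheme = scheme, data_kind = "clinical"))
  r_both <- suppressWarnings(
    repeated_cv_evaluate(coh$counts, coh$survival, coh$clinical,
                         scheme = scheme, data_kind = "omics+clinical"))
  expect_equal(nrow(r_clin), 4)
  expect_equal(nrow(r_both), 4)
  expect_true(all(is.finite(r_clin$value)))
  expect_true(all(is.finite(r_both$value)))
})

test_that("saturation grids stack scenarios with consistent bookkeeping", {
  coh <- quick_cohort(seed = 62, n = 50, p = 15, effect = 0.6)
  scheme <- cv_scheme(2, 1, seed = 13)
  g <- saturation_grid(coh$counts, coh$survival, scheme = scheme,
                       deltas = c(1, 10), train_fractions = c(0.3, 0.5))
  expect_equal(nrow(g), 2 * 2 * 2 * 2)  # deltas x fractions x splits x metrics
  # a single-point grid reproduces repeated_cv_evaluate exactly
  g1 <- saturation_grid(coh$counts, coh$survival, scheme = scheme,
                        deltas = 1, train_fractions = 0.5)
  r1 <- repeated_cv_evaluate(coh$counts, coh$survival, scheme = scheme,
                             delta = 1, train_fraction = 0.5)
  expect_equal(g1$value, r1$value)
  expect_error(saturation_grid(coh$counts, coh$survival, deltas = 0.5),
               "at least 1")
})

test_that("hypothesis decomposition shares splits and gene sets across conditions", {
  coh <- simulate_cohort(simulation_config(
    n_patients = 60, p_genes = 100, median_depth = 1e5, depth_log_sd = 0.2,
    abundance_log_sd = 2.5, n_prognostic = 5, effect_size = 1,
    target_censoring = 0.3, prognostic_abundance = 5e-3, seed = 63))
  hd <- hypothesis_decomposition(coh$counts, coh$survival,
                                 scheme = cv_scheme(2, 1, seed = 17),
                                 delta_extreme = 10000, seed = 5)
  expect_setequal(unique(hd$samples$condition), c("A", "B", "C"))
  expect_equal(nrow(hd$samples), 3 * 4)
  expect_true(length(hd$detectable_genes) < nrow(coh$counts))
  expect_equal(nrow(hd$comparisons), 4)
  expect_true(all(hd$comparisons$p >= 0 & hd$comparisons$p <= 1))
})

test_that("external validation evaluates a fixed never-thinned test cohort", {
  # one generated cohort split in two, so both halves share the same
  # prognostic genes and effect sizes (an exchangeable external cohort)
  coh <- quick_cohort(seed = 64, n = 110, p = 25, effect = 1.2,
                      n_prognostic = 5, censoring = 0.3)
  tr_ids <- 1:70
  te_ids <- 71:110
  test_expr <- log_cpm(count_matrix(coh$counts[, te_ids]))
  ev <- external_validation(coh$counts[, tr_ids], coh$survival[tr_ids, ],
                            test_expr, coh$survival[te_ids, ],
                            deltas = 1, n_repeats = 5, seed = 3)
  expect_equal(nrow(ev), 10)
  ci <- ev$value[ev$metric == "cindex"]
  expect_true(all(ci >= 0 & ci <= 1))
  # the same generator produced both cohorts, so the signal transfers
  expect_gt(median(ci), 0.55)
})
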