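# The experimental engine: repeated cross-validation over the
# (fold-reduction delta) x (training fraction x) scenario grid, clinical
# integration, Wilcoxon/Benjamini-Hochberg comparison machinery, the
# depth-degradation decision rule, the cancer-inclusion rule, the
# detection-vs-noise hypothesis decomposition and external-cohort
# validation.

#' Repeated cross-validation scheme
#'
#' `repetitions` independent K-fold partitions; every patient appears in
#' the test fold exactly once per repetition, so the scheme yields
#' `folds * repetitions` metric values per scenario (50 with the defaults).
#' The test fraction is `1/folds` (20% with K = 5) and is never thinned
#' down in the patient-reduction experiments.
#'
#' @param folds K (default 5).
#' @param repetitions number of repetitions (default 10).
#' @param seed partition seed.
#' @return a `cv_scheme` list.
#' @export
cv_scheme <- function(folds = 5, repetitions = 10, seed = 1) {
  if (folds < 2) stopf("folds must be at least 2")
  if (repetitions < 1) stopf("repetitions must be at least 1")
  structure(list(folds = as.integer(folds), repetitions = as.integer(repetitions),
                 test_fraction = 1 / folds, seed = as.integer(seed)),
            class = "cv_scheme")
}

# K-fold partitions per repetition; redrawn (up to 20 times) until every
# test fold holds at least one event and every training complement at
# least two.
make_cv_splits <- function(scheme, outcome) {
  stopifnot(inherits(scheme, "cv_scheme"))
  n <- nrow(outcome)
  status <- outcome$status
  splits <- list()
  for (rep_i in seq_len(scheme$repetitions)) {
    assignment <- NULL
    for (attempt in seq_len(20)) {
      cand <- with_seed(derive_seed(scheme$seed, rep_i * 100 + attempt),
                        sample(rep_len(seq_len(scheme$folds), n)))
      ok <- all(vapply(seq_len(scheme$folds), function(k) {
        sum(status[cand == k]) >= 1 && sum(status[cand != k]) >= 2
      }, logical(1)))
      if (ok) { assignment <- cand; break }
    }
    if (is.null(assignment)) stopf("could not partition repetition %d with enough events", rep_i)
    for (k in seq_len(scheme$folds)) {
      splits[[length(splits) + 1]] <- list(repetition = rep_i, fold = k,
                                           test_idx = which(assignment == k))
    }
  }
  splits
}

# One-hot design matrices for clinical covariates, with factor levels
# anchored on the training fold. Single-level columns are dropped with a
# warning; unseen test levels are mapped to the training reference level.
.clinical_design <- function(train, test = NULL, sex_specific = FALSE) {
  strip <- function(x) x[, setdiff(names(x), "patient_id"), drop = FALSE]
  tr <- strip(train)
  if (sex_specific) tr$gender <- NULL
  levels_of <- list()
  for (col in names(tr)) {
    if (!is.numeric(tr[[col]])) {
      tr[[col]] <- factor(as.character(tr[[col]]))
      if (nlevels(tr[[col]]) < 2) {
        warnf("clinical column '%s' has a single level in training; dropped", col)
        tr[[col]] <- NULL
        next
      }
      levels_of[[col]] <- levels(tr[[col]])
    } else if (stats::sd(tr[[col]]) < 1e-12) {
      warnf("clinical column '%s' is constant in training; dropped", col)
      tr[[col]] <- NULL
    }
  }
  if (ncol(tr) == 0) stopf("no usable clinical covariates")
  mm_tr <- stats::model.matrix(~ ., data = tr)[, -1, drop = FALSE]
  out <- list(train = t(mm_tr))
  if (!is.null(test)) {
    te <- strip(test)[, names(tr), drop = FALSE]
    for (col in names(levels_of)) {
      v <- as.character(te[[col]])
      unseen <- !(v %in% levels_of[[col]])
      if (any(unseen)) {
        warnf("clinical column '%s': %d unseen level(s) mapped to reference",
              col, sum(unseen))
        v[unseen] <- levels_of[[col]][1]
      }
      te[[col]] <- factor(v, levels = levels_of[[col]])
    }
    mm_te <- stats::model.matrix(~ ., data = te)[, -1, drop = FALSE]
    out$test <- t(mm_te[, colnames(mm_tr), drop = FALSE])
  }
  out
}

# Unpenalized Cox fit on a small covariate matrix (vars x patients),
# packaged as a coxnet_model so risk scores and Breslow survival curves
# reuse the same machinery.
.fit_unpenalized_cox <- function(X, outcome) {
  y <- .surv_y(outcome)
  cf <- survival::coxph.fit(t(X), y, strata = NULL, offset = NULL,
                            init = NULL, control = survival::coxph.control(),
                            weights = NULL, method = "breslow", rownames = NULL)
  beta <- cf$coefficients
  beta[!is.finite(beta)] <- 0
  names(beta) <- rownames(X)
  new_coxnet_model(beta, X, outcome)
}

#' Combine an omics risk score with clinical covariates
#'
#' Refits an unpenalized Cox model on the training fold with the omics risk
#' score and the one-hot clinical covariates as predictors
#' (`RS = beta * RS_omics + sum_l beta_l * Clin_l`); the combined risk
#' score on the test fold is the fitted linear predictor. This avoids
#' diluting a handful of clinical variables among thousands of penalized
#' genes.
#'
#' @param rs_train,rs_test omics risk scores from a model fitted on the same
#'   training fold.
#' @param clinical_train,clinical_test clinical tables aligned to the folds.
#' @param outcome_train training survival.
#' @param sex_specific omit the gender column (sex-specific cancers).
#' @return list with `train` and `test` combined risk scores, the fitted
#'   `model` (a `coxnet_model`), and the `design` matrices used.
#' @export
integrate_clinical_risk <- function(rs_train, rs_test, clinical_train,
                                    clinical_test, outcome_train,
                                    sex_specific = FALSE) {
  des <- .clinical_design(clinical_train, clinical_test, sex_specific)
  Xtr <- rbind(risk_score = rs_train, des$train)
  Xte <- rbind(risk_score = rs_test, des$test)
  model <- .fit_unpenalized_cox(Xtr, outcome_train)
  list(train = cox_risk_score(model, Xtr), test = cox_risk_score(model, Xte),
       model = model, design = list(train = Xtr, test = Xte))
}

# The per-split pipeline: thin -> normalize -> detect -> prescreen ->
# standardize -> fit -> score the untouched test fold with both metrics.
.eval_split <- function(counts, outcome, clinical, train_idx, test_idx,
                        delta, model, data_kind, opts, seed_fit,
                        seed_thin_train, seed_thin_test) {
  out_tr <- outcome[train_idx, , drop = FALSE]
  out_te <- outcome[test_idx, , drop = FALSE]
  eps <- 1 / delta
  score_model <- NULL
  score_expr <- NULL
  rs_tr <- rs_te <- NULL
  if (data_kind %in% c("omics", "omics+clinical")) {
    tr_c <- thin_counts(counts[, train_idx, drop = FALSE], eps, seed_thin_train)
    te_c <- thin_counts(counts[, test_idx, drop = FALSE], eps, seed_thin_test)
    trf <- tmm_factors(tr_c)
    tef <- tmm_factors(te_c)
    genes <- rownames(counts)
    if (opts$detect_filter) {
      mask <- detect_genes(tr_c, trf)
      genes <- names(mask)[mask]
      if (length(genes) < 2) stopf("fewer than 2 genes detected in a training fold")
    }
    tr_e <- log_cpm(tr_c, trf)[genes, , drop = FALSE]
    te_e <- log_cpm(te_c, tef)[genes, , drop = FALSE]
    keep <- prescreen_genes(tr_e, out_tr, k = opts$prescreen_k)
    std <- standardize_train_test(tr_e[keep, , drop = FALSE],
                                  te_e[keep, , drop = FALSE])
    if (nrow(std$train) < 2) stopf("fewer than 2 usable genes after standardization")
    if (model == "cox") {
      m <- fit_cox(std$train, out_tr, alpha = opts$alpha,
                   cv_folds = opts$lambda_folds, seed = seed_fit)
      rs_tr <- cox_risk_score(m, std$train)
      rs_te <- cox_risk_score(m, std$test)
    } else {
      mt <- if (isTRUE(opts$rsf_tune)) {
        tune_mtry(std$train, out_tr, n_trees = opts$rsf_trees,
                  min_node = opts$rsf_min_node, seed = seed_fit)
      } else {
        opts$rsf_mtry %||% ceiling(sqrt(nrow(std$train)))
      }
      m <- fit_forest(std$train, out_tr, n_trees = opts$rsf_trees,
                      min_node = opts$rsf_min_node, mtry = mt, seed = seed_fit)
      rs_tr <- forest_risk_score(m, std$train)
      rs_te <- forest_risk_score(m, std$test)
    }
    score_model <- m
    score_expr <- std$test
  }
  if (data_kind == "clinical") {
    des <- .clinical_design(clinical[train_idx, , drop = FALSE],
                            clinical[test_idx, , drop = FALSE],
                            opts$sex_specific)
    score_model <- .fit_unpenalized_cox(des$train, out_tr)
    score_expr <- des$test
    rs_te <- cox_risk_score(score_model, des$test)
  } else if (data_kind == "omics+clinical") {
    comb <- integrate_clinical_risk(rs_tr, rs_te,
                                    clinical[train_idx, , drop = FALSE],
                                    clinical[test_idx, , drop = FALSE],
                                    out_tr, opts$sex_specific)
    score_model <- comb$model
    score_expr <- comb$design$test
    rs_te <- comb$test
  }
  grid <- sort(unique(c(0, out_te$time[out_te$status == 1])))
  curves <- predict_survival(score_model, score_expr, grid)
  G <- censoring_km(out_te)
  c(cindex = concordance_index(rs_te, out_te),
    ibs = integrated_brier_score(curves, grid, out_te, G))
}

.benchmark_opts <- function(alpha = 0.3, lambda_folds = 5, prescreen_k = 2500,
                            detect_filter = TRUE, rsf_trees = 50,
                            rsf_min_node = 3, rsf_mtry = NULL,
                            rsf_tune = FALSE, sex_specific = FALSE) {
  list(alpha = alpha, lambda_folds = lambda_folds, prescreen_k = prescreen_k,
       detect_filter = detect_filter, rsf_trees = rsf_trees,
       rsf_min_node = rsf_min_node, rsf_mtry = rsf_mtry, rsf_tune = rsf_tune,
       sex_specific = sex_specific)
}

#' Repeated cross-validated evaluation of one scenario point
#'
#' For each of the `folds x repetitions` splits: thin the counts at fold
#' reduction `delta` (training AND test halves, with independent thinning
#' seeds), optionally subsample the training fold to `train_fraction` of
#' the cohort, renormalize (TMM + log2-CPM on the thinned counts), filter
#' undetected genes, prescreen, standardize by the training fold, fit the
#' model, and score the untouched-size test fold with the concordance index
#' and the integrated Brier score.
#'
#' @param counts count matrix (genes x patients).
#' @param outcome survival data.frame aligned to the patients of `counts`.
#' @param clinical optional clinical table (required for the clinical data
#'   kinds).
#' @param scheme a [cv_scheme()].
#' @param delta fold reduction of sequencing depth (1 = no thinning).
#' @param train_fraction fraction of the cohort used for training (at most
#'   `1 - 1/folds`; smaller values subsample the training pool).
#' @param model `"cox"` or `"rsf"`.
#' @param data_kind `"omics"`, `"clinical"`, or `"omics+clinical"`.
#' @param thin_seed seed stream for the binomial thinning (independent of
#'   the fold-assignment seed, so thinning can be re-randomized without
#'   changing the splits).
#' @param ... tuning options: `alpha`, `lambda_folds`, `prescreen_k`,
#'   `detect_filter`, `rsf_trees`, `rsf_min_node`, `rsf_mtry`, `rsf_tune`,
#'   `sex_specific`.
#' @return long data.frame: `delta`, `train_fraction`, `model`,
#'   `data_kind`, `repetition`, `fold`, `metric` (`"cindex"`/`"ibs"`),
#'   `value`.
#' @export
repeated_cv_evaluate <- function(counts, outcome, clinical = NULL,
                                 scheme = cv_scheme(), delta = 1,
                                 train_fraction = NULL, model = c("cox", "rsf"),
                                 data_kind = c("omics", "clinical", "omics+clinical"),
                                 thin_seed = NULL, ...) {
  model <- match.arg(model)
  data_kind <- match.arg(data_kind)
  opts <- .benchmark_opts(...)
  outcome <- as_survival(outcome)
  if (!identical(outcome$patient_id, colnames(counts))) {
    if (!setequal(outcome$patient_id, colnames(counts))) {
      stopf("counts and outcome cover different patients; run align_cohort() first")
    }
    outcome <- outcome[match(colnames(counts), outcome$patient_id), , drop = FALSE]
  }
  if (data_kind != "omics" && is.null(clinical)) {
    stopf("data kind '%s' needs a clinical table", data_kind)
  }
  if (!is.null(clinical)) {
    clinical <- clinical[match(colnames(counts), clinical$patient_id), , drop = FALSE]
  }
  n <- ncol(counts)
  max_frac <- 1 - scheme$test_fraction
  train_fraction <- train_fraction %||% max_frac
  if (train_fraction > max_frac + 1e-9) {
    stopf("train_fraction cannot exceed %.2f with %d folds", max_frac, scheme$folds)
  }
  thin_seed <- thin_seed %||% derive_seed(scheme$seed, 999)
  splits <- make_cv_splits(scheme, outcome)
  rows <- vector("list", length(splits))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    pool <- setdiff(seq_len(n), sp$test_idx)
    n_train <- min(length(pool), max(2L, round(train_fraction * n)))
    train_idx <- pool
    if (n_train < length(pool)) {
      ok <- FALSE
      for (attempt in seq_len(20)) {
        cand <- with_seed(derive_seed(scheme$seed, 7000 + s * 50 + attempt),
                          sample(pool, n_train))
        if (sum(outcome$status[cand]) >= 2) { train_idx <- cand; ok <- TRUE; break }
        message("redrawing training subsample for split ", s,
                " (fewer than 2 events)")
      }
      if (!ok) stopf("could not subsample a training fold with 2 events (split %d)", s)
    }
    metrics <- .eval_split(counts, outcome, clinical, train_idx, sp$test_idx,
                           delta, model, data_kind, opts,
                           seed_fit = derive_seed(scheme$seed, 5000 + s),
                           seed_thin_train = derive_seed(thin_seed, 2 * s),
                           seed_thin_test = derive_seed(thin_seed, 2 * s + 1))
    rows[[s]] <- data.frame(delta = delta, train_fraction = train_fraction,
                            model = model, data_kind = data_kind,
                            repetition = sp$repetition, fold = sp$fold,
                            metric = names(metrics), value = unname(metrics),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("saturation_grid", "data.frame")
  out
}

#' Evaluate the full depth x cohort-size scenario grid
#'
#' Runs [repeated_cv_evaluate()] for every combination of fold reduction,
#' training fraction, model kind and data kind, sharing the same CV splits
#' (so scenario points are paired across the grid) and independent thinning
#' streams.
#'
#' @inheritParams repeated_cv_evaluate
#' @param deltas fold reductions (default `c(1, 10, 100, 1000, 10000)`).
#' @param train_fractions training fractions of the cohort (default 0.8;
#'   the patient-reduction experiment uses `seq(0.1, 0.8, by = 0.1)`).
#' @param models model kinds to fit.
#' @param data_kinds data kinds to evaluate.
#' @return long `saturation_grid` data.frame (one row per scenario x split
#'   x metric).
#' @export
saturation_grid <- function(counts, outcome, clinical = NULL,
                            scheme = cv_scheme(),
                            deltas = c(1, 10, 100, 1000, 10000),
                            train_fractions = 0.8, models = "cox",
                            data_kinds = "omics", thin_seed = NULL, ...) {
  if (any(deltas < 1)) stopf("fold reductions must be at least 1")
  combos <- expand.grid(delta = sort(deltas), train_fraction = train_fractions,
                        model = models, data_kind = data_kinds,
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    repeated_cv_evaluate(counts, outcome, clinical, scheme = scheme,
                         delta = combos$delta[i],
                         train_fraction = combos$train_fraction[i],
                         model = combos$model[i],
                         data_kind = combos$data_kind[i],
                         thin_seed = thin_seed, ...)
  }))
  rownames(out) <- NULL
  class(out) <- c("saturation_grid", "data.frame")
  out
}

#' One-sided Wilcoxon comparison of two metric samples
#'
#' Paired samples (same CV splits) use the signed-rank test with zero
#' differences removed (all-zero differences give p = 1); independent
#' samples use the rank-sum test. The exact null distribution is used for
#' n <= 25 without ties; the normal approximation with continuity
#' correction otherwise.
#'
#' @param a,b numeric metric samples. `alternative = "greater"` tests
#'   whether `a` tends larger than `b`.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @param paired TRUE for the signed-rank test.
#' @return the p-value.
#' @export
compare_metric_samples <- function(a, b, alternative = c("greater", "less", "two.sided"),
                                   paired = TRUE) {
  alternative <- match.arg(alternative)
  if (paired) {
    if (length(a) != length(b)) stopf("paired samples must have equal length")
    d <- a - b
    d <- d[d != 0]
    if (length(d) == 0) return(1)
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                        exact = exact, correct = TRUE)$p.value)
  } else {
    exact <- length(a) <= 25 && length(b) <= 25 && !any(duplicated(c(a, b)))
    suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                        exact = exact, correct = TRUE)$p.value)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (thin wrapper over [stats::p.adjust()] kept for a stable surface).
#'
#' @param pvalues raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Maximum depth reduction without degraded prediction
#'
#' For each fold reduction `delta > 1` in ascending order, runs paired
#' one-sided Wilcoxon tests against the `delta = 1` reference: degradation
#' means a LOWER C-index or a HIGHER IBS. The sequencing depth counts as
#' reducible by `delta` if and only if neither metric is degraded at
#' `level` for `delta` and every smaller reduction; the decision uses
#' BH-adjusted p-values across the comparison family. Returns `"<1"` when
#' the smallest tested reduction already degrades. All p-values are
#' indicative only: the 50 CV values per scenario share patients and are
#' not independent.
#'
#' @param grid a `saturation_grid` covering `delta = 1` and the reductions
#'   of interest at a fixed training fraction.
#' @param model,data_kind,train_fraction scenario selectors (defaulting to
#'   the single value present, largest train fraction).
#' @param level significance level (default 0.05).
#' @param adjust use BH-adjusted p-values for the decision (default TRUE).
#' @return a `degradation_decision`: `max_fold_reduction` (largest
#'   non-degrading delta, or `"<1"`), `metric_degraded_first`
#'   (`"C-index"`, `"IBS"`, `"both"`, `"none"`), and the p-value table.
#' @export
max_fold_reduction <- function(grid, model = NULL, data_kind = NULL,
                               train_fraction = NULL, level = 0.05,
                               adjust = TRUE) {
  sel <- function(col, want) {
    u <- unique(grid[[col]])
    if (is.null(want)) {
      if (length(u) > 1) stopf("multiple %s values in grid; pick one", col)
      u
    } else want
  }
  model <- sel("model", model)
  data_kind <- sel("data_kind", data_kind)
  train_fraction <- train_fraction %||% max(grid$train_fraction)
  g <- grid[grid$model == model & grid$data_kind == data_kind &
              abs(grid$train_fraction - train_fraction) < 1e-9, , drop = FALSE]
  deltas <- sort(unique(g$delta))
  if (!(1 %in% deltas)) stopf("grid must contain the delta = 1 reference")
  pull <- function(delta, metric) {
    x <- g[g$delta == delta & g$metric == metric, , drop = FALSE]
    x <- x[order(x$repetition, x$fold), , drop = FALSE]
    x$value
  }
  ref_c <- pull(1, "cindex")
  ref_i <- pull(1, "ibs")
  higher <- deltas[deltas > 1]
  if (length(higher) == 0) stopf("grid contains no fold reduction above 1")
  ptab <- do.call(rbind, lapply(higher, function(d) {
    data.frame(delta = d,
               metric = c("C-index", "IBS"),
               p = c(compare_metric_samples(ref_c, pull(d, "cindex"), "greater"),
                     compare_metric_samples(pull(d, "ibs"), ref_i, "greater")),
               stringsAsFactors = FALSE)
  }))
  ptab$p_adjusted <- bh_adjust(ptab$p)
  p_use <- if (adjust) ptab$p_adjusted else ptab$p
  degraded <- matrix(p_use < level, nrow = 2)  # rows: C-index, IBS
  delta_star <- "<1"
  metric_first <- "none"
  passing <- !colSums(degraded)
  n_pass <- if (all(passing)) length(higher) else which(!passing)[1] - 1
  if (n_pass > 0) delta_star <- higher[n_pass]
  if (n_pass < length(higher)) {
    fail <- degraded[, n_pass + 1]
    metric_first <- if (all(fail)) "both" else if (fail[1]) "C-index" else "IBS"
  }
  structure(list(max_fold_reduction = delta_star,
                 metric_degraded_first = metric_first,
                 pvalues = ptab, level = level, model = model,
                 data_kind = data_kind, train_fraction = train_fraction),
            class = "degradation_decision")
}

#' @export
print.degradation_decision <- function(x, ...) {
  cat(sprintf("Maximum fold reduction without degraded prediction (%s, %s, x = %.0f%%): %s\n",
              x$model, x$data_kind, 100 * x$train_fraction,
              as.character(x$max_fold_reduction)))
  cat(sprintf("Metric degraded first: %s\n", x$metric_degraded_first))
  print(x$pvalues, row.names = FALSE)
  cat("(p-values are indicative: CV samples share patients and are not independent)\n")
  invisible(x)
}

#' Cohort inclusion rule
#'
#' A cohort conveys prognostic value when its median C-index is
#' significantly above `threshold` by a one-sample one-sided Wilcoxon
#' signed-rank test at `level`.
#'
#' @param values metric sample (e.g., the 50 CV C-indices).
#' @param threshold reference value (default 0.6).
#' @param level significance level (default 0.05).
#' @return TRUE/FALSE with the p-value in the `"p_value"` attribute.
#' @export
inclusion_test <- function(values, threshold = 0.6, level = 0.05) {
  d <- values - threshold
  d <- d[d != 0]
  if (length(d) == 0) return(structure(FALSE, p_value = 1))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  p <- suppressWarnings(stats::wilcox.test(d, alternative = "greater",
                                           exact = exact, correct = TRUE)$p.value)
  structure(p < level, p_value = p)
}

#' Decompose the depth-degradation mechanism
#'
#' Evaluates three conditions on shared CV splits to separate the two
#' candidate explanations for performance loss at extreme thinning:
#' (A) full depth, all genes; (B) full depth, restricted to the gene set
#' still detectable after thinning by `delta_extreme` (tests whether losing
#' the low-expressed genes alone hurts -- hypothesis 1, detection loss);
#' (C) thinned by `delta_extreme` on that same gene set (tests whether the
#' per-gene signal-to-noise loss hurts -- hypothesis 2). Detection
#' filtering is disabled inside the splits so B and C use identical gene
#' sets per split.
#'
#' @inheritParams repeated_cv_evaluate
#' @param delta_extreme the extreme fold reduction (default 10000).
#' @param seed seed for the reference thinning that defines the detectable
#'   gene set.
#' @return a `hypothesis_decomposition`: the detectable gene set, the
#'   metric samples per condition, and one-sided paired p-values for
#'   A vs B (hypothesis 1) and B vs C (hypothesis 2), per metric.
#' @export
hypothesis_decomposition <- function(counts, outcome, scheme = cv_scheme(),
                                     delta_extreme = 10000, model = "cox",
                                     seed = 1, ...) {
  thinned <- thin_counts(counts, 1 / delta_extreme, seed = derive_seed(seed, 77))
  detectable <- names(which(detect_genes(thinned)))
  if (length(detectable) < 2) stopf("fewer than 2 genes detectable after extreme thinning")
  run <- function(cts, delta, condition) {
    r <- repeated_cv_evaluate(cts, outcome, scheme = scheme, delta = delta,
                              model = model, detect_filter = FALSE, ...)
    r$condition <- condition
    r
  }
  A <- run(counts, 1, "A")
  B <- run(counts[detectable, , drop = FALSE], 1, "B")
  C <- run(counts[detectable, , drop = FALSE], delta_extreme, "C")
  pick <- function(x, metric) {
    v <- x[x$metric == metric, , drop = FALSE]
    v[order(v$repetition, v$fold), "value"]
  }
  comparisons <- data.frame(
    comparison = rep(c("A_vs_B", "B_vs_C"), each = 2),
    hypothesis = rep(c("detection loss", "signal-to-noise loss"), each = 2),
    metric = rep(c("C-index", "IBS"), 2),
    p = c(compare_metric_samples(pick(A, "cindex"), pick(B, "cindex"), "greater"),
          compare_metric_samples(pick(B, "ibs"), pick(A, "ibs"), "greater"),
          compare_metric_samples(pick(B, "cindex"), pick(C, "cindex"), "greater"),
          compare_metric_samples(pick(C, "ibs"), pick(B, "ibs"), "greater")),
    stringsAsFactors = FALSE)
  structure(list(detectable_genes = detectable, samples = rbind(A, B, C),
                 comparisons = comparisons, delta_extreme = delta_extreme),
            class = "hypothesis_decomposition")
}

#' @export
print.hypothesis_decomposition <- function(x, ...) {
  cat(sprintf("Detectable genes after %g-fold thinning: %d\n",
              x$delta_extreme, length(x$detectable_genes)))
  print(x$comparisons, row.names = FALSE)
  cat("(p-values are indicative: CV samples share patients and are not independent)\n")
  invisible(x)
}

#' Validation on a fixed external cohort
#'
#' Repeatedly draws training subsamples from the sequencing cohort, thins
#' them at each fold reduction, fits the model, and evaluates on a FIXED
#' external test set whose expression is never thinned and is standardized
#' independently (its own per-gene mean and SD). Because the test set never
#' changes, the spread of the repeated metrics reflects training
#' variability only.
#'
#' @param train_counts count matrix of the sequencing cohort.
#' @param train_outcome its survival table (aligned).
#' @param test_expression log-expression matrix of the external cohort
#'   (genes x patients), already on its own normalized scale.
#' @param test_outcome external survival table (aligned to
#'   `test_expression`).
#' @param deltas fold reductions applied to the training counts.
#' @param n_repeats number of training subsamples per delta (default 50).
#' @param train_fraction fraction of the cohort drawn per repeat.
#' @param model `"cox"` or `"rsf"`.
#' @param seed seed for subsampling and thinning.
#' @param ... options as in [repeated_cv_evaluate()].
#' @return long data.frame: `delta`, `repeat_id`, `metric`, `value`.
#' @export
external_validation <- function(train_counts, train_outcome, test_expression,
                                test_outcome, deltas = 1, n_repeats = 50,
                                train_fraction = 0.8, model = "cox",
                                seed = 1, ...) {
  opts <- .benchmark_opts(...)
  train_outcome <- as_survival(train_outcome)
  test_outcome <- as_survival(test_outcome)
  shared <- intersect(rownames(train_counts), rownames(test_expression))
  if (length(shared) == 0) stopf("no shared features between cohorts")
  n <- ncol(train_counts)
  out_te <- test_outcome
  rows <- list()
  for (di in seq_along(deltas)) {
    delta <- deltas[di]
    for (r in seq_len(n_repeats)) {
      base <- derive_seed(seed, di * 100000 + r)
      tr <- NULL
      for (attempt in seq_len(20)) {
        cand <- with_seed(derive_seed(base, attempt),
                          sample.int(n, round(train_fraction * n)))
        if (sum(train_outcome$status[cand]) >= 2) { tr <- cand; break }
      }
      if (is.null(tr)) stopf("could not draw a training subsample with 2 events")
      tr_c <- thin_counts(train_counts[, tr, drop = FALSE], 1 / delta,
                          seed = derive_seed(base, 55))
      trf <- tmm_factors(tr_c)
      genes <- shared
      if (opts$detect_filter) {
        mask <- detect_genes(tr_c, trf)
        genes <- intersect(shared, names(mask)[mask])
        if (length(genes) < 2) stopf("fewer than 2 detected genes shared with the external cohort")
      }
      tr_e <- log_cpm(tr_c, trf)[genes, , drop = FALSE]
      keep <- prescreen_genes(tr_e, train_outcome[tr, , drop = FALSE],
                              k = opts$prescreen_k)
      std <- standardize_train_test(tr_e[keep, , drop = FALSE],
                                    test_expression[keep, , drop = FALSE],
                                    external = TRUE)
      out_tr <- train_outcome[tr, , drop = FALSE]
      if (model == "cox") {
        m <- fit_cox(std$train, out_tr, alpha = opts$alpha,
                     cv_folds = opts$lambda_folds, seed = derive_seed(base, 66))
        rs_te <- cox_risk_score(m, std$test)
      } else {
        m <- fit_forest(std$train, out_tr, n_trees = opts$rsf_trees,
                        min_node = opts$rsf_min_node,
                        mtry = opts$rsf_mtry %||% ceiling(sqrt(nrow(std$train))),
                        seed = derive_seed(base, 66))
        rs_te <- forest_risk_score(m, std$test)
      }
      grid <- sort(unique(c(0, out_te$time[out_te$status == 1])))
      curves <- predict_survival(m, std$test, grid)
      rows[[length(rows) + 1]] <- data.frame(
        delta = delta, repeat_id = r,
        metric = c("cindex", "ibs"),
        value = c(concordance_index(rs_te, out_te),
                  integrated_brier_score(curves, grid, out_te)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
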