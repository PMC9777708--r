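#' Binomially thin a count matrix
#'
#' Each read count `R` is replaced by an independent `Binomial(R, epsilon)`
#' draw, simulating a sequencing run at a fraction `epsilon` of the original
#' depth; `delta = 1/epsilon` is the fold reduction in library size.
#' Thinning by `e1` then `e2` is distributionally identical to thinning once
#' by `e1 * e2`.
#'
#' @param counts count matrix (genes x patients).
#' @param epsilon retention probability in `(0, 1]`; `epsilon = 1` returns
#'   the input unchanged.
#' @param seed integer seed for the binomial draws.
#' @return thinned count matrix, same shape and identifiers.
#' @export
thin_counts <- function(counts, epsilon, seed = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon > 1) {
    stopf("epsilon must lie in (0, 1]")
  }
  validate_counts(counts)
  if (epsilon == 1) return(counts)
  with_seed(seed, {
    thinned <- stats::rbinom(length(counts), size = as.integer(round(counts)),
                             prob = epsilon)
    out <- matrix(as.double(thinned), nrow = nrow(counts),
                  dimnames = dimnames(counts))
    out
  })
}

#' TMM normalization factors
#'
#' Per-patient trimmed-mean-of-M-values factors (via
#' [edgeR::calcNormFactors()]) with the method's canonical settings: 30%
#' trim on log-ratios (M), 5% trim on average log-expression (A), precision
#' weights from the binomial variance approximation, and `"auto"` reference
#' = the patient whose upper-quartile count is closest to the mean
#' upper-quartile. Factors are rescaled to geometric mean 1. Patients with
#' zero library size get factor 1 with a warning.
#'
#' @param counts count matrix (genes x patients).
#' @param reference `"auto"` or a patient id naming the reference library.
#' @return a `norm_factors` list: `factors` and `lib_size`, both named by
#'   patient, and the `reference` used.
#' @export
tmm_factors <- function(counts, reference = "auto") {
  validate_counts(counts)
  if (ncol(counts) < 2) stopf("TMM needs at least 2 patients")
  lib <- colSums(counts)
  refcol <- NULL
  if (!identical(reference, "auto")) {
    refcol <- match(reference, colnames(counts))
    if (is.na(refcol)) stopf("reference patient '%s' not found", reference)
  }
  zero <- lib == 0
  factors <- rep(1, ncol(counts))
  names(factors) <- colnames(counts)
  if (any(zero)) {
    warnf("%d patient(s) with zero library size; factor set to 1", sum(zero))
  }
  use <- which(!zero)
  if (length(use) >= 2) {
    sub <- counts[, use, drop = FALSE]
    subref <- if (!is.null(refcol)) match(refcol, use) else NULL
    f <- if (is.null(subref) || is.na(subref)) {
      edgeR::calcNormFactors(sub, lib.size = lib[use], method = "TMM")
    } else {
      edgeR::calcNormFactors(sub, lib.size = lib[use], method = "TMM",
                             refColumn = subref)
    }
    factors[use] <- f
  }
  factors <- factors / geometric_mean(factors)
  structure(list(factors = factors, lib_size = lib,
                 reference = if (is.null(refcol)) "auto" else colnames(counts)[refcol]),
            class = "norm_factors")
}

.check_factors <- function(counts, factors) {
  if (is.null(factors)) return(tmm_factors(counts))
  stopifnot(inherits(factors, "norm_factors"))
  if (!identical(names(factors$factors), colnames(counts))) {
    stopf("normalization factors are not aligned with the patients")
  }
  factors
}

#' Counts per million (CPM)
#'
#' Un-logged CPM on the TMM-corrected library size:
#' `count / (lib_size * factor) * 1e6`. Patients with zero effective library
#' size get CPM 0.
#'
#' @param counts count matrix.
#' @param factors optional `norm_factors` (computed from `counts` if NULL).
#' @return CPM matrix, same shape.
#' @export
cpm <- function(counts, factors = NULL) {
  factors <- .check_factors(counts, factors)
  eff <- factors$lib_size * factors$factors
  out <- sweep(counts, 2, ifelse(eff > 0, eff, Inf), "/") * 1e6
  dimnames(out) <- dimnames(counts)
  out
}

#' Normalized log2-CPM expression
#'
#' The voom-style transformation
#' `log2((count + prior) / (lib_size * factor + 1) * 1e6)` with the TMM
#' factors carried as provenance in the `"norm_factors"` attribute.
#'
#' @param counts count matrix.
#' @param factors optional `norm_factors` (computed from `counts` if NULL).
#' @param prior prior count added to the numerator (default 0.5).
#' @return numeric matrix of log2-CPM values (genes x patients).
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  factors <- .check_factors(counts, factors)
  eff <- factors$lib_size * factors$factors
  out <- log2(sweep(counts + prior, 2, eff + 1, "/") * 1e6)
  dimnames(out) <- dimnames(counts)
  attr(out, "norm_factors") <- factors
  out
}

#' Train-anchored standardization of expression matrices
#'
#' Each retained gene is centered and scaled by its mean and standard
#' deviation among the TRAINING patients; genes constant in the training
#' data are dropped from both matrices and reported in the `"dropped"`
#' attribute. With `external = TRUE` (independent external cohort) the test
#' matrix is standardized by its OWN mean and SD instead.
#'
#' @param train,test log-expression matrices (genes x patients) sharing a
#'   gene set; `test` may be NULL.
#' @param external standardize the test matrix independently.
#' @return list with `train`, `test` (NULL if not given) and `dropped`
#'   (character vector of dropped gene ids).
#' @export
standardize_train_test <- function(train, test = NULL, external = FALSE) {
  if (!is.null(test)) {
    shared <- intersect(rownames(train), rownames(test))
    if (length(shared) == 0) stopf("train and test share no genes")
    if (length(shared) < nrow(train) || length(shared) < nrow(test)) {
      train <- train[shared, , drop = FALSE]
      test <- test[shared, , drop = FALSE]
    } else {
      test <- test[rownames(train), , drop = FALSE]
    }
  }
  m <- rowMeans(train)
  s <- apply(train, 1, stats::sd)
  degenerate <- !is.finite(s) | s < 1e-10
  if (!is.null(test) && external) {
    s2 <- apply(test, 1, stats::sd)
    degenerate <- degenerate | !is.finite(s2) | s2 < 1e-10
  }
  dropped <- rownames(train)[degenerate]
  keep <- !degenerate
  train_std <- (train[keep, , drop = FALSE] - m[keep]) / s[keep]
  test_std <- NULL
  if (!is.null(test)) {
    test <- test[keep, , drop = FALSE]
    test_std <- if (external) {
      (test - rowMeans(test)) / apply(test, 1, stats::sd)
    } else {
      (test - m[keep]) / s[keep]
    }
  }
  list(train = train_std, test = test_std, dropped = dropped)
}

#' Detected-gene mask
#'
#' A gene counts as detected when its (un-logged) CPM exceeds
#' `cpm_threshold` for at least `patient_fraction` of the patients
#' (boundaries inclusive, so 1 patient out of 100 meets the default 1%).
#'
#' @param counts count matrix.
#' @param factors optional `norm_factors`.
#' @param cpm_threshold CPM cutoff (default 1, strict inequality).
#' @param patient_fraction minimum fraction of patients (default 0.01).
#' @return named logical vector over genes.
#' @export
detect_genes <- function(counts, factors = NULL, cpm_threshold = 1,
                         patient_fraction = 0.01) {
  if (cpm_threshold <= 0 || patient_fraction <= 0) {
    stopf("detection thresholds must be positive")
  }
  x <- cpm(counts, factors)
  rowMeans(x > cpm_threshold) >= patient_fraction - 1e-12
}

#' Univariate-Cox prescreen
#'
#' Retains the `k` genes with the smallest likelihood-ratio p-values from
#' single-gene Cox models (Breslow ties), the dimension-reduction step used
#' before forest fitting on large gene sets. When the pool has at most `k`
#' genes, all genes are returned without fitting. Intended to be run on the
#' training fold only.
#'
#' @param expr log-expression matrix (genes x patients).
#' @param outcome survival data.frame (`time`, `status`) aligned to the
#'   patients of `expr`.
#' @param k number of genes to retain (default 2500).
#' @return character vector of retained gene ids (in the input gene order),
#'   with the p-values in the `"pvalues"` attribute when computed.
#' @export
prescreen_genes <- function(expr, outcome, k = 2500) {
  if (k < 1) stopf("k must be at least 1")
  if (any(!is.finite(expr))) stopf("expression contains non-finite values")
  if (nrow(expr) <= k) return(rownames(expr))
  outcome <- as_survival(data.frame(patient_id = colnames(expr),
                                    time = outcome$time, status = outcome$status))
  p <- univariate_cox_pvalue(expr, outcome)
  keep <- sort(order(p)[seq_len(k)])
  structure(rownames(expr)[keep], pvalues = p[keep])
}
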