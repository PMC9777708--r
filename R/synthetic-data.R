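#' Configuration for the synthetic cohort generator
#'
#' Defines a miRNA-seq- or mRNA-seq-like cohort: log-normal library sizes
#' around a target median depth, log-normal (heavy-tailed) gene relative
#' abundances, gamma-Poisson counts, and Weibull proportional-hazards
#' survival driven by a sparse set of prognostic genes with exponential
#' censoring calibrated to a target rate.
#'
#' Defaults emulate a miRNA-seq cohort: a few hundred genes, a median of
#' 5e6 aligned reads per patient, and a censoring rate of 0.65 (mid-range
#' of typical TCGA cohorts).
#'
#' @param n_patients number of patients.
#' @param p_genes number of genes.
#' @param median_depth median library size (aligned reads per patient).
#' @param depth_log_sd sd of log library size (spread of sequencing depth).
#' @param abundance_log_sd sd of log relative abundance; larger values give a
#'   heavier right tail so a minority of genes dominates the reads.
#' @param dispersion gamma-Poisson overdispersion (0 gives Poisson counts).
#' @param n_prognostic number of genes with nonzero log-hazard effect.
#' @param effect_size absolute log-hazard ratio per SD of standardized
#'   log-expression for each prognostic gene (signs alternate).
#' @param nonlinear_fraction fraction of the prognostic signal carried by
#'   thresholded interaction terms (`1(Xj > 0) * Xk` over prognostic pairs)
#'   instead of the linear predictor; 0 keeps the model purely linear.
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (time units arbitrary).
#' @param target_censoring desired censoring fraction in `[0, 1)`.
#' @param clinical_effects named numeric vector of log-hazard coefficients
#'   for clinical covariates (names among `age`, `gender`, `grade`, `T`,
#'   `N`, `M`; `age` is per year). NULL for no clinical contribution.
#' @param prognostic_quantile optional abundance quantile in (0, 1]; when
#'   set, prognostic genes are the genes whose relative abundance is nearest
#'   that quantile ("low" vs "high" expression placement). NULL = random.
#' @param prognostic_abundance optional fixed relative abundance assigned to
#'   every prognostic gene (overrides `prognostic_quantile`); used to plant
#'   depth-limited signal at a known number of reads per gene.
#' @param sex_specific if TRUE the clinical table omits the gender column
#'   (sex-specific cancers).
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 100, p_genes = 500,
                              median_depth = 5e6, depth_log_sd = 0.3,
                              abundance_log_sd = 2, dispersion = 0.15,
                              n_prognostic = 10, effect_size = 1,
                              nonlinear_fraction = 0,
                              baseline_shape = 1.2, baseline_scale = 5,
                              target_censoring = 0.65,
                              clinical_effects = NULL,
                              prognostic_quantile = NULL,
                              prognostic_abundance = NULL,
                              sex_specific = FALSE, seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients), p_genes = as.integer(p_genes),
              median_depth = median_depth, depth_log_sd = depth_log_sd,
              abundance_log_sd = abundance_log_sd, dispersion = dispersion,
              n_prognostic = as.integer(n_prognostic), effect_size = effect_size,
              nonlinear_fraction = nonlinear_fraction,
              baseline_shape = baseline_shape, baseline_scale = baseline_scale,
              target_censoring = target_censoring,
              clinical_effects = clinical_effects,
              prognostic_quantile = prognostic_quantile,
              prognostic_abundance = prognostic_abundance,
              sex_specific = isTRUE(sex_specific), seed = as.integer(seed))
  scalars <- c("median_depth", "baseline_shape", "baseline_scale")
  for (nm in scalars) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) stopf("'%s' must be positive and finite", nm)
  }
  for (nm in c("depth_log_sd", "abundance_log_sd", "dispersion",
               "nonlinear_fraction")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0) stopf("'%s' must be nonnegative and finite", nm)
  }
  if (cfg$n_patients < 2 || cfg$p_genes < 1) stopf("cohort dimensions too small")
  if (cfg$n_prognostic > cfg$p_genes) stopf("n_prognostic exceeds p_genes")
  if (cfg$target_censoring < 0 || cfg$target_censoring >= 1) {
    stopf("target_censoring must lie in [0, 1)")
  }
  if (cfg$nonlinear_fraction > 1) stopf("nonlinear_fraction must lie in [0, 1]")
  class(cfg) <- "simulation_config"
  cfg
}

# Per-stage RNG substreams derived from the one cohort seed.
.sim_seed <- function(cfg, stage) {
  derive_seed(cfg$seed, match(stage, c("abundance", "counts", "prognostic",
                                       "clinical", "survival", "censoring")))
}

# Gene relative abundances (sum to one). Prognostic indices are chosen here
# because placement rules depend on the abundance ranking.
.sim_abundance <- function(cfg) {
  with_seed(.sim_seed(cfg, "abundance"), {
    raw <- exp(stats::rnorm(cfg$p_genes, 0, cfg$abundance_log_sd))
    prog <- if (cfg$n_prognostic == 0) {
      integer(0)
    } else if (!is.null(cfg$prognostic_abundance) || is.null(cfg$prognostic_quantile)) {
      sort(sample.int(cfg$p_genes, cfg$n_prognostic))
    } else {
      target_rank <- max(1, round(cfg$prognostic_quantile * cfg$p_genes))
      ranks <- order(raw)
      lo <- max(1, target_rank - floor((cfg$n_prognostic - 1) / 2))
      lo <- min(lo, cfg$p_genes - cfg$n_prognostic + 1)
      sort(ranks[lo:(lo + cfg$n_prognostic - 1)])
    }
    if (!is.null(cfg$prognostic_abundance) && length(prog) > 0) {
      v <- cfg$prognostic_abundance
      if (v <= 0 || v * cfg$n_prognostic >= 1) stopf("prognostic_abundance infeasible")
      other_sum <- sum(raw[-prog])
      raw[prog] <- v / (1 - cfg$n_prognostic * v) * other_sum
    }
    list(rel = raw / sum(raw), prognostic = prog)
  })
}

#' Simulate a read-count matrix
#'
#' Library sizes are drawn log-normally around `median_depth`, gene relative
#' abundances log-normally (heavy right tail), and counts gamma-Poisson
#' (negative binomial) given the product. Gamma-Poisson counts stay
#' gamma-Poisson under binomial thinning, which keeps the depth-degradation
#' experiment internally consistent.
#'
#' @param config a [simulation_config()].
#' @return genes x patients count matrix.
#' @export
simulate_expression_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ab <- .sim_abundance(config)
  with_seed(.sim_seed(config, "counts"), {
    lib <- exp(stats::rnorm(config$n_patients, log(config$median_depth),
                            config$depth_log_sd))
    mu <- outer(ab$rel, lib)
    counts <- if (config$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    counts <- matrix(as.double(counts), nrow = config$p_genes)
    count_matrix(counts,
                 gene_ids = sprintf("g%04d", seq_len(config$p_genes)),
                 patient_ids = sprintf("p%04d", seq_len(config$n_patients)))
  })
}

#' Simulate clinical covariates
#'
#' Age is normal around 60 years (sd 10); gender, grade, T, N, M are
#' categorical with fixed realistic level frequencies. When
#' `config$sex_specific` is TRUE the gender column is omitted.
#'
#' @param config a [simulation_config()].
#' @return data.frame with `patient_id` plus the covariate columns.
#' @export
simulate_clinical <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_patients
  with_seed(.sim_seed(config, "clinical"), {
    out <- data.frame(
      patient_id = sprintf("p%04d", seq_len(n)),
      age = round(stats::rnorm(n, 60, 10), 1),
      gender = factor(sample(c("female", "male"), n, replace = TRUE)),
      grade = factor(sample(paste0("G", 1:4), n, replace = TRUE,
                            prob = c(0.15, 0.35, 0.35, 0.15))),
      T = factor(sample(paste0("T", 1:4), n, replace = TRUE,
                        prob = c(0.3, 0.35, 0.25, 0.1))),
      N = factor(sample(paste0("N", 0:2), n, replace = TRUE,
                        prob = c(0.6, 0.25, 0.15))),
      M = factor(sample(paste0("M", 0:1), n, replace = TRUE,
                        prob = c(0.85, 0.15))),
      stringsAsFactors = FALSE
    )
    if (config$sex_specific) out$gender <- NULL
    out
  })
}

# Numeric encoding of clinical covariates used by the generative hazard.
.clinical_predictor <- function(clinical, effects) {
  if (is.null(effects) || length(effects) == 0) return(rep(0, nrow(clinical)))
  eta <- rep(0, nrow(clinical))
  for (nm in names(effects)) {
    v <- switch(nm,
      age = clinical$age - 60,
      gender = if (is.null(clinical$gender)) NULL else as.numeric(clinical$gender == "male"),
      grade = as.integer(clinical$grade) - 1,
      T = as.integer(clinical$T) - 1,
      N = as.integer(clinical$N),
      M = as.integer(clinical$M) - 1,
      stopf("unknown clinical effect '%s'", nm))
    if (!is.null(v)) eta <- eta + effects[[nm]] * v
  }
  eta
}

#' Simulate proportional-hazards survival from expression
#'
#' Event times follow a Weibull proportional-hazards model whose linear
#' predictor is `beta' X` over the prognostic genes of standardized
#' log-expression `X`, optionally mixed with thresholded interaction terms
#' (`nonlinear_fraction`). Censoring is exponential with the rate calibrated
#' by bisection so the expected censoring fraction matches
#' `target_censoring`.
#'
#' @param expression standardized log-expression matrix (genes x patients);
#'   typically from [simulate_cohort()]'s internal normalization.
#' @param config a [simulation_config()].
#' @param clinical optional clinical table contributing
#'   `config$clinical_effects` to the linear predictor.
#' @return survival data.frame (`patient_id`, `time`, `status`) with
#'   attributes `true_beta` (length `p_genes`) and `true_linear_predictor`.
#' @export
simulate_survival <- function(expression, config, clinical = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  ab <- .sim_abundance(config)
  p <- config$p_genes
  n <- ncol(expression)
  beta <- numeric(p)
  names(beta) <- rownames(expression)
  if (length(ab$prognostic) > 0) {
    beta[ab$prognostic] <- config$effect_size * rep_len(c(1, -1), length(ab$prognostic))
  }
  eta_lin <- drop(crossprod(expression, beta))
  eta_nl <- 0
  nf <- config$nonlinear_fraction
  if (nf > 0 && length(ab$prognostic) >= 2) {
    prog <- ab$prognostic
    pairs <- cbind(prog, prog[c(2:length(prog), 1)])
    z <- rowSums(apply(pairs, 1, function(pr) {
      (expression[pr[1], ] > 0) * expression[pr[2], ]
    }))
    z <- z / max(stats::sd(z), 1e-12)
    eta_nl <- config$effect_size * sqrt(length(ab$prognostic)) * z
  }
  eta <- (1 - nf) * eta_lin + nf * eta_nl
  if (!is.null(clinical)) {
    eta <- eta + .clinical_predictor(clinical, config$clinical_effects)
  }
  with_seed(.sim_seed(config, "survival"), {
    u <- stats::runif(n)
    tev <- config$baseline_scale * (-log(u) / exp(eta))^(1 / config$baseline_shape)
    if (config$target_censoring == 0) {
      time <- tev
      status <- rep(1, n)
    } else {
      rate <- .calibrate_censoring(tev, config$target_censoring)
      cens <- stats::rexp(n, rate)
      time <- pmin(tev, cens)
      status <- as.numeric(tev <= cens)
    }
    out <- data.frame(patient_id = colnames(expression) %||% sprintf("p%04d", seq_len(n)),
                      time = time, status = status, stringsAsFactors = FALSE)
    attr(out, "true_beta") <- beta
    attr(out, "true_linear_predictor") <- eta
    out
  })
}

# Bisection on the exponential censoring rate c: with C ~ Exp(c) independent
# of T, E[censored fraction] = mean(1 - exp(-c * T_i)) over the simulated
# event times; monotone increasing in c, so the target is always reachable
# for target < 1.
.calibrate_censoring <- function(event_times, target, tol = 1e-6) {
  f <- function(rate) mean(1 - exp(-rate * event_times))
  lo <- 1e-12
  hi <- 1 / max(stats::median(event_times), 1e-12)
  it <- 0
  while (f(hi) < target) {
    hi <- hi * 2
    it <- it + 1
    if (it > 200) stopf("censoring calibration failed: reachable bound %.3f < target %.3f",
                        f(hi), target)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if (abs(f(mid) - target) < tol) break
  }
  (lo + hi) / 2
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates counts, normalization (TMM + log2-CPM + per-gene
#' standardization), clinical covariates and survival into one object, so
#' the whole benchmark pipeline can run without any external data.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_cohort` list: `counts`, `survival`, `clinical`,
#'   `true_beta` (exactly `n_prognostic` nonzero entries),
#'   `true_linear_predictor`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  counts <- simulate_expression_counts(config)
  factors <- tmm_factors(counts)
  expr <- log_cpm(counts, factors)
  m <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  s[s < 1e-12] <- 1
  std <- (expr - m) / s
  clinical <- simulate_clinical(config)
  survival <- simulate_survival(std, config, clinical = clinical)
  structure(list(counts = counts, survival = survival, clinical = clinical,
                 true_beta = attr(survival, "true_beta"),
                 true_linear_predictor = attr(survival, "true_linear_predictor"),
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Writes `counts.tsv` (and `counts.mtx` + sidecars), `survival.tsv`,
#' `clinical.tsv`, and the ground truth `true_beta.tsv`
#' (`gene_id`, `beta`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @param mtx also write the MatrixMarket encoding (default TRUE).
#' @export
write_cohort <- function(cohort, dir, mtx = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(cohort$counts, file.path(dir, "counts.tsv"), "tsv")
  if (mtx) write_count_matrix(cohort$counts, file.path(dir, "counts.mtx"), "mtx")
  write_survival_table(cohort$survival, file.path(dir, "survival.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(
    data.frame(gene_id = names(cohort$true_beta), beta = cohort$true_beta),
    file.path(dir, "true_beta.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d genes x %d patients\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  median library size: %.3g reads\n", stats::median(colSums(x$counts))))
  cat(sprintf("  events: %d / %d (censoring %.2f)\n", sum(x$survival$status),
              nrow(x$survival), mean(1 - x$survival$status)))
  cat(sprintf("  prognostic genes: %d\n", sum(x$true_beta != 0)))
  invisible(x)
}
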