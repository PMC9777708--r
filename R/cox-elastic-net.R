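# Penalized Cox proportional-hazards estimation. Path fitting and the
# internal lambda cross-validation are delegated to glmnet (coordinate
# descent with warm starts); the Breslow partial likelihood, baseline
# cumulative hazard, risk scores and survival-curve prediction are
# implemented here so the model contract is self-contained.

.surv_y <- function(outcome) {
  outcome <- as_survival(outcome)
  if (sum(outcome$status) < 1) stopf("at least one event is required")
  survival::Surv(outcome$time, outcome$status)
}

#' Breslow partial log-likelihood
#'
#' Log partial likelihood of a Cox model with Breslow handling of tied
#' event times: tied events share the same risk-set denominator.
#'
#' @param beta coefficient vector over genes.
#' @param expr covariate matrix (genes x patients).
#' @param outcome survival data.frame (`time`, `status`) aligned to the
#'   patients of `expr`.
#' @return the log partial likelihood (a scalar).
#' @export
partial_log_likelihood <- function(beta, expr, outcome) {
  outcome <- as_survival(data.frame(patient_id = colnames(expr) %||% seq_len(ncol(expr)),
                                    time = outcome$time, status = outcome$status))
  if (sum(outcome$status) == 0) stopf("partial likelihood undefined without events")
  eta <- drop(crossprod(expr, beta))
  ll <- 0
  for (t in sort(unique(outcome$time[outcome$status == 1]))) {
    d <- outcome$status == 1 & outcome$time == t
    risk <- outcome$time >= t
    ll <- ll + sum(eta[d]) - sum(d) * log(sum(exp(eta[risk])))
  }
  ll
}

# Analytic gradient of the Breslow partial log-likelihood (used for KKT
# verification and the Newton oracle in the tests).
pll_gradient <- function(beta, expr, outcome) {
  eta <- drop(crossprod(expr, beta))
  g <- numeric(length(beta))
  for (t in sort(unique(outcome$time[outcome$status == 1]))) {
    d <- outcome$status == 1 & outcome$time == t
    risk <- outcome$time >= t
    w <- exp(eta[risk])
    xbar <- drop(expr[, risk, drop = FALSE] %*% w) / sum(w)
    g <- g + rowSums(expr[, d, drop = FALSE]) - sum(d) * xbar
  }
  g
}

#' Fit the elastic-net Cox path
#'
#' Coordinate-wise optimization of the penalized Breslow partial likelihood
#' (via [glmnet::glmnet()], the canonical implementation) along a decreasing
#' lambda path of `nlambda` values from `lambda_max` (smallest lambda giving
#' an all-zero fit) down to `lambda_min_ratio * lambda_max` on the log
#' scale. Inputs are expected standardized (see
#' [standardize_train_test()]); no standardization happens inside the
#' fitter and the penalty weighs all genes equally.
#'
#' @param expr standardized expression matrix (genes x patients).
#' @param outcome survival data.frame aligned to the patients.
#' @param alpha elastic-net mixing in `[0, 1]` (default 0.3).
#' @param lambda optional explicit lambda path (decreasing).
#' @param nlambda,lambda_min_ratio path geometry (defaults 100 and 0.01).
#' @param thresh,maxit coordinate-descent convergence tolerance and sweep
#'   cap (defaults 1e-7 and 1e5).
#' @param penalty_factor optional per-feature penalty multipliers (0 leaves
#'   a feature unpenalized).
#' @return a `coxnet_path` object wrapping the glmnet fit.
#' @export
fit_cox_elastic_net <- function(expr, outcome, alpha = 0.3, lambda = NULL,
                                nlambda = 100, lambda_min_ratio = 0.01,
                                thresh = 1e-7, maxit = 1e5,
                                penalty_factor = NULL) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  y <- .surv_y(outcome)
  x <- t(expr)
  args <- list(x = x, y = y, family = "cox", alpha = alpha,
               standardize = FALSE, thresh = thresh, maxit = maxit)
  if (!is.null(lambda)) args$lambda <- lambda
  else { args$nlambda <- nlambda; args$lambda.min.ratio <- lambda_min_ratio }
  if (!is.null(penalty_factor)) args$penalty.factor <- penalty_factor
  fit <- do.call(glmnet::glmnet, args)
  structure(list(glmnet = fit, alpha = alpha, feature_ids = rownames(expr),
                 thresh = thresh, maxit = maxit,
                 penalty_factor = penalty_factor),
            class = "coxnet_path")
}

#' Select lambda by internal cross-validation
#'
#' K-fold cross-validation of the partial-likelihood deviance along the
#' fitted path; returns the deviance-minimizing lambda ("lambda-min" rule)
#' or the one-standard-error lambda. Folds are seeded and redrawn (up to 20
#' times) if any fold would leave the training complement with fewer than 2
#' events.
#'
#' @param path a `coxnet_path` from [fit_cox_elastic_net()].
#' @param expr,outcome the training data the path was fitted on.
#' @param folds number of internal folds (default 5).
#' @param seed fold-assignment seed.
#' @param rule `"min"` or `"1se"`.
#' @return the selected lambda (scalar) with the `cv.glmnet` object in the
#'   `"cv"` attribute.
#' @export
select_lambda_cv <- function(path, expr, outcome, folds = 5, seed = 1,
                             rule = c("min", "1se")) {
  rule <- match.arg(rule)
  stopifnot(inherits(path, "coxnet_path"))
  y <- .surv_y(outcome)
  n <- ncol(expr)
  status <- as_survival(data.frame(patient_id = seq_len(n), time = outcome$time,
                                   status = outcome$status))$status
  foldid <- NULL
  for (attempt in seq_len(20)) {
    cand <- with_seed(derive_seed(seed, attempt),
                      sample(rep_len(seq_len(folds), n)))
    ok <- all(vapply(seq_len(folds), function(k) {
      sum(status[cand != k]) >= 2 && sum(status[cand == k]) >= 1
    }, logical(1)))
    if (ok) { foldid <- cand; break }
  }
  if (is.null(foldid)) stopf("could not draw CV folds with enough events")
  args <- list(x = t(expr), y = y, family = "cox", alpha = path$alpha,
               standardize = FALSE, foldid = foldid,
               lambda = path$glmnet$lambda, thresh = path$thresh,
               maxit = path$maxit)
  if (!is.null(path$penalty_factor)) args$penalty.factor <- path$penalty_factor
  cv <- do.call(glmnet::cv.glmnet, args)
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  structure(lam, cv = cv)
}

#' Fit a cross-validated elastic-net Cox model
#'
#' One-shot wrapper: fits the lambda path, selects lambda by internal CV,
#' extracts the coefficients and attaches the Breslow baseline cumulative
#' hazard, yielding a model that can produce risk scores and survival
#' curves.
#'
#' @inheritParams fit_cox_elastic_net
#' @inheritParams select_lambda_cv
#' @param cv_folds internal CV folds for lambda (default 5).
#' @return a `coxnet_model`: `beta` (named), `alpha`, `lambda`, `baseline`
#'   (Breslow step function), `feature_ids`.
#' @export
fit_cox <- function(expr, outcome, alpha = 0.3, cv_folds = 5, seed = 1,
                    rule = "min", lambda = NULL, penalty_factor = NULL, ...) {
  path <- fit_cox_elastic_net(expr, outcome, alpha = alpha, lambda = lambda,
                              penalty_factor = penalty_factor, ...)
  lam <- select_lambda_cv(path, expr, outcome, folds = cv_folds, seed = seed,
                          rule = rule)
  beta <- drop(as.matrix(stats::coef(path$glmnet, s = as.numeric(lam))))
  names(beta) <- rownames(expr)
  new_coxnet_model(beta, expr, outcome, alpha = alpha, lambda = as.numeric(lam))
}

new_coxnet_model <- function(beta, expr, outcome, alpha = NA_real_,
                             lambda = NA_real_) {
  baseline <- breslow_baseline(beta, expr, outcome)
  structure(list(beta = beta, alpha = alpha, lambda = lambda,
                 baseline = baseline, feature_ids = names(beta)),
            class = "coxnet_model")
}

#' Breslow baseline cumulative hazard
#'
#' `H0(t) = sum over event times tj <= t of d_j / sum_{k at risk} exp(beta'
#' X_k)`; reduces to the Nelson-Aalen estimator at `beta = 0`.
#'
#' @param model a `coxnet_model`, or a bare coefficient vector.
#' @param expr training covariates (genes x patients).
#' @param outcome training survival.
#' @return a `breslow_chf` step function: list with sorted `time` (distinct
#'   event times) and non-decreasing `chf`.
#' @export
breslow_baseline <- function(model, expr, outcome) {
  beta <- if (inherits(model, "coxnet_model")) model$beta else model
  outcome <- as_survival(data.frame(patient_id = seq_len(ncol(expr)),
                                    time = outcome$time, status = outcome$status))
  eta <- drop(crossprod(expr, beta))
  times <- sort(unique(outcome$time[outcome$status == 1]))
  inc <- vapply(times, function(t) {
    sum(outcome$status == 1 & outcome$time == t) /
      sum(exp(eta[outcome$time >= t]))
  }, numeric(1))
  structure(list(time = times, chf = cumsum(inc)), class = "breslow_chf")
}

# Right-continuous step evaluation of a cumulative hazard; 0 before the
# first event time.
eval_chf <- function(baseline, t) {
  idx <- findInterval(t, baseline$time)
  c(0, baseline$chf)[idx + 1]
}

#' Cox risk scores
#'
#' The linear predictor `beta' X_i` per patient; features are aligned to
#' the model's feature ids and missing features raise an error naming them.
#'
#' @param model a `coxnet_model`.
#' @param expr expression matrix (genes x patients) on the model's scale.
#' @return named numeric vector of risk scores.
#' @export
cox_risk_score <- function(model, expr) {
  stopifnot(inherits(model, "coxnet_model"))
  missing <- setdiff(model$feature_ids, rownames(expr))
  if (length(missing) > 0) {
    stopf("features missing from expression matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  drop(crossprod(expr[model$feature_ids, , drop = FALSE], model$beta))
}

#' Predicted survival curves
#'
#' `S(t | X) = exp(-H0(t) * exp(beta' X))` with the Breslow baseline (for
#' Cox models) or `S = exp(-CHF)` from the ensemble cumulative hazard (for
#' survival forests). Times beyond the training horizon are extrapolated
#' flat and flagged via the `"extrapolated"` attribute.
#'
#' @param model a `coxnet_model` or `rsf_model`.
#' @param expr expression matrix (genes x patients).
#' @param times evaluation times.
#' @return patients x times matrix of survival probabilities in `(0, 1]`,
#'   non-increasing along each row.
#' @export
predict_survival <- function(model, expr, times) UseMethod("predict_survival")

#' @export
predict_survival.coxnet_model <- function(model, expr, times) {
  rs <- cox_risk_score(model, expr)
  h0 <- eval_chf(model$baseline, times)
  out <- exp(-outer(exp(rs), h0))
  dimnames(out) <- list(colnames(expr), NULL)
  attr(out, "extrapolated") <- any(times > max(model$baseline$time))
  out
}

#' Likelihood-ratio p-value of a single-covariate Cox model
#'
#' One Cox model per gene (Breslow ties); the chi-squared(1)
#' likelihood-ratio p-value measures the gene's association with survival.
#' Constant covariates get p = 1 with a warning.
#'
#' @param x numeric vector over patients, or a genes x patients matrix (one
#'   test per row).
#' @param outcome survival data.frame aligned to the patients.
#' @return p-value(s), named by gene for matrix input.
#' @export
univariate_cox_pvalue <- function(x, outcome) {
  outcome <- as_survival(data.frame(patient_id = seq_len(if (is.matrix(x)) ncol(x) else length(x)),
                                    time = outcome$time, status = outcome$status))
  y <- .surv_y(outcome)
  ctrl <- survival::coxph.control()
  one <- function(v) {
    if (!all(is.finite(v))) stopf("covariate contains non-finite values")
    if (stats::sd(v) < 1e-12) {
      warnf("constant covariate: p-value set to 1")
      return(1)
    }
    fit <- tryCatch(
      survival::coxph.fit(matrix(v, ncol = 1), y, strata = NULL,
                          offset = NULL, init = NULL, control = ctrl,
                          weights = NULL, method = "breslow", rownames = NULL),
      error = function(e) NULL)
    if (is.null(fit)) return(1)
    stat <- 2 * (fit$loglik[2] - fit$loglik[1])
    stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }
  if (is.matrix(x)) {
    p <- apply(x, 1, one)
    names(p) <- rownames(x)
    p
  } else {
    one(x)
  }
}

#' Serialize a fitted model to JSON
#'
#' Cox models store feature ids, coefficients, alpha, lambda and the
#' baseline step function as (time, value) pairs; forests store the node
#' structure and leaf step functions.
#'
#' @param model a `coxnet_model` or `rsf_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  payload <- if (inherits(model, "coxnet_model")) {
    list(kind = "cox_elastic_net", feature_ids = model$feature_ids,
         beta = unname(model$beta), alpha = model$alpha, lambda = model$lambda,
         baseline = list(time = model$baseline$time, chf = model$baseline$chf))
  } else if (inherits(model, "rsf_model")) {
    list(kind = "survival_forest", feature_ids = model$feature_ids,
         mtry = model$mtry, min_node = model$min_node,
         time_grid = model$time_grid, trees = model$trees,
         bootstrap = model$bootstrap)
  } else {
    stopf("unsupported model class")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
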