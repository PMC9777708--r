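# Independent oracles and small fixtures used across the test files.

toy_outcome <- function(time, status = rep(1, length(time)),
                        ids = sprintf("p%03d", seq_along(time))) {
  data.frame(patient_id = ids, time = time, status = status,
             stringsAsFactors = FALSE)
}

# Exhaustive pair enumeration of the concordance index, following the
# documented conventions: a pair is comparable when the earlier time is an
# event or both fail at the same time; risk ties and tied-time event pairs
# score 1/2.
cindex_enum <- function(risk, time, status) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      comparable <-
        (time[i] < time[k] && status[i] == 1) ||
        (time[k] < time[i] && status[k] == 1) ||
        (time[i] == time[k] && status[i] == 1 && status[k] == 1)
      if (!comparable) next
      den <- den + 1
      if (risk[i] == risk[k] || time[i] == time[k]) {
        num <- num + 0.5
      } else {
        earlier_higher <- (time[i] < time[k]) == (risk[i] > risk[k])
        num <- num + as.numeric(earlier_higher)
      }
    }
  }
  if (den == 0) stop("no comparable pairs in oracle")
  num / den
}

# Newton-Raphson maximizer of the Breslow partial likelihood with
# finite-difference derivatives; self-contained so it shares no code with
# the package.
newton_cox_oracle <- function(X, time, status, tol = 1e-10, maxit = 100) {
  pll <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- 0
    for (t in sort(unique(time[status == 1]))) {
      d <- which(status == 1 & time == t)
      ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[time >= t])))
    }
    ll
  }
  p <- ncol(X)
  h <- 1e-5
  grad <- function(beta) {
    vapply(seq_len(p), function(j) {
      e <- replace(numeric(p), j, h)
      (pll(beta + e) - pll(beta - e)) / (2 * h)
    }, numeric(1))
  }
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    g <- grad(beta)
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      e <- replace(numeric(p), j, h)
      H[, j] <- (grad(beta + e) - grad(beta - e)) / (2 * h)
    }
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Exact one-sided signed-rank p-value by enumeration over all sign
# patterns (no ties in |d| assumed; n must be small).
signed_rank_enum <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 15, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 2^n
  count <- 0
  for (mask in 0:(total - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    v <- sum(r[signs])
    hit <- switch(alternative,
                  greater = v >= v_obs,
                  less = v <= v_obs,
                  stop("unsupported"))
    if (hit) count <- count + 1
  }
  count / total
}

# A small fast cohort for pipeline-level tests.
quick_cohort <- function(seed = 1, n = 100, p = 30, effect = 0.8,
                         n_prognostic = 4, censoring = 0.5, ...) {
  simulate_cohort(simulation_config(
    n_patients = n, p_genes = p, median_depth = 1e6, depth_log_sd = 0.2,
    abundance_log_sd = 1.5, dispersion = 0.15, n_prognostic = n_prognostic,
    effect_size = effect, target_censoring = censoring, seed = seed, ...))
}
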