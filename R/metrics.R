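# Censoring-aware evaluation: concordance index with explicit tie
# conventions, Kaplan-Meier estimate of the censoring distribution, and the
# IPCW (inverse probability of censoring weighted) Brier score integrated
# to the last test event time.

#' Concordance index for censored survival
#'
#' Estimates `C = P(T_i < T_k | RS_i > RS_k)` over comparable patient
#' pairs. A pair is comparable when the earlier of the two times is an
#' observed event (so the ordering of failure is known), or when both
#' patients fail at the same time. Tie conventions: tied risk scores score
#' 1/2; tied event times with both events are counted as comparable and
#' score 1/2 (the pair carries no ordering information); a tied time
#' between an event and a censoring is not comparable.
#'
#' @param risk numeric risk scores (higher = shorter expected survival).
#' @param outcome survival data.frame aligned to `risk`.
#' @return concordance in `[0, 1]`; errors when no pair is comparable.
#' @export
concordance_index <- function(risk, outcome) {
  outcome <- as_survival(data.frame(patient_id = seq_along(risk),
                                    time = outcome$time, status = outcome$status))
  if (length(risk) != nrow(outcome)) stopf("risk and outcome lengths differ")
  n <- length(risk)
  i <- rep(seq_len(n), times = n)
  k <- rep(seq_len(n), each = n)
  keep <- i < k
  i <- i[keep]; k <- k[keep]
  ti <- outcome$time[i]; tk <- outcome$time[k]
  di <- outcome$status[i]; dk <- outcome$status[k]
  ri <- risk[i]; rk <- risk[k]
  comparable <- (ti < tk & di == 1) | (tk < ti & dk == 1) |
    (ti == tk & di == 1 & dk == 1)
  if (!any(comparable)) stopf("no comparable pairs")
  ti <- ti[comparable]; tk <- tk[comparable]
  ri <- ri[comparable]; rk <- rk[comparable]
  score <- ifelse(ri == rk, 0.5,
           ifelse(ti == tk, 0.5,
           ifelse((ti < tk) == (ri > rk), 1, 0)))
  sum(score) / sum(comparable)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' KM estimator with the status flipped (censorings become the events),
#' used for the inverse-probability-of-censoring weights of the Brier
#' score. Provides right-continuous evaluation `G(t)` and the left limit
#' `G(t-)`.
#'
#' @param outcome survival data.frame.
#' @return a `censor_km` object (step function).
#' @export
censoring_km <- function(outcome) {
  outcome <- as_survival(data.frame(patient_id = seq_len(nrow(outcome)),
                                    time = outcome$time, status = outcome$status))
  fit <- survival::survfit(survival::Surv(outcome$time, 1 - outcome$status) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "censor_km")
}

#' Evaluate a censoring KM step function
#'
#' @param G a `censor_km` from [censoring_km()].
#' @param t evaluation times.
#' @param left if TRUE return the left limit `G(t-)`.
#' @return survival probabilities of the censoring distribution.
#' @export
eval_censoring <- function(G, t, left = FALSE) {
  idx <- findInterval(t, G$time, left.open = left)
  c(1, G$surv)[idx + 1]
}

#' IPCW Brier score at a single time
#'
#' Mean over patients of the inverse-probability-of-censoring weighted
#' squared error between the predicted survival probability at `t` and the
#' realized survival status:
#' `S_hat(t)^2 * 1(T <= t, event) / G(T-) + (1 - S_hat(t))^2 * 1(T > t) / G(t)`.
#' Patients censored before `t` contribute 0; patients whose weight would
#' divide by `G = 0` are excluded and counted in the `"n_excluded"`
#' attribute.
#'
#' @param pred predicted survival probabilities at time `t` (one per
#'   patient, in `[0, 1]`).
#' @param t evaluation time.
#' @param outcome test survival data.frame.
#' @param G censoring distribution (default: estimated from `outcome`).
#' @return the Brier score (scalar).
#' @export
brier_score <- function(pred, t, outcome, G = NULL) {
  outcome <- as_survival(data.frame(patient_id = seq_along(pred),
                                    time = outcome$time, status = outcome$status))
  if (any(pred < 0 | pred > 1)) stopf("predictions must lie in [0, 1]")
  G <- G %||% censoring_km(outcome)
  died <- outcome$time <= t & outcome$status == 1
  alive <- outcome$time > t
  w_died <- eval_censoring(G, outcome$time, left = TRUE)
  w_alive <- eval_censoring(G, t)
  need_w <- (died & w_died <= 0) | (alive & w_alive <= 0)
  term <- pred^2 * died / ifelse(w_died > 0, w_died, Inf) +
    (1 - pred)^2 * alive / ifelse(w_alive > 0, w_alive, Inf)
  term <- term[!need_w]
  structure(mean(term), n_excluded = sum(need_w))
}

#' Integrated Brier score (IBS)
#'
#' Trapezoidal integral of the IPCW Brier score from 0 to the maximum event
#' time of the test set, divided by that maximum integration time.
#'
#' @param curves patients x times matrix of predicted survival
#'   probabilities, columns matching `times`.
#' @param times the evaluation grid (must span `[0, max test event time]`).
#' @param outcome test survival data.frame.
#' @param G censoring distribution (default: estimated from `outcome`).
#' @return the IBS (scalar).
#' @export
integrated_brier_score <- function(curves, times, outcome, G = NULL) {
  outcome <- as_survival(data.frame(patient_id = seq_len(nrow(curves)),
                                    time = outcome$time, status = outcome$status))
  if (sum(outcome$status) == 0) stopf("no events in the test set; IBS undefined")
  tau <- max(outcome$time[outcome$status == 1])
  if (min(times) > 0 || max(times) < tau) {
    stopf("evaluation grid must cover [0, %g]", tau)
  }
  G <- G %||% censoring_km(outcome)
  ord <- order(times)
  times <- times[ord]
  curves <- curves[, ord, drop = FALSE]
  keep <- times <= tau
  times <- times[keep]
  curves <- curves[, keep, drop = FALSE]
  bs <- vapply(seq_along(times), function(j) {
    as.numeric(brier_score(curves[, j], times[j], outcome, G))
  }, numeric(1))
  sum(diff(times) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / tau
}
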