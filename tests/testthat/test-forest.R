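make_signal_data <- function(seed = 1, n = 150, p = 20, effect = 1.2,
                             censor_rate = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), nrow = p,
              dimnames = list(sprintf("g%02d", seq_len(p)),
                              sprintf("p%03d", seq_len(n))))
  eta <- effect * X[1, ]
  tt <- rexp(n, exp(eta))
  cens <- rexp(n, censor_rate)
  list(X = X, outcome = toy_outcome(pmin(tt, cens), as.numeric(tt <= cens),
                                    ids = colnames(X)))
}

test_that("log-rank statistic matches the hand-computed 6-patient table", {
  out <- toy_outcome(1:6)
  group <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  # O_A = 3, E_A = 0.5 + 0.6 + 0.75 + 1 + 1 + 1 = 4.85,
  # V = 0.25 + 0.24 + 0.1875 = 0.6775 -> z = -1.85 / sqrt(0.6775)
  expect_equal(logrank_statistic(group, out), -1.85 / sqrt(0.6775),
               tolerance = 1e-12)
  # cross-check against survdiff's chi-squared
  sd <- survival::survdiff(survival::Surv(out$time, out$status) ~ group)
  expect_equal(logrank_statistic(group, out)^2, unname(sd$chisq),
               tolerance = 1e-10)
})

test_that("log-rank statistic is null-symmetric and rank-based", {
  set.seed(4)
  out <- toy_outcome(rexp(40), rbinom(40, 1, 0.8))
  stats <- vapply(1:200, function(i) {
    logrank_statistic(sample(rep(c(TRUE, FALSE), 20)), out)
  }, numeric(1))
  expect_lt(abs(mean(stats)), 0.15)
  # invariant under monotone relabeling of the times
  group <- rep(c(TRUE, FALSE), 20)
  out2 <- out
  out2$time <- exp(out$time)
  expect_equal(logrank_statistic(group, out),
               logrank_statistic(group, out2))
})

test_that("best_split matches brute-force enumeration over all (feature, threshold)", {
  brute_force <- function(X, out, min_node) {
    best <- NULL
    for (f in seq_len(nrow(X))) {
      v <- X[f, ]
      for (thr in (head(sort(unique(v)), -1) + diff(sort(unique(v))) / 2)) {
        g <- v > thr
        if (sum(g) < min_node || sum(!g) < min_node) next
        z <- logrank_statistic(g, out)
        if (abs(z) > 0 && (is.null(best) || abs(z) > abs(best$statistic) + 1e-12)) {
          best <- list(feature_index = f, threshold = thr, statistic = z)
        }
      }
    }
    best
  }
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    X <- matrix(rnorm(5 * n), nrow = 5,
                dimnames = list(paste0("g", 1:5), sprintf("p%02d", 1:n)))
    out <- toy_outcome(rexp(n, exp(X[1, ])), rbinom(n, 1, 0.8))
    got <- best_split(X, out, min_node = 3)
    want <- brute_force(X, out, 3)
    expect_equal(got$feature_index, want$feature_index)
    expect_equal(got$threshold, want$threshold)
    expect_equal(abs(got$statistic), abs(want$statistic), tolerance = 1e-10)
  }
})

test_that("best_split returns NULL for constant features and breaks ties low", {
  out <- toy_outcome(1:10)
  Xc <- matrix(1, 2, 10, dimnames = list(c("g1", "g2"), sprintf("p%02d", 1:10)))
  expect_null(best_split(Xc, out))
  # duplicated informative rows: the lower feature index wins
  set.seed(2)
  v <- rnorm(10)
  Xd <- rbind(g1 = v, g2 = v, g3 = rnorm(10))
  colnames(Xd) <- sprintf("p%02d", 1:10)
  out2 <- toy_outcome(rexp(10, exp(2 * v)))
  got <- best_split(Xd, out2, min_node = 2)
  expect_equal(got$feature_index, 1)
})

test_that("a min_node above n produces single-leaf trees holding the bootstrap Nelson-Aalen", {
  dat <- make_signal_data(3, n = 25, p = 4)
  f <- fit_forest(dat$X, dat$outcome, n_trees = 3, min_node = 50, seed = 11)
  for (b in seq_along(f$trees)) {
    expect_length(f$trees[[b]]$nodes, 1)
    idx <- f$bootstrap[[b]]
    km <- survival::survfit(
      survival::Surv(dat$outcome$time[idx], dat$outcome$status[idx]) ~ 1,
      stype = 2, ctype = 1)
    oracle <- stats::stepfun(km$time, c(0, km$cumhaz))(f$time_grid)
    expect_equal(f$trees[[b]]$nodes[[1]]$chf, oracle, tolerance = 1e-10)
  }
  # single-leaf forest: every patient receives the same CHF and risk score
  chf <- ensemble_chf(f, dat$X)
  expect_equal(chf[1, ], chf[10, ])
  rs <- forest_risk_score(f, dat$X)
  expect_equal(unname(rs), rep(unname(rs[1]), length(rs)))
})

test_that("hand-built two-leaf tree averages to the documented risk scores", {
  grid <- c(1, 2, 3)
  tree <- list(nodes = list(
    list(feature = 1L, threshold = 0, left = 2L, right = 3L),
    list(feature = NA_integer_, chf = c(0.1, 0.2, 0.3), n = 3L),
    list(feature = NA_integer_, chf = c(0.2, 0.4, 0.6), n = 3L)
  ), root = 1L)
  model <- structure(list(trees = list(tree), bootstrap = list(1:2),
                          time_grid = grid, mtry = 1L, min_node = 3L,
                          feature_ids = "g1", seed = 1L),
                     class = "rsf_model")
  X <- matrix(c(-1, 1), 1, dimnames = list("g1", c("low", "high")))
  expect_equal(unname(forest_risk_score(model, X)), c(0.2, 0.4))
  chf <- ensemble_chf(model, X)
  expect_equal(unname(chf["low", ]), c(0.1, 0.2, 0.3))
  # survival curves from the CHF stay in (0, 1] and are non-increasing
  s <- predict_survival(model, X, times = c(0.5, 1.5, 2.5, 3.5))
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(apply(s, 1, diff) <= 1e-12))
})

test_that("forests are deterministic given the seed and detect planted signal OOB", {
  dat <- make_signal_data(5)
  f1 <- fit_forest(dat$X, dat$outcome, n_trees = 5, seed = 7)
  f2 <- fit_forest(dat$X, dat$outcome, n_trees = 5, seed = 7)
  expect_identical(f1, f2)
  f <- fit_forest(dat$X, dat$outcome, n_trees = 50, seed = 1)
  expect_gt(1 - oob_error(f, dat$X, dat$outcome), 0.6)
  expect_error(fit_forest(dat$X, toy_outcome(1:150, rep(0, 150))), "censored")
})

test_that("more trees do not hurt OOB concordance beyond noise", {
  diffs <- vapply(1:5, function(s) {
    dat <- make_signal_data(s + 20, n = 100, p = 10)
    f10 <- fit_forest(dat$X, dat$outcome, n_trees = 10, seed = s)
    f50 <- fit_forest(dat$X, dat$outcome, n_trees = 50, seed = s)
    oob_error(f10, dat$X, dat$outcome) - oob_error(f50, dat$X, dat$outcome)
  }, numeric(1))
  expect_gt(mean(diffs), -0.02)
})

test_that("mtry tuning is seeded, respects bounds, and does not overfit noise", {
  dat <- make_signal_data(9, n = 60, p = 10, effect = 0)
  m1 <- tune_mtry(dat$X, dat$outcome, n_trees = 20, seed = 3)
  m2 <- tune_mtry(dat$X, dat$outcome, n_trees = 20, seed = 3)
  expect_identical(as.integer(m1), as.integer(m2))
  # p = 1 forces mtry = 1
  one <- dat$X[1, , drop = FALSE]
  expect_equal(as.integer(tune_mtry(one, dat$outcome, n_trees = 10, seed = 1)), 1L)
  expect_warning(tune_mtry(dat$X[, 1:20], dat$outcome[1:20, ], n_trees = 5),
                 "fewer than 30")
  # pure-noise data: tuning cannot manufacture prognostic skill
  conc <- vapply(1:6, function(s) {
    d <- make_signal_data(400 + s, n = 60, p = 10, effect = 0)
    mt <- tune_mtry(d$X, d$outcome, n_trees = 20, seed = s)
    1 - min(attr(mt, "oob_errors"))
  }, numeric(1))
  expect_lt(mean(conc), 0.57)
})

test_that("forest agrees directionally with ranger on a planted signal", {
  skip_if_not_installed("ranger")
  dat <- make_signal_data(33, n = 150, p = 15)
  f <- fit_forest(dat$X, dat$outcome, n_trees = 50, seed = 2)
  ours <- 1 - oob_error(f, dat$X, dat$outcome)
  df <- data.frame(time = dat$outcome$time, status = dat$outcome$status,
                   t(dat$X))
  rf <- ranger::ranger(survival::Surv(time, status) ~ ., data = df,
                       num.trees = 50, min.node.size = 3,
                       splitrule = "logrank", seed = 2)
  theirs <- 1 - rf$prediction.error
  expect_gt(ours, 0.6)
  expect_gt(theirs, 0.6)
  expect_lt(abs(ours - theirs), 0.15)
})

test_that("Cox vs forest ordering shifts with nonlinearity of the signal", {
  gap <- vapply(c(linear = 0, nonlinear = 1), function(nf) {
    mean(vapply(1:4, function(s) {
      coh <- simulate_cohort(simulation_config(
        n_patients = 120, p_genes = 20, median_depth = 1e6, depth_log_sd = 0.2,
        n_prognostic = 6, effect_size = 1.2, nonlinear_fraction = nf,
        target_censoring = 0.3, seed = 600 + s))
      e <- standardize_train_test(log_cpm(coh$counts))$train
      tr <- 1:84
      te <- 85:120
      std <- standardize_train_test(e[, tr], e[, te])
      out_tr <- coh$survival[tr, ]
      out_te <- coh$survival[te, ]
      cm <- fit_cox(std$train, out_tr, seed = s)
      fm <- fit_forest(std$train, out_tr, n_trees = 30, seed = s)
      concordance_index(forest_risk_score(fm, std$test), out_te) -
        concordance_index(cox_risk_score(cm, std$test), out_te)
    }, numeric(1)))
  }, numeric(1))
  # the forest gains ground (relative to Cox) when the signal is nonlinear
  expect_gt(gap["nonlinear"], gap["linear"])
})
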