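# Random survival forest: bootstrap survival trees split by the two-sample
# log-rank statistic over exhaustive midpoint thresholds, Nelson-Aalen leaf
# cumulative hazards on a global event-time grid shared by all trees, and
# out-of-bag concordance for mtry tuning. Tie-breaks are deterministic
# (lowest feature index, then lowest threshold).

#' Two-sample log-rank statistic
#'
#' Standard log-rank z statistic (observed minus expected events in the
#' second group over the shared risk sets, normalized by the hypergeometric
#' variance). Returns 0 when the variance is zero (e.g., one group carries
#' no events within the shared risk sets).
#'
#' @param group logical vector (TRUE = group A) or a factor/vector with two
#'   levels (the second sorted level plays group A).
#' @param outcome survival data.frame aligned to `group`.
#' @return signed z statistic (squares to the usual chi-squared form).
#' @export
logrank_statistic <- function(group, outcome) {
  if (!is.logical(group)) {
    lv <- sort(unique(as.character(group)))
    if (length(lv) != 2) stopf("group must have exactly two levels")
    group <- as.character(group) == lv[2]
  }
  if (all(group) || !any(group)) stopf("both groups must be non-empty")
  outcome <- as_survival(data.frame(patient_id = seq_along(group),
                                    time = outcome$time, status = outcome$status))
  pre <- .node_precompute(outcome$time, outcome$status)
  if (pre$K == 0) return(0)
  nA <- vapply(pre$evt, function(t) sum(group & outcome$time >= t), numeric(1))
  dA <- vapply(pre$evt, function(t) {
    sum(group & outcome$status == 1 & outcome$time == t)
  }, numeric(1))
  .logrank_z(nA, dA, pre)
}

# Risk-set bookkeeping shared by all threshold scans within a node.
.node_precompute <- function(time, status) {
  evt <- sort(unique(time[status == 1]))
  K <- length(evt)
  if (K == 0) {
    return(list(evt = evt, K = 0L, n_k = numeric(0), d_k = numeric(0),
                r = integer(length(time)), e = integer(length(time))))
  }
  n_k <- vapply(evt, function(t) sum(time >= t), numeric(1))
  d_k <- vapply(evt, function(t) sum(status == 1 & time == t), numeric(1))
  r <- findInterval(time, evt)          # event times <= each patient's time
  e <- ifelse(status == 1, match(time, evt), NA_integer_)
  list(evt = evt, K = K, n_k = n_k, d_k = d_k, r = r, e = e)
}

.logrank_z <- function(nA, dA, pre) {
  O <- sum(dA)
  E <- sum(pre$d_k * nA / pre$n_k)
  keep <- pre$n_k > 1
  V <- sum((pre$d_k * (nA / pre$n_k) * (1 - nA / pre$n_k) *
              (pre$n_k - pre$d_k) / (pre$n_k - 1))[keep])
  if (!is.finite(V) || V <= 0) return(0)
  (O - E) / sqrt(V)
}

# Scan all midpoint thresholds of one feature within a node, maintaining
# group-A risk counts incrementally as patients cross the threshold.
# Returns the best (threshold, |z|-maximizing) admissible split or NULL.
.scan_feature <- function(v, time, status, min_node, pre) {
  n <- length(v)
  ordv <- order(v)
  vs <- v[ordv]
  nA <- numeric(pre$K)
  dA <- numeric(pre$K)
  best <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && vs[j + 1] == vs[i]) j <- j + 1
    for (idx in ordv[i:j]) {
      ri <- pre$r[idx]
      if (ri > 0) nA[seq_len(ri)] <- nA[seq_len(ri)] + 1
      if (!is.na(pre$e[idx])) dA[pre$e[idx]] <- dA[pre$e[idx]] + 1
    }
    if (j < n && j >= min_node && n - j >= min_node) {
      z <- .logrank_z(nA, dA, pre)
      if (abs(z) > 0 && (is.null(best) || abs(z) > abs(best$statistic) + 1e-12)) {
        best <- list(threshold = unname((vs[j] + vs[j + 1]) / 2), statistic = z)
      }
    }
    i <- j + 1
  }
  best
}

#' Best log-rank split of a node
#'
#' Among the candidate features and all midpoints between consecutive
#' distinct values, returns the split maximizing the absolute log-rank
#' statistic with both children holding at least `min_node` patients.
#' Ties are broken deterministically toward the lowest feature index, then
#' the lowest threshold. Returns NULL when no admissible split exists or
#' all statistics are zero.
#'
#' @param expr covariate matrix (genes x patients).
#' @param outcome survival data.frame aligned to the patients.
#' @param candidates feature indices to consider (default: all).
#' @param min_node minimum child size (default 3).
#' @param members optional patient indices (with multiplicity) defining the
#'   node; default all patients.
#' @return list(`feature`, `feature_index`, `threshold`, `statistic`) or
#'   NULL.
#' @export
best_split <- function(expr, outcome, candidates = NULL, min_node = 3,
                       members = NULL) {
  outcome <- as_survival(data.frame(patient_id = seq_len(ncol(expr)),
                                    time = outcome$time, status = outcome$status))
  members <- members %||% seq_len(ncol(expr))
  candidates <- sort(candidates %||% seq_len(nrow(expr)))
  time <- outcome$time[members]
  status <- outcome$status[members]
  pre <- .node_precompute(time, status)
  if (pre$K == 0) return(NULL)
  best <- NULL
  for (f in candidates) {
    v <- expr[f, members]
    if (length(unique(v)) < 2) next
    sp <- .scan_feature(v, time, status, min_node, pre)
    if (!is.null(sp) &&
        (is.null(best) || abs(sp$statistic) > abs(best$statistic) + 1e-12)) {
      best <- list(feature = rownames(expr)[f] %||% f, feature_index = f,
                   threshold = sp$threshold, statistic = sp$statistic)
    }
  }
  best
}

# Nelson-Aalen cumulative hazard of a patient multiset, evaluated on the
# global time grid.
.na_chf <- function(time, status, grid) {
  evt <- sort(unique(time[status == 1]))
  if (length(evt) == 0) return(numeric(length(grid)))
  inc <- vapply(evt, function(s) {
    sum(status == 1 & time == s) / sum(time >= s)
  }, numeric(1))
  c(0, cumsum(inc))[findInterval(grid, evt) + 1]
}

.grow_tree <- function(expr, time, status, members, mtry, min_node, grid) {
  nodes <- list()
  p <- nrow(expr)
  add <- function(node) {
    nodes[[length(nodes) + 1]] <<- node
    length(nodes)
  }
  build <- function(members) {
    tm <- time[members]
    st <- status[members]
    if (length(members) >= 2 * min_node && any(st == 1)) {
      cand <- sort(sample.int(p, min(mtry, p)))
      pre <- .node_precompute(tm, st)
      best <- NULL
      for (f in cand) {
        v <- expr[f, members]
        if (length(unique(v)) < 2) next
        sp <- .scan_feature(v, tm, st, min_node, pre)
        if (!is.null(sp) &&
            (is.null(best) || abs(sp$statistic) > abs(best$statistic) + 1e-12)) {
          best <- list(feature = f, threshold = sp$threshold,
                       statistic = sp$statistic)
        }
      }
      if (!is.null(best)) {
        id <- add(list(feature = best$feature, threshold = best$threshold,
                       left = NA_integer_, right = NA_integer_))
        v <- expr[best$feature, members]
        l <- build(members[v <= best$threshold])
        r <- build(members[v > best$threshold])
        nodes[[id]]$left <<- l
        nodes[[id]]$right <<- r
        return(id)
      }
    }
    add(list(feature = NA_integer_, chf = .na_chf(tm, st, grid),
             n = length(members)))
  }
  root <- build(members)
  list(nodes = nodes, root = root)
}

#' Fit a random survival forest
#'
#' Each tree is grown on a bootstrap sample (n draws with replacement) to
#' exhaustion of admissible log-rank splits; every leaf holds at least
#' `min_node` (bootstrap) patients and stores the Nelson-Aalen cumulative
#' hazard of its members on the global grid of distinct training event
#' times, so ensemble averaging is well defined.
#'
#' @param expr covariate matrix (genes x patients).
#' @param outcome survival data.frame aligned to the patients.
#' @param n_trees number of trees (default 50).
#' @param min_node minimum terminal-node size (default 3).
#' @param mtry features sampled per node; default `ceiling(sqrt(p))`.
#' @param seed integer seed (bootstraps and feature sampling).
#' @return an `rsf_model`: `trees`, `bootstrap` indices per tree,
#'   `time_grid`, `mtry`, `min_node`, `feature_ids`, `seed`.
#' @export
fit_forest <- function(expr, outcome, n_trees = 50, min_node = 3,
                       mtry = NULL, seed = 1) {
  outcome <- as_survival(data.frame(patient_id = seq_len(ncol(expr)),
                                    time = outcome$time, status = outcome$status))
  if (sum(outcome$status) == 0) stopf("all patients censored; cannot fit a forest")
  p <- nrow(expr)
  n <- ncol(expr)
  mtry <- as.integer(mtry %||% ceiling(sqrt(p)))
  if (mtry < 1 || mtry > p) stopf("mtry must lie in [1, p]")
  grid <- sort(unique(outcome$time[outcome$status == 1]))
  trees <- vector("list", n_trees)
  boots <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    with_seed(derive_seed(seed, b), {
      idx <- sample.int(n, n, replace = TRUE)
      trees[[b]] <- .grow_tree(expr, outcome$time, outcome$status, idx,
                               mtry, min_node, grid)
      boots[[b]] <- idx
    })
  }
  structure(list(trees = trees, bootstrap = boots, time_grid = grid,
                 mtry = mtry, min_node = min_node,
                 feature_ids = rownames(expr), seed = seed),
            class = "rsf_model")
}

# Leaf index reached by each patient when routed down one tree.
.route_tree <- function(tree, expr) {
  n <- ncol(expr)
  leaf_of <- integer(n)
  rec <- function(ids, nid) {
    node <- tree$nodes[[nid]]
    if (is.na(node$feature)) {
      leaf_of[ids] <<- nid
      return(invisible())
    }
    v <- expr[node$feature, ids]
    go_left <- v <= node$threshold
    if (any(go_left)) rec(ids[go_left], node$left)
    if (any(!go_left)) rec(ids[!go_left], node$right)
  }
  rec(seq_len(n), tree$root)
  leaf_of
}

.align_features <- function(model, expr) {
  missing <- setdiff(model$feature_ids, rownames(expr))
  if (length(missing) > 0) {
    stopf("features missing from expression matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  expr[model$feature_ids, , drop = FALSE]
}

#' Ensemble cumulative hazard function
#'
#' Routes each patient through every tree and averages the leaf
#' Nelson-Aalen cumulative hazards over trees.
#'
#' @param model an `rsf_model`.
#' @param expr expression matrix (genes x patients).
#' @param tree_subset optional tree indices (used for out-of-bag scoring).
#' @return patients x time-grid matrix of cumulative hazards
#'   (non-decreasing along each row).
#' @export
ensemble_chf <- function(model, expr, tree_subset = NULL) {
  stopifnot(inherits(model, "rsf_model"))
  expr <- .align_features(model, expr)
  trees <- tree_subset %||% seq_along(model$trees)
  acc <- matrix(0, ncol(expr), length(model$time_grid))
  for (b in trees) {
    tree <- model$trees[[b]]
    leaf_of <- .route_tree(tree, expr)
    chfs <- do.call(rbind, lapply(tree$nodes[unique(leaf_of)], `[[`, "chf"))
    acc <- acc + chfs[match(leaf_of, unique(leaf_of)), , drop = FALSE]
  }
  out <- acc / length(trees)
  rownames(out) <- colnames(expr)
  out
}

#' Forest risk score
#'
#' Mean of the ensemble cumulative hazard over the event-time grid:
#' `RS_i = mean_j H(t_j | X_i)`.
#'
#' @param model an `rsf_model`.
#' @param expr expression matrix (genes x patients).
#' @return named numeric vector of risk scores.
#' @export
forest_risk_score <- function(model, expr) {
  chf <- ensemble_chf(model, expr)
  if (ncol(chf) == 0) stopf("empty time grid")
  rowMeans(chf)
}

#' @export
predict_survival.rsf_model <- function(model, expr, times) {
  chf <- ensemble_chf(model, expr)
  idx <- findInterval(times, model$time_grid)
  H <- cbind(0, chf)[, idx + 1, drop = FALSE]
  out <- exp(-H)
  dimnames(out) <- list(colnames(expr), NULL)
  attr(out, "extrapolated") <- any(times > max(model$time_grid))
  out
}

#' Out-of-bag error of a survival forest
#'
#' 1 minus the concordance of out-of-bag ensemble risk scores: each
#' patient's cumulative hazard is averaged over the trees whose bootstrap
#' sample did not contain the patient. Patients in every bootstrap are
#' excluded from the concordance.
#'
#' @param model an `rsf_model` fitted on `expr` / `outcome`.
#' @param expr the training expression matrix.
#' @param outcome the training survival.
#' @return OOB error in `[0, 1]` (lower is better).
#' @export
oob_error <- function(model, expr, outcome) {
  stopifnot(inherits(model, "rsf_model"))
  expr <- .align_features(model, expr)
  n <- ncol(expr)
  acc <- matrix(0, n, length(model$time_grid))
  cnt <- integer(n)
  for (b in seq_along(model$trees)) {
    oob <- setdiff(seq_len(n), unique(model$bootstrap[[b]]))
    if (length(oob) == 0) next
    leaf_of <- .route_tree(model$trees[[b]], expr[, oob, drop = FALSE])
    chfs <- do.call(rbind, lapply(model$trees[[b]]$nodes[unique(leaf_of)],
                                  `[[`, "chf"))
    acc[oob, ] <- acc[oob, , drop = FALSE] +
      chfs[match(leaf_of, unique(leaf_of)), , drop = FALSE]
    cnt[oob] <- cnt[oob] + 1L
  }
  covered <- cnt > 0
  risk <- rowMeans(acc[covered, , drop = FALSE]) / cnt[covered]
  out_cov <- data.frame(patient_id = which(covered),
                        time = outcome$time[covered],
                        status = outcome$status[covered])
  1 - concordance_index(risk, out_cov)
}

#' Tune mtry by out-of-bag error
#'
#' Fits one forest per candidate mtry (same seed, so bootstraps are shared
#' across candidates) and returns the mtry minimizing the out-of-bag error;
#' ties go to the smaller mtry. The `"auto"` grid is
#' `{ceil(sqrt(p)/2), ceil(sqrt(p)), ceil(2 sqrt(p)), ceil(p/3)}`
#' deduplicated. With fewer than 30 patients OOB coverage is unreliable and
#' the default `ceiling(sqrt(p))` is returned with a warning.
#'
#' @inheritParams fit_forest
#' @param grid `"auto"` or an integer vector of candidate mtry values.
#' @return selected mtry (integer) with the per-candidate OOB errors in the
#'   `"oob_errors"` attribute.
#' @export
tune_mtry <- function(expr, outcome, grid = "auto", n_trees = 50,
                      min_node = 3, seed = 1) {
  p <- nrow(expr)
  if (ncol(expr) < 30) {
    warnf("fewer than 30 patients: OOB coverage too thin to tune mtry; using sqrt(p)")
    return(as.integer(ceiling(sqrt(p))))
  }
  if (identical(grid, "auto")) {
    grid <- unique(pmin(p, pmax(1L, as.integer(ceiling(
      c(sqrt(p) / 2, sqrt(p), 2 * sqrt(p), p / 3))))))
  }
  if (any(grid < 1 | grid > p)) stopf("mtry grid must lie within [1, p]")
  errs <- vapply(grid, function(m) {
    fit <- fit_forest(expr, outcome, n_trees = n_trees, min_node = min_node,
                      mtry = m, seed = seed)
    oob_error(fit, expr, outcome)
  }, numeric(1))
  best <- grid[which.min(errs)]
  structure(as.integer(best), oob_errors = stats::setNames(errs, grid))
}
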