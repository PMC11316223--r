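#' Exact Shapley values by subset enumeration
#'
#' Computes \eqn{\phi_i = \sum_S \frac{|S|!(n-|S|-1)!}{n!}
#' [v(S\cup\{i\}) - v(S)]} over all \eqn{2^n} subsets. Intended as the
#' independent oracle for tree-based attribution engines; limited to
#' `n_features <= 10`.
#'
#' @param value_function function taking an integer vector of player/feature
#'   indices (possibly empty) and returning a scalar score `v(S)`.
#' @param n_features number of players (<= 10).
#' @return Numeric vector of attributions, one per player.
#' @export
exact_shapley <- function(value_function, n_features) {
  stopifnot(n_features >= 1L)
  if (n_features > 10L) stop("exact enumeration limited to 10 features")
  n <- as.integer(n_features)
  nsub <- bitwShiftL(1L, n)
  v <- numeric(nsub)
  for (m in 0:(nsub - 1L))
    v[m + 1L] <- value_function(which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L))
  sizes <- vapply(0:(nsub - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L), numeric(1))
  wts <- factorial(0:(n - 1L)) * factorial(n - 1L - (0:(n - 1L))) / factorial(n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(nsub - 1L), bit) == 0L)  # 1-based subset ids
    m <- without - 1L
    phi[i] <- sum(wts[sizes[without] + 1L] * (v[bitwOr(m, bit) + 1L] - v[without]))
  }
  phi
}

# Path-dependent expected value of an xgboost model when only the features
# in `subset` are known: at a split on a known feature follow the data
# point, otherwise average the children weighted by their training cover.
# This is the value function whose exact Shapley values the TreeSHAP
# algorithm computes.
# round a double vector through IEEE single precision (xgboost compares
# feature values to split points in float32)
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          size = 4L, n = length(v))
}

xgb_path_value <- function(trees, x, subset) {
  known <- logical(length(x))
  known[subset] <- TRUE
  total <- 0
  for (tr in trees) {
    rec <- function(node) {
      row <- tr[node, ]
      if (row$Feature == "Leaf") return(row$Gain)
      fi <- row$FeatureIndex
      if (known[fi]) {
        nxt <- if (x[fi] < row$Split) row$YesNode else row$NoNode
        return(rec(nxt))
      }
      wy <- tr$Cover[row$YesNode]
      wn <- tr$Cover[row$NoNode]
      (wy * rec(row$YesNode) + wn * rec(row$NoNode)) / (wy + wn)
    }
    total <- total + rec(1L)
  }
  total
}

# Parse an xgboost model into a list of per-tree node tables with 1-based
# node references, for xgb_path_value().
parse_xgb_trees <- function(booster, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  trees <- split(dt, dt$Tree)
  lapply(trees, function(tr) {
    tr <- tr[order(tr$Node), ]
    id2row <- stats::setNames(seq_len(nrow(tr)), tr$ID)
    tr$YesNode <- ifelse(is.na(tr$Yes), NA_integer_, id2row[tr$Yes])
    tr$NoNode <- ifelse(is.na(tr$No), NA_integer_, id2row[tr$No])
    tr$FeatureIndex <- match(tr$Feature, feature_names)
    # the dump prints splits at float32 precision; restore the exact float32
    # value so double comparisons replicate the engine's float32 routing
    tr$Split <- as_float32(tr$Split)
    tr
  })
}

#' Rank morphometric determinants by Shapley attribution magnitude
#'
#' Fits a seeded gradient-boosted tree classifier for each non-control
#' condition against the control (one-vs-control), computes exact tree-path
#' Shapley attributions for every cell, and ranks features by the mean
#' absolute attribution pooled over conditions. Model quality is reported
#' as seeded cross-validated accuracy so rankings from near-chance models
#' are flagged unreliable rather than trusted.
#'
#' @param matrix feature matrix from [assemble_feature_matrix()], or any
#'   data.frame with numeric feature columns.
#' @param labels condition label per row; if `NULL`, the `condition` column
#'   of `matrix`.
#' @param control control condition (default: first level encountered).
#' @param seed RNG seed controlling model fitting and cross-validation.
#' @param nrounds,max_depth,eta fixed booster hyperparameters.
#' @param n_folds cross-validation folds for the accuracy estimate.
#' @return A list of class `shap_report`: `importance` (data.frame
#'   `feature`, `mean_abs_phi`, `rank`), `phi` (rows = cells used, columns =
#'   features), `models` (per-condition accuracy and reliability flag),
#'   `unreliable` (TRUE when every per-condition model is near chance),
#'   `seed`.
#' @export
rank_features_shap <- function(matrix, labels = NULL, control = NULL,
                               seed = 1L, nrounds = 60L, max_depth = 3L,
                               eta = 0.3, n_folds = 5L) {
  stopifnot(is.data.frame(matrix))
  if (is.null(labels)) {
    stopifnot("condition" %in% names(matrix))
    labels <- matrix$condition
  }
  feats <- attr(matrix, "feature_names")
  if (is.null(feats))
    feats <- names(matrix)[vapply(matrix, is.numeric, logical(1))]
  X <- as.matrix(matrix[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  conds <- unique(labels)
  if (length(conds) < 2L) stop("need at least 2 conditions")
  if (is.null(control)) control <- conds[1L]
  stopifnot(control %in% conds)
  if (min(table(labels)) < 10L)
    stop("need at least 10 cells per condition")
  # drop constant features (uninformative and break standardization)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Xs <- scale(X)
  used_feats <- colnames(Xs)

  models <- list()
  phi_sum <- matrix(0, 0, length(used_feats))
  phi_all <- list()
  for (cond in setdiff(conds, control)) {
    sel <- labels %in% c(control, cond)
    Xc <- Xs[sel, , drop = FALSE]
    y <- as.numeric(labels[sel] == cond)
    set.seed(seed)
    booster <- fit_booster(Xc, y, nrounds, max_depth, eta)
    contrib <- predict(booster, xgboost::xgb.DMatrix(Xc, nthread = 1),
                       predcontrib = TRUE)
    contrib <- contrib[, seq_along(used_feats), drop = FALSE]  # drop BIAS
    acc <- cv_accuracy(Xc, y, seed, n_folds, nrounds, max_depth, eta)
    # near-chance flag: accuracy not above the binomial 95% band at p = 0.5
    thr <- stats::qbinom(0.95, length(y), 0.5) / length(y)
    models[[cond]] <- list(condition = cond, cv_accuracy = acc,
                           near_chance = acc <= thr)
    phi_all[[cond]] <- contrib
  }
  mean_abs <- Reduce(`+`, lapply(phi_all, function(p) colMeans(abs(p)))) /
    length(phi_all)
  ord <- order(mean_abs, decreasing = TRUE)
  importance <- data.frame(feature = used_feats,
                           mean_abs_phi = as.numeric(mean_abs))
  importance$rank <- match(seq_along(used_feats), ord)
  importance <- importance[ord, ]
  rownames(importance) <- NULL
  unreliable <- all(vapply(models, function(m) m$near_chance, logical(1)))
  structure(list(importance = importance, phi = phi_all, models = models,
                 unreliable = unreliable, seed = seed,
                 feature_names = used_feats),
            class = "shap_report")
}

fit_booster <- function(X, y, nrounds, max_depth, eta) {
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, base_score = 0.5, nthread = 1,
                  lambda = 1, subsample = 1, colsample_bytree = 1),
    data = dm, nrounds = nrounds, verbose = 0)
}

cv_accuracy <- function(X, y, seed, n_folds, nrounds, max_depth, eta) {
  set.seed(seed + 1L)
  n <- length(y)
  folds <- sample(rep_len(seq_len(n_folds), n))
  correct <- 0L
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    booster <- fit_booster(X[tr, , drop = FALSE], y[tr], nrounds, max_depth,
                           eta)
    p <- predict(booster, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE],
                                               nthread = 1))
    correct <- correct + sum((p > 0.5) == (y[!tr] == 1))
  }
  correct / n
}

#' Tree-path Shapley attributions by exact enumeration
#'
#' Computes, for one sample, the exact Shapley values of the cover-weighted
#' tree-path expectation game of a fitted booster by full subset
#' enumeration ([exact_shapley()]). This is the slow, independent
#' double-precision route against which the fast TreeSHAP attributions of
#' [rank_features_shap()] are checked; usable up to 10 features.
#'
#' @param booster an xgboost booster.
#' @param x numeric feature vector (named or in training column order).
#' @param feature_names feature names in training order.
#' @return Numeric vector of per-feature attributions (excluding the base
#'   value, which is `v(empty set)`).
#' @export
shapley_tree_attributions <- function(booster, x, feature_names) {
  trees <- parse_xgb_trees(booster, feature_names)
  n <- length(feature_names)
  xf <- as_float32(x)
  vf <- function(S) xgb_path_value(trees, xf, S)
  exact_shapley(vf, n)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Standard one-way ANOVA (F and p), followed by Dunnett's test comparing
#' every non-control group mean against the control. Adjusted p-values are
#' computed from the null distribution of the maximum absolute Dunnett
#' statistic by seeded Monte Carlo (the draws are generated group-by-group,
#' so enlarging the group set reuses the same underlying draws), and are
#' floored at the unadjusted per-comparison t p-value, a bound the exact
#' Dunnett distribution satisfies analytically.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param control name of the control group.
#' @param seed RNG seed for the Monte Carlo null.
#' @param n_draws Monte Carlo draws (default 1e5).
#' @param compare groups to compare against the control (default all
#'   non-control groups); the pooled variance and F always use all groups.
#' @return A list of class `group_stats_result`: `F`, `p`, `df`,
#'   `summary` (group means, sd, n), `comparisons` (data.frame with
#'   `group`, `diff`, `t`, `p_unadjusted`, `p_adjusted`).
#' @export
anova_dunnett <- function(groups, control, seed = 1L, n_draws = 1e5,
                          compare = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)),
            control %in% names(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("each group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  if (all(vapply(groups, function(v) stats::var(v) == 0, logical(1))) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1L) {
    # all observations identical: F = 0, everything p = 1
    cmp0 <- if (is.null(compare)) setdiff(names(groups), control) else compare
    comparisons <- data.frame(group = cmp0,
                              diff = 0, t = 0, p_unadjusted = 1,
                              p_adjusted = 1, stringsAsFactors = FALSE)
    return(structure(list(F = 0, p = 1, df = c(length(groups) - 1L,
                                               sum(ns) - length(groups)),
                          summary = group_summary(groups),
                          comparisons = comparisons),
                     class = "group_stats_result"))
  }
  fit <- stats::lm(values ~ g)
  av <- stats::anova(fit)
  Fstat <- av$`F value`[1]
  pval <- av$`Pr(>F)`[1]
  df2 <- av$Df[2]
  s2 <- av$`Mean Sq`[2]
  if (s2 == 0) stop("zero within-group variance in all groups")

  others <- if (is.null(compare)) setdiff(names(groups), control) else {
    stopifnot(all(compare %in% names(groups)), !control %in% compare)
    compare
  }
  n0 <- ns[[control]]
  m0 <- mean(groups[[control]])
  tstat <- vapply(others, function(nm) {
    (mean(groups[[nm]]) - m0) / sqrt(s2 * (1 / ns[[nm]] + 1 / n0))
  }, numeric(1))
  p_unadj <- 2 * stats::pt(-abs(tstat), df2)

  # Monte Carlo null of max_k |T_k|; draws generated column-by-column so a
  # run with a prefix of the groups sees identical draws
  set.seed(seed)
  s2_draw <- stats::rchisq(n_draws, df2) / df2
  z0 <- stats::rnorm(n_draws)
  maxT <- rep(0, n_draws)
  for (nm in others) {
    zi <- stats::rnorm(n_draws)
    Ti <- (zi / sqrt(ns[[nm]]) - z0 / sqrt(n0)) /
      sqrt(s2_draw * (1 / ns[[nm]] + 1 / n0))
    maxT <- pmax(maxT, abs(Ti))
  }
  p_adj <- vapply(seq_along(others), function(i) {
    max(mean(maxT >= abs(tstat[i])), p_unadj[i])
  }, numeric(1))

  comparisons <- data.frame(group = others,
                            diff = vapply(others, function(nm)
                              mean(groups[[nm]]) - m0, numeric(1)),
                            t = tstat, p_unadjusted = p_unadj,
                            p_adjusted = pmin(p_adj, 1),
                            stringsAsFactors = FALSE)
  rownames(comparisons) <- NULL
  structure(list(F = Fstat, p = pval, df = av$Df, summary = group_summary(groups),
                 comparisons = comparisons),
            class = "group_stats_result")
}

group_summary <- function(groups) {
  data.frame(group = names(groups),
             n = vapply(groups, length, integer(1)),
             mean = vapply(groups, mean, numeric(1)),
             sd = vapply(groups, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
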