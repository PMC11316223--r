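test_that("exact Shapley values satisfy the axioms", {
  # additivity: v(S) = sum of member weights -> phi = the weights
  expect_equal(exact_shapley(function(S) sum(c(2, 3, 5)[S]), 3), c(2, 3, 5))
  # symmetry: interchangeable players get equal shares
  v_sym <- function(S) as.numeric(length(S) >= 2)
  phi <- exact_shapley(v_sym, 4)
  expect_true(all(abs(phi - phi[1]) < 1e-12))
  expect_equal(sum(phi), 1)  # efficiency: shares sum to v(grand coalition)
  # dummy player contributes nothing
  v_dummy <- function(S) as.numeric(1 %in% S) * 7
  expect_equal(exact_shapley(v_dummy, 3), c(7, 0, 0))
  expect_error(exact_shapley(function(S) 0, 11), "limited")
})

test_that("TreeSHAP attributions match exact enumeration and sum to the margin", {
  set.seed(3)
  n <- 150; p <- 8
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", 1:p)
  y <- as.numeric(X[, 2] - X[, 5] + 0.5 * X[, 7] + rnorm(n, 0, 0.5) > 0)
  bst <- fibromorph:::fit_booster(X, y, nrounds = 10, max_depth = 3, eta = 0.3)
  nd <- xgboost::xgb.DMatrix(X[1:10, , drop = FALSE], nthread = 1)
  contrib <- predict(bst, nd, predcontrib = TRUE)
  margin <- predict(bst, nd, outputmargin = TRUE)
  # local accuracy: contributions + base value reproduce the model output
  expect_lt(max(abs(rowSums(contrib) - margin)), 1e-6)
  # the fast engine agrees with the exact cover-weighted path enumeration
  for (i in c(1, 4, 9)) {
    phi <- shapley_tree_attributions(bst, X[i, ], colnames(X))
    expect_lt(max(abs(phi - contrib[i, 1:p])), 1e-6)
  }
})

test_that("a planted discriminative feature is ranked first", {
  top_rank <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 30; p <- 10
    X <- as.data.frame(matrix(rnorm(2 * n * p), 2 * n))
    names(X) <- paste0("f", 1:p)
    X$f4 <- X$f4 + rep(c(0, 3), each = n)   # 3 SD shift in one feature
    X$condition <- rep(c("ctrl", "treat"), each = n)
    rep <- rank_features_shap(X[, paste0("f", 1:p)],
                              labels = X$condition, control = "ctrl",
                              seed = s, nrounds = 40)
    rep$importance$feature[1]
  }, character(1))
  expect_gte(sum(top_rank == "f4"), 19)
})

test_that("permuted labels are flagged as a near-chance model", {
  set.seed(77)
  n <- 40; p <- 6
  X <- as.data.frame(matrix(rnorm(2 * n * p), 2 * n))
  names(X) <- paste0("f", 1:p)
  labels <- sample(rep(c("a", "b"), each = n))  # labels carry no signal
  rep <- rank_features_shap(X, labels = labels, control = "a", seed = 5)
  expect_true(rep$models[["b"]]$near_chance)
  expect_true(rep$unreliable)
})

test_that("one-way ANOVA F matches the sums-of-squares oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- anova_dunnett(groups, control = "a", seed = 1, n_draws = 1e4)
  # explicit between/within sum-of-squares decomposition
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F_oracle <- (ss_b / 2) / (ss_w / 6)
  expect_equal(res$F, F_oracle, tolerance = 1e-12)
  expect_equal(res$p, stats::pf(F_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups: F = 0, all p = 1
  same <- list(x = c(2, 2, 2), y = c(2, 2, 2))
  r0 <- anova_dunnett(same, "x", seed = 1, n_draws = 1e3)
  expect_identical(r0$F, 0)
  expect_identical(r0$comparisons$p_adjusted, 1)
})

test_that("Dunnett adjustment dominates the per-comparison t test", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(4:9, 1), mean = rnorm(1)))
    names(groups) <- c("ctrl", paste0("g", seq_len(k - 1)))
    res <- anova_dunnett(groups, "ctrl", seed = i, n_draws = 2e4)
    expect_true(all(res$comparisons$p_adjusted >=
                      res$comparisons$p_unadjusted - 1e-12))
  }
})

test_that("Dunnett Monte Carlo is seed-stable, monotone and matches multcomp", {
  set.seed(30)
  groups <- list(ctrl = rnorm(8), g1 = rnorm(7, 0.8), g2 = rnorm(9, 0.4),
                 g3 = rnorm(6, -0.6))
  r1 <- anova_dunnett(groups, "ctrl", seed = 4)
  r2 <- anova_dunnett(groups, "ctrl", seed = 4)
  expect_identical(r1$comparisons$p_adjusted, r2$comparisons$p_adjusted)

  # more comparison groups cannot lower the adjusted p (same data, seed)
  p1 <- anova_dunnett(groups, "ctrl", seed = 4,
                      compare = "g1")$comparisons$p_adjusted[1]
  p12 <- anova_dunnett(groups, "ctrl", seed = 4,
                       compare = c("g1", "g2"))$comparisons$p_adjusted[1]
  p123 <- anova_dunnett(groups, "ctrl", seed = 4,
                        compare = c("g1", "g2", "g3"))$comparisons$p_adjusted[1]
  expect_true(p1 <= p12 && p12 <= p123)

  skip_if_not_installed("multcomp")
  d <- data.frame(y = unlist(groups),
                  g = factor(rep(names(groups), lengths(groups)),
                             levels = names(groups)))
  gl <- summary(multcomp::glht(stats::aov(y ~ g, d),
                               linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(r1$comparisons$p_adjusted, as.numeric(gl$test$pvalues),
               tolerance = 0.02)
})
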