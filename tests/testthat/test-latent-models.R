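test_that("a single informative variable gets the whole component-1 weight", {
  y <- rep(c("a", "b"), each = 4)
  X <- cbind(j = c(1, 1, 1, 1, 5, 5, 5, 5),
             dead1 = rep(0, 8), dead2 = rep(0, 8))
  m <- fit_plsda(X, y, n_components = 1)
  expect_equal(abs(m$W[, 1]), c(j = 1, dead1 = 0, dead2 = 0))
  expect_gt(m$W["j", 1], 0)  # sign convention: dominant element positive
})

test_that("NIPALS deflation exhausts a rank-1 X in one component", {
  set.seed(3)
  t0 <- rnorm(8); p0 <- rnorm(4)
  X <- tcrossprod(t0, p0)
  colnames(X) <- paste0("v", 1:4)
  y <- ifelse(t0 > median(t0), "a", "b")
  m <- fit_plsda(X, y, n_components = 1)
  Xc <- scale(X, scale = FALSE)
  residual <- Xc - tcrossprod(m$T[, 1], m$P[, 1])
  expect_lt(max(abs(residual)), 1e-10)
  expect_gt(abs(cor(m$T[, 1], t0)), 1 - 1e-10)
})

test_that("NIPALS component 1 solves the X'YY'X eigenproblem (power-iteration oracle)", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- sample(5:10, 1); p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- factor(rep_len(c("a", "b", "c"), n))
    Xc <- scale(X, scale = FALSE)
    Y <- model.matrix(~ y - 1)
    Yc <- scale(Y, scale = FALSE)
    M <- crossprod(Xc, Yc) %*% crossprod(Yc, Xc)
    w <- rnorm(p)
    for (i in 1:2000) w <- { v <- M %*% w; v / sqrt(sum(v^2)) }
    w <- drop(w)
    m <- fit_plsda(X, y, n_components = 1)
    got <- m$W[, 1]
    if (sign(sum(got * w)) < 0) w <- -w
    expect_equal(got, w, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("score vectors of successive components are mutually orthogonal", {
  set.seed(21)
  X <- matrix(rnorm(12 * 7), 12, 7, dimnames = list(NULL, paste0("v", 1:7)))
  y <- rep(c("a", "b", "c"), each = 4)
  m <- fit_plsda(X, y, n_components = 4)
  G <- crossprod(m$T)
  off <- G - diag(diag(G))
  norms <- sqrt(diag(G))
  expect_lt(max(abs(off) / tcrossprod(norms)), 1e-8)
})

test_that("VIP concentrates on informative variables and its squares average to one", {
  y <- rep(c("a", "b"), each = 4)
  even <- cbind(v1 = c(1, 1, 1, 1, 2, 2, 2, 2))
  X_even <- even[, rep(1, 5)] + 0; colnames(X_even) <- paste0("v", 1:5)
  m_even <- fit_plsda(X_even, y, n_components = 1)
  expect_equal(unname(compute_vip(m_even)), rep(1, 5), tolerance = 1e-10)

  X_conc <- cbind(hot = c(1, 1, 1, 1, 9, 9, 9, 9),
                  z1 = 0, z2 = 0, z3 = 0)[, , drop = FALSE]
  m_conc <- fit_plsda(X_conc + 0, y, n_components = 1)
  vip <- compute_vip(m_conc)
  expect_equal(unname(vip), c(2, 0, 0, 0))

  # 2-component model: term-by-term evaluation of the formula
  set.seed(31)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y2 <- rep(c("a", "b"), 3)
  m2 <- fit_plsda(X, y2, n_components = 2)
  manual <- sapply(seq_len(4), function(j) {
    num <- sum(m2$ss * (m2$W[j, ] / sqrt(colSums(m2$W^2)))^2)
    sqrt(4 * num / sum(m2$ss))
  })
  expect_equal(unname(compute_vip(m2)), manual)

  # normalization holds for every fitted model kind
  for (mod in list(m_even, m2, fit_oplsda(X, y2, n_orthogonal = 1))) {
    expect_equal(sum(compute_vip(mod)^2), nrow(mod$W), tolerance = 1e-8)
  }
})

test_that("OPLS-DA separates predictive from orthogonal variation", {
  # 0 orthogonal components: reduces to one-component PLS-DA up to sign
  set.seed(41)
  X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- rep(c("a", "b"), each = 5)
  o0 <- fit_oplsda(X, y, n_orthogonal = 0)
  p1 <- fit_plsda(X, y, n_components = 1)
  expect_equal(abs(drop(o0$W)), abs(drop(p1$W)), tolerance = 1e-8)
  expect_equal(abs(drop(o0$T)), abs(drop(p1$T)), tolerance = 1e-8)

  # constructed design: v1 tracks the class, v2 is structured but orthogonal
  yd <- rep(c(0, 1), each = 6)
  struct <- rep(c(-1, 1), 6)
  X2 <- cbind(v1 = yd + rnorm(12, 0, 0.01), v2 = struct)
  o1 <- fit_oplsda(X2, rep(c("a", "b"), each = 6), n_orthogonal = 1)
  expect_gt(abs(cor(o1$T_ortho[, 1], struct)), 0.99)
  expect_lt(abs(cor(o1$T[, 1], o1$T_ortho[, 1])), 1e-8)
  yc <- yd - mean(yd)
  expect_lt(abs(cor(o1$T_ortho[, 1], yc)), 1e-8)

  # modeled + residual variance reconstructs total X variance
  o2 <- fit_oplsda(X, y, n_orthogonal = 2)
  Xc <- scale(X, scale = FALSE)
  modeled <- tcrossprod(o2$T, o2$P) +
    o2$T_ortho %*% t(o2$P_ortho)
  resid <- Xc - modeled
  expect_equal(sum(Xc^2),
               sum(tcrossprod(o2$T, o2$P)^2) +
                 sum((o2$T_ortho %*% t(o2$P_ortho))^2) + sum(resid^2),
               tolerance = 1e-8)

  expect_error(fit_oplsda(X, rep(c("a", "b", "c"), length.out = 10), 1),
               class = "aromakit_model_error", regexp = "fit_plsda")
})

test_that("cross-validation: perfect designs give Q2 near 1, shuffled labels give negative Q2", {
  y <- rep(c("a", "b"), each = 6)
  base <- as.numeric(factor(y)) - 1.5
  X <- cbind(base, base, base, base)  # duplicated-column, noiseless
  colnames(X) <- paste0("v", 1:4)
  cv <- cross_validate(X, y, plsda_spec(1), folds = 3, seed = 2)
  expect_gt(cv$q2, 1 - 1e-6)
  expect_gt(cv$r2, 1 - 1e-6)

  qs <- vapply(1:200, function(s) {
    set.seed(2000 + s)
    Xn <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("v", 1:8)))
    yn <- sample(rep(c("a", "b"), each = 6))
    cross_validate(Xn, yn, plsda_spec(1), folds = 3, seed = s)$q2
  }, numeric(1))
  expect_lt(mean(qs), 0)

  # determinism given seed, sensitivity to it
  expect_identical(cross_validate(X, y, plsda_spec(1), folds = 3, seed = 9),
                   cross_validate(X, y, plsda_spec(1), folds = 3, seed = 9))

  # losing a class in training is a stratification error
  y_rare <- c("a", rep("b", 11))
  expect_error(cross_validate(X, y_rare, plsda_spec(1), folds = 3, seed = 1),
               class = "aromakit_stratification_error")
})

test_that("permutation p-values respect the add-one lower bound and detect real separation", {
  spec2 <- two_group_spec(n_compounds = 10, n_wines = 3, cv = 0.10, seed = 11)
  spec2$means[1:5, spec2$wines$wine_label[spec2$wines$group_label == "B"]] <- 800
  panel <- generate_panel(spec2)
  X <- panel_matrix(panel)
  g <- panel_groups(panel, X)
  pt <- permutation_test(X, g, plsda_spec(2), n_permutations = 100,
                         folds = 5, seed = 17)
  expect_equal(pt$permutation_p, 1 / 101)
  expect_gte(pt$permutation_p, 1 / (pt$n_permutations + 1))
  expect_gt(pt$q2, 0.5)
  expect_gt(pt$r2, 0.5)

  # degenerate: one label for everyone
  expect_warning(
    deg <- permutation_test(X, rep("a", nrow(X)), plsda_spec(1), 10, seed = 1),
    "identical"
  )
  expect_equal(deg$permutation_p, 1)
})

test_that("permutation p-values are approximately uniform under the null", {
  rejections <- 0
  for (s in 1:200) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("v", 1:8)))
    yn <- rep(c("a", "b"), each = 6)
    p <- permutation_test(Xn, yn, plsda_spec(1), n_permutations = 19,
                          folds = 3, seed = s)$permutation_p
    if (p <= 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 200, 0.02)
  expect_lte(rejections / 200, 0.09)
})

test_that("discriminant selection uses a strict VIP cutoff", {
  expect_equal(nrow(select_discriminants(c(a = 1, b = 1, c = 1))), 0)
  one <- select_discriminants(c(a = 2, b = 0, c = 0))
  expect_equal(one$compound_id, "a")
  expect_equal(one$vip, 2)
})

test_that("component-1 agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(55)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(paste0("s", 1:12), paste0("v", 1:5)))
  y <- rep(c("a", "b"), each = 6)
  ours <- fit_plsda(X, y, n_components = 2)
  ref <- mixOmics::plsda(X, factor(y), ncomp = 2, scale = FALSE)
  for (a in 1:2) {
    w_ref <- ref$loadings$X[, a]
    w_our <- ours$W[, a]
    if (sign(sum(w_ref * w_our)) < 0) w_ref <- -w_ref
    expect_equal(unname(w_our), unname(w_ref), tolerance = 1e-6)
  }
  vip_ref <- mixOmics::vip(ref)
  expect_equal(unname(compute_vip(ours)), unname(vip_ref[, 2]), tolerance = 1e-6)
})
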