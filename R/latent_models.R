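#' Partial least squares discriminant analysis (NIPALS)
#'
#' Fits a PLS2 model of the one-hot encoded, mean-centered class matrix Y on
#' the mean-centered feature matrix X, extracting components sequentially by
#' NIPALS with deflation of both blocks. Score vectors of successive
#' components are mutually orthogonal. Each component's weight vector is
#' sign-fixed so that its largest-magnitude element is positive, making
#' score plots reproducible across platforms.
#'
#' @param X Numeric matrix, rows = samples (replicate injections enter as
#'   independent rows), columns = variables; typically Pareto-scaled.
#' @param y Class labels (factor or character), at least two classes.
#' @param n_components Number of components, at most `min(nrow(X) - 1, ncol(X))`.
#' @param max_iter,tol NIPALS iteration controls.
#' @return An `aroma_latent` model with weights `W`, X-loadings `P`, scores
#'   `T`, Y-loadings `Q`, per-component explained Y-variance `ss`, and the
#'   centering information needed for prediction.
#' @export
fit_plsda <- function(X, y, n_components = 2, max_iter = 500, tol = 1e-10) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) {
    abort("PLS-DA needs at least two classes", class = "aromakit_model_error")
  }
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    abort("n_components exceeds min(rows - 1, columns)", class = "aromakit_model_error")
  }
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  x_means <- colMeans(X)
  y_means <- colMeans(Y)
  Xc <- sweep(X, 2, x_means)
  Yc <- sweep(Y, 2, y_means)

  n <- nrow(X); p <- ncol(X); m <- ncol(Y); A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); Q <- matrix(0, m, A)
  ss <- numeric(A)
  x_tot0 <- sum(Xc^2); y_tot0 <- sum(Yc^2)
  for (a in seq_len(A)) {
    # an exhausted block (noiseless low-rank designs) cannot support
    # further components: truncate instead of iterating on rounding noise
    if (sum(Xc^2) <= 1e-18 * x_tot0 || sum(Yc^2) <= 1e-18 * y_tot0) {
      warn(paste0("X/Y variance exhausted after ", a - 1,
                  " component(s); model truncated"))
      A <- a - 1L
      W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
      Tm <- Tm[, seq_len(A), drop = FALSE]; Q <- Q[, seq_len(A), drop = FALSE]
      ss <- ss[seq_len(A)]
      break
    }
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(Inf, n)
    no_covariance <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      if (sum(w^2) <= 1e-24 * x_tot0) {  # X carries no Y-covariant direction
        no_covariance <- TRUE
        break
      }
      w <- w / sqrt(sum(w^2))
      t_scr <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, t_scr)) / sum(t_scr^2)
      u <- drop(Yc %*% q) / sum(q^2)
      delta2 <- sum((t_scr - t_old)^2)
      # relative criterion, plus an absolute floor on the scale of X for
      # score vectors so close to zero that rounding noise never settles
      if (delta2 < tol^2 * sum(t_scr^2) || delta2 <= 1e-20 * x_tot0) break
      t_old <- t_scr
      if (it == max_iter) {
        abort("NIPALS did not converge", class = "aromakit_convergence_error")
      }
    }
    if (no_covariance) {
      A <- a - 1L
      W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
      Tm <- Tm[, seq_len(A), drop = FALSE]; Q <- Q[, seq_len(A), drop = FALSE]
      ss <- ss[seq_len(A)]
      break
    }
    sgn <- sign(w[which.max(abs(w))])
    w <- sgn * w; t_scr <- sgn * t_scr; q <- sgn * q
    p_load <- drop(crossprod(Xc, t_scr)) / sum(t_scr^2)
    Xc <- Xc - tcrossprod(t_scr, p_load)
    Yc <- Yc - tcrossprod(t_scr, q)
    W[, a] <- w; P[, a] <- p_load; Tm[, a] <- t_scr; Q[, a] <- q
    ss[a] <- sum(t_scr^2) * sum(q^2)  # Y-variance captured by component a
  }
  comp_names <- sprintf("comp%d", seq_len(A))
  dimnames(W) <- dimnames(P) <- list(colnames(X), comp_names)
  dimnames(Tm) <- list(rownames(X), comp_names)
  dimnames(Q) <- list(colnames(Y), comp_names)
  structure(
    list(
      kind = "PLSDA", W = W, P = P, T = Tm, Q = Q, ss = ss,
      n_predictive = A, n_orthogonal = 0L,
      x_means = x_means, y_means = y_means, levels = levels(y), y = y
    ),
    class = "aroma_latent"
  )
}

#' Orthogonal PLS discriminant analysis (two classes)
#'
#' Splits X-variation into a single class-predictive component and
#' `n_orthogonal` components that are structured but uncorrelated with the
#' class, which concentrates all between-class separation on one axis and
#' eases interpretation. With `n_orthogonal = 0` the predictive component
#' equals a one-component PLS-DA on the same data (up to sign).
#'
#' @param X Numeric matrix as in [fit_plsda()].
#' @param y Two-class labels.
#' @param n_orthogonal Number of orthogonal components (>= 0).
#' @return An `aroma_latent` model: predictive `W`, `P`, `T`, `Q` plus
#'   orthogonal `W_ortho`, `P_ortho`, `T_ortho`.
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) {
    abort("OPLS-DA is defined for exactly two classes; use fit_plsda() for more",
          class = "aromakit_model_error")
  }
  stopifnot(n_orthogonal >= 0)
  yd <- as.numeric(y == levels(y)[2])
  x_means <- colMeans(X)
  y_mean <- mean(yd)
  Xc <- sweep(X, 2, x_means)
  yc <- yd - y_mean

  p <- ncol(X)
  w <- drop(crossprod(Xc, yc)) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  Wo <- matrix(0, p, n_orthogonal); Po <- matrix(0, p, n_orthogonal)
  To <- matrix(0, nrow(X), n_orthogonal)
  for (a in seq_len(n_orthogonal)) {
    t_scr <- drop(Xc %*% w)
    p_load <- drop(crossprod(Xc, t_scr)) / sum(t_scr^2)
    w_o <- p_load - drop(crossprod(w, p_load)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) {
      abort("no orthogonal variation left to extract", class = "aromakit_model_error")
    }
    w_o <- w_o / nrm
    t_o <- drop(Xc %*% w_o)
    p_o <- drop(crossprod(Xc, t_o)) / sum(t_o^2)
    Xc <- Xc - tcrossprod(t_o, p_o)
    Wo[, a] <- w_o; Po[, a] <- p_o; To[, a] <- t_o
  }
  sgn <- sign(w[which.max(abs(w))])
  w <- sgn * w
  t_scr <- drop(Xc %*% w)
  p_load <- drop(crossprod(Xc, t_scr)) / sum(t_scr^2)
  q <- sum(yc * t_scr) / sum(t_scr^2)
  structure(
    list(
      kind = "OPLSDA",
      W = matrix(w, ncol = 1, dimnames = list(colnames(X), "pred")),
      P = matrix(p_load, ncol = 1), T = matrix(t_scr, ncol = 1),
      Q = matrix(q, 1, 1), ss = sum(t_scr^2) * q^2,
      W_ortho = Wo, P_ortho = Po, T_ortho = To,
      n_predictive = 1L, n_orthogonal = as.integer(n_orthogonal),
      x_means = x_means, y_means = y_mean, levels = levels(y), y = y
    ),
    class = "aroma_latent"
  )
}

#' Predict class membership from a fitted latent model
#'
#' @param object An `aroma_latent` model.
#' @param newdata Matrix with the same columns as the training data.
#' @param ... Unused.
#' @return List with `scores` (numeric predictions on the response scale)
#'   and `class` (assigned labels, by maximal predicted response column).
#' @export
predict.aroma_latent <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2, object$x_means)
  if (object$kind == "OPLSDA") {
    for (a in seq_len(object$n_orthogonal)) {
      t_o <- drop(Xc %*% object$W_ortho[, a])
      Xc <- Xc - tcrossprod(t_o, object$P_ortho[, a])
    }
    t_new <- drop(Xc %*% object$W[, 1])
    yhat <- t_new * object$Q[1, 1] + object$y_means
    cls <- object$levels[ifelse(yhat >= 0.5, 2L, 1L)]
    scores <- cbind(yhat)
  } else if (ncol(object$W) == 0) {
    # fully truncated model: the class means are the only prediction
    scores <- matrix(object$y_means, nrow(Xc), length(object$y_means),
                     byrow = TRUE, dimnames = list(NULL, object$levels))
    return(list(scores = scores,
                class = object$levels[apply(scores, 1, which.max)]))
  } else {
    # regression coefficients of the deflated-block algorithm
    B <- object$W %*% solve(crossprod(object$P, object$W), t(object$Q))
    scores <- Xc %*% B
    scores <- sweep(scores, 2, object$y_means, "+")
    colnames(scores) <- object$levels
    cls <- object$levels[apply(scores, 1, which.max)]
  }
  list(scores = scores, class = cls)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a ss_a (w_ja / ||w_a||)^2 / sum_a ss_a)`: a
#' weighted sum of squared normalized weights, with each component weighted
#' by the Y-variance it explains. Squared VIPs average to 1 over variables,
#' so VIP > 1 flags above-average contributors. For OPLS-DA only the
#' predictive component enters.
#'
#' @param model An `aroma_latent` model.
#' @return Named numeric vector of VIP scores (one per variable).
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "aroma_latent"), model$n_predictive >= 1)
  W <- model$W
  ss <- model$ss
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  vip <- sqrt(nrow(W) * drop(wn2 %*% ss) / sum(ss))
  stats::setNames(vip, rownames(W))
}

#' Rank discriminant variables by VIP
#'
#' @param vip Named VIP vector from [compute_vip()].
#' @param cutoff Strict VIP cutoff, default 1.
#' @return Tibble (`compound_id`, `vip`) sorted by decreasing VIP.
#' @export
select_discriminants <- function(vip, cutoff = 1) {
  sel <- vip[vip > cutoff]
  sel <- sort(sel, decreasing = TRUE)
  tibble::tibble(compound_id = names(sel), vip = unname(sel))
}

#' Model specifications for validation helpers
#'
#' Lightweight descriptions of which latent model to refit inside
#' cross-validation and permutation loops.
#'
#' @param n_components,n_orthogonal Model size.
#' @export
plsda_spec <- function(n_components = 2) {
  structure(list(kind = "plsda", n_components = n_components), class = "aroma_model_spec")
}

#' @rdname plsda_spec
#' @export
oplsda_spec <- function(n_orthogonal = 1) {
  structure(list(kind = "oplsda", n_orthogonal = n_orthogonal), class = "aroma_model_spec")
}

fit_spec <- function(spec, X, y) {
  switch(spec$kind,
    plsda = fit_plsda(X, y, n_components = spec$n_components),
    oplsda = fit_oplsda(X, y, n_orthogonal = spec$n_orthogonal),
    abort("unknown model spec kind", class = "aromakit_configuration_error")
  )
}

one_hot <- function(y) {
  Y <- stats::model.matrix(~ factor(y) - 1)
  colnames(Y) <- levels(factor(y))
  Y
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stratified_folds <- function(y, folds) {
  y <- factor(y)
  fold_of <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Stratified k-fold cross-validation of a latent model
#'
#' `R2 = 1 - RSS/TSS` on the full fit measures goodness of fit; `Q2 = 1 -
#' PRESS/TSS`, with prediction errors accumulated over held-out folds,
#' measures out-of-sample predictive ability. Folds are stratified by class
#' and deterministic given `seed`.
#'
#' @param X,y Data and labels as in [fit_plsda()].
#' @param spec A [plsda_spec()] or [oplsda_spec()].
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return List (`r2`, `q2`, `folds`, `seed`).
#' @export
cross_validate <- function(X, y, spec, folds = 5, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  stopifnot(folds >= 2)
  Y <- one_hot(y)
  Yc <- sweep(Y, 2, colMeans(Y))
  tss <- sum(Yc^2)

  full <- fit_spec(spec, X, y)
  if (full$kind == "OPLSDA") {
    yd <- as.numeric(y == levels(y)[2])
    rss <- sum((yd - drop(predict(full, X)$scores))^2)
    tss_fit <- sum((yd - mean(yd))^2)
  } else {
    rss <- sum((Y - predict(full, X)$scores)^2)
    tss_fit <- tss
  }
  r2 <- 1 - rss / tss_fit

  fold_of <- with_seed(seed, stratified_folds(y, folds))
  press <- 0; tss_cv <- 0
  for (k in seq_len(folds)) {
    test <- fold_of == k
    if (!all(levels(y) %in% y[!test])) {
      abort("a training split lost a class; reduce folds or rebalance",
            class = "aromakit_stratification_error")
    }
    fit_k <- fit_spec(spec, X[!test, , drop = FALSE], y[!test])
    pred <- predict(fit_k, X[test, , drop = FALSE])$scores
    if (full$kind == "OPLSDA") {
      yd <- as.numeric(y == levels(y)[2])
      press <- press + sum((yd[test] - drop(pred))^2)
      tss_cv <- sum((yd - mean(yd))^2)
    } else {
      press <- press + sum((Y[test, , drop = FALSE] - pred)^2)
      tss_cv <- tss
    }
  }
  list(r2 = r2, q2 = 1 - press / tss_cv, folds = folds, seed = seed)
}

#' Permutation test of a latent model
#'
#' Refits the model under `n_permutations` random shufflings of the class
#' labels (X untouched) and compares the resulting cross-validated Q2
#' values with the observed one. The reported p-value uses the add-one
#' estimator `p = (1 + #\{Q2_perm >= Q2_obs\}) / (1 + n_permutations)`, so
#' `p >= 1/(n_permutations + 1)` always.
#'
#' @inheritParams cross_validate
#' @param n_permutations Number of label shufflings (default 100).
#' @param seed Seed controlling both fold assignment and the shufflings.
#' @return List (`r2`, `q2`, `permutation_p`, `n_permutations`,
#'   `permuted_q2`, `folds`).
#' @export
permutation_test <- function(X, y, spec, n_permutations = 100, folds = 5, seed = 1) {
  stopifnot(n_permutations >= 1)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) {
    warn("all labels identical: every permutation reproduces the observed model")
    return(list(r2 = NA_real_, q2 = NA_real_, permutation_p = 1,
                n_permutations = n_permutations, permuted_q2 = NULL, folds = folds))
  }
  obs <- cross_validate(X, y, spec, folds = folds, seed = seed)
  perm_q2 <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      yb <- sample(y)
      cross_validate(X, yb, spec, folds = folds, seed = seed)$q2
    }, numeric(1))
  })
  p <- (1 + sum(perm_q2 >= obs$q2)) / (1 + n_permutations)
  list(r2 = obs$r2, q2 = obs$q2, permutation_p = p,
       n_permutations = n_permutations, permuted_q2 = perm_q2, folds = folds)
}
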