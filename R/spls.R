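#' Sparse partial least squares (SPLS) regression
#'
#' Extracts `L` sparse latent components from centered (optionally scaled)
#' predictors.  Each direction vector solves the sparse surrogate problem for
#' the current cross-product matrix `M = X' Y Y' X`: it is the soft-thresholded
#' leading eigenvector of `M`, with the threshold set to `alpha_sparsity`
#' times the largest absolute entry, renormalized to unit norm.  After each
#' component the predictors are deflated by regression on the score, which
#' makes successive scores orthogonal.  Regression coefficients are mapped
#' back to the original predictor scale.
#'
#' @param X numeric matrix, samples x predictors.
#' @param Y numeric response matrix (n x m); a binary class vector may be
#'   passed as a one-column dummy matrix.
#' @param L number of latent components, `1 <= L <= min(n, p)`.
#' @param alpha_sparsity soft-threshold fraction in `[0, 1)`; 0 is plain PLS.
#' @param scale_x scale predictor columns to unit variance (default FALSE;
#'   columns are always centered).
#' @return object of class `pls_fit`: direction vectors `W` (unit norm),
#'   scores `T` (n x L), loadings `P`, projection `W_star` (so that
#'   `T = Xc W_star`), per-component active sets, coefficients `beta`
#'   (original scale) and `intercept`.
#' @export
fit_spls <- function(X, Y, L, alpha_sparsity = 0, scale_x = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (length(L) != 1 || L < 1 || L > min(n, p)) {
    stop("L must be an integer in [1, min(n, p)]")
  }
  if (alpha_sparsity < 0 || alpha_sparsity >= 1) {
    stop("alpha_sparsity must be in [0, 1)")
  }
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center, "-")
  x_scale <- NULL
  if (scale_x) {
    x_scale <- apply(Xc, 2, stats::sd)
    x_scale[x_scale < 1e-12] <- 1
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center, "-")

  W <- matrix(0, p, L); P <- matrix(0, p, L)
  Tm <- matrix(0, n, L)
  active <- vector("list", L)
  X1 <- Xc
  L_eff <- L
  for (l in seq_len(L)) {
    w <- tryCatch(sparse_direction(X1, Yc, alpha_sparsity),
                  error = function(e) NULL)
    if (is.null(w)) {
      # response covariance exhausted: the PLS fit already equals the
      # least-squares fit on the extracted components
      if (l == 1) stop("X carries no covariance with the response")
      L_eff <- l - 1L
      break
    }
    t_l <- drop(X1 %*% w)
    tt <- sum(t_l^2)
    if (tt < 1e-12) {
      if (l == 1) stop("degenerate latent score at first component")
      L_eff <- l - 1L
      break
    }
    p_l <- drop(crossprod(X1, t_l)) / tt
    X1 <- X1 - tcrossprod(t_l, p_l)
    W[, l] <- w; P[, l] <- p_l; Tm[, l] <- t_l
    active[[l]] <- which(w != 0)
  }
  if (L_eff < L) {
    W <- W[, seq_len(L_eff), drop = FALSE]
    P <- P[, seq_len(L_eff), drop = FALSE]
    Tm <- Tm[, seq_len(L_eff), drop = FALSE]
    active <- active[seq_len(L_eff)]
    L <- L_eff
  }
  W_star <- W %*% solve(crossprod(P, W))
  qcoef <- solve(crossprod(Tm), crossprod(Tm, Yc))     # L x m
  beta_std <- W_star %*% qcoef                          # p x m
  beta <- if (scale_x) beta_std / x_scale else beta_std
  intercept <- y_center - drop(crossprod(beta, x_center))
  structure(list(
    W = W, T = Tm, P = P, W_star = W_star, q = qcoef,
    active_sets = active, beta = beta, intercept = intercept,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    L = L, alpha_sparsity = alpha_sparsity
  ), class = "pls_fit")
}

# soft-thresholded leading eigenvector of M = X'Y Y'X, unit norm
sparse_direction <- function(Xc, Yc, alpha_sparsity) {
  Z <- crossprod(Xc, Yc)                    # p x m
  v <- if (ncol(Z) == 1) {
    drop(Z)
  } else {
    svd(Z, nu = 1, nv = 0)$u[, 1] * norm(Z, "2")
  }
  amax <- max(abs(v))
  if (amax < 1e-14) stop("X carries no covariance with the response")
  w <- sign(v) * pmax(abs(v) - alpha_sparsity * amax, 0)
  w / sqrt(sum(w^2))
}

#' SPLS discriminant analysis (SPLS-DA)
#'
#' Two-stage classifier: SPLS regression on the dummy-coded (0/1) class
#' labels extracts `L` sparse latent scores; an unpenalized logistic
#' regression of the labels on those scores provides fitted probabilities.
#' If the stage-2 logistic fit separates, a lightly ridged IRLS fit is used
#' instead, with a warning.
#'
#' @inheritParams fit_logit_en
#' @param L number of latent components.
#' @param alpha_sparsity soft-threshold fraction in `[0, 1)`.
#' @param scale_x scale predictor columns (default FALSE).
#' @return object of class `c("splsda_fit", "sparse_fit")`; `selected` is the
#'   union of the per-component active sets, `pls` the stage-1 fit, `stage2`
#'   the logistic model on the scores.
#' @export
fit_splsda <- function(X, y, L, alpha_sparsity = 0, scale_x = FALSE,
                       train_idx = NULL, model_id = "splsda") {
  X <- as.matrix(X)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(X))
  Xt <- X[train_idx, , drop = FALSE]
  yt <- y[train_idx]
  check_binary(yt)
  pls <- fit_spls(Xt, matrix(yt, ncol = 1), L = L,
                  alpha_sparsity = alpha_sparsity, scale_x = scale_x)
  stage2 <- safe_logistic(cbind(`(Intercept)` = 1, pls$T), yt)
  fit <- structure(list(
    method = "splsda", model_id = model_id,
    hyper = list(alpha = alpha_sparsity, L = L),
    pls = pls, stage2 = stage2,
    selected = sort(unique(unlist(pls$active_sets))),
    n = length(train_idx), p = ncol(X), train_idx = train_idx,
    converged = TRUE
  ), class = c("splsda_fit", "sparse_fit"))
  fit$fitted_prob <- clip_prob(stats::plogis(
    drop(cbind(1, pls$T) %*% stage2$coef)))
  fit$beta0 <- stage2$coef[1]
  beta <- drop(pls$W_star %*% stage2$coef[-1])
  if (!is.null(pls$x_scale)) beta <- beta / pls$x_scale
  fit$beta <- stats::setNames(beta, colnames(X))
  fit
}

# Logistic fit with ridge-stabilized fallback under separation.
safe_logistic <- function(design, y, ridge = 1e-4) {
  g <- tryCatch(
    suppressWarnings(stats::glm.fit(design, y, family = stats::binomial())),
    error = function(e) NULL)
  ok <- !is.null(g) && g$converged &&
    !any(g$fitted.values < 1e-8 | g$fitted.values > 1 - 1e-8) &&
    all(is.finite(stats::coef(g)))
  if (ok) return(list(coef = stats::coef(g), ridge = 0, separation = FALSE))
  warning("stage-2 logistic fit separated; using ridge-stabilized fit")
  list(coef = ridge_irls(design, y, lambda = ridge * nrow(design)),
       ridge = ridge * nrow(design), separation = TRUE)
}

# Ridge-penalized logistic IRLS (intercept in column 1 is also ridged by a
# negligible amount; used only as a separation fallback).
ridge_irls <- function(design, y, lambda, max_iter = 100, tol = 1e-8) {
  m <- ncol(design)
  beta <- numeric(m)
  pen <- diag(c(1e-8, rep(lambda, m - 1)), m)
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    p <- clip_prob(stats::plogis(eta), 1e-8)
    v <- p * (1 - p)
    z <- eta + (y - p) / v
    A <- crossprod(design * sqrt(v)) + pen
    beta_new <- solve(A, crossprod(design, v * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' Sparse generalized PLS (SGPLS) logistic classifier
#'
#' Embeds sparse PLS extraction in the IRLS loop for logistic regression.
#' At each iteration the working responses `z_i = eta_i + (y_i - p_i)/v_i`
#' and weights `v_i = p_i (1 - p_i)` are formed; sparse directions are
#' extracted from `M = X' V z z' V X` (soft-thresholded leading eigenvector,
#' weighted deflation), the weighted least-squares problem
#' `min_beta sum_i v_i (z_i - x_i' beta)^2` is solved on the `L` scores, and
#' the linear predictor is updated until `max |delta beta| < tol`.
#'
#' @inheritParams fit_splsda
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the coefficient update.
#' @return object of class `c("sgpls_fit", "sparse_fit")`; carries the final
#'   IRLS weights and working responses, the latent scores and a
#'   `converged` flag (a non-converged fit is returned with a warning).
#' @export
fit_sgpls <- function(X, y, L, alpha_sparsity = 0, scale_x = FALSE,
                      max_iter = 50, tol = 1e-4,
                      train_idx = NULL, model_id = "sgpls") {
  X <- as.matrix(X)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(X))
  Xt <- X[train_idx, , drop = FALSE]
  yt <- y[train_idx]
  check_binary(yt)
  n <- nrow(Xt); p <- ncol(Xt)
  if (L < 1 || L > min(n, p)) stop("L must be in [1, min(n, p)]")

  x_center <- colMeans(Xt)
  Xc <- sweep(Xt, 2, x_center, "-")
  x_scale <- NULL
  if (scale_x) {
    x_scale <- apply(Xc, 2, stats::sd)
    x_scale[x_scale < 1e-12] <- 1
    Xc <- sweep(Xc, 2, x_scale, "/")
  }

  beta <- numeric(p)
  beta0 <- stats::qlogis(clip_prob(mean(yt), 0.01))
  deviance_at <- function(b0, b) {
    pr <- clip_prob(stats::plogis(b0 + drop(Xc %*% b)), 1e-8)
    -2 * sum(yt * log(pr) + (1 - yt) * log(1 - pr))
  }
  dev_old <- deviance_at(beta0, beta)
  converged <- FALSE
  pls <- NULL; gamma <- NULL; v <- NULL; z <- NULL; Tm <- NULL
  for (it in seq_len(max_iter)) {
    eta <- beta0 + drop(Xc %*% beta)
    pr <- clip_prob(stats::plogis(eta), 1e-5)
    v <- pr * (1 - pr)
    z <- eta + (yt - pr) / v
    sw <- sum(v)
    zc <- z - sum(v * z) / sw
    xm <- colSums(Xc * v) / sw
    Xv <- sweep(Xc, 2, xm, "-")
    pls <- weighted_spls(Xv, zc, v, L, alpha_sparsity)
    Tm <- pls$T
    A <- crossprod(Tm * sqrt(v))
    gamma <- solve(A, crossprod(Tm, v * zc))
    beta_new <- drop(pls$W_star %*% gamma)
    beta0_new <- sum(v * (z - drop(Xc %*% beta_new))) / sw
    # step-halving guard: sparse active sets can flip between iterations and
    # cycle, so the update is shrunk towards the previous iterate until the
    # deviance no longer increases
    dev_new <- deviance_at(beta0_new, beta_new)
    halvings <- 0
    while (dev_new > dev_old + 1e-8 && halvings < 12) {
      beta_new <- (beta_new + beta) / 2
      beta0_new <- (beta0_new + beta0) / 2
      dev_new <- deviance_at(beta0_new, beta_new)
      halvings <- halvings + 1
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new; beta0 <- beta0_new; dev_old <- dev_new
    if (delta < tol * max(1, max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("SGPLS IRLS did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  # canonicalization: step halving can leave beta between two score-space
  # representations; re-extract directions and re-solve the score regression
  # at the final weights so beta = W_star gamma exactly
  eta <- beta0 + drop(Xc %*% beta)
  pr <- clip_prob(stats::plogis(eta), 1e-5)
  v <- pr * (1 - pr)
  z <- eta + (yt - pr) / v
  sw <- sum(v)
  zc <- z - sum(v * z) / sw
  Xv <- sweep(Xc, 2, colSums(Xc * v) / sw, "-")
  pls <- weighted_spls(Xv, zc, v, L, alpha_sparsity)
  Tm <- pls$T
  gamma <- solve(crossprod(Tm * sqrt(v)), crossprod(Tm, v * zc))
  beta <- drop(pls$W_star %*% gamma)
  beta0 <- sum(v * (z - drop(Xc %*% beta))) / sw
  eta <- beta0 + drop(Xc %*% beta)
  pr <- clip_prob(stats::plogis(eta), 1e-5)
  active <- pls$active_sets
  beta_orig <- if (scale_x) beta / x_scale else beta
  fit <- structure(list(
    method = "sgpls", model_id = model_id,
    hyper = list(alpha = alpha_sparsity, L = L,
                 max_iter = max_iter, tol = tol),
    pls = list(W = pls$W, W_star = pls$W_star, T = Tm, P = pls$P,
               x_center = x_center, x_scale = x_scale,
               active_sets = active, irls_weights = v,
               working_response = z),
    stage2 = list(coef = c(`(Intercept)` = beta0, drop(gamma)), ridge = 0,
                  separation = FALSE),
    selected = sort(unique(unlist(active))),
    beta0 = beta0 - if (scale_x) sum(x_center * beta / x_scale) else sum(x_center * beta),
    beta = stats::setNames(drop(beta_orig), colnames(X)),
    fitted_prob = pr,
    n = n, p = ncol(X), train_idx = train_idx,
    converged = converged
  ), class = c("sgpls_fit", "sparse_fit"))
  fit
}

# One pass of sparse PLS on weighted, centered data (direction vectors from
# M = X'V z z'V X, weighted deflation).
weighted_spls <- function(Xv, zc, v, L, alpha_sparsity) {
  n <- nrow(Xv); p <- ncol(Xv)
  W <- matrix(0, p, L); P <- matrix(0, p, L); Tm <- matrix(0, n, L)
  active <- vector("list", L)
  X1 <- Xv
  for (l in seq_len(L)) {
    s <- drop(crossprod(X1, v * zc))          # X'Vz, leading eigvec of rank-1 M
    amax <- max(abs(s))
    if (amax < 1e-14) {
      # response exhausted: keep remaining components as zero scores
      L_eff <- l - 1L
      if (L_eff == 0) stop("no covariance between predictors and working response")
      W <- W[, seq_len(L_eff), drop = FALSE]
      P <- P[, seq_len(L_eff), drop = FALSE]
      Tm <- Tm[, seq_len(L_eff), drop = FALSE]
      active <- active[seq_len(L_eff)]
      break
    }
    w <- sign(s) * pmax(abs(s) - alpha_sparsity * amax, 0)
    w <- w / sqrt(sum(w^2))
    t_l <- drop(X1 %*% w)
    vtt <- sum(v * t_l^2)
    p_l <- drop(crossprod(X1, v * t_l)) / vtt
    X1 <- X1 - tcrossprod(t_l, p_l)
    W[, l] <- w; P[, l] <- p_l; Tm[, l] <- t_l
    active[[l]] <- which(w != 0)
  }
  W_star <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, T = Tm, W_star = W_star, active_sets = active)
}
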