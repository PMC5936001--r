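#' Cross-validated hyperparameter selection by mean squared error
#'
#' Stratified k-fold cross-validation over a hyperparameter grid, scoring
#' each grid point by the mean over folds of the held-out mean squared error
#' `mean((y_i - p_hat_i)^2)`.  For `method = "logit_en"` the grid is
#' `alpha_grid` x a lambda path (by default 50 log-spaced values from the
#' smallest lambda that zeroes all coefficients down four decades); for the
#' PLS classifiers it is `alpha_grid` x `L_grid`.  Ties are broken towards
#' the smaller `L`, then the larger `alpha`.
#'
#' @param X samples x genes matrix.
#' @param y binary response.
#' @param method `"logit_en"`, `"splsda"` or `"sgpls"`.
#' @param alpha_grid elastic-net mixing values (logit_en) or sparsity
#'   fractions (PLS methods).
#' @param L_grid latent-component counts (PLS methods only; default 1:5).
#' @param lambda_grid optional explicit lambda values for logit_en.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold split.
#' @return object of class `cv_result`: `grid` (data.frame with mean CV MSE
#'   per point), `best` (named list of hyperparameters), `best_mse`,
#'   `fold_id`, `seed`.
#' @export
cv_select <- function(X, y, method = c("logit_en", "splsda", "sgpls"),
                      alpha_grid, L_grid = 1:5, lambda_grid = NULL,
                      folds = 10, seed = 1) {
  method <- match.arg(method)
  X <- as.matrix(X)
  check_binary(y)
  if (folds < 2) stop("folds must be >= 2")
  if (length(alpha_grid) < 1) stop("alpha_grid must be non-empty")
  fold_id <- stratified_folds(y, folds, seed)

  if (method == "logit_en") {
    if (is.null(lambda_grid)) lambda_grid <- default_lambda_path(X, y, min(alpha_grid))
    grid <- expand.grid(alpha = sort(alpha_grid), lambda = lambda_grid)
    mse <- matrix(0, nrow(grid), folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      for (a in unique(grid$alpha)) {
        gfit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                               family = "binomial", alpha = a,
                               lambda = sort(lambda_grid, decreasing = TRUE),
                               standardize = TRUE)
        ph <- stats::predict(gfit, X[!tr, , drop = FALSE],
                             s = grid$lambda[grid$alpha == a],
                             type = "response", exact = FALSE)
        mse[grid$alpha == a, f] <- colMeans((y[!tr] - ph)^2)
      }
    }
    grid$mse <- rowMeans(mse)
    # tie-break: larger alpha first (no L for this method)
    ord <- order(grid$mse, -grid$alpha, grid$lambda)
    best <- grid[ord[1], ]
    best_hp <- list(alpha = best$alpha, lambda = best$lambda)
  } else {
    fitter <- if (method == "splsda") fit_splsda else fit_sgpls
    grid <- expand.grid(alpha = sort(alpha_grid), L = sort(L_grid))
    mse <- matrix(NA_real_, nrow(grid), folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      for (g in seq_len(nrow(grid))) {
        fit <- tryCatch(
          suppressWarnings(fitter(X[tr, , drop = FALSE], y[tr],
                                  L = grid$L[g],
                                  alpha_sparsity = grid$alpha[g])),
          error = function(e) NULL)
        mse[g, f] <- if (is.null(fit)) {
          mean((y[te] - mean(y[tr]))^2)  # degenerate fit scored as null model
        } else {
          mean((y[te] - predict_proba(fit, X[te, , drop = FALSE]))^2)
        }
      }
    }
    grid$mse <- rowMeans(mse)
    ord <- order(grid$mse, grid$L, -grid$alpha)
    best <- grid[ord[1], ]
    best_hp <- list(alpha = best$alpha, L = best$L)
  }
  structure(list(method = method, grid = grid, best = best_hp,
                 best_mse = best$mse, fold_id = fold_id, seed = seed),
            class = "cv_result")
}

# Stratified fold assignment; re-drawn (with a warning) if some fold lacks a
# class, which can only happen when a class has fewer members than folds.
stratified_folds <- function(y, folds, seed, max_tries = 20) {
  rng <- local_rng(seed)
  on.exit(rng())
  n <- length(y)
  for (try in seq_len(max_tries)) {
    fold_id <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[fold_id == f])) == 2 || sum(fold_id == f) == 0
    }, logical(1)))
    # training sides must also contain both classes
    ok <- ok && all(vapply(seq_len(folds), function(f) {
      length(unique(y[fold_id != f])) == 2
    }, logical(1)))
    if (ok) return(fold_id)
    warning("a fold was missing a class; re-drawing folds")
  }
  stop("could not construct class-balanced folds")
}

# default elastic-net lambda path: 50 log-spaced values from lambda_max
# (smallest lambda with an all-zero solution) down four decades
default_lambda_path <- function(X, y, alpha_min, nlambda = 50, decades = 4) {
  n <- nrow(X)
  Xs <- scale(X)
  Xs[is.na(Xs)] <- 0
  r <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, r))) / (n * max(alpha_min, 1e-3))
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = nlambda))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV for %s over %d grid points\n",
              max(x$fold_id), x$method, nrow(x$grid)))
  cat("best:", paste(names(x$best), signif(unlist(x$best), 4),
                     sep = " = ", collapse = ", "),
      sprintf("(CV MSE %.4g)\n", x$best_mse))
  invisible(x)
}

# Seed scoping helper: sets the RNG to a derived seed and returns a restore
# function, so package internals never perturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Derive a reproducible child seed from a master seed
#'
#' Ensemble runs derive one child seed per member/run from the master seed so
#' each run is individually reproducible; the derivation is a fixed affine
#' hash modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index run or member index (1-based).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + index * 7919) %%
               2147483646 + 1)
}
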