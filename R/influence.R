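#' Leverages (hat diagonals) for a weighted logistic design
#'
#' Computes `h_ii = v_i * x_i' (X'VX)^{-1} x_i`, the diagonal of the logistic
#' hat matrix `H = V^{1/2} X (X'VX)^{-1} X' V^{1/2}`, without forming the full
#' n x n matrix.  The inverse information is built from `design`/`weights`
#' (the rows used in fitting); leverages can additionally be evaluated at
#' held-out rows via `new_design`/`new_weights`, as needed when a model is
#' trained on a patient subset but all patients are scored.
#'
#' @param design numeric matrix (n x m), the effective model design including
#'   any intercept column.
#' @param weights positive IRLS weights `v_i = p_i (1 - p_i)`, length n.
#' @param new_design,new_weights optional rows to evaluate instead of the
#'   training rows.
#' @param ridge optional ridge added to `X'VX` (used for penalized fallbacks).
#' @return numeric vector of leverages in `[0, 1]`.
#' @export
hat_diagonals <- function(design, weights, new_design = NULL,
                          new_weights = NULL, ridge = 0) {
  design <- as.matrix(design)
  if (length(weights) != nrow(design)) stop("weights/design mismatch")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite")
  }
  A <- crossprod(design * sqrt(weights))
  if (ridge > 0) A <- A + diag(ridge, ncol(A))
  U <- tryCatch(chol(A), error = function(e) NULL)
  # a tiny Cholesky pivot signals (near-)rank deficiency even when chol()
  # succeeds numerically
  if (!is.null(U) && min(diag(U)) <= max(diag(U)) * 1e-7) U <- NULL
  if (is.null(U)) {
    kap <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
    lam <- max(diag(A)) * 1e-8 + 1e-12
    warning(sprintf(
      "weighted design rank-deficient (condition number ~ %.3g); ridge-stabilized",
      kap))
    U <- chol(A + diag(lam, ncol(A)))
  }
  Xe <- if (is.null(new_design)) design else as.matrix(new_design)
  ve <- if (is.null(new_weights)) weights else new_weights
  if (length(ve) != nrow(Xe)) stop("new_weights/new_design mismatch")
  B <- backsolve(U, t(Xe), transpose = TRUE)  # solves U' B = X'
  h <- ve * colSums(B^2)
  pmin(pmax(h, 0), 1)
}

#' Standardized Pearson residuals for a binary fit
#'
#' `r_i = (y_i - p_i) / (sqrt(p_i (1 - p_i)) * sqrt(1 - h_ii))`, with fitted
#' probabilities clipped to `[1e-10, 1 - 1e-10]`.
#'
#' @param y binary response (0/1).
#' @param p_hat fitted probabilities.
#' @param h leverages, each strictly below 1.
#' @return numeric vector of residuals.
#' @export
standardized_pearson_residuals <- function(y, p_hat, h) {
  if (length(y) != length(p_hat) || length(y) != length(h)) {
    stop("y, p_hat and h must have equal length")
  }
  if (any(h >= 1)) stop("leverage h_ii >= 1: residual undefined")
  eps <- 1e-10
  p <- pmin(pmax(p_hat, eps), 1 - eps)
  (y - p) / (sqrt(p * (1 - p)) * sqrt(1 - h))
}

#' Cook's distance for every observation under a fitted ensemble member
#'
#' Assembles the model-appropriate effective design (see Details), the IRLS
#' weights `v_i = p_i(1 - p_i)`, leverages, standardized Pearson residuals,
#' and the one-step Cook's distance `D_i = r_i^2 h_ii / (1 - h_ii)` for every
#' row of `X` -- including rows not used in fitting, whose leverage is
#' evaluated against the training information matrix.
#'
#' Effective designs: for elastic-net logistic fits, intercept plus the
#' selected (nonzero-coefficient) genes, with probabilities from the
#' unpenalized logistic refit stored in the fit (falling back to the
#' penalized curvature when the refit is unstable); for SPLS-DA and SGPLS,
#' intercept plus the L latent scores with the stage-2 / final-IRLS weights.
#'
#' @param fit a fit from [fit_logit_en()], [fit_splsda()] or [fit_sgpls()].
#' @param X expression matrix covering all samples to score (same columns as
#'   used in fitting).
#' @param y binary response for all scored samples.
#' @return data.frame with columns `sample_id`, `h`, `r`, `D`, `model_id`.
#' @export
cooks_distance_model <- function(fit, X, y) {
  UseMethod("cooks_distance_model")
}

cooks_frame <- function(ids, h, r, model_id) {
  data.frame(sample_id = ids, h = h, r = r,
             D = r^2 * h / (1 - h),
             model_id = model_id, stringsAsFactors = FALSE)
}

check_scoring_inputs <- function(fit, X, y) {
  X <- as.matrix(X)
  if (ncol(X) != fit$p) {
    stop("feature mismatch: model was fitted on ", fit$p, " genes, got ",
         ncol(X))
  }
  if (length(y) != nrow(X)) stop("y must match rows of X")
  X
}

#' @export
cooks_distance_model.logit_en_fit <- function(fit, X, y) {
  X <- check_scoring_inputs(fit, X, y)
  sel <- fit$selected
  design <- cbind(`(Intercept)` = 1, X[, sel, drop = FALSE])
  eta <- drop(design %*% fit$refit$coef)
  p <- clip_prob(stats::plogis(eta))
  v <- p * (1 - p)
  tr <- fit$train_idx
  h <- hat_diagonals(design[tr, , drop = FALSE], v[tr],
                     new_design = design, new_weights = v,
                     ridge = fit$refit$ridge)
  h <- pmin(h, 1 - 1e-12)
  r <- standardized_pearson_residuals(y, p, h)
  cooks_frame(scoring_ids(X), h, r, fit$model_id)
}

scores_design <- function(fit, X) {
  Xs <- sweep(X, 2, fit$pls$x_center, "-")
  if (!is.null(fit$pls$x_scale)) Xs <- sweep(Xs, 2, fit$pls$x_scale, "/")
  Tm <- Xs %*% fit$pls$W_star
  colnames(Tm) <- paste0("LV", seq_len(ncol(Tm)))
  cbind(`(Intercept)` = 1, Tm)
}

cooks_pls <- function(fit, X, y) {
  design <- scores_design(fit, X)
  eta <- drop(design %*% fit$stage2$coef)
  p <- clip_prob(stats::plogis(eta))
  v <- p * (1 - p)
  tr <- fit$train_idx
  h <- hat_diagonals(design[tr, , drop = FALSE], v[tr],
                     new_design = design, new_weights = v,
                     ridge = fit$stage2$ridge)
  h <- pmin(h, 1 - 1e-12)
  r <- standardized_pearson_residuals(y, p, h)
  cooks_frame(scoring_ids(X), h, r, fit$model_id)
}

#' @export
cooks_distance_model.splsda_fit <- function(fit, X, y) {
  X <- check_scoring_inputs(fit, X, y)
  cooks_pls(fit, X, y)
}

#' @export
cooks_distance_model.sgpls_fit <- function(fit, X, y) {
  X <- check_scoring_inputs(fit, X, y)
  cooks_pls(fit, X, y)
}

scoring_ids <- function(X) {
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  ids
}

clip_prob <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)
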