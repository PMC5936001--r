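#' Elastic-net regularized logistic regression (LOGIT-EN)
#'
#' Fits the penalized logistic model
#' `min -loglik/n + lambda * ((1 - alpha) ||beta||_2^2 / 2 + alpha ||beta||_1)`
#' via \pkg{glmnet} (intercept unpenalized, columns standardized internally,
#' coefficients reported on the original scale).  `alpha = 1` is the LASSO,
#' `alpha = 0` ridge.  For the influence diagnostics an unpenalized logistic
#' refit on the selected support is stored; when that refit is unstable
#' (support size >= n, or separation) the penalized fit is kept and the
#' curvature is ridge-augmented instead, with a warning.
#'
#' @param X numeric matrix, samples x genes.
#' @param y binary response (0/1), both classes present.
#' @param alpha elastic-net mixing in `[0, 1]`.
#' @param lambda penalty strength, a single value >= 0.
#' @param standardize standardize columns inside the solver (default TRUE).
#' @param train_idx rows of `X` actually used for fitting (default all); the
#'   fit remembers them so Cook's distances can be evaluated out of sample.
#' @param model_id label used in influence/rank tables.
#' @return object of class `c("logit_en_fit", "sparse_fit")` with elements
#'   `beta0`, `beta` (length p, original scale), `selected`, `fitted_prob`
#'   (training rows), `hyper`, `refit`, `train_idx`.
#' @export
fit_logit_en <- function(X, y, alpha, lambda, standardize = TRUE,
                         train_idx = NULL, model_id = "logit_en") {
  X <- as.matrix(X)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(X))
  Xt <- X[train_idx, , drop = FALSE]
  yt <- y[train_idx]
  check_binary(yt)
  if (nrow(Xt) < 2) stop("need at least 2 training samples")
  if (length(alpha) != 1 || alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0) {
    stop("lambda must be a single value >= 0")
  }
  # short descending path ending at the target lambda helps glmnet converge
  path <- unique(sort(lambda * c(16, 8, 4, 2, 1), decreasing = TRUE))
  if (lambda == 0) path <- c(0.1, 0.01, 0)
  gfit <- glmnet::glmnet(Xt, yt, family = "binomial", alpha = alpha,
                         lambda = path, standardize = standardize,
                         thresh = 1e-12, maxit = 1e6)
  cf <- as.matrix(stats::coef(gfit, s = lambda, exact = FALSE))
  beta0 <- cf[1, 1]
  beta <- cf[-1, 1]
  names(beta) <- colnames(X)
  selected <- which(abs(beta) > 0)
  fit <- structure(list(
    method = "logit_en", model_id = model_id,
    hyper = list(alpha = alpha, lambda = lambda),
    beta0 = beta0, beta = beta, selected = selected,
    n = length(train_idx), p = ncol(X), train_idx = train_idx,
    converged = TRUE
  ), class = c("logit_en_fit", "sparse_fit"))
  fit$fitted_prob <- clip_prob(stats::plogis(beta0 + drop(Xt %*% beta)))
  fit$refit <- refit_support(Xt, yt, selected,
                             penalized = list(beta0 = beta0, beta = beta,
                                              lambda = lambda, alpha = alpha))
  fit
}

# Unpenalized logistic refit on the selected support (intercept + selected
# genes).  Falls back to the penalized coefficients with a ridged curvature
# when the support is too large or the refit separates.
refit_support <- function(Xt, yt, selected, penalized) {
  m <- length(selected) + 1L
  design <- cbind(1, Xt[, selected, drop = FALSE])
  fallback <- function(reason) {
    warning("unpenalized refit unavailable (", reason,
            "); using penalized fit with ridged curvature for influence")
    ridge <- nrow(Xt) * penalized$lambda * (1 - penalized$alpha)
    list(coef = c(penalized$beta0, penalized$beta[selected]),
         ridge = max(ridge, 1e-8), separation = TRUE)
  }
  if (m >= nrow(Xt)) return(fallback("support size >= n"))
  g <- tryCatch(
    suppressWarnings(stats::glm.fit(design, yt,
                                    family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(g) || !g$converged) return(fallback("no convergence"))
  p <- g$fitted.values
  if (any(p < 1e-8) || any(p > 1 - 1e-8)) return(fallback("separation"))
  list(coef = stats::coef(g), ridge = 0, separation = FALSE)
}

check_binary <- function(y) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  invisible(TRUE)
}

#' Predicted class probabilities
#'
#' Probabilities via the logistic function on the model's coefficient scale.
#' For elastic-net fits this uses the penalized coefficients; for the PLS
#' classifiers the stage-2 logistic model on the latent scores.
#'
#' @param object a `sparse_fit`.
#' @param newdata matrix with the same gene columns as used in fitting.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(object, newdata, ...) UseMethod("predict_proba")

#' @export
predict_proba.logit_en_fit <- function(object, newdata, ...) {
  newdata <- check_scoring_inputs(object, newdata, numeric(nrow(as.matrix(newdata))))
  clip_prob(stats::plogis(object$beta0 + drop(newdata %*% object$beta)))
}

#' @export
predict_proba.splsda_fit <- function(object, newdata, ...) {
  newdata <- check_scoring_inputs(object, newdata, numeric(nrow(as.matrix(newdata))))
  clip_prob(stats::plogis(drop(scores_design(object, newdata) %*% object$stage2$coef)))
}

#' @export
predict_proba.sgpls_fit <- predict_proba.splsda_fit

#' @export
predict.sparse_fit <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "response") p else as.integer(p > 0.5)
}

#' Misclassification count at a probability threshold
#'
#' @param fit a `sparse_fit`.
#' @param X matrix of samples to score.
#' @param y observed binary labels.
#' @param threshold classification threshold (default 0.5).
#' @return integer count of `1[p > threshold] != y`.
#' @export
misclassifications <- function(fit, X, y, threshold = 0.5) {
  p <- predict_proba(fit, X)
  sum(as.integer(p > threshold) != y)
}

#' @export
print.sparse_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, p = %d, %d genes selected\n",
              x$method, x$n, x$p, length(x$selected)))
  hp <- x$hyper
  cat("hyperparameters:",
      paste(names(hp), unlist(hp), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.sparse_fit <- function(object, ...) {
  c(`(Intercept)` = object$beta0, object$beta)
}
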