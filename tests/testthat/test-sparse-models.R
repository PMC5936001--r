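test_that("ridge logistic (alpha = 0) matches an independent Newton oracle", {
  set.seed(3)
  n <- 60; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5 * X[, 2]))
  lam <- 0.05
  fit <- fit_logit_en(X, y, alpha = 0, lambda = lam, standardize = FALSE)
  # oracle: Newton iterations for -mean loglik + lam/2 ||beta||^2
  b <- rep(0, p + 1); Xd <- cbind(1, X)
  for (i in 1:100) {
    pr <- plogis(drop(Xd %*% b)); v <- pr * (1 - pr)
    grad <- -crossprod(Xd, y - pr) / n + lam * c(0, b[-1])
    H <- crossprod(Xd * sqrt(v)) / n + lam * diag(c(0, rep(1, p)))
    b <- b - drop(solve(H, grad))
  }
  expect_lt(max(abs(c(fit$beta0, fit$beta) - b)), 1e-6)
})

test_that("full shrinkage leaves the intercept-only model", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(0:1, 20)
  fit <- fit_logit_en(X, y, alpha = 1, lambda = 10)
  expect_length(fit$selected, 0)
  expect_equal(unname(fit$fitted_prob), rep(mean(y), 40), tolerance = 1e-8)
})

test_that("lasso picks the strongly predictive column among noise", {
  set.seed(5)
  n <- 20
  X <- matrix(rnorm(n * 5), n, 5)
  y <- as.integer(X[, 3] > 0)
  fit <- fit_logit_en(X, y, alpha = 1, lambda = 0.05)
  expect_true(3 %in% fit$selected)
  # coordinate-descent oracle at the same lambda (standardized objective)
  expect_true(which.max(abs(fit$beta)) == 3)
})

test_that("input contracts: single class, negative lambda, feature mismatch", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_logit_en(X, rep(1, 10), alpha = 0.5, lambda = 0.1),
               "both classes")
  expect_error(fit_logit_en(X, rep(0:1, 5), alpha = 0.5, lambda = -1),
               "lambda")
  fit <- fit_logit_en(X, rep(0:1, 5), alpha = 0.5, lambda = 0.1)
  expect_error(predict_proba(fit, matrix(0, 2, 3)), "feature mismatch")
})

test_that("probabilities follow the logistic function of the linear predictor", {
  X <- rbind(c(0, 0), c(10, -10))
  fit <- structure(list(method = "logit_en", beta0 = 0,
                        beta = c(0, 0), selected = integer(0), p = 2,
                        train_idx = 1:2),
                   class = c("logit_en_fit", "sparse_fit"))
  expect_equal(unname(predict_proba(fit, X)), c(0.5, 0.5))
  fit$beta <- c(5, 0)
  p <- predict_proba(fit, X)
  expect_equal(unname(p[1]), 0.5)
  expect_gte(p[2], 1 - 1e-10)  # eta -> +inf saturates towards 1 (clipped)
  expect_equal(misclassifications(fit, X, c(1, 1)), 1)
})

test_that("column permutation permutes the selected set and nothing else", {
  set.seed(6)
  dat <- small_classes(n_per_class = 25, p = 8)
  fit <- fit_logit_en(dat$X, dat$y, alpha = 0.9, lambda = 0.02)
  perm <- sample(ncol(dat$X))
  fit2 <- fit_logit_en(dat$X[, perm], dat$y, alpha = 0.9, lambda = 0.02)
  expect_setequal(colnames(dat$X)[fit$selected],
                  colnames(dat$X[, perm])[fit2$selected])
  expect_equal(fit$beta[colnames(dat$X)[perm]], fit2$beta, tolerance = 1e-6)
})

test_that("elastic-net l1 norm is non-increasing along an increasing lambda path", {
  set.seed(7)
  dat <- small_classes(n_per_class = 25, p = 8)
  lams <- exp(seq(log(1e-3), log(1), length.out = 20))
  l1 <- vapply(lams, function(l) {
    sum(abs(fit_logit_en(dat$X, dat$y, alpha = 0.6, lambda = l)$beta))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("repeated fits are bit-identical (determinism)", {
  dat <- small_classes(n_per_class = 20, p = 6, seed = 8)
  f1 <- fit_logit_en(dat$X, dat$y, alpha = 0.5, lambda = 0.05)
  f2 <- fit_logit_en(dat$X, dat$y, alpha = 0.5, lambda = 0.05)
  expect_identical(f1$beta, f2$beta)
  s1 <- fit_sgpls(dat$X, dat$y, L = 2, alpha_sparsity = 0.5)
  s2 <- fit_sgpls(dat$X, dat$y, L = 2, alpha_sparsity = 0.5)
  expect_identical(s1$beta, s2$beta)
})

test_that("cv_select: single grid point, null data, and separable feature", {
  set.seed(9)
  dat <- small_classes(n_per_class = 25, p = 6)
  one <- cv_select(dat$X, dat$y, "logit_en", alpha_grid = 0.5,
                   lambda_grid = 0.1, folds = 5, seed = 1)
  expect_equal(one$best, list(alpha = 0.5, lambda = 0.1))
  expect_equal(nrow(one$grid), 1L)

  # permuted labels: CV MSE near prevalence * (1 - prevalence) = 0.25
  set.seed(10)
  Xn <- matrix(rnorm(80 * 10), 80, 10)
  yn <- rep(0:1, 40)
  cvn <- cv_select(Xn, yn, "logit_en", alpha_grid = 1,
                   lambda_grid = c(5, 1), folds = 5, seed = 2)
  expect_lt(abs(cvn$best_mse - 0.25), 0.03)

  # perfectly predictive feature: tiny CV MSE
  Xs <- cbind(dat$X, strong = dat$y * 4 + rnorm(50, sd = 0.1))
  cvs <- cv_select(Xs, dat$y, "logit_en", alpha_grid = 1, folds = 5, seed = 3)
  expect_lt(cvs$best_mse, 0.05)

  # folds partition all samples and stratify both classes
  expect_setequal(unique(cvs$fold_id), 1:5)
  expect_true(all(table(cvs$fold_id, dat$y) > 0))
})
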