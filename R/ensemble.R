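#' Default three-member ensemble specification
#'
#' The member set and hyperparameters used for the TNBC analysis: elastic-net
#' logistic regression (alpha = 0.9), SPLS-DA (sparsity 0.8, L = 4) and SGPLS
#' (sparsity 0.7, L = 4).  `lambda = "cv"` selects the elastic-net penalty by
#' 10-fold cross-validation on the full data.
#'
#' @return named list of member specifications for [outlier_ensemble()].
#' @export
default_members <- function() {
  list(
    logit_en = list(method = "logit_en", alpha = 0.9, lambda = "cv"),
    splsda   = list(method = "splsda", alpha = 0.8, L = 4),
    sgpls    = list(method = "sgpls", alpha = 0.7, L = 4)
  )
}

fit_member <- function(name, spec, X, y, cv_folds, seed) {
  method <- spec$method
  fit <- switch(
    method,
    logit_en = {
      lambda <- spec$lambda
      if (identical(lambda, "cv")) {
        cv <- cv_select(X, y, method = "logit_en", alpha_grid = spec$alpha,
                        folds = cv_folds, seed = seed)
        lambda <- cv$best$lambda
      }
      fit_logit_en(X, y, alpha = spec$alpha, lambda = lambda, model_id = name)
    },
    splsda = fit_splsda(X, y, L = spec$L, alpha_sparsity = spec$alpha,
                        model_id = name),
    sgpls = fit_sgpls(X, y, L = spec$L, alpha_sparsity = spec$alpha,
                      model_id = name),
    stop("unknown method: ", method)
  )
  fit
}

#' Fit the model ensemble and call consensus outliers by the Rank Product
#'
#' The core procedure of the package: every member classifier is fitted to
#' the full data, each observation's influence on each member is scored by
#' Cook's distance, the per-member outlierness rankings are combined with the
#' Rank Product statistic ([rp_test()]), and observations with a BH q-value
#' below `q_threshold` are flagged as consensus outliers.  Gene selections of
#' the members are summarized as per-gene selection frequencies, the common
#' set (selected by every member) and the frequent set (frequency above
#' `selection_freq_threshold`).
#'
#' A member that fails to fit aborts the whole ensemble (the number of
#' rankings k defines the null distribution, so members are never silently
#' dropped).
#'
#' @param X samples x genes matrix (rownames used as sample ids).
#' @param y binary response aligned with rows of `X`.
#' @param members named list of member specs (see [default_members()]).
#' @param q_threshold outlier flag threshold on the q-value (default 0.05).
#' @param selection_freq_threshold consensus gene frequency cutoff
#'   (default 0.75).
#' @param pvalue_mode p-value engine passed to [rp_test()].
#' @param cv_folds folds for any member using `lambda = "cv"`.
#' @param seed master seed; member seeds are derived with [derive_seed()].
#' @return object of class `outlier_ensemble`: `fits`, `D` (n x k Cook's
#'   distances), `rp_table`, `consensus` (gene frequencies/sets),
#'   `misclassified` (n x k logical), `outliers` (flagged sample ids).
#' @seealso [run_random_patients()], [run_random_variables()],
#'   [outlier_report()], [relabel_and_refit()]
#' @export
outlier_ensemble <- function(X, y, members = default_members(),
                             q_threshold = 0.05,
                             selection_freq_threshold = 0.75,
                             pvalue_mode = "auto", cv_folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  check_binary(y)
  if (length(members) < 2) stop("an ensemble needs at least 2 members")
  if (is.null(names(members))) names(members) <- paste0("m", seq_along(members))

  fits <- vector("list", length(members))
  names(fits) <- names(members)
  for (j in seq_along(members)) {
    fits[[j]] <- tryCatch(
      fit_member(names(members)[j], members[[j]], X, y,
                 cv_folds = cv_folds, seed = derive_seed(seed, j)),
      error = function(e) stop("ensemble member '", names(members)[j],
                               "' failed: ", conditionMessage(e)))
  }
  infl <- lapply(fits, function(f) cooks_distance_model(f, X, y))
  D <- vapply(infl, function(v) v$D, numeric(nrow(X)))
  dimnames(D) <- list(rownames(X), names(members))
  rp <- rp_test(D, q_threshold = q_threshold, pvalue_mode = pvalue_mode)
  miscl <- vapply(fits, function(f) {
    as.integer(predict_proba(f, X) > 0.5) != y
  }, logical(nrow(X)))
  dimnames(miscl) <- dimnames(D)
  consensus <- consensus_genes(lapply(fits, `[[`, "selected"), ncol(X),
                               colnames(X), selection_freq_threshold)
  structure(list(
    fits = fits, D = D, rp_table = rp, consensus = consensus,
    misclassified = miscl,
    outliers = rp$sample_id[rp$outlier],
    X = X, y = y, seed = seed, q_threshold = q_threshold,
    call = match.call()
  ), class = "outlier_ensemble")
}

# selection frequencies across members/runs; draw_counts allows per-gene
# denominators (feature-bagging, where a gene is only eligible when drawn)
consensus_genes <- function(selected_list, p, gene_ids = NULL,
                            freq_threshold = 0.75, draw_counts = NULL) {
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(p))
  counts <- integer(p)
  for (s in selected_list) counts[s] <- counts[s] + 1L
  if (is.null(draw_counts)) {
    freq <- counts / length(selected_list)
  } else {
    freq <- counts / pmax(draw_counts, 1L)
    freq[draw_counts == 0] <- NA_real_
  }
  common <- if (is.null(draw_counts)) {
    which(counts == length(selected_list))
  } else integer(0)
  structure(list(
    frequency = stats::setNames(freq, gene_ids),
    n_selected_per_member = lengths(selected_list),
    common = gene_ids[common],
    frequent = gene_ids[which(freq > freq_threshold)],
    freq_threshold = freq_threshold
  ), class = "consensus_genes")
}

#' @export
print.consensus_genes <- function(x, ...) {
  cat(sprintf("consensus genes: %d common to all members, %d above frequency %.2f\n",
              length(x$common), length(x$frequent), x$freq_threshold))
  invisible(x)
}

#' @export
print.outlier_ensemble <- function(x, ...) {
  cat("Ensemble model-based outlier detection\n")
  cat(sprintf("  %d samples, %d genes, %d members (%s)\n",
              nrow(x$X), ncol(x$X), length(x$fits),
              paste(names(x$fits), collapse = ", ")))
  cat(sprintf("  %d consensus outliers at q < %g\n",
              length(x$outliers), x$q_threshold))
  invisible(x)
}

#' @export
summary.outlier_ensemble <- function(object, ...) {
  sizes <- vapply(object$fits, function(f) length(f$selected), integer(1))
  mse <- vapply(object$fits, function(f) {
    mean((object$y - predict_proba(f, object$X))^2)
  }, numeric(1))
  miscl <- colSums(object$misclassified)
  out <- list(members = data.frame(member = names(object$fits),
                                   variables_selected = sizes,
                                   mse = mse, misclassifications = miscl,
                                   row.names = NULL),
              n_outliers = length(object$outliers),
              outliers = object$outliers,
              common_genes = object$consensus$common,
              q_threshold = object$q_threshold)
  class(out) <- "summary.outlier_ensemble"
  out
}

#' @export
print.summary.outlier_ensemble <- function(x, ...) {
  cat("Member fits:\n")
  print(x$members, digits = 4)
  cat(sprintf("\n%d consensus outliers at q < %g:\n",
              x$n_outliers, x$q_threshold))
  if (x$n_outliers > 0) print(utils::head(x$outliers, 25))
  cat(sprintf("%d genes selected by every member\n", length(x$common_genes)))
  invisible(x)
}

#' @export
plot.outlier_ensemble <- function(x, ...) {
  rp <- x$rp_table
  idx <- seq_len(nrow(rp))
  plot(idx, rp$log_rp, xlab = "observations sorted by rank product",
       ylab = "log rank product",
       col = ifelse(rp$outlier, "red", "grey40"),
       pch = ifelse(rp$outlier, 17, 1), ...)
  graphics::legend("bottomright", legend = c("outlier (q < threshold)", "regular"),
                   col = c("red", "grey40"), pch = c(17, 1), bty = "n")
  invisible(x)
}

#' Random-patients resampling ensemble
#'
#' Repeatedly fits an elastic-net logistic model to a random subset of
#' patients (drawn without replacement), scores Cook's distance for all
#' patients -- leverages of held-out patients are evaluated against the
#' training information matrix -- and combines the per-run rankings of all n
#' observations with the Rank Product test.
#'
#' @inheritParams outlier_ensemble
#' @param runs number of resampling runs (default 100).
#' @param fraction fraction of patients drawn per run (default 0.8).
#' @param alpha elastic-net mixing (default 0.7).
#' @param lambda penalty; `"cv"` (default) selects it once on the full data
#'   and reuses it across runs.
#' @param min_train minimal training size per draw (default 30); draws
#'   violating it or missing a class are re-drawn.
#' @return object of class `resampling_ensemble` with `rp_table`, `D`
#'   (n x runs), `gene_frequency`, `frequent` genes, `outliers`.
#' @export
run_random_patients <- function(X, y, runs = 100, fraction = 0.8,
                                alpha = 0.7, lambda = "cv",
                                q_threshold = 0.05,
                                selection_freq_threshold = 0.75,
                                min_train = 30, cv_folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  check_binary(y)
  if (runs < 1) stop("runs must be >= 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- nrow(X)
  m <- floor(fraction * n)
  if (m < min_train) stop("fraction * n below the minimal training size")
  if (identical(lambda, "cv")) {
    cv <- cv_select(X, y, method = "logit_en", alpha_grid = alpha,
                    folds = cv_folds, seed = derive_seed(seed, 0L))
    lambda <- cv$best$lambda
  }
  D <- matrix(NA_real_, n, runs, dimnames = list(rownames(X), paste0("run", seq_len(runs))))
  selected <- vector("list", runs)
  for (r in seq_len(runs)) {
    restore <- local_rng(derive_seed(seed, r))
    tr <- NULL
    for (att in 1:50) {
      cand <- sort(sample.int(n, m))
      if (length(unique(y[cand])) == 2) {
        tr <- cand
        break
      }
    }
    restore()
    if (is.null(tr)) stop("could not draw a training set containing both classes")
    fit <- fit_logit_en(X, y, alpha = alpha, lambda = lambda,
                        train_idx = tr, model_id = paste0("run", r))
    D[, r] <- cooks_distance_model(fit, X, y)$D
    selected[[r]] <- fit$selected
  }
  rp <- rp_test(D, q_threshold = q_threshold)
  consensus <- consensus_genes(selected, ncol(X), colnames(X),
                               selection_freq_threshold)
  structure(list(mode = "random_patients", rp_table = rp, D = D,
                 consensus = consensus,
                 mean_selected = mean(lengths(selected)),
                 outliers = rp$sample_id[rp$outlier],
                 runs = runs, fraction = fraction,
                 alpha = alpha, lambda = lambda, seed = seed),
            class = "resampling_ensemble")
}

#' Random-variables (feature bagging) resampling ensemble
#'
#' Repeatedly fits an elastic-net logistic model on all patients using a
#' random gene subset drawn without replacement, scores Cook's distance for
#' all patients, and combines the per-run rankings with the Rank Product
#' test.  Gene selection frequencies are computed over the runs in which the
#' gene was drawn.
#'
#' @inheritParams run_random_patients
#' @param n_features genes drawn per run (default 1000, must be <= p).
#' @return object of class `resampling_ensemble`.
#' @export
run_random_variables <- function(X, y, runs = 100, n_features = 1000,
                                 alpha = 0.7, lambda = "cv",
                                 q_threshold = 0.05,
                                 selection_freq_threshold = 0.75,
                                 cv_folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  check_binary(y)
  p <- ncol(X)
  if (n_features > p) stop("n_features must be <= number of genes")
  if (identical(lambda, "cv")) {
    cv <- cv_select(X, y, method = "logit_en", alpha_grid = alpha,
                    folds = cv_folds, seed = derive_seed(seed, 0L))
    lambda <- cv$best$lambda
  }
  n <- nrow(X)
  D <- matrix(NA_real_, n, runs, dimnames = list(rownames(X), paste0("run", seq_len(runs))))
  selected <- vector("list", runs)
  draw_counts <- integer(p)
  for (r in seq_len(runs)) {
    restore <- local_rng(derive_seed(seed, r))
    feat <- NULL
    for (att in 1:50) {
      cand <- sort(sample.int(p, n_features))
      if (any(apply(X[, cand, drop = FALSE], 2, stats::sd) > 0)) {
        feat <- cand
        break
      }
      warning("degenerate all-constant feature draw; re-drawing")
    }
    restore()
    if (is.null(feat)) stop("could not draw a non-degenerate feature subset")
    draw_counts[feat] <- draw_counts[feat] + 1L
    fit <- fit_logit_en(X[, feat, drop = FALSE], y, alpha = alpha,
                        lambda = lambda, model_id = paste0("run", r))
    D[, r] <- cooks_distance_model(fit, X[, feat, drop = FALSE], y)$D
    selected[[r]] <- feat[fit$selected]
  }
  rp <- rp_test(D, q_threshold = q_threshold)
  consensus <- consensus_genes(selected, p, colnames(X),
                               selection_freq_threshold,
                               draw_counts = draw_counts)
  structure(list(mode = "random_variables", rp_table = rp, D = D,
                 consensus = consensus,
                 mean_selected = mean(lengths(selected)),
                 outliers = rp$sample_id[rp$outlier],
                 runs = runs, n_features = n_features,
                 alpha = alpha, lambda = lambda, seed = seed),
            class = "resampling_ensemble")
}

#' @export
print.resampling_ensemble <- function(x, ...) {
  cat(sprintf("%s resampling ensemble: %d runs, %d outliers flagged\n",
              x$mode, x$runs, length(x$outliers)))
  cat(sprintf("mean number of genes selected per run: %.1f\n",
              x$mean_selected))
  invisible(x)
}

#' Report table for flagged outliers
#'
#' One row per flagged observation, mirroring the structure of a clinical
#' outlier summary: receptor expression (when supplied), receptor labels and
#' HER2 source (when supplied), per-model ranks, rank product, p- and
#' q-value, suspect flag and the fraction of ensemble members that
#' misclassify the observation.  Rows are sorted by ascending rank product.
#'
#' @param ens an `outlier_ensemble`.
#' @param labels optional labels data.frame from [build_tnbc_labels()]
#'   (columns `sample_id`, `y`, `her2_source`, `suspect`).
#' @param receptor_expression optional data.frame/matrix with rownames =
#'   sample ids and receptor expression columns (e.g. ER, PR, HER2).
#' @return data.frame, one row per flagged outlier; samples without clinical
#'   rows get NA fields and a note.
#' @export
outlier_report <- function(ens, labels = NULL, receptor_expression = NULL) {
  stopifnot(inherits(ens, "outlier_ensemble"))
  rp <- ens$rp_table
  flagged <- rp[rp$outlier, , drop = FALSE]
  ranks <- attr(rp, "ranks")[rp$outlier, , drop = FALSE]
  colnames(ranks) <- paste0("rank.", colnames(ranks))
  miscl_frac <- rowMeans(ens$misclassified)[flagged$sample_id]
  rep_df <- data.frame(sample_id = flagged$sample_id, ranks,
                       rp = flagged$rp, p_value = flagged$p_value,
                       q_value = flagged$q_value,
                       misclassified_fraction = unname(miscl_frac),
                       stringsAsFactors = FALSE)
  if (!is.null(receptor_expression)) {
    re <- as.data.frame(receptor_expression)
    rep_df <- cbind(rep_df,
                    re[match(rep_df$sample_id, rownames(re)), , drop = FALSE])
  }
  rep_df$note <- ""
  if (!is.null(labels)) {
    m <- match(rep_df$sample_id, labels$sample_id)
    rep_df$y <- labels$y[m]
    rep_df$her2_source <- labels$her2_source[m]
    rep_df$suspect <- labels$suspect[m]
    rep_df$note[is.na(m)] <- "no clinical row"
  }
  rownames(rep_df) <- NULL
  rep_df
}

#' Flip outlier labels and refit the ensemble
#'
#' Flips the class label of the given samples (typically influential
#' observations suspected of mislabeling), re-runs the ensemble under the
#' same seed and members, and reports the overlap between the original and
#' refit consensus gene sets.
#'
#' @param ens a fitted `outlier_ensemble`.
#' @param flip_ids sample ids whose labels are flipped; unknown ids error.
#' @return list with `refit` (the new `outlier_ensemble`), `flipped_ids`,
#'   `common_gene_overlap` (Jaccard index between the original and refit
#'   common gene sets) and `shared_common_genes`.
#' @export
relabel_and_refit <- function(ens, flip_ids) {
  stopifnot(inherits(ens, "outlier_ensemble"))
  ids <- rownames(ens$X)
  unknown <- setdiff(flip_ids, ids)
  if (length(unknown) > 0) {
    stop("unknown sample ids: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  y2 <- ens$y
  idx <- match(flip_ids, ids)
  y2[idx] <- 1L - y2[idx]
  members <- lapply(ens$fits, function(f) {
    sp <- c(list(method = f$method), f$hyper)
    sp[setdiff(names(sp), c("max_iter", "tol"))]
  })
  refit <- outlier_ensemble(ens$X, y2, members = members,
                            q_threshold = ens$q_threshold, seed = ens$seed)
  a <- ens$consensus$common
  b <- refit$consensus$common
  jac <- if (length(union(a, b)) == 0) 1 else
    length(intersect(a, b)) / length(union(a, b))
  list(refit = refit, flipped_ids = flip_ids,
       common_gene_overlap = jac,
       shared_common_genes = intersect(a, b))
}
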