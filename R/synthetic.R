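#' Simulate a two-class expression matrix with correlated gene blocks
#'
#' Class-conditional multivariate Gaussian data emulating bulk expression on
#' the log scale: genes are organized in blocks with exchangeable
#' within-block correlation `rho` (a one-factor model per block), and the
#' first `n_informative` genes are shifted by `delta` in class 1.  The
#' defaults reproduce the benchmark conditions used throughout the package:
#' 500 observations per class (N = 1000) and an N << p gene space.
#'
#' @param n_per_class observations per class (default 500).
#' @param p number of genes (default 5000).
#' @param n_informative number of genes carrying the class mean shift.
#' @param delta mean shift (in within-class standard deviations) of the
#'   informative genes in class 1.
#' @param block_size genes per correlated block (default 50).
#' @param rho within-block correlation in `[0, 1)`.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return list with `X` (n x p matrix, samples `S0001...` by genes
#'   `G00001...`), `y_true` (0/1), and `config`.
#' @export
simulate_two_class <- function(n_per_class = 500, p = 5000,
                               n_informative = 100, delta = 1,
                               block_size = 50, rho = 0.3, seed = 1) {
  if (n_per_class < 1 || p < 1) stop("invalid sizes")
  if (n_informative > p) stop("n_informative must be <= p")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  restore <- local_rng(seed)
  on.exit(restore())
  n <- 2L * n_per_class
  n_blocks <- ceiling(p / block_size)
  X <- matrix(stats::rnorm(n * p), n, p) * sqrt(1 - rho)
  if (rho > 0) {
    shared <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(p)]
    X <- X + sqrt(rho) * shared[, block_of, drop = FALSE]
  }
  y_true <- rep(c(0L, 1L), each = n_per_class)
  if (n_informative > 0) {
    X[y_true == 1, seq_len(n_informative)] <-
      X[y_true == 1, seq_len(n_informative)] + delta
  }
  dimnames(X) <- list(sprintf("S%04d", seq_len(n)),
                      sprintf("G%05d", seq_len(p)))
  list(X = X, y_true = y_true,
       config = list(n_per_class = n_per_class, p = p,
                     n_informative = n_informative, delta = delta,
                     block_size = block_size, rho = rho, seed = seed))
}

#' Flip a random subset of class labels
#'
#' Marks `round(fraction * n)` uniformly chosen observations as mislabeled by
#' flipping their class; these are the planted outliers of the benchmark.
#'
#' @param y_true binary vector of true labels.
#' @param fraction fraction of labels to flip, in `[0, 0.5]`.
#' @param seed integer seed.
#' @return list with `y_observed`, `flipped_ids` (integer indices).
#' @export
inject_label_flips <- function(y_true, fraction, seed = 1) {
  if (fraction < 0 || fraction > 0.5) stop("fraction must be in [0, 0.5]")
  n <- length(y_true)
  m <- round(fraction * n)
  restore <- local_rng(seed)
  on.exit(restore())
  flipped <- if (m > 0) sort(sample.int(n, m)) else integer(0)
  y_obs <- y_true
  y_obs[flipped] <- 1L - y_obs[flipped]
  list(y_observed = y_obs, flipped_ids = flipped)
}

#' Generate a complete labeled benchmark with planted label-flip outliers
#'
#' Convenience wrapper around [simulate_two_class()] and
#' [inject_label_flips()].
#'
#' @inheritParams simulate_two_class
#' @param flip_fraction fraction of labels flipped (default 0.05).
#' @return object of class `synthetic_truth`: `X`, `y_true`, `y_observed`,
#'   `flipped_ids`, `config`.
#' @export
simulate_study <- function(n_per_class = 500, p = 5000, n_informative = 100,
                           delta = 1, block_size = 50, rho = 0.3,
                           flip_fraction = 0.05, seed = 1) {
  sim <- simulate_two_class(n_per_class, p, n_informative, delta,
                            block_size, rho, seed = seed)
  fl <- inject_label_flips(sim$y_true, flip_fraction,
                           seed = derive_seed(seed, 1L))
  structure(list(X = sim$X, y_true = sim$y_true,
                 y_observed = fl$y_observed, flipped_ids = fl$flipped_ids,
                 config = c(sim$config, flip_fraction = flip_fraction)),
            class = "synthetic_truth")
}

#' Top-k evaluation of an outlier ranking against planted flips
#'
#' For each `k`, counts false positives (top-k observations that were not
#' flipped) and false negatives (flipped observations outside the top k).
#' By construction `FP - FN = k - #flips`; at `k = #flips`, `FP = FN`.
#'
#' @param ranking vector of sample indices or ids ordered from most to least
#'   outlying; must cover all samples.
#' @param flipped_ids indices/ids of the planted outliers.
#' @param n total number of samples.
#' @param k_list cutoffs to evaluate (default `c(25, 50, 100)`).
#' @return data.frame with columns `k`, `false_positives`, `false_negatives`.
#' @export
evaluate_topk <- function(ranking, flipped_ids, n, k_list = c(25, 50, 100)) {
  if (length(ranking) != n || anyDuplicated(ranking)) {
    stop("ranking must cover all n samples exactly once")
  }
  if (any(k_list > n)) stop("k exceeds the number of samples")
  res <- lapply(k_list, function(k) {
    top <- ranking[seq_len(k)]
    fp <- sum(!top %in% flipped_ids)
    fn <- sum(!flipped_ids %in% top)
    data.frame(k = k, false_positives = fp, false_negatives = fn)
  })
  do.call(rbind, res)
}
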