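#' Outlierness ranks from an influence matrix
#'
#' Converts a matrix of Cook's distances (observations in rows, models in
#' columns) into per-model ordinal ranks: rank 1 is the largest distance,
#' i.e. the most outlying observation under that model.  Ties are broken
#' deterministically by ascending row index.
#'
#' @param D numeric matrix (n observations x k models) of finite influence
#'   values.
#' @return integer matrix of the same dimension; each column is a permutation
#'   of `1:n`.  The tie policy is recorded in attribute `tie_policy`.
#' @export
outlierness_ranks <- function(D) {
  D <- as.matrix(D)
  bad <- which(!is.finite(D), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite influence value at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  }
  n <- nrow(D)
  R <- matrix(0L, n, ncol(D), dimnames = dimnames(D))
  for (j in seq_len(ncol(D))) {
    ord <- order(-D[, j], seq_len(n))
    R[ord, j] <- seq_len(n)
  }
  attr(R, "tie_policy") <- "descending value, ties by ascending row index"
  R
}

#' Rank product of one observation's ranks
#'
#' @param ranks integer vector, one rank per model, each in `1..n`.
#' @return the exact integer product (as numeric; exact while below 2^53).
#' @export
rank_product <- function(ranks) {
  ranks <- as.numeric(ranks)
  if (length(ranks) < 1 || any(!is.finite(ranks)) ||
      any(ranks < 1) || any(ranks != floor(ranks))) {
    stop("ranks must be positive integers")
  }
  rp <- prod(ranks)
  if (rp > 2^53) {
    warning("rank product exceeds 2^53; value is no longer an exact integer")
  }
  rp
}

#' Exact null p-value for a rank product
#'
#' Under the null hypothesis that each of the `k` rankings of `n`
#' observations is an independent uniform permutation, the p-value of an
#' observed rank product `rp` is `P(RP <= rp) = C_k(rp) / n^k`, where
#' `C_k(rho)` counts integer tuples in `{1..n}^k` whose product is at most
#' `rho`.  The count is computed by a divisor-blocking dynamic programme,
#' exactly (all intermediate integers stay below 2^53).
#'
#' @param rp numeric vector of rank products, each in `[1, n^k]`.
#' @param n number of observations per ranking.
#' @param k number of rankings.
#' @param budget operation budget for the dynamic programme; exceeded budgets
#'   raise an error (callers such as [rp_test()] fall back to bounds).
#' @return numeric vector of p-values in `(0, 1]`.
#' @seealso [rp_pvalue_bounds()] for large problems.
#' @export
rp_pvalue_exact <- function(rp, n, k, budget = 5e7) {
  stopifnot(length(n) == 1, length(k) == 1, n >= 1, k >= 1)
  if (any(!is.finite(rp)) || any(rp < 1) || any(rp > n^k)) {
    stop("rp out of range [1, n^k]")
  }
  rp_count_tuples(floor(rp), as.integer(n), as.integer(k), budget) / n^k
}

# log of W_k(t) = int_0^t v^(k-1) e^v dv / (k-1)!  (t > 0), via the
# all-positive series sum_j t^(k+j) / ((k-1)! j! (k+j)); stable in log space.
log_wk <- function(t, k) {
  if (t <= 0) return(-Inf)
  lt <- log(t)
  j <- 0:max(50, ceiling(3 * t) + 50)
  terms <- (k + j) * lt - lgamma(k) - lgamma(j + 1) - log(k + j)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

#' Recursive lower/upper bounds and geometric-mean approximation for the
#' rank product null p-value
#'
#' The exact null count `C_k(rho)` is bracketed by two volumes obtained from
#' the recursion `C_k(rho) = sum_r C_{k-1}(floor(rho/r))` by replacing the sum
#' over integer ranks with integrals: the upper bound is the volume of
#' `{x in [0,n]^k : prod x_j <= rho}` (closed form, a regularized incomplete
#' gamma function) and the lower bound the volume of
#' `{x in [1,n+1]^k : prod x_j <= rho}` (inclusion-exclusion over the box,
#' evaluated in log space).  The reported approximation is the geometric mean
#' of the two bounds.  When the alternating inclusion-exclusion sum loses too
#' much precision (large `k` at mid-range products) the lower bound falls back
#' to the elementary count bound `min(n, floor(rp)) / n^k`, which is crude but
#' valid; see [rp_test()] for the convolution engine used in that regime.
#'
#' @inheritParams rp_pvalue_exact
#' @return data.frame with columns `lower`, `upper`, `approx` (p-value scale).
#' @export
rp_pvalue_bounds <- function(rp, n, k) {
  stopifnot(length(n) == 1, length(k) == 1, n >= 1, k >= 1)
  if (any(!is.finite(rp)) || any(rp < 1)) stop("rp out of range [1, n^k]")
  lognk <- k * log(n)
  if (any(log(rp) > lognk + 1e-9)) stop("rp out of range [1, n^k]")
  one <- function(r) {
    s <- log(r)
    if (s >= lognk - 1e-12) return(c(1, 1, 1))
    # upper: P(Gamma(k) >= k log n - s)
    log_upper <- stats::pgamma(lognk - s, shape = k,
                               lower.tail = FALSE, log.p = TRUE)
    # lower: inclusion-exclusion volume on [1, n+1]^k
    cc <- log(n + 1)
    mmax <- min(k, floor(s / cc))
    lp <- -Inf  # log of positive part
    ln <- -Inf  # log of negative part
    for (m in 0:mmax) {
      tm <- s - m * cc
      if (tm <= 0) next
      lt <- lchoose(k, m) + m * cc + log_wk(tm, k)
      if (m %% 2 == 0) lp <- logsumexp2(lp, lt) else ln <- logsumexp2(ln, lt)
    }
    log_vol <- if (is.infinite(lp)) {
      -Inf
    } else if (ln >= lp) {
      -Inf
    } else {
      lp + log1p(-exp(ln - lp))
    }
    # cancellation guard: require ~1e-6 relative headroom against 2^-52
    unstable <- is.finite(lp) && is.finite(log_vol) && (lp - log_vol > 23)
    log_lower_vol <- if (unstable) -Inf else log_vol - lognk
    log_lower_floor <- log(min(n, floor(r))) - lognk
    log_lower <- max(log_lower_vol, log_lower_floor, na.rm = TRUE)
    log_lower <- min(log_lower, log_upper)
    c(exp(log_lower), exp(log_upper), exp((log_lower + log_upper) / 2))
  }
  out <- t(vapply(rp, one, numeric(3)))
  data.frame(lower = out[, 1], upper = out[, 2], approx = out[, 3])
}

logsumexp2 <- function(a, b) {
  if (is.infinite(a) && a < 0) return(b)
  if (is.infinite(b) && b < 0) return(a)
  m <- max(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# Bracketing p-values for large k by k-fold FFT convolution of the pmf of
# log(rank), rounded down (upper bound on p) or up (lower bound) to a grid of
# width h.  Absolute accuracy is limited by FFT noise (~1e-11); below that the
# conservative continuous upper bound is used as the working p-value.
rp_pvalue_conv <- function(log_rp, n, k, h = NULL) {
  if (is.null(h)) h <- min(0.05 / k, 1e-3)
  gmax <- ceiling(log(n) / h) + 1L
  need <- k * gmax + 1
  N <- 2^ceiling(log2(need))
  h <- h  # grid fixed; need recomputed sizes consistent
  lg <- log(seq_len(n))
  pmf_of <- function(g) {
    v <- numeric(N)
    tb <- table(g)
    v[as.integer(names(tb)) + 1L] <- as.numeric(tb) / n
    v
  }
  cdf_k <- function(pmf) {
    Fz <- stats::fft(pmf)
    dist <- Re(stats::fft(Fz^k, inverse = TRUE)) / N
    dist[dist < 0] <- 0
    cumsum(dist)
  }
  cdf_dn <- cdf_k(pmf_of(floor(lg / h)))
  cdf_up <- cdf_k(pmf_of(ceiling(lg / h)))
  idx <- pmin(N, floor(log_rp / h) + 1L)
  upper <- pmin(1, cdf_dn[idx])
  lower <- pmin(upper, cdf_up[idx])
  # continuous gamma upper bound, reliable at any magnitude
  log_gu <- stats::pgamma(k * log(n) - log_rp, shape = k,
                          lower.tail = FALSE, log.p = TRUE)
  upper <- pmin(upper, exp(log_gu))
  floorp <- 1e-9
  unreliable <- upper < floorp | lower < floorp
  approx <- sqrt(lower * upper)
  approx[unreliable] <- exp(log_gu[unreliable])
  lower[unreliable] <- NA_real_
  upper[unreliable] <- exp(log_gu[unreliable])
  data.frame(lower = lower, upper = upper, approx = approx)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: p-values are sorted ascending,
#' `q_(i) = min_(j >= i) p_(j) * m / j` clipped at 1, and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return numeric vector of q-values, same order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Rank Product consensus test for outlying observations
#'
#' Full pipeline from an influence matrix to a consensus outlier table:
#' per-model outlierness ranks, rank products, null p-values, BH q-values and
#' an outlier flag at `q < q_threshold`.
#'
#' The null p-value engine is selected by `pvalue_mode`:
#' \describe{
#'   \item{exact}{dynamic-programming count (requires `n^k < 2^53` and a
#'     bounded DP cost).}
#'   \item{bounds_geomean}{geometric mean of the recursive lower/upper
#'     bounds ([rp_pvalue_bounds()]).}
#'   \item{auto}{exact when feasible within the DP budget; otherwise the
#'     bound-based approximation for small `k`, and for large `k` (for
#'     example 100-run resampling ensembles) a bracketing FFT convolution of
#'     the log-rank null distribution.}
#' }
#'
#' @param D numeric matrix (n x k) of Cook's distances, k >= 2.
#' @param q_threshold flag observations with q-value strictly below this
#'   (default 0.05).
#' @param pvalue_mode one of `"auto"`, `"exact"`, `"bounds_geomean"`.
#' @param dp_budget operation budget for the exact engine in auto mode.
#' @return data.frame of class `rp_table`, rows sorted by ascending rank
#'   product (ties by sample index), with columns `sample_id`, `rp`,
#'   `log_rp`, `p_value`, `q_value`, `outlier`.  The full rank matrix is in
#'   `attr(, "ranks")`, the engine used in `attr(, "pvalue_engine")`.
#' @export
rp_test <- function(D, q_threshold = 0.05,
                    pvalue_mode = c("auto", "exact", "bounds_geomean"),
                    dp_budget = 5e7) {
  pvalue_mode <- match.arg(pvalue_mode)
  D <- as.matrix(D)
  n <- nrow(D)
  k <- ncol(D)
  if (k < 2) stop("rp_test needs at least 2 models (columns)")
  R <- outlierness_ranks(D)
  log_rp <- rowSums(log(R))
  rp <- exp(log_rp)
  exactable <- k * log(n) < 53 * log(2)
  if (exactable) rp <- round(apply(R, 1, prod))  # exact integer product

  engine <- pvalue_mode
  p <- NULL
  if (pvalue_mode %in% c("auto", "exact")) {
    if (exactable) {
      p <- tryCatch(rp_pvalue_exact(rp, n, k, budget = dp_budget),
                    error = function(e) NULL)
    }
    if (is.null(p) && pvalue_mode == "exact") {
      stop("exact rank-product p-values infeasible for this (n, k)")
    }
    if (!is.null(p)) engine <- "exact"
  }
  if (is.null(p)) {
    if (k <= 20) {
      b <- rp_pvalue_bounds(exp(log_rp), n, k)
      p <- b$approx
      engine <- "bounds_geomean"
    } else {
      b <- rp_pvalue_conv(log_rp, n, k)
      p <- b$approx
      engine <- "conv_bracket"
    }
  }
  p <- pmin(1, pmax(p, .Machine$double.xmin))
  q <- fdr_bh(p)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(log_rp, seq_len(n))
  out <- data.frame(sample_id = ids, rp = rp, log_rp = log_rp,
                    p_value = p, q_value = q,
                    outlier = q < q_threshold,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  attr(out, "ranks") <- R[ord, , drop = FALSE]
  attr(out, "n") <- n
  attr(out, "k") <- k
  attr(out, "pvalue_engine") <- engine
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("rp_table", "data.frame")
  out
}

#' @export
print.rp_table <- function(x, max_rows = 10L, ...) {
  cat(sprintf("Rank Product outlier table: n = %d observations, k = %d models (p-values: %s)\n",
              attr(x, "n"), attr(x, "k"), attr(x, "pvalue_engine")))
  cat(sprintf("%d observations flagged at q < %g\n",
              sum(x$outlier), attr(x, "q_threshold")))
  print.data.frame(utils::head(x, max_rows), digits = 4)
  if (nrow(x) > max_rows) cat("...", nrow(x) - max_rows, "more rows\n")
  invisible(x)
}
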