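# Programmatic fixtures shared across test files.

# tiny expression table on disk (samples x genes unless transpose = TRUE)
write_expr_file <- function(values, sample_ids, gene_ids, sep = "\t",
                            transpose = FALSE, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  if (transpose) {
    df <- data.frame(gene_id = gene_ids, t(values), check.names = FALSE)
    colnames(df) <- c("gene_id", sample_ids)
  } else {
    df <- data.frame(sample_id = sample_ids, values, check.names = FALSE)
    colnames(df) <- c("sample_id", gene_ids)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# clinical rows covering the receptor-status codes
clin_row <- function(id, er = "negative", pr = "negative", level = NA,
                     ihc = NA, fish = NA) {
  data.frame(sample_id = id, er_status = er, pr_status = pr,
             her2_ihc_level = level, her2_ihc_status = ihc,
             her2_fish = fish, stringsAsFactors = FALSE)
}

# two-class Gaussian training set with a handful of informative genes
small_classes <- function(n_per_class = 30, p = 10, delta = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(0:1, each = n_per_class)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + delta
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  colnames(X) <- sprintf("G%03d", seq_len(p))
  list(X = X, y = y)
}

# brute-force rank-product null counts by full enumeration
brute_rp_count <- function(rho, n, k) {
  prods <- apply(expand.grid(rep(list(seq_len(n)), k)), 1, prod)
  vapply(rho, function(r) sum(prods <= r), numeric(1))
}
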