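# Shared fixtures and independent oracles used across the test files.

# tiny count matrix: counts named by gene/sample, conditions in column order
make_cm <- function(counts, condition, replicate = NULL) {
  count_matrix(counts, condition, replicate)
}

# matrix with auto gene/sample names
named_matrix <- function(values, nrow, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = nrow)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_tmp <- function(df, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

# Independent GSEA enrichment-score oracle: the full N-step running-sum walk.
es_walk_oracle <- function(scores, members, weight_p = 1) {
  hit <- names(scores) %in% members
  w <- abs(scores)^weight_p
  w[!hit] <- 0
  if (sum(w) > 0) w <- w / sum(w) else w[hit] <- 1 / sum(hit)
  miss <- 1 / (length(scores) - sum(hit))
  run <- cumsum(ifelse(hit, w, -miss))
  hi <- max(run); lo <- min(run)
  # same tolerance-based tie rule as the implementation: exact |max| == |min|
  # ties (symmetric walks) go to the positive deviation
  if (hi >= -lo - 1e-9) hi else lo
}

# Independent TMM oracle: explicit enumeration of the doubly trimmed gene set
# by sorting (order statistics), then the precision-weighted mean of M values.
tmm_oracle <- function(y, trim_m = 0.3, trim_a = 0.05) {
  N <- colSums(y)
  uq <- apply(sweep(y, 2, N, "/"), 2, function(col) quantile(col, 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(k) {
    if (k == ref) return(1)
    ok <- y[, k] > 0 & y[, ref] > 0
    yk <- y[ok, k]; yr <- y[ok, ref]
    M <- log2((yk / N[k]) / (yr / N[ref]))
    A <- 0.5 * log2((yk / N[k]) * (yr / N[ref]))
    n <- length(M)
    keepM <- order(M)[(floor(n * trim_m) + 1):(n - floor(n * trim_m))]
    keepA <- order(A)[(floor(n * trim_a) + 1):(n - floor(n * trim_a))]
    keep <- intersect(keepM, keepA)
    w <- 1 / ((N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr))
    2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# small config used by several simulation-style tests
small_config <- function(seed, n_genes = 2000, bias_sd = 0, gc_bias_sd = 0,
                         blocks = list(), de = list(), reps = c(a = 3, b = 3)) {
  synth_config(n_genes = n_genes, conditions = reps, bias_sd = bias_sd,
               gc_bias_sd = gc_bias_sd, block_specs = blocks, de_specs = de,
               seed = seed)
}

# log2 cpm expression matrix helper
log2_cpm <- function(cm, offset = 0.5) {
  expr_matrix(log2(as.matrix(cpm(cm)) + offset), "log2")
}

# strip expr_matrix class/attributes for comparison against plain matrices
as_plain <- function(e) {
  matrix(as.numeric(e), nrow(e), ncol(e), dimnames = dimnames(e))
}
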