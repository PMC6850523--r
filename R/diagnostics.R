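# Bias diagnostics: length/GC vs fold-change correlation, all-pairs replicate
# scanning, and length-bin expression profiles.

#' Spearman correlation with a t-approximation p-value
#'
#' Rho is Pearson correlation of average ranks (ties allowed); the two-sided
#' p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. `rho = +/-1` is reported with the smallest positive double rather
#' than 0.
#'
#' @param x,y numeric vectors of equal length `n >= 5`.
#' @return A list with elements `rho` and `p`.
#' @export
spearman_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 5) stop("need n >= 5")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rho undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
    if (p == 0) p <- .Machine$double.xmin
  }
  list(rho = rho, p = p)
}

#' Test the coupling between a gene covariate and fold change
#'
#' Computes Spearman correlation (with t-approximation p-value) between the
#' gene covariate -- length on the log10 scale for reporting; the rank
#' statistic is unaffected by any monotone transform -- and log2 fold change.
#' The comparison is flagged as biased when `p < flag_p` (default `1e-8`).
#'
#' @param fc a [log2_fold_change()] table.
#' @param ann a [gene_annotation()] covering all fc genes.
#' @param covariate `"length"` or `"gc"`.
#' @param flag_p flagging threshold on the p-value.
#' @return A one-row data.frame of class `bias_report` with columns
#'   `comparison_label`, `covariate`, `rho`, `p`, `n_genes`, `flagged`.
#' @export
length_fc_bias <- function(fc, ann, covariate = c("length", "gc"),
                           flag_p = 1e-8) {
  covariate <- match.arg(covariate)
  idx <- match(fc$gene_id, ann$gene_id)
  if (anyNA(idx))
    stop("missing annotation for gene: ",
         paste(head(fc$gene_id[is.na(idx)], 5), collapse = ", "))
  v <- if (covariate == "length") log10(ann$length_bp[idx])
       else ann$gc_fraction[idx]
  if (anyNA(v)) stop("covariate '", covariate, "' has missing values")
  n <- nrow(fc)
  if (n < 100)
    warning("fewer than 100 genes (", n, "); bias report is unreliable")
  st <- spearman_with_p(v, fc$log2_fc)
  structure(data.frame(comparison_label = fc$comparison_label[1],
                       covariate = covariate,
                       rho = st$rho, p = st$p,
                       n_genes = n,
                       flagged = st$p < flag_p,
                       stringsAsFactors = FALSE),
            class = c("bias_report", "data.frame"))
}

#' Scan all within-condition replicate pairs for length bias
#'
#' Normalizes the counts once with the chosen scheme, computes a
#' single-sample vs single-sample fold change for every unordered pair of
#' replicates within each condition, and reports the length--fold-change
#' Spearman correlation per pair. Output is sorted by `|rho|` descending
#' (ties broken by the lexicographic sample-id pair), so the first row is
#' the strongest pair.
#'
#' @param counts a [count_matrix()] with at least one condition having >= 2
#'   replicates.
#' @param ann a [gene_annotation()].
#' @param normalizer normalization scheme, see [normalize_counts()].
#' @param flag_p flagging threshold (default `1e-8`).
#' @param pseudocount fold-change pseudocount for linear-scale schemes.
#' @param ... further arguments to [normalize_counts()].
#' @return A data.frame with one row per pair: `comparison_label`,
#'   `condition`, `sample_a`, `sample_b`, `covariate`, `rho`, `p`,
#'   `n_genes`, `flagged`.
#' @export
replicate_pair_scan <- function(counts, ann, normalizer = "rpkm",
                                flag_p = 1e-8, pseudocount = 1.0, ...) {
  stopifnot(inherits(counts, "count_matrix"))
  smp <- counts$samples
  conds <- unique(smp$condition)
  pairs <- list()
  for (cond in conds) {
    ids <- sort(smp$sample_id[smp$condition == cond])
    if (length(ids) < 2) next
    cmb <- combn(ids, 2)
    for (j in seq_len(ncol(cmb)))
      pairs[[length(pairs) + 1]] <- list(cond = cond, a = cmb[1, j], b = cmb[2, j])
  }
  if (!length(pairs))
    stop("no condition has >= 2 replicate samples")

  expr <- normalize_counts(counts, ann, normalizer, ...)
  rows <- lapply(pairs, function(p) {
    fc <- log2_fold_change(expr, p$a, p$b, pseudocount = pseudocount)
    rep <- length_fc_bias(fc, ann, "length", flag_p)
    cbind(data.frame(condition = p$cond, sample_a = p$a, sample_b = p$b,
                     stringsAsFactors = FALSE),
          rep[, c("comparison_label", "covariate", "rho", "p",
                  "n_genes", "flagged")])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$rho), out$sample_a, out$sample_b), ]
  rownames(out) <- NULL
  out
}

#' Length-bin expression profile for two samples
#'
#' Genes are sorted by annotated length (ties by gene id) and partitioned
#' into `n_bins` contiguous bins whose sizes differ by at most one (larger
#' bins first). Per bin: the mean length and the quartiles of each sample's
#' expression and of their difference (a - b).
#'
#' @param expr an [expr_matrix()] on the log2 scale.
#' @param sample_a,sample_b column ids of `expr`.
#' @param ann a [gene_annotation()].
#' @param n_bins number of bins (default 10; must be <= number of genes).
#' @return A data.frame with one row per bin: `bin`, `n_genes`,
#'   `mean_length`, quartiles `a_q25/a_q50/a_q75`, `b_q25/b_q50/b_q75`,
#'   `d_q25/d_q50/d_q75`.
#' @export
length_bin_profile <- function(expr, sample_a, sample_b, ann, n_bins = 10) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr_scale(expr) != "log2")
    stop("length_bin_profile expects log2-scale expression")
  if (n_bins < 2) stop("n_bins must be >= 2")
  genes <- rownames(expr)
  n <- length(genes)
  if (n_bins > n) stop("n_bins exceeds the number of genes")
  idx <- match(genes, ann$gene_id)
  if (anyNA(idx)) stop("missing annotation for some genes")
  L <- ann$length_bp[idx]
  ord <- order(L, genes)

  base <- n %/% n_bins; extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)

  a <- expr[ord, sample_a]; b <- expr[ord, sample_b]; Ls <- L[ord]
  qs <- function(v) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- lapply(seq_len(n_bins), function(k) {
    i <- bin == k
    data.frame(bin = k, n_genes = sum(i), mean_length = mean(Ls[i]),
               t(setNames(qs(a[i]), c("a_q25", "a_q50", "a_q75"))),
               t(setNames(qs(b[i]), c("b_q25", "b_q50", "b_q75"))),
               t(setNames(qs(a[i] - b[i]), c("d_q25", "d_q50", "d_q75"))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
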