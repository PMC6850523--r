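# Between-sample normalization: RPKM/CPM, quantile normalization, TMM/RLE/UQ
# scale factors, and the covariate-aware corrector for per-sample length/GC
# effects.

#' Construct a set of per-sample scale factors
#'
#' Factors multiply library sizes: the effective library size of sample `s`
#' is `N_s * factor_s`. By convention every factor set is rescaled so its
#' geometric mean is 1.
#'
#' @param factors positive numeric vector named by sample id.
#' @param method method tag (e.g. `"tmm"`).
#' @return A named numeric vector of class `scale_factors`.
#' @export
scale_factors <- function(factors, method = "custom") {
  if (is.null(names(factors))) stop("factors must be named by sample id")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("scale factors must be finite and > 0")
  f <- factors / exp(mean(log(factors)))
  structure(f, method = method, class = "scale_factors")
}

#' Reads per kilobase of transcript length per million mapped reads
#'
#' `rpkm(g, s) = counts(g, s) * 1e9 / (N_s * L_g)` with `L_g` the
#' principal-transcript length in base pairs.
#'
#' @param counts a [count_matrix()].
#' @param ann a [gene_annotation()] covering every gene in `counts`.
#' @return An [expr_matrix()] on the linear scale.
#' @export
rpkm <- function(counts, ann) {
  stopifnot(inherits(counts, "count_matrix"))
  L <- setNames(ann$length_bp, ann$gene_id)[rownames(counts$counts)]
  if (anyNA(L))
    stop("missing length for gene: ",
         paste(head(rownames(counts$counts)[is.na(L)], 5), collapse = ", "))
  N <- counts$samples$lib_size
  if (any(N <= 0)) stop("zero library size")
  expr_matrix(sweep(counts$counts, 2, N / 1e9, "/") / L, "linear")
}

#' Quantile normalization
#'
#' Forces every column to share the same distribution: the reference is the
#' row-wise mean of the column-sorted matrix, and each column's values are
#' replaced by reference values according to their within-column ranks. A
#' group of `k` tied values receives the mean of the `k` reference values
#' their rank positions span, so within-column order is preserved.
#'
#' @param expr an [expr_matrix()] (or plain matrix) with >= 2 columns.
#' @return The normalized matrix; `expr_matrix` scale is preserved.
#' @export
quantile_normalize <- function(expr) {
  x <- as.matrix(expr)
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "min")
    # mean of the reference values each tie group spans
    cnt <- table(r)
    spanned <- vapply(as.integer(names(cnt)), function(p)
      mean(ref[p:(p + cnt[[as.character(p)]] - 1L)]), numeric(1))
    spanned[match(r, as.integer(names(cnt)))]
  })
  dimnames(out) <- dimnames(x)
  if (inherits(expr, "expr_matrix")) expr_matrix(out, expr_scale(expr)) else out
}

# Reference sample for TMM: the column whose upper quartile of scaled counts
# is closest to the mean upper quartile.
.tmm_ref <- function(y, N) {
  uq <- apply(sweep(y, 2, N, "/"), 2, quantile, probs = 0.75)
  which.min(abs(uq - mean(uq)))
}

#' Trimmed mean of M-values scale factors
#'
#' Per sample `k` against the reference sample `r` (chosen as the column
#' whose upper quartile of library-scaled counts is closest to the mean upper
#' quartile), over genes positive in both samples:
#' `M_g = log2((y_gk/N_k)/(y_gr/N_r))` and
#' `A_g = 0.5 * log2((y_gk/N_k)*(y_gr/N_r))`. After dropping the top and
#' bottom `trim_m` fraction of genes by M and `trim_a` by A (ranks
#' `floor(n*trim)+1 .. n-floor(n*trim)` are kept, ties resolved in first-seen
#' order), the factor is `2^` the precision-weighted mean of the remaining
#' `M_g`, with weights the inverse of
#' `(N_k - y_gk)/(N_k*y_gk) + (N_r - y_gr)/(N_r*y_gr)` (delta-method
#' variance of M). Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix()] with >= 2 samples.
#' @param trim_m fraction trimmed from each tail by M (default 0.3).
#' @param trim_a fraction trimmed from each tail by A (default 0.05).
#' @return A [scale_factors()] vector.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  y <- counts$counts
  if (ncol(y) < 2) stop("TMM needs >= 2 samples")
  N <- counts$samples$lib_size
  ref <- .tmm_ref(y, N)
  f <- vapply(seq_len(ncol(y)), function(k) {
    if (k == ref) return(1)
    ok <- y[, k] > 0 & y[, ref] > 0
    yk <- y[ok, k]; yr <- y[ok, ref]
    M <- log2((yk / N[k]) / (yr / N[ref]))
    A <- 0.5 * log2((yk / N[k]) * (yr / N[ref]))
    n <- length(M)
    loM <- floor(n * trim_m) + 1L; hiM <- n - floor(n * trim_m)
    loA <- floor(n * trim_a) + 1L; hiA <- n - floor(n * trim_a)
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(keep) < 10)
      stop("fewer than 10 genes remain after TMM trimming; ",
           "consider smaller trim_m/trim_a")
    w <- 1 / ((N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr))
    2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  }, numeric(1))
  scale_factors(setNames(f, colnames(y)), "tmm")
}

#' Relative log expression scale factors
#'
#' Per sample, the median over all-positive genes of
#' `y_gs / geomean_g`, where `geomean_g` is the gene's geometric mean count
#' across samples. Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix()].
#' @return A [scale_factors()] vector.
#' @export
rle_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  y <- counts$counts
  allpos <- rowSums(y <= 0) == 0
  if (!any(allpos))
    stop("RLE needs at least one gene with positive counts in all samples")
  gm <- exp(rowMeans(log(y[allpos, , drop = FALSE])))
  f <- apply(y[allpos, , drop = FALSE] / gm, 2, median)
  scale_factors(setNames(f, colnames(y)), "rle")
}

#' Upper-quartile scale factors
#'
#' Per sample, the 75th percentile of the nonzero counts divided by the
#' library size (percentile by linear interpolation between order
#' statistics, R quantile type 7). Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix()]; every sample needs >= 4 nonzero counts.
#' @return A [scale_factors()] vector.
#' @export
uq_factors <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  y <- counts$counts
  N <- counts$samples$lib_size
  f <- vapply(seq_len(ncol(y)), function(s) {
    nz <- y[y[, s] > 0, s]
    if (length(nz) < 4)
      stop("sample ", colnames(y)[s], " has fewer than 4 nonzero counts")
    quantile(nz, probs = 0.75, names = FALSE, type = 7) / N[s]
  }, numeric(1))
  scale_factors(setNames(f, colnames(y)), "uq")
}

#' Apply scale factors, producing CPM- or RPKM-style expression
#'
#' Recomputes [cpm()] (or [rpkm()] when an annotation is supplied) using the
#' effective library sizes `N_s * factor_s`.
#'
#' @param counts a [count_matrix()].
#' @param factors a [scale_factors()] vector covering all samples.
#' @param ann optional [gene_annotation()]; when given, values are on the
#'   RPKM scale (per kilobase).
#' @return An [expr_matrix()] on the linear scale.
#' @export
apply_factors <- function(counts, factors, ann = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  missing <- setdiff(colnames(counts$counts), names(factors))
  if (length(missing))
    stop("factors missing for sample: ", paste(missing, collapse = ", "))
  eff <- counts$samples$lib_size *
    as.numeric(factors[colnames(counts$counts)])
  if (is.null(ann)) {
    expr_matrix(sweep(counts$counts, 2, eff / 1e6, "/"), "linear")
  } else {
    L <- setNames(ann$length_bp, ann$gene_id)[rownames(counts$counts)]
    if (anyNA(L)) stop("missing length for gene: ",
                       paste(head(rownames(counts$counts)[is.na(L)], 5), collapse = ", "))
    expr_matrix(sweep(counts$counts, 2, eff / 1e9, "/") / L, "linear")
  }
}

# Huber M-estimation of y on a fixed design matrix by iteratively reweighted
# least squares (tuning constant 1.345 x median absolute residual). Robust to
# the minority of truly differential genes when fitting per-sample systematic
# covariate curves, while keeping near least-squares efficiency -- a pure
# median (L1) fit is too noisy at the sparse covariate extremes to meet the
# r < 0.05 removal criterion.
.huber_fit <- function(X, y, max_iter = 30, tol = 1e-8) {
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  for (i in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- median(abs(r))
    if (s <= 0) break
    k <- 1.345 * s
    w <- pmin(1, k / pmax(abs(r), 1e-12))
    bnew <- lm.wfit(X, y, w = w)$coefficients
    bnew[is.na(bnew)] <- 0
    if (max(abs(bnew - beta)) < tol) { beta <- bnew; break }
    beta <- bnew
  }
  beta
}

#' Covariate-aware normalization removing per-sample length/GC effects
#'
#' For each sample `s`, a Huber-robust regression of `log2(count + 0.5)` on
#' natural cubic spline transforms of the selected gene-level covariates
#' (log10 length, GC fraction; internal knots at equally spaced quantiles,
#' boundary knots at the 2.5th/97.5th covariate percentiles so the fit is
#' linear through the sparse covariate tails) estimates the sample's
#' systematic covariate curve `h_s(g)`. The corrected
#' value is `log2(count + 0.5) - (h_s(g) - hbar(g))`, with `hbar` the
#' across-sample mean fitted curve, so only the *sample-specific* part of the
#' covariate effect is removed and the average length/GC trend of the data is
#' left intact. A full quantile normalization across samples follows.
#'
#' The 0.5 log offset is internal to the corrector and distinct from the
#' fold-change pseudocount of [log2_fold_change()].
#'
#' @param counts a [count_matrix()].
#' @param ann a [gene_annotation()]; must carry `gc_fraction` when `"gc"` is
#'   requested.
#' @param covariates subset of `c("length", "gc")`.
#' @param n_knots number of internal spline knots (default 5), placed at
#'   equally spaced quantiles of each covariate.
#' @return A list with elements `expr` (an [expr_matrix()], log2 scale) and
#'   `fit` (class `covariate_fit`: per-sample coefficients, knot locations,
#'   and per-sample median absolute residuals).
#' @export
covariate_normalize <- function(counts, ann, covariates = c("length"),
                                n_knots = 5) {
  stopifnot(inherits(counts, "count_matrix"))
  covariates <- match.arg(covariates, c("length", "gc"), several.ok = TRUE)
  idx <- match(rownames(counts$counts), ann$gene_id)
  if (anyNA(idx))
    stop("missing annotation for gene: ",
         paste(head(rownames(counts$counts)[is.na(idx)], 5), collapse = ", "))

  cov_values <- list()
  if ("length" %in% covariates)
    cov_values$length <- log10(ann$length_bp[idx])
  if ("gc" %in% covariates) {
    gc <- ann$gc_fraction[idx]
    if (anyNA(gc)) stop("covariate 'gc' requested but gc_fraction is missing")
    cov_values$gc <- gc
  }

  basis <- list(); knots <- list()
  for (nm in names(cov_values)) {
    v <- cov_values[[nm]]
    if (length(unique(v)) < 2) stop("covariate '", nm, "' is constant")
    bk <- quantile(v, c(0.025, 0.975), names = FALSE)
    if (bk[1] >= bk[2]) bk <- range(v)
    kn <- unique(quantile(v, probs = seq_len(n_knots) / (n_knots + 1),
                          names = FALSE))
    kn <- kn[kn > bk[1] & kn < bk[2]]
    basis[[nm]] <- splines::ns(pmin(pmax(v, bk[1]), bk[2]), knots = kn,
                               Boundary.knots = bk)
    knots[[nm]] <- list(internal = kn, boundary = bk)
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, unname(basis)))

  y <- log2(counts$counts + 0.5)
  S <- ncol(y)
  # Fit each sample's systematic curve on the deviation from the gene's
  # cross-sample mean: the (large) between-gene baseline heterogeneity
  # cancels, so the per-sample curves are estimated with far less noise --
  # crucial at the sparse covariate extremes, where curve-estimation error
  # would otherwise act like a coordinated shift of the extreme-length genes.
  dev <- y - rowMeans(y)
  coefs <- matrix(0, ncol(X), S,
                  dimnames = list(NULL, colnames(y)))
  H <- matrix(0, nrow(y), S, dimnames = dimnames(y))
  for (s in seq_len(S)) {
    beta <- .huber_fit(X, dev[, s])
    coefs[, s] <- beta
    H[, s] <- drop(X %*% beta)
  }
  hbar <- rowMeans(H)
  corrected <- y - (H - hbar)
  out <- quantile_normalize(expr_matrix(corrected, "log2"))

  fit <- structure(list(coefficients = coefs,
                        covariates = covariates,
                        knots = knots,
                        residual_mad = apply(abs(y - H), 2, median)),
                   class = "covariate_fit")
  list(expr = out, fit = fit)
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat("covariate_fit: covariates =", paste(x$covariates, collapse = ", "),
      "| samples =", ncol(x$coefficients), "\n")
  cat("median |residual| per sample:",
      paste(sprintf("%.3f", x$residual_mad), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize a count matrix by a named scheme
#'
#' Dispatcher used by the diagnostics scan and the pipeline. Linear schemes
#' return linear-scale expression; `"covariate"` returns the log2-scale
#' corrected matrix of [covariate_normalize()].
#'
#' @param counts a [count_matrix()].
#' @param ann a [gene_annotation()] (required by all length-aware schemes).
#' @param method one of `"cpm"`, `"rpkm"`, `"rpkm-qnorm"`, `"tmm"`, `"rle"`,
#'   `"rle-rpkm"`, `"uq-rpkm"`, `"covariate"`.
#' @param covariates,n_knots passed to [covariate_normalize()].
#' @return An [expr_matrix()].
#' @export
normalize_counts <- function(counts, ann = NULL,
                             method = c("rpkm", "cpm", "rpkm-qnorm", "tmm",
                                        "rle", "rle-rpkm", "uq-rpkm",
                                        "covariate"),
                             covariates = c("length"), n_knots = 5) {
  method <- match.arg(method)
  needs_ann <- method %in% c("rpkm", "rpkm-qnorm", "rle-rpkm", "uq-rpkm",
                             "covariate")
  if (needs_ann && is.null(ann))
    stop("method '", method, "' requires a gene annotation")
  switch(method,
    "cpm" = cpm(counts),
    "rpkm" = rpkm(counts, ann),
    "rpkm-qnorm" = quantile_normalize(rpkm(counts, ann)),
    "tmm" = apply_factors(counts, tmm_factors(counts)),
    "rle" = apply_factors(counts, rle_factors(counts)),
    "rle-rpkm" = apply_factors(counts, rle_factors(counts), ann),
    "uq-rpkm" = apply_factors(counts, uq_factors(counts), ann),
    "covariate" = covariate_normalize(counts, ann, covariates, n_knots)$expr)
}
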