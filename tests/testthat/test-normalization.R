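# Classical normalizers and the covariate corrector.

test_that("cpm and rpkm follow their defining formulas", {
  counts <- named_matrix(c(10, 0, 1e6 - 10, 100, 5, 1e6 - 105), nrow = 3)
  cm <- make_cm(counts, c("A", "A"))
  x <- cpm(cm)
  expect_equal(unname(x["g01", "s1"]), 10)
  expect_equal(unname(x["g02", "s1"]), 0)

  ann <- gene_annotation(rownames(counts), c(2000, 500, 1000))
  r <- rpkm(cm, ann)
  # 100 counts, 2 kb, 1e6 reads -> 50... here gene g01 has 10 counts: 5
  expect_equal(unname(r["g01", "s1"]), 10 * 1e9 / (1e6 * 2000))
  expect_equal(unname(r["g01", "s2"]), 100 * 1e9 / (1e6 * 2000))
  expect_equal(unname(r["g02", "s1"]), 0)

  # doubling all counts (and hence library sizes) leaves rpkm unchanged
  cm2 <- make_cm(2 * counts, c("A", "A"))
  expect_equal(as.matrix(rpkm(cm2, ann)), as.matrix(r))

  expect_error(rpkm(cm, gene_annotation("g01", 100)), "g02")
})

test_that("quantile normalization matches the hand example and its defining properties", {
  x <- named_matrix(c(1, 3, 6, 2), nrow = 2)
  q <- quantile_normalize(expr_matrix(x, "linear"))
  expect_equal(unname(q[, "s1"]), c(1.5, 4.5))
  expect_equal(unname(q[, "s2"]), c(4.5, 1.5))

  # identical columns unchanged
  y <- named_matrix(c(2, 7, 5, 2, 7, 5), nrow = 3)
  expect_equal(as_plain(quantile_normalize(expr_matrix(y, "linear"))), y)

  # all columns share the same sorted values afterwards; ranks preserved
  set.seed(11)
  z <- named_matrix(rnorm(60), nrow = 20)
  qz <- quantile_normalize(z)
  ref <- unname(sort(qz[, 1]))
  for (j in 2:3) {
    expect_equal(unname(sort(qz[, j])), ref)
    expect_equal(order(qz[, j]), order(z[, j]))
  }

  # ties receive the mean of the reference values they span
  tied <- named_matrix(c(1, 1, 5, 10, 20, 30), nrow = 3)
  qt <- quantile_normalize(tied)
  ref2 <- rowMeans(apply(tied, 2, sort))
  expect_equal(unname(qt[1:2, "s1"]), rep(mean(ref2[1:2]), 2))
  expect_equal(unname(qt[3, "s1"]), unname(ref2[3]))

  # cross-check against limma on tie-free data
  ql <- limma::normalizeQuantiles(z)
  expect_equal(unname(as.matrix(qz)), unname(ql), tolerance = 1e-10)

  expect_error(quantile_normalize(z[, 1, drop = FALSE]), ">= 2")
})

test_that("tmm_factors equals the brute-force trimmed weighted mean oracle", {
  # 12-gene fixture with trim_m = 0.1 (default trims would leave < 10 genes,
  # which the precondition forbids at this size)
  set.seed(42)
  y <- named_matrix(rpois(24, lambda = rep(c(60, 300, 900), each = 8)) + 1,
                    nrow = 12, samples = c("s1", "s2"))
  # fixture must be tie-free in M and A for the order-statistic oracle
  N <- colSums(y)
  M <- log2((y[, 1] / N[1]) / (y[, 2] / N[2]))
  stopifnot(!anyDuplicated(M))
  cm <- make_cm(y, c("A", "B"))
  f <- tmm_factors(cm, trim_m = 0.1, trim_a = 0.05)
  expect_equal(unname(as.numeric(f)),
               unname(tmm_oracle(y, trim_m = 0.1, trim_a = 0.05)),
               tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1)

  # default trims on a 40-gene fixture against the same oracle
  set.seed(43)
  y40 <- named_matrix(rpois(120, lambda = rep(exp(runif(40, 2, 7)), 3)) + 1,
                      nrow = 40)
  f40 <- tmm_factors(make_cm(y40, rep("A", 3)))
  expect_equal(unname(as.numeric(f40)), unname(tmm_oracle(y40)),
               tolerance = 1e-12)

  # identical columns and pure depth scaling give unit factors (30 genes so
  # that >= 10 survive the default trims)
  set.seed(44)
  vals <- sort(rpois(30, 150)) + seq_len(30)  # distinct, tie-free
  same <- named_matrix(rep(vals, 2), nrow = 30)
  expect_equal(unname(as.numeric(tmm_factors(make_cm(same, c("A", "A"))))),
               c(1, 1))
  dep <- same; dep[, 2] <- 2 * dep[, 1]
  expect_equal(unname(as.numeric(tmm_factors(make_cm(dep, c("A", "A"))))),
               c(1, 1))
})

test_that("tmm_factors agrees with edgeR's TMM on tie-free data", {
  set.seed(5)
  y <- named_matrix(rpois(80 * 4, lambda = rep(exp(runif(80, 2, 8)), 4)),
                    nrow = 80)
  y[y == 0] <- 1
  cm <- make_cm(y, rep("A", 4))
  mine <- as.numeric(tmm_factors(cm))
  ref <- edgeR::calcNormFactors(y, method = "TMM")
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("rle_factors matches the hand example and is equivariant", {
  y <- named_matrix(c(2, 4, 1, 8, 16, 4), nrow = 3)
  f <- rle_factors(make_cm(y, c("A", "A")))
  # per-gene geometric means (4, 8, 2); ratios all 0.5 and 2
  expect_equal(unname(as.numeric(f)), c(0.5, 2))

  same <- named_matrix(rep(c(3, 9, 27), 2), nrow = 3)
  expect_equal(unname(as.numeric(rle_factors(make_cm(same, c("A", "A"))))),
               c(1, 1))

  # scaling one column by c scales its factor by c (up to the geomean rescale)
  yc <- y; yc[, 2] <- y[, 2] * 4
  fc <- rle_factors(make_cm(yc, c("A", "A")))
  expect_equal(fc[[2]] / fc[[1]], 4 * f[[2]] / f[[1]])

  zeros <- named_matrix(c(0, 5, 3, 0), nrow = 2)
  expect_error(rle_factors(make_cm(zeros, c("A", "A"))), "positive")
})

test_that("uq_factors uses the type-7 75th percentile of nonzero counts", {
  y <- named_matrix(c(1:100, rep(50, 100)), nrow = 100)
  cm <- make_cm(y, c("A", "A"))
  f <- uq_factors(cm)
  # 75th percentile of 1..100 is 75.25 under linear order-statistic interpolation
  N <- colSums(y)
  expect_equal(f[[1]] / f[[2]], unname((75.25 / N[1]) / (50 / N[2])))
  expect_equal(exp(mean(log(f))), 1)

  same <- named_matrix(rep(c(0, 2, 5, 9, 14), 2), nrow = 5)
  expect_equal(unname(as.numeric(uq_factors(make_cm(same, c("A", "A"))))),
               c(1, 1))

  # the factor is percentile / library size, so scaling a whole column (which
  # scales its library size equally) leaves the factors unchanged: a pure
  # depth difference needs no upper-quartile adjustment
  yc <- y; yc[, 2] <- y[, 2] * 3
  fc <- uq_factors(make_cm(yc, c("A", "A")))
  expect_equal(as.numeric(fc), as.numeric(f))

  few <- named_matrix(c(1, 2, 3, 0, 0, 0, 1, 2), nrow = 4)
  expect_error(uq_factors(make_cm(few, c("A", "A"))), "fewer than 4")
})

test_that("apply_factors rescales effective library sizes for cpm and rpkm", {
  y <- named_matrix(c(2, 4, 1, 8, 16, 4), nrow = 3)
  cm <- make_cm(y, c("A", "A"))
  unit <- scale_factors(setNames(c(1, 1), colnames(y)))
  expect_equal(as.matrix(apply_factors(cm, unit)), as.matrix(cpm(cm)))

  ann <- gene_annotation(rownames(y), c(1000, 2000, 500))
  expect_equal(as.matrix(apply_factors(cm, unit, ann)),
               as.matrix(rpkm(cm, ann)))

  # a factor of 2 on one sample halves its values (after geomean rescale,
  # relative to the other sample's doubling)
  f2 <- scale_factors(setNames(c(1, 2), colnames(y)))
  a <- apply_factors(cm, f2)
  expect_equal(unname(a[, "s2"] / as.matrix(cpm(cm))[, "s2"]),
               rep(1 / (2 / sqrt(2)), 3))

  # RLE then RPKM: sample-1 values doubled vs plain rpkm, sample-2 halved
  rr <- apply_factors(cm, rle_factors(cm), ann)
  plain <- rpkm(cm, ann)
  expect_equal(unname(rr[, "s1"] / plain[, "s1"]), rep(2, 3))
  expect_equal(unname(rr[, "s2"] / plain[, "s2"]), rep(0.5, 3))
})

test_that("factor methods are invariant to gene row order", {
  set.seed(8)
  y <- named_matrix(rpois(180, 200) + 1, nrow = 60)
  cm <- make_cm(y, rep("A", 3))
  perm <- sample(nrow(y))
  cmp <- make_cm(y[perm, ], rep("A", 3))
  expect_equal(as.numeric(tmm_factors(cm)), as.numeric(tmm_factors(cmp)))
  expect_equal(as.numeric(rle_factors(cm)), as.numeric(rle_factors(cmp)))
  expect_equal(as.numeric(uq_factors(cm)), as.numeric(uq_factors(cmp)))
})

test_that("covariate corrector leaves unbiased data essentially unchanged", {
  # bias_sd = 0: null generator at the full 12,100-gene scale, where the
  # no-signal length-FC correlation has sd ~ 0.009
  d <- generate_dataset(small_config(seed = 401, n_genes = 12100))
  cm <- filter_expressed(d$counts)
  ann <- d$annotation
  # with nothing to correct, the output equals the quantile-normalized log2
  # input up to fitting noise ...
  baseline <- quantile_normalize(expr_matrix(log2(cm$counts + 0.5), "log2"))
  corrected <- covariate_normalize(cm, ann, "length")$expr
  expect_lt(mean(abs(as_plain(corrected) - as_plain(baseline))), 0.05)
  # ... and per-pair length-FC |rho| is unchanged within +/- 0.02
  lg <- log10(ann$length_bp[match(rownames(cm$counts), ann$gene_id)])
  smp <- cm$samples
  for (cond in unique(smp$condition)) {
    ids <- smp$sample_id[smp$condition == cond]
    for (p in combn(ids, 2, simplify = FALSE)) {
      r0 <- abs(cor(rank(lg), rank(baseline[, p[1]] - baseline[, p[2]])))
      r1 <- abs(cor(rank(lg), rank(corrected[, p[1]] - corrected[, p[2]])))
      expect_lt(abs(r0 - r1), 0.02)
    }
  }
})

test_that("GC-only correction does not remove a length bias", {
  cfg <- preset_paperlike(seed = 402)
  d <- generate_dataset(cfg)
  cm <- filter_expressed(d$counts)
  pre <- max(abs(replicate_pair_scan(cm, d$annotation, "rpkm")$rho))
  gc_only <- max(abs(replicate_pair_scan(cm, d$annotation, "covariate",
                                         covariates = "gc")$rho))
  len <- max(abs(replicate_pair_scan(cm, d$annotation, "covariate",
                                     covariates = "length")$rho))
  expect_gt(gc_only, 0.5 * pre)   # length bias persists under GC-only
  expect_lt(len, 0.05)            # but the length covariate removes it
})

test_that("covariate_normalize validates inputs and reports its fit", {
  y <- named_matrix(rpois(40, 100), nrow = 10)
  cm <- make_cm(y, rep(c("A", "B"), each = 2))
  ann_nogc <- gene_annotation(rownames(y), seq(500, 5000, length.out = 10))
  expect_error(covariate_normalize(cm, ann_nogc, c("length", "gc")), "gc")
  ann_const <- gene_annotation(rownames(y), rep(1000, 10))
  expect_error(covariate_normalize(cm, ann_const, "length"), "constant")

  out <- covariate_normalize(cm, ann_nogc, "length", n_knots = 3)
  expect_s3_class(out$expr, "expr_matrix")
  expect_equal(expr_scale(out$expr), "log2")
  expect_s3_class(out$fit, "covariate_fit")
  expect_true(all(is.finite(out$fit$coefficients)))
})

test_that("normalize_counts dispatches all schemes", {
  set.seed(31)
  y <- named_matrix(rpois(200, 300) + 1, nrow = 50)
  cm <- make_cm(y, rep(c("A", "B"), each = 2))
  ann <- gene_annotation(rownames(y), round(10^runif(50, 2.5, 4.5)),
                         runif(50, 0.3, 0.7))
  for (m in c("cpm", "rpkm", "rpkm-qnorm", "tmm", "rle", "rle-rpkm", "uq-rpkm")) {
    e <- normalize_counts(cm, ann, m)
    expect_equal(expr_scale(e), "linear")
    expect_equal(dim(e), dim(y))
  }
  e <- normalize_counts(cm, ann, "covariate", n_knots = 3)
  expect_equal(expr_scale(e), "log2")
  expect_error(normalize_counts(cm, NULL, "rpkm"), "annotation")
})
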