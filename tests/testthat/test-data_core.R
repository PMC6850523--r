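# Data model, readers, expression filter and fold changes.

test_that("read_counts round-trips a well-formed file and assigns replicates", {
  counts <- named_matrix(c(5, 0, 3, 2, 7, 1), nrow = 3)
  design <- data.frame(sample_id = c("s1", "s2"), condition = c("A", "A"))
  cp <- write_tsv_tmp(data.frame(gene_id = rownames(counts), counts,
                                 check.names = FALSE))
  dp <- write_tsv_tmp(design)
  cm <- read_counts(cp, dp)
  expect_s3_class(cm, "count_matrix")
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(unique(cm$samples$condition), "A")
  expect_equal(cm$samples$replicate, 1:2)
  expect_equal(unname(cm$counts[, "s1"]), c(5, 0, 3))

  # 4 genes x 6 samples, two conditions x three replicates
  counts6 <- named_matrix(rpois(24, 50) + 1, nrow = 4)
  design6 <- data.frame(sample_id = colnames(counts6),
                        condition = rep(c("treated", "vehicle"), each = 3))
  cm6 <- read_counts(write_tsv_tmp(data.frame(gene_id = rownames(counts6),
                                              counts6, check.names = FALSE)),
                     write_tsv_tmp(design6))
  for (cond in c("treated", "vehicle"))
    expect_setequal(cm6$samples$replicate[cm6$samples$condition == cond], 1:3)
})

test_that("read_counts rejects malformed input with informative errors", {
  counts <- named_matrix(c(1, -1, 2, 3), nrow = 2)
  design <- data.frame(sample_id = c("s1", "s2"), condition = c("A", "A"))
  dp <- write_tsv_tmp(design)
  cp <- write_tsv_tmp(data.frame(gene_id = rownames(counts), counts,
                                 check.names = FALSE))
  expect_error(read_counts(cp, dp), ">= 0")

  dup <- data.frame(gene_id = c("g1", "g1"), s1 = c(1, 2), s2 = c(3, 4))
  expect_error(read_counts(write_tsv_tmp(dup), dp), "g1")

  ok <- data.frame(gene_id = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4))
  d_missing <- data.frame(sample_id = "s1", condition = "A")
  expect_error(read_counts(write_tsv_tmp(ok), write_tsv_tmp(d_missing)), "s2")

  frac <- data.frame(gene_id = c("g1", "g2"), s1 = c(1.5, 2), s2 = c(3, 4))
  expect_error(read_counts(write_tsv_tmp(frac), dp), "integer")
})

test_that("read_annotation parses lengths and optional gc, validating ranges", {
  p <- write_tsv_tmp(data.frame(gene_id = c("G1", "G2"),
                                length_bp = c(2000, 1500),
                                gc_fraction = c(0.45, NA)))
  ann <- read_annotation(p)
  expect_equal(ann$length_bp, c(2000, 1500))
  expect_equal(ann$gc_fraction[1], 0.45)
  expect_true(is.na(ann$gc_fraction[2]))

  p2 <- write_tsv_tmp(data.frame(gene_id = "G2", length_bp = 1500))
  expect_true(is.na(read_annotation(p2)$gc_fraction))

  expect_error(gene_annotation("G3", 0, 0.5), "length_bp")
  expect_error(gene_annotation("G4", 100, 1.2), "gc_fraction")
  expect_error(gene_annotation(c("G5", "G5"), c(10, 20)), "duplicate")
})

gtf_lines <- c(
  'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "GA"; transcript_id "TA1"; tag "basic"; tag "appris_principal_1";',
  'chr1\tx\texon\t201\t300\t.\t+\t.\tgene_id "GA"; transcript_id "TA1"; tag "appris_principal_1";',
  'chr1\tx\texon\t1\t900\t.\t+\t.\tgene_id "GA"; transcript_id "TA2";',
  'chr1\tx\texon\t1\t500\t.\t+\t.\tgene_id "GB"; transcript_id "TB1"; tag "appris_principal_1";',
  'chr1\tx\texon\t1\t900\t.\t+\t.\tgene_id "GB"; transcript_id "TB2";',
  'chr1\tx\texon\t1\t300\t.\t+\t.\tgene_id "GC"; transcript_id "TC1";',
  'chr1\tx\texon\t1\t700\t.\t+\t.\tgene_id "GC"; transcript_id "TC2";')

test_that("lengths_from_gtf picks APPRIS principal, else longest transcript", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c("# comment line", gtf_lines), p)
  ann <- lengths_from_gtf(p)
  L <- setNames(ann$length_bp, ann$gene_id)
  # exon spans [1,100] + [201,300] of the principal transcript
  expect_equal(unname(L["GA"]), 200)
  # principal (500) beats longer untagged (900)
  expect_equal(unname(L["GB"]), 500)
  # no principal tag: longest wins
  expect_equal(unname(L["GC"]), 700)
  expect_true(all(is.na(ann$gc_fraction)))
})

test_that("lengths_from_gtf is invariant to record order and warns on exon-less genes", {
  p1 <- tempfile(fileext = ".gtf"); p2 <- tempfile(fileext = ".gtf")
  writeLines(gtf_lines, p1)
  set.seed(7)
  writeLines(sample(gtf_lines), p2)
  a1 <- lengths_from_gtf(p1); a2 <- lengths_from_gtf(p2)
  expect_equal(a1[order(a1$gene_id), ], a2[order(a2$gene_id), ])

  p3 <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_lines,
               'chr1\tx\tgene\t1\t50\t.\t+\t.\tgene_id "GD";'), p3)
  expect_warning(a3 <- lengths_from_gtf(p3), "GD")
  expect_false("GD" %in% a3$gene_id)
})

test_that("read_gmt parses, deduplicates members and validates", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tna\tG1\tG2\tG2", "S2\tdesc\tG3"), p)
  sets <- read_gmt(p)
  expect_length(sets, 2)
  expect_equal(sets$S1, c("G1", "G2"))
  expect_equal(attr(sets, "description")[["S2"]], "desc")

  empty <- tempfile(fileext = ".gmt"); file.create(empty)
  expect_length(read_gmt(empty), 0)

  bad <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tna\tG1", "S2\tonlytwo"), bad)
  expect_error(read_gmt(bad), "line 2")

  dup <- tempfile(fileext = ".gmt")
  writeLines(c("S1\tna\tG1", "S1\tna\tG2"), dup)
  expect_error(read_gmt(dup), "S1")

  # round trip
  out <- tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(unclass(read_gmt(out))[], unclass(sets)[])
})

test_that("cpm columns sum to 1e6 and filter_expressed applies the per-condition rule", {
  # library sizes 2e6 so cpm = count / 2; 2 conditions x 2 replicates,
  # cpm rows (2,2|2,2), (2,0.5|0.5,2), (1,1|0,0), (0.5,0.5|0.5,0.5)
  rows <- 2 * rbind(c(2, 2, 2, 2),
                    c(2, 0.5, 0.5, 2),
                    c(1, 1, 0, 0),
                    c(0.5, 0.5, 0.5, 0.5))
  filler <- 2e6 - colSums(rows)
  counts <- named_matrix(rbind(rows, filler), nrow = 5)
  cm <- make_cm(counts, c("A", "A", "B", "B"))

  x <- cpm(cm)
  expect_equal(unname(colSums(x)), rep(1e6, 4))
  expect_equal(expr_scale(x), "linear")

  kept <- filter_expressed(cm, 1.0)
  # brute-force evaluation of the rule per gene
  expect_setequal(rownames(kept$counts)[1:2], c("g01", "g03"))
  expect_equal(nrow(kept$counts), 3)  # g01, g03 and the filler gene

  # retained when >= threshold in all samples of at least one condition:
  # cpm (1.2, 1.5) in condition A, (0, 0.1) in B at library size 1e7
  one <- named_matrix(rbind(c(12, 15, 0, 1), 1e7 - c(12, 15, 0, 1)), nrow = 2)
  cm1 <- make_cm(one, c("A", "A", "B", "B"))
  expect_true("g01" %in% rownames(filter_expressed(cm1)$counts))

  # all-zero gene removed
  zero <- named_matrix(rbind(c(0, 0), c(10, 10)), nrow = 2)
  cmz <- make_cm(zero, c("A", "A"))
  expect_false("g01" %in% rownames(filter_expressed(cmz, 1e-3)$counts))

  # idempotency
  twice <- filter_expressed(filter_expressed(cm, 1.0), 1.0)
  expect_identical(twice$counts, kept$counts)

  expect_error(filter_expressed(cmz, 1e9), "threshold")
})

test_that("log2_fold_change follows the pseudocount rule and is antisymmetric", {
  e <- expr_matrix(named_matrix(c(3, 1, 3, 1, 1, 3, 1, 3), nrow = 2,
                                samples = c("a1", "a2", "b1", "b2")), "linear")
  fc <- log2_fold_change(e, c("a1", "a2"), c("b1", "b2"), pseudocount = 1)
  # mean_a 3, mean_b 1 -> log2(4/2) = 1
  expect_equal(fc$log2_fc, c(1, -1))
  expect_equal(fc$mean_abundance, c(2, 2))
  expect_equal(fc$comparison_label[1], "a1+a2_vs_b1+b2")

  # identical groups
  fc0 <- log2_fold_change(e, c("a1", "b1"), c("a2", "b2"))
  expect_equal(fc0$log2_fc, c(0, 0))

  # antisymmetry, exactly
  rev <- log2_fold_change(e, c("b1", "b2"), c("a1", "a2"))
  expect_identical(fc$log2_fc, -rev$log2_fc)

  # single-sample groups use the single values
  fc1 <- log2_fold_change(e, "a1", "b1")
  expect_equal(fc1$log2_fc[1], log2(4 / 2))

  expect_error(log2_fold_change(e, "a1", "nope"), "nope")
  expect_error(log2_fold_change(e, c("a1", "b1"), c("b1", "b2")), "disjoint")

  # log2 scale: difference of means, pseudocount not applied
  el <- expr_matrix(named_matrix(c(3, 1, 1, 5), nrow = 2,
                                 samples = c("x", "y")), "log2")
  fcl <- log2_fold_change(el, "x", "y")
  expect_equal(fcl$log2_fc, c(2, -4))
})
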