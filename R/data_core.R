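# Data model, file I/O, expression filtering and fold-change estimation.

#' Construct a validated count matrix with sample metadata
#'
#' The universal input container: a genes x samples matrix of raw integer
#' counts together with the condition label and replicate index of every
#' sample. Library sizes are the column sums.
#'
#' @param counts integer matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids); all entries whole numbers >= 0.
#' @param condition character vector of condition labels, one per sample,
#'   either named by sample id or in column order.
#' @param replicate optional integer vector of replicate indices (positive,
#'   unique within each condition). Defaults to 1..k in column order within
#'   each condition.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `samples` (data.frame with columns `sample_id`,
#'   `condition`, `replicate`, `lib_size`).
#' @export
count_matrix <- function(counts, condition, replicate = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id")
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0))
    stop("counts must be >= 0")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # holds integers exactly; avoids overflow in sums

  sample_ids <- colnames(counts)
  if (!is.null(names(condition))) {
    missing <- setdiff(sample_ids, names(condition))
    if (length(missing))
      stop("sample missing from design: ", paste(missing, collapse = ", "))
    condition <- condition[sample_ids]
  } else if (length(condition) != ncol(counts)) {
    stop("condition must have one entry per sample")
  }
  condition <- as.character(condition)

  if (is.null(replicate)) {
    replicate <- integer(length(sample_ids))
    for (cond in unique(condition)) {
      idx <- which(condition == cond)
      replicate[idx] <- seq_along(idx)
    }
  } else {
    if (!is.null(names(replicate))) replicate <- replicate[sample_ids]
    replicate <- as.integer(replicate)
    if (anyNA(replicate) || any(replicate < 1))
      stop("replicate indices must be positive integers")
    for (cond in unique(condition)) {
      r <- replicate[condition == cond]
      if (anyDuplicated(r))
        stop("replicate indices must be unique within condition '", cond, "'")
    }
  }

  structure(list(
    counts = counts,
    samples = data.frame(sample_id = sample_ids,
                         condition = condition,
                         replicate = replicate,
                         lib_size = colSums(counts),
                         stringsAsFactors = FALSE)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  tab <- table(x$samples$condition)
  cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its design file
#'
#' The counts file is tab-separated with a header row of sample ids and a
#' first column of gene ids (header `gene_id`). The design file is
#' tab-separated with columns `sample_id`, `condition` and optionally
#' `replicate`; every sample in the counts file must appear in it.
#'
#' @param path path to the counts TSV.
#' @param design_path path to the design TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, design_path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts file needs a gene id column and >= 1 sample")
  gene_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count entries in ", path)
  rownames(mat) <- gene_ids

  design <- read.delim(design_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(design)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(mat), design$sample_id)
  if (length(missing))
    stop("sample missing from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(mat), design$sample_id), ]
  rep_idx <- if ("replicate" %in% names(design))
    setNames(as.integer(design$replicate), design$sample_id) else NULL
  count_matrix(mat, setNames(design$condition, design$sample_id), rep_idx)
}

#' Write a count matrix and design to TSV files
#'
#' @param x a [count_matrix()].
#' @param path counts TSV path.
#' @param design_path design TSV path.
#' @return Invisibly, `x`.
#' @export
write_counts <- function(x, path, design_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples[, c("sample_id", "condition", "replicate")],
              design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `length_bp` (principal-transcript
#' length in base pairs) and optionally `gc_fraction` in \[0, 1\].
#'
#' @param path path to the annotation TSV.
#' @return A data.frame of class `gene_annotation` with columns `gene_id`,
#'   `length_bp`, `gc_fraction` (NA when absent).
#' @export
read_annotation <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(tab)))
    stop("annotation file must have columns gene_id and length_bp")
  if (!"gc_fraction" %in% names(tab)) tab$gc_fraction <- NA_real_
  gene_annotation(tab$gene_id, tab$length_bp, tab$gc_fraction)
}

#' Construct a validated gene annotation table
#'
#' @param gene_id unique gene identifiers.
#' @param length_bp positive integer transcript lengths (base pairs).
#' @param gc_fraction GC fraction in \[0, 1\], or NA when unknown.
#' @return A data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, length_bp, gc_fraction = NA_real_) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id in annotation: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  length_bp <- as.numeric(length_bp)
  if (anyNA(length_bp) || any(length_bp < 1))
    stop("length_bp must be >= 1 for every gene")
  gc_fraction <- rep_len(as.numeric(gc_fraction), length(gene_id))
  bad <- !is.na(gc_fraction) & (gc_fraction < 0 | gc_fraction > 1)
  if (any(bad)) stop("gc_fraction outside [0,1] for: ",
                     paste(gene_id[bad], collapse = ", "))
  structure(data.frame(gene_id = gene_id, length_bp = length_bp,
                       gc_fraction = gc_fraction, stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Write a gene annotation table to TSV
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @return Invisibly, `ann`.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

# Parse the attribute column of one GTF record into gene_id, transcript_id and
# the full vector of `tag` values. GENCODE repeats the `tag` key, so a generic
# key/value parser that keeps one value per key would silently drop APPRIS tags.
.gtf_attr <- function(attr) {
  m <- regmatches(attr, gregexpr('(\\w+) "([^"]*)"', attr))[[1]]
  keys <- sub('^(\\w+) ".*$', "\\1", m)
  vals <- sub('^\\w+ "([^"]*)"$', "\\1", m)
  list(gene_id = vals[match("gene_id", keys)],
       transcript_id = vals[match("transcript_id", keys)],
       tags = vals[keys == "tag"])
}

#' Derive per-gene principal-transcript lengths from a GTF file
#'
#' For each gene the representative transcript is the one carrying an APPRIS
#' `appris_principal` tag (lowest principal rank wins; ties go to the longest
#' transcript, then the lexicographically smallest transcript id). Genes
#' without any APPRIS-tagged transcript use their longest transcript. The
#' gene length is the sum of that transcript's exon spans
#' (`end - start + 1`, 1-based inclusive coordinates).
#'
#' @param gtf_path path to a GTF file (GENCODE dialect; exon records must
#'   carry `gene_id` and `transcript_id` attributes).
#' @return A [gene_annotation()] with `gc_fraction` set to NA. Genes that
#'   appear in the GTF without exon records are skipped with a warning.
#' @export
lengths_from_gtf <- function(gtf_path) {
  lines <- readLines(gtf_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 9
  if (!all(ok)) stop("malformed GTF record at line ", which(!ok)[1])
  feature <- vapply(fields, `[[`, "", 3)

  seen_genes <- character(0)
  # transcript accumulator: exonic length and best (lowest) APPRIS rank
  tx_gene <- tx_len <- tx_rank <- list()
  for (f in fields) {
    at <- .gtf_attr(f[9])
    gid <- at$gene_id
    if (!is.na(gid)) seen_genes <- c(seen_genes, gid)
    if (f[3] != "exon") next
    tid <- at$transcript_id
    if (is.na(gid) || is.na(tid))
      stop("exon record without gene_id/transcript_id attribute")
    span <- as.numeric(f[5]) - as.numeric(f[4]) + 1
    if (is.na(span) || span < 1) stop("invalid exon coordinates for ", tid)
    pr <- at$tags[startsWith(at$tags, "appris_principal")]
    rank <- if (length(pr)) {
      suf <- suppressWarnings(as.integer(sub("^appris_principal_?", "", pr)))
      min(ifelse(is.na(suf), 1L, suf))
    } else NA_integer_
    cur <- tx_len[[tid]]
    tx_len[[tid]] <- if (is.null(cur)) span else cur + span
    tx_gene[[tid]] <- gid
    old <- tx_rank[[tid]]
    tx_rank[[tid]] <- if (is.null(old)) rank else suppressWarnings(min(old, rank, na.rm = TRUE))
    if (is.infinite(tx_rank[[tid]])) tx_rank[[tid]] <- NA_integer_
  }
  if (!length(tx_len)) stop("no exon records found in ", gtf_path)

  tx <- data.frame(transcript_id = names(tx_len),
                   gene_id = unlist(tx_gene)[names(tx_len)],
                   length = unlist(tx_len),
                   rank = vapply(tx_rank[names(tx_len)], function(r)
                     if (is.null(r) || is.na(r)) NA_integer_ else as.integer(r), 1L),
                   stringsAsFactors = FALSE)

  pick <- function(d) {
    cand <- if (any(!is.na(d$rank))) d[!is.na(d$rank) & d$rank == min(d$rank, na.rm = TRUE), ]
            else d
    cand <- cand[cand$length == max(cand$length), ]
    cand <- cand[order(cand$transcript_id), ]
    cand$length[1]
  }
  lens <- vapply(split(tx, tx$gene_id), pick, numeric(1))

  no_exons <- setdiff(unique(seen_genes), tx$gene_id)
  if (length(no_exons))
    warning("skipping ", length(no_exons), " gene(s) with no exon records: ",
            paste(head(no_exons, 5), collapse = ", "))
  gene_annotation(names(lens), lens)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene ids. Duplicate members within a set are
#' collapsed; duplicate set names are an error.
#'
#' @param path path to the GMT file.
#' @return A named list of character vectors (class `gene_set_collection`)
#'   with a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1)
  desc <- vapply(parts, `[[`, "", 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, setNames(desc, nm))
}

#' Construct a validated gene-set collection
#'
#' @param sets named list of character vectors of gene ids; names unique,
#'   sets non-empty.
#' @param description optional named character vector of set descriptions.
#' @return The list with class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every gene set must be named")
    if (anyDuplicated(names(sets)))
      stop("duplicate set name: ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
    sets <- lapply(sets, function(s) unique(as.character(s)))
  }
  structure(sets, description = description, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets a [gene_set_collection()] (or named list of gene id vectors).
#' @param path output path.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

#' Counts per million for each gene and sample
#'
#' `cpm(g, s) = counts(g, s) * 1e6 / N_s` with `N_s` the library size
#' (column sum) of sample `s`.
#'
#' @param counts a [count_matrix()].
#' @return An [expr_matrix()] on the linear scale.
#' @export
cpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  N <- counts$samples$lib_size
  if (any(N <= 0)) stop("zero library size for sample: ",
                        paste(counts$samples$sample_id[N <= 0], collapse = ", "))
  expr_matrix(sweep(counts$counts, 2, N / 1e6, "/"), "linear")
}

#' Filter to expressed genes
#'
#' Keeps gene `g` iff there is at least one condition in which every
#' replicate sample has `cpm(g, s) >= cpm_threshold`. Row order is preserved.
#'
#' @param counts a [count_matrix()].
#' @param cpm_threshold positive CPM threshold (default 1.0).
#' @return The filtered [count_matrix()]. CPM is defined against the full
#'   library, so `samples$lib_size` keeps the pre-filtering column sums
#'   (this also makes the filter exactly idempotent).
#' @export
filter_expressed <- function(counts, cpm_threshold = 1.0) {
  stopifnot(inherits(counts, "count_matrix"), cpm_threshold > 0)
  x <- unclass(cpm(counts))
  keep <- rep(FALSE, nrow(x))
  for (cond in unique(counts$samples$condition)) {
    cols <- counts$samples$condition == cond
    keep <- keep | apply(x[, cols, drop = FALSE] >= cpm_threshold, 1, all)
  }
  if (!any(keep))
    stop("no gene passes the expression filter; review cpm_threshold = ",
         cpm_threshold)
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  out
}

#' Construct an expression matrix with a declared scale
#'
#' @param values numeric genes x samples matrix (finite; >= 0 when linear).
#' @param scale `"linear"` or `"log2"`.
#' @return The matrix with class `expr_matrix` and attribute `scale`.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression must be >= 0")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix (", attr(x, "scale"), " scale): ",
      nrow(x), " genes x ", ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' Expression scale of a matrix
#' @param x an [expr_matrix()].
#' @return `"linear"` or `"log2"`.
#' @export
expr_scale <- function(x) attr(x, "scale")

#' Log2 fold change between two sample groups
#'
#' On the linear scale, per gene:
#' `log2_fc = log2((mean_a + pseudocount) / (mean_b + pseudocount))`, with
#' means taken over each group's samples. On the log2 scale the fold change
#' is the difference of group means and the pseudocount is ignored (the
#' log transform applied upstream already included its own offset).
#' Single-sample groups give replicate-vs-replicate fold changes.
#'
#' @param expr an [expr_matrix()].
#' @param group_a,group_b non-overlapping, non-empty vectors of sample ids
#'   (columns of `expr`); `group_a` is the numerator.
#' @param pseudocount positive value added to both group means (default 1.0).
#' @param label comparison label; defaults to `"<a...>_vs_<b...>"`.
#' @return A data.frame of class `fold_change_table` with columns `gene_id`,
#'   `log2_fc`, `mean_abundance` (mean over both groups, linear scale or
#'   log2 units as supplied) and `comparison_label`.
#' @export
log2_fold_change <- function(expr, group_a, group_b, pseudocount = 1.0,
                             label = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  unknown <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(unknown))
    stop("unknown sample id: ", paste(unknown, collapse = ", "))
  if (pseudocount <= 0 && expr_scale(expr) == "linear")
    stop("pseudocount must be > 0")
  ma <- rowMeans(expr[, group_a, drop = FALSE])
  mb <- rowMeans(expr[, group_b, drop = FALSE])
  lfc <- if (expr_scale(expr) == "linear")
    log2((ma + pseudocount) / (mb + pseudocount)) else ma - mb
  if (is.null(label))
    label <- paste0(paste(group_a, collapse = "+"), "_vs_",
                    paste(group_b, collapse = "+"))
  structure(data.frame(gene_id = rownames(expr),
                       log2_fc = as.numeric(lfc),
                       mean_abundance = as.numeric((ma + mb) / 2),
                       comparison_label = label,
                       stringsAsFactors = FALSE),
            class = c("fold_change_table", "data.frame"))
}

#' Write a fold-change table to TSV
#'
#' @param fc a [log2_fold_change()] result.
#' @param path output path.
#' @return Invisibly, `fc`.
#' @export
write_fold_changes <- function(fc, path) {
  write.table(fc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fc)
}
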