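# Gene-set tests: pre-ranked GSEA with a gene-permutation null, a
# correlation-adjusted (variance inflation factor) competitive test, and the
# set-vs-background length comparison.

#' Build a deterministic ranked gene list from scores
#'
#' Sorts genes by score descending; ties are broken by gene id so the order
#' is reproducible.
#'
#' @param scores numeric vector named by gene id (e.g. the `log2_fc` column
#'   of [log2_fold_change()]), or a `fold_change_table`.
#' @return A named numeric vector sorted for [gsea_preranked()].
#' @export
ranked_list <- function(scores) {
  if (inherits(scores, "fold_change_table"))
    scores <- setNames(scores$log2_fc, scores$gene_id)
  if (is.null(names(scores))) stop("scores must be named by gene id")
  if (anyDuplicated(names(scores))) stop("duplicate gene id in scores")
  scores[order(-scores, names(scores))]
}

# Enrichment score from sorted member positions.
# pos: 1-based hit positions in the ranked list (ascending),
# w:   nonnegative hit weights aligned with pos (|score|^p), N: universe size.
# Running sum adds w_i/sum(w) at a hit and subtracts 1/(N-m) at a miss; ES is
# the extreme deviation (sign kept). Symmetric walks produce mathematically
# exact |max| == |min| ties (e.g. a single member at the list midpoint), so
# the tie is decided with a small tolerance -- ties go to the positive
# deviation -- rather than left to floating-point rounding.
.es_from_positions <- function(pos, w, N) {
  m <- length(pos)
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / m, m)
  miss <- 1 / (N - m)
  cw <- cumsum(w)
  i <- seq_len(m)
  after  <- cw - (pos - i) * miss          # value just after each hit
  before <- c(0, cw[-m]) - (pos - i) * miss # value just before each hit
  hi <- max(after)
  lo <- min(before, 0)
  if (hi >= -lo - 1e-9) hi else lo
}

#' Pre-ranked gene-set enrichment analysis (gene-permutation null)
#'
#' Walks the ranked list computing the weighted Kolmogorov-Smirnov-like
#' running sum: a member gene ("hit") adds `|score|^weight_p` normalized by
#' the sum over members, a non-member subtracts `1/(N - m)`. The enrichment
#' score (ES) is the extreme deviation of the running sum, sign retained;
#' an exact positive/negative tie in deviation magnitude (possible for
#' symmetric walks) resolves to the positive deviation.
#' The null distribution per set is generated by `n_perm` random placements
#' of `m` member labels among the `N` universe genes (gene permutation --
#' deliberately, since its sensitivity to intergene correlation is the
#' analysis target). NES is ES divided by the mean |null ES| of the same
#' sign; the nominal p is the one-sided same-sign frequency with an add-one
#' correction; FDR q follows the pooled-null procedure: for each observed
#' NES the fraction of pooled same-sign null NES at least as extreme divided
#' by the fraction of observed same-sign NES at least as extreme, clipped to
#' \[0, 1\] and made monotone from the most extreme NES down.
#'
#' @param ranked a [ranked_list()] (named scores, sorted; any named numeric
#'   vector is re-sorted deterministically).
#' @param sets a [gene_set_collection()].
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param weight_p hit-weight exponent (default 1).
#' @param min_size,max_size set-size bounds after intersecting with the
#'   universe (defaults 15 and 500).
#' @param seed RNG seed for the permutations.
#' @return A data.frame of class `enrichment_result`: `set_name`, `size`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`, `direction` (`"up"`/`"down"`).
#'   Sets falling outside the size bounds are recorded in the
#'   `skipped` attribute.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, weight_p = 1,
                           min_size = 15, max_size = 500, seed = 1) {
  ranked <- ranked_list(ranked)
  if (n_perm < 100) warning("n_perm < 100 gives unstable p-values and FDR")
  N <- length(ranked)
  universe <- names(ranked)
  absw <- abs(ranked)^weight_p

  members <- lapply(sets, function(s) sort(match(s, universe)))
  members <- lapply(members, function(p) p[!is.na(p)])
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  skipped <- names(sets)[!keep]
  members <- members[keep]
  if (!length(members))
    return(structure(data.frame(set_name = character(0), size = integer(0),
                                es = numeric(0), nes = numeric(0),
                                p_nominal = numeric(0), fdr_q = numeric(0),
                                direction = character(0)),
                     skipped = skipped,
                     class = c("enrichment_result", "data.frame")))

  es_obs <- vapply(members, function(pos)
    .es_from_positions(pos, absw[pos], N), numeric(1))

  set.seed(seed)
  null_es <- matrix(NA_real_, n_perm, length(members),
                    dimnames = list(NULL, names(members)))
  for (j in seq_along(members)) {
    m <- length(members[[j]])
    for (b in seq_len(n_perm)) {
      pos <- sort(sample.int(N, m))
      null_es[b, j] <- .es_from_positions(pos, absw[pos], N)
    }
  }

  norm_const <- function(es_null, sign_pos) {
    v <- if (sign_pos) es_null[es_null > 0] else -es_null[es_null < 0]
    if (!length(v)) mean(abs(es_null)) else mean(v)
  }
  nes <- numeric(length(es_obs))
  p_nom <- numeric(length(es_obs))
  null_nes <- null_es
  for (j in seq_along(es_obs)) {
    col <- null_es[, j]
    pos_c <- norm_const(col, TRUE)
    neg_c <- norm_const(col, FALSE)
    null_nes[, j] <- ifelse(col >= 0, col / pos_c, col / neg_c)
    if (es_obs[j] >= 0) {
      same <- col[col >= 0]
      p_nom[j] <- (1 + sum(same >= es_obs[j])) / (1 + length(same))
      nes[j] <- es_obs[j] / pos_c
    } else {
      same <- col[col < 0]
      p_nom[j] <- (1 + sum(same <= es_obs[j])) / (1 + length(same))
      nes[j] <- es_obs[j] / neg_c
    }
  }

  pool <- as.numeric(null_nes)
  fdr <- vapply(seq_along(nes), function(j) {
    if (nes[j] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[j])
      den <- mean(nes[nes >= 0] >= nes[j])
    } else {
      num <- mean(pool[pool < 0] <= nes[j])
      den <- mean(nes[nes < 0] <= nes[j])
    }
    min(1, max(0, if (den > 0) num / den else 1))
  }, numeric(1))
  # enforce monotonicity within each direction: q non-decreasing as |NES| falls
  for (sgn in c(1, -1)) {
    i <- which(sign(nes) == sgn | (sgn == 1 & nes == 0))
    if (length(i) > 1) {
      ord <- i[order(-abs(nes[i]))]
      fdr[ord] <- cummax(fdr[ord])
    }
  }

  structure(data.frame(set_name = names(members),
                       size = lengths(members),
                       es = es_obs, nes = nes,
                       p_nominal = p_nom, fdr_q = fdr,
                       direction = ifelse(es_obs >= 0, "up", "down"),
                       stringsAsFactors = FALSE, row.names = NULL),
            skipped = skipped,
            class = c("enrichment_result", "data.frame"))
}

#' Correlation-adjusted (VIF) competitive gene-set test
#'
#' Per gene, an ordinary two-sample pooled-variance t statistic between the
#' groups is converted to a z score by the probability integral transform.
#' Per set of size `m`, the mean pairwise correlation `mean_rho` of the
#' group-mean-centered expression residuals is estimated across samples
#' (floored at 0; negative estimates would deflate the variance), giving the
#' variance inflation factor `vif = 1 + (m - 1) * mean_rho`. The test
#' statistic is
#' `(mean z in set - mean z outside) / (sd(z) * sqrt(vif/m + 1/(N - m)))`,
#' referred to the standard normal (two-sided).
#'
#' @param expr an [expr_matrix()] on the log2 scale.
#' @param group_a,group_b disjoint sample-id vectors, each of size >= 2.
#' @param sets a [gene_set_collection()].
#' @param fixed_rho optional fixed intergene correlation overriding the
#'   estimate; `fixed_rho = 0` gives the unadjusted (VIF = 1) test. Without
#'   it, at least 4 samples are required to estimate correlations.
#' @param min_size sets smaller than this within the universe are skipped
#'   (default 5).
#' @return A data.frame of class `set_test_result`: `set_name`, `m`,
#'   `mean_rho`, `vif`, `statistic`, `p_two_sided`. Skipped sets are in the
#'   `skipped` attribute.
#' @export
vif_adjusted_set_test <- function(expr, group_a, group_b, sets,
                                  fixed_rho = NULL, min_size = 5) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  cols <- c(group_a, group_b)
  unknown <- setdiff(cols, colnames(expr))
  if (length(unknown)) stop("unknown sample id: ", paste(unknown, collapse = ", "))
  if (is.null(fixed_rho) && length(cols) < 4)
    stop("need >= 4 samples to estimate intergene correlation; ",
         "supply fixed_rho instead")

  x <- expr[, cols, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(x[, group_a, drop = FALSE])
  mb <- rowMeans(x[, group_b, drop = FALSE])
  va <- apply(x[, group_a, drop = FALSE], 1, stats::var)
  vb <- apply(x[, group_b, drop = FALSE], 1, stats::var)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, (ma - mb) / se, 0)
  # t -> z via the probability integral transform, tail-stable
  z <- qnorm(pt(tstat, df, log.p = TRUE), log.p = TRUE)
  z[!is.finite(z)] <- 0

  # group-mean-centered residuals for correlation estimation
  resid <- x
  resid[, group_a] <- x[, group_a, drop = FALSE] - ma
  resid[, group_b] <- x[, group_b, drop = FALSE] - mb

  N <- nrow(x)
  sd0 <- sd(z)
  universe <- rownames(x)

  rows <- list(); skipped <- character(0)
  for (nm in names(sets)) {
    idx <- match(intersect(sets[[nm]], universe), universe)
    m <- length(idx)
    if (m < min_size || m >= N) { skipped <- c(skipped, nm); next }
    if (!is.null(fixed_rho)) {
      rho <- fixed_rho
    } else {
      cm <- suppressWarnings(cor(t(resid[idx, , drop = FALSE])))
      rho <- mean(cm[upper.tri(cm)], na.rm = TRUE)
      if (!is.finite(rho)) rho <- 0
      rho <- max(0, rho)
    }
    vif <- 1 + (m - 1) * rho
    delta <- mean(z[idx]) - mean(z[-idx])
    stat <- delta / (sd0 * sqrt(vif / m + 1 / (N - m)))
    rows[[nm]] <- data.frame(set_name = nm, m = m, mean_rho = rho, vif = vif,
                             statistic = stat,
                             p_two_sided = 2 * pnorm(-abs(stat)),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_name = character(0), m = integer(0), mean_rho = numeric(0),
               vif = numeric(0), statistic = numeric(0),
               p_two_sided = numeric(0))
  rownames(out) <- NULL
  structure(out, skipped = skipped,
            class = c("set_test_result", "data.frame"))
}

#' Compare a gene set's lengths with the expressed background
#'
#' Two-sided Wilcoxon rank-sum test of the set members' lengths against all
#' other universe genes' lengths (exact enumeration when both groups have
#' <= 50 tie-free values, otherwise the normal approximation with tie and
#' continuity correction), plus the direction of the shift by median
#' comparison.
#'
#' @param set_genes gene ids of the set.
#' @param ann a [gene_annotation()].
#' @param universe gene ids of the expressed background (set included).
#' @return A list: `direction` (`"shorter"`/`"longer"`/`"equal"`), `p`,
#'   `median_set`, `median_background`, `n_set`, `n_background`.
#' @export
set_length_comparison <- function(set_genes, ann, universe) {
  set_genes <- intersect(set_genes, universe)
  rest <- setdiff(universe, set_genes)
  if (!length(set_genes)) stop("set has no genes in the universe")
  if (!length(rest)) stop("set equals the universe; no background remains")
  L <- setNames(ann$length_bp, ann$gene_id)
  ls <- L[set_genes]; lb <- L[rest]
  if (anyNA(ls) || anyNA(lb)) stop("missing length annotation")
  use_exact <- length(ls) <= 50 && length(lb) <= 50 &&
    !anyDuplicated(c(ls, lb))
  wt <- suppressWarnings(
    wilcox.test(ls, lb, alternative = "two.sided", exact = use_exact,
                correct = TRUE))
  ms <- median(ls); mb <- median(lb)
  list(direction = if (ms < mb) "shorter" else if (ms > mb) "longer" else "equal",
       p = wt$p.value, median_set = ms, median_background = mb,
       n_set = length(ls), n_background = length(lb))
}
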