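# Single-sample GSEA scoring, quartile stratification, preranked GSEA with
# permutation p-values, and score-expression correlation.

#' Single-sample GSEA score
#'
#' Per sample, genes are ranked by expression (descending) and the score is
#' the sum over ranks of the difference between the weighted in-set ECDF and
#' the uniform out-of-set ECDF.  Weights are `rank^alpha` where the rank
#' statistic assigns N to the most expressed gene; at `alpha = 0` the score
#' depends only on gene order (rank invariance).  Input must already be on a
#' log scale (e.g. `log2(depth-normalized + 1)` or a variance-stabilized
#' matrix).
#'
#' @param expression log-scale matrix, genes x samples.
#' @param signature `gene_signature` or character vector of gene ids.
#' @param alpha rank-weight exponent (default 0.25, the original ssGSEA
#'   convention).
#' @param normalize divide all scores by `max - min` across samples
#'   (default TRUE; a no-op for a single sample).
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expression, signature, alpha = 0.25,
                         normalize = TRUE) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else as.character(signature)
  expression <- as.matrix(expression)
  in_set <- rownames(expression) %in% genes
  if (sum(in_set) < 1) stopf("signature has no genes in the expression matrix")
  if (sum(!in_set) < 1) stopf("signature covers the whole matrix")
  n <- nrow(expression)
  scores <- apply(expression, 2, function(x) {
    r <- rank(x, ties.method = "average")        # N = most expressed
    ord <- order(x, decreasing = TRUE)
    inset_o <- in_set[ord]
    w <- r[ord]^alpha
    w[!inset_o] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset_o) / sum(!in_set)
    sum(p_in - p_out)
  })
  if (normalize && length(scores) > 1) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Quantile stratification of signature scores
#'
#' Splits a cohort into signature-high (top `hi_frac`), signature-low
#' (bottom `lo_frac`) and mid strata; the quartile defaults mirror the
#' expected ~25% prevalence of STAG2 alterations in Ewing sarcoma, and the
#' mid stratum is set aside for binary comparisons.  Stratum sizes are
#' `floor(n * frac)`; ties and ordering are broken deterministically by
#' sample id.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param hi_frac,lo_frac fractions (defaults 0.25 each; sum must be <= 1).
#' @return data.frame `sample`, `score`, `stratum` in {"high","low","mid"}.
#' @export
stratify_quantiles <- function(scores, hi_frac = 0.25, lo_frac = 0.25) {
  stopifnot(hi_frac >= 0, lo_frac >= 0, hi_frac + lo_frac <= 1)
  n <- length(scores)
  n_hi <- floor(n * hi_frac); n_lo <- floor(n * lo_frac)
  if (n_hi < 1 || n_lo < 1)
    stopf("cohort too small for stratification (n = %d)", n)
  ids <- names(scores) %||% as.character(seq_len(n))
  if (length(unique(scores)) == 1L)
    warnf("all scores identical; strata assigned by sample-id order")
  ord <- order(-scores, ids)            # deterministic tie-break by id
  stratum <- rep("mid", n)
  stratum[ord[seq_len(n_hi)]] <- "high"
  stratum[ord[seq(n - n_lo + 1L, n)]] <- "low"
  data.frame(sample = ids, score = unname(scores), stratum = stratum)
}

gsea_es <- function(stat_sorted, inset_sorted, p = 1) {
  w <- abs(stat_sorted)^p
  w[!inset_sorted] <- 0
  sw <- sum(w)
  if (sw == 0) return(0)
  p_hit <- cumsum(w) / sw
  p_miss <- cumsum(!inset_sorted) / sum(!inset_sorted)
  dev <- p_hit - p_miss
  unname(dev[which.max(abs(dev))])
}

#' Preranked GSEA with permutation p-values
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment of a gene set
#' toward the extremes of a ranked statistic.  The null is formed by
#' gene-label permutation (the preranked input has no sample structure);
#' NES is the ES divided by the mean |null ES| of matching sign, and the
#' permutation p counts same-signed null ES at least as extreme.
#'
#' @param stats named numeric vector (gene-level ranking statistic, no
#'   duplicated names).
#' @param gene_set character vector; must be smaller than the ranking.
#' @param p weight exponent on |stat| (default 1).
#' @param n_perm number of gene-label permutations (0 = ES only).
#' @param seed integer seed for the permutations.
#' @return list `es`, `nes`, `p_value`, `leading_edge`, `n_perm`.
#' @export
preranked_gsea <- function(stats, gene_set, p = 1, n_perm = 1000,
                           seed = 1L) {
  if (anyDuplicated(names(stats))) stopf("duplicate gene names in ranking")
  gene_set <- unique(gene_set)
  k <- sum(names(stats) %in% gene_set)
  if (k < 1) stopf("gene set has no genes in the ranking")
  if (k >= length(stats)) stopf("gene set as large as the ranking")
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  inset <- names(s) %in% gene_set
  es <- gsea_es(s, inset, p)
  # leading edge: genes in-set at or before the running-sum extremum
  w <- abs(s)^p; w[!inset] <- 0
  dev <- cumsum(w) / sum(w) - cumsum(!inset) / sum(!inset)
  peak <- which.max(abs(dev))
  leading <- if (es >= 0) names(s)[seq_len(peak)][inset[seq_len(peak)]]
             else names(s)[seq(peak, length(s))][inset[seq(peak, length(s))]]
  if (n_perm < 1) {
    return(list(es = es, nes = NA_real_, p_value = NA_real_,
                leading_edge = leading, n_perm = 0L))
  }
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    gsea_es(s, sample(inset), p)
  }, numeric(1))
  same <- if (es >= 0) null_es >= 0 else null_es <= 0
  n_same <- sum(same)
  nes <- if (n_same) es / mean(abs(null_es[same])) else NA_real_
  pval <- (1 + sum(abs(null_es[same]) >= abs(es))) / (1 + n_same)
  list(es = es, nes = nes, p_value = pval, leading_edge = leading,
       n_perm = as.integer(n_perm))
}

#' Correlation of signature scores with a gene's expression
#'
#' Pearson correlation (two-sided) between per-sample scores and one gene's
#' expression, e.g. the inverse coupling between the multimeric-GGAA
#' prognostic score and STAG2 transcript abundance.
#'
#' @param scores named numeric vector of sample scores.
#' @param gene_expression named numeric vector over samples.
#' @return list `r`, `p_value`, `n`.
#' @export
score_vs_gene_correlation <- function(scores, gene_expression) {
  shared <- intersect(names(scores), names(gene_expression))
  if (length(shared) < 3) stopf("need >= 3 paired samples")
  x <- scores[shared]; y <- gene_expression[shared]
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Helper log transform for count matrices
#'
#' `log2(depth-normalized counts + 1)`: a simple log-scale stabilization
#' applied before ssGSEA when no variance-stabilized matrix is supplied.
#' @param counts genes x samples count matrix.
#' @param target_depth depth to normalize columns to (default 1e6).
#' @return log2 matrix.
#' @export
log_normalize_counts <- function(counts, target_depth = 1e6) {
  counts <- as.matrix(counts)
  ls <- colSums(counts)
  if (any(ls <= 0)) stopf("empty sample column")
  log2(sweep(counts, 2, target_depth / ls, `*`) + 1)
}
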