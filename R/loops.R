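# Chromatin-loop ingestion, replicate consensus, and anchor-to-peak /
# anchor-to-promoter annotation for enhancer -> gene assignment.

#' Read a bedPE-like loop file
#'
#' Columns: `chrom1 start1 end1 chrom2 start2 end2 [score]`, tab-separated,
#' 0-based half-open.  Anchors are normalized so anchor1 precedes anchor2;
#' trans-chromosomal rows are dropped (a message reports the count).
#'
#' @param path loop file.
#' @return data.frame `chrom`, `start1`, `end1`, `start2`, `end2`, `score`.
#' @export
read_loops <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(raw) < 6) stopf("loop file needs >= 6 columns, got %d", ncol(raw))
  names(raw)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  raw$score <- if (ncol(raw) >= 7) as.numeric(raw[[7]]) else 1
  bad <- which(!is.finite(raw$start1) | !is.finite(raw$end1) |
                 !is.finite(raw$start2) | !is.finite(raw$end2) |
                 raw$start1 >= raw$end1 | raw$start2 >= raw$end2)
  if (length(bad)) stopf("malformed loop row at line %d of %s", bad[1], path)
  trans <- raw$chrom1 != raw$chrom2
  if (any(trans)) {
    message(sprintf("read_loops: dropped %d trans-chromosomal row(s)",
                    sum(trans)))
    raw <- raw[!trans, , drop = FALSE]
  }
  normalize_loops(data.frame(chrom = raw$chrom1,
                             start1 = raw$start1, end1 = raw$end1,
                             start2 = raw$start2, end2 = raw$end2,
                             score = raw$score))
}

normalize_loops <- function(loops) {
  flip <- loops$start2 < loops$start1
  if (any(flip)) {
    s1 <- loops$start1[flip]; e1 <- loops$end1[flip]
    loops$start1[flip] <- loops$start2[flip]
    loops$end1[flip] <- loops$end2[flip]
    loops$start2[flip] <- s1
    loops$end2[flip] <- e1
  }
  selfov <- loops$end1 > loops$start2
  if (any(selfov)) {
    message(sprintf("dropped %d loop(s) with overlapping anchors",
                    sum(selfov)))
    loops <- loops[!selfov, , drop = FALSE]
  }
  rownames(loops) <- NULL
  loops
}

#' Replicate-consensus loops
#'
#' Keeps only high-confidence loops supported by both replicates: a
#' replicate-1 loop is consensus when some replicate-2 loop on the same
#' chromosome matches it at both anchors after each anchor is widened by
#' `tolerance / 2`.  Matching is greedy 1-to-1 in descending score order so
#' one loop can never absorb several partners.  The merged anchor is the
#' intersection of the matched anchors when they overlap, otherwise a
#' midpoint interval between them.
#'
#' @param rep1,rep2 loop tables ([read_loops()] format).
#' @param tolerance matching tolerance in bp (default 10000, on the order
#'   of typical loop-call resolution).
#' @return consensus loop table with `support = 2` and the matched replicate
#'   row indices (`rep1_idx`, `rep2_idx`).
#' @export
consensus_loops <- function(rep1, rep2, tolerance = 10000) {
  if (tolerance < 0) stopf("tolerance must be non-negative")
  half <- tolerance / 2
  ord1 <- order(-rep1$score)
  taken2 <- logical(nrow(rep2))
  m1 <- integer(0); m2 <- integer(0)
  for (i in ord1) {
    cand <- which(!taken2 & rep2$chrom == rep1$chrom[i] &
                    rep2$start1 - half < rep1$end1[i] + half &
                    rep2$end1 + half > rep1$start1[i] - half &
                    rep2$start2 - half < rep1$end2[i] + half &
                    rep2$end2 + half > rep1$start2[i] - half)
    if (!length(cand)) next
    j <- cand[which.max(rep2$score[cand])]
    taken2[j] <- TRUE
    m1 <- c(m1, i); m2 <- c(m2, j)
  }
  if (!length(m1)) {
    return(data.frame(chrom = character(), start1 = integer(),
                      end1 = integer(), start2 = integer(), end2 = integer(),
                      score = numeric(), support = integer(),
                      rep1_idx = integer(), rep2_idx = integer()))
  }
  merge_anchor <- function(s1, e1, s2, e2) {
    s <- pmax(s1, s2); e <- pmin(e1, e2)
    degen <- s >= e
    if (any(degen)) {   # disjoint after jitter: midpoint interval
      mid <- floor((pmin(e1, e2)[degen] + pmax(s1, s2)[degen]) / 2)
      s[degen] <- mid; e[degen] <- mid + 1L
    }
    list(start = s, end = e)
  }
  a1 <- merge_anchor(rep1$start1[m1], rep1$end1[m1],
                     rep2$start1[m2], rep2$end1[m2])
  a2 <- merge_anchor(rep1$start2[m1], rep1$end2[m1],
                     rep2$start2[m2], rep2$end2[m2])
  out <- data.frame(chrom = rep1$chrom[m1],
                    start1 = a1$start, end1 = a1$end,
                    start2 = a2$start, end2 = a2$end,
                    score = pmax(rep1$score[m1], rep2$score[m2]),
                    support = 2L, rep1_idx = m1, rep2_idx = m2)
  out <- out[order(out$chrom, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter intervals from a gene/TSS table
#'
#' The promoter is the 1.5 kb region immediately upstream of the TSS:
#' `[tss - upstream, tss)` on the plus strand, `[tss + 1, tss + upstream]`
#' equivalents on minus (half-open: `(tss, tss + upstream]` becomes
#' `[tss + 1, tss + upstream + 1)`); an optional downstream margin extends
#' across the TSS.
#'
#' @param genes data.frame `gene`, `chrom`, `strand`, `tss` (0-based
#'   position of the transcription start).
#' @param upstream bp upstream of the TSS (default 1500).
#' @param downstream bp downstream margin (default 0, TSS excluded).
#' @return interval table with `name` = gene id.
#' @export
promoters_from_genes <- function(genes, upstream = 1500L, downstream = 0L) {
  stopifnot(all(c("gene", "chrom", "strand", "tss") %in% names(genes)))
  plus <- genes$strand != "-"
  start <- ifelse(plus, genes$tss - upstream, genes$tss + 1L - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + 1L + upstream)
  data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(start)),
             end = as.integer(end), name = genes$gene,
             strand = genes$strand)
}

#' Annotate consensus-loop anchors with peaks and promoters
#'
#' For every loop, records which peaks overlap each anchor and which genes'
#' promoters overlap each anchor.  Both orientations are kept: either anchor
#' may carry the enhancer and the other the promoter.
#'
#' @param consensus consensus loop table.
#' @param peaks peak interval table with a `name` column of peak ids.
#' @param genes gene/TSS table (see [promoters_from_genes()]).
#' @param promoter_upstream,promoter_downstream promoter definition.
#' @return the loop table with list-columns `anchor1_peaks`,
#'   `anchor2_peaks`, `anchor1_genes`, `anchor2_genes`.
#' @export
annotate_anchors <- function(consensus, peaks, genes,
                             promoter_upstream = 1500L,
                             promoter_downstream = 0L) {
  prom <- promoters_from_genes(genes, promoter_upstream, promoter_downstream)
  hit_ids <- function(anch, feat, ids) {
    res <- rep(list(character(0)), nrow(anch))
    if (nrow(feat) && nrow(anch)) {
      ov <- intersect_intervals(anch, feat)$pairs
      if (nrow(ov)) {
        sp <- split(ids[ov$b_idx], ov$a_idx)
        res[as.integer(names(sp))] <- lapply(sp, unique)
      }
    }
    res
  }
  a1 <- data.frame(chrom = consensus$chrom, start = consensus$start1,
                   end = consensus$end1)
  a2 <- data.frame(chrom = consensus$chrom, start = consensus$start2,
                   end = consensus$end2)
  pk <- peaks[, c("chrom", "start", "end")]
  pid <- peaks$name
  out <- consensus
  out$anchor1_peaks <- hit_ids(a1, pk, pid)
  out$anchor2_peaks <- hit_ids(a2, pk, pid)
  out$anchor1_genes <- hit_ids(a1, prom[, c("chrom", "start", "end")],
                               prom$name)
  out$anchor2_genes <- hit_ids(a2, prom[, c("chrom", "start", "end")],
                               prom$name)
  out
}

#' Enhancer-to-gene map through consensus loops
#'
#' Selects loops in which one anchor overlaps a peak satisfying a predicate
#' (e.g. upregulated multimeric-GGAA) and collects the genes whose promoters
#' overlap the opposite anchor.  A loop whose peak-bearing anchor has no
#' promoter on the other end contributes nothing (no nearest-gene fallback:
#' the map is loop-defined only).
#'
#' @param annotated output of [annotate_anchors()].
#' @param peak_table [differential_peaks()] output joined with profiles
#'   (columns `peak`, `log2fc`, `max_run`, `repeat_class`).
#' @param predicate function(peak_table rows) -> logical; selects qualifying
#'   peaks.
#' @return data.frame `gene`, `n_loops`, `best_peak`, `peak_class`
#'   (`best_peak` = qualifying peak with largest |log2fc| among supporting
#'   loops), deduplicated by gene.
#' @export
enhancer_gene_map <- function(annotated, peak_table, predicate) {
  ok_peaks <- peak_table$peak[predicate(peak_table)]
  pairs <- list()
  add_pairs <- function(peaks_here, genes_there) {
    for (i in seq_along(peaks_here)) {
      pk <- intersect(peaks_here[[i]], ok_peaks)
      gs <- genes_there[[i]]
      if (length(pk) && length(gs)) {
        pairs[[length(pairs) + 1L]] <<-
          expand.grid(gene = gs, peak = pk, stringsAsFactors = FALSE)
      }
    }
  }
  add_pairs(annotated$anchor1_peaks, annotated$anchor2_genes)
  add_pairs(annotated$anchor2_peaks, annotated$anchor1_genes)
  if (!length(pairs)) {
    return(data.frame(gene = character(), n_loops = integer(),
                      best_peak = character(), peak_class = character()))
  }
  pp <- do.call(rbind, pairs)
  j <- match(pp$peak, peak_table$peak)
  pp$abs_fc <- abs(peak_table$log2fc[j])
  pp$class <- peak_table$repeat_class[j]
  sp <- split(pp, pp$gene)
  out <- do.call(rbind, lapply(sp, function(d) {
    b <- which.max(d$abs_fc)
    data.frame(gene = d$gene[1], n_loops = nrow(d),
               best_peak = d$peak[b], peak_class = d$class[b])
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
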