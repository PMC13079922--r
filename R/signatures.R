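# Repeat-class-specific EWS-FLI1 gene-signature derivation, per-gene Cox
# screening, the prognostic refinement, and the STAG2-inactivation activity
# signature.

#' Gene-signature container
#'
#' A named gene set with its direction relative to the defining contrast and
#' provenance (rule parameters plus digests of every input) sufficient to
#' verify re-derivation.
#'
#' @param name signature name (e.g. `"10x_promoter"`).
#' @param genes character vector of unique gene ids.
#' @param direction `"up"` or `"down"`.
#' @param provenance named list of rule parameters and input digests.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, direction = c("up", "down"),
                           provenance = list()) {
  direction <- match.arg(direction)
  genes <- sort(unique(as.character(genes)))
  structure(list(name = name, genes = genes, direction = direction,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s (%s): %d genes\n",
              x$name, x$direction, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

sig_provenance <- function(params, ...) {
  inputs <- list(...)
  c(params, list(input_digests = lapply(inputs, digest_object)))
}

# genes whose promoter overlaps >= 1 qualifying peak
promoter_overlap_genes <- function(peaks_bed, ok_peaks, genes,
                                   promoter_upstream, promoter_downstream) {
  sel <- peaks_bed[peaks_bed$name %in% ok_peaks, , drop = FALSE]
  prom <- promoters_from_genes(genes, promoter_upstream, promoter_downstream)
  if (!nrow(sel) || !nrow(prom)) return(character(0))
  ov <- intersect_intervals(prom[, c("chrom", "start", "end")],
                            sel[, c("chrom", "start", "end")])$a_hit
  prom$name[ov]
}

#' Multimeric (10x) GGAA promoter signature
#'
#' Genes whose promoter overlaps at least one upregulated multimeric peak
#' (largest GGAA run >= `min_run` and log2 fold > `fc_gt`).
#'
#' @param peak_table [differential_peaks()] output with profiles joined
#'   (`peak`, `log2fc`, `max_run`).
#' @param peaks_bed peak intervals with `name` matching `peak_table$peak`.
#' @param genes gene/TSS table.
#' @param min_run minimum consecutive-GGAA count (default 10).
#' @param fc_gt log2 fold-change lower bound (default 0.5, the
#'   methods-preset gain threshold).
#' @param promoter_upstream,promoter_downstream promoter definition
#'   (default 1.5 kb strictly upstream).
#' @return `gene_signature`, direction `"up"`.
#' @export
build_10x_promoter <- function(peak_table, peaks_bed, genes,
                               min_run = 10L, fc_gt = 0.5,
                               promoter_upstream = 1500L,
                               promoter_downstream = 0L) {
  ok <- peak_table$peak[peak_table$max_run >= min_run &
                          peak_table$log2fc > fc_gt]
  gs <- promoter_overlap_genes(peaks_bed, ok, genes,
                               promoter_upstream, promoter_downstream)
  gene_signature("10x_promoter", gs, "up",
                 sig_provenance(list(rule = "promoter_overlap",
                                     min_run = min_run, fc_gt = fc_gt,
                                     n_qualifying_peaks = length(ok)),
                                peak_table = peak_table, genes = genes))
}

#' Monomeric (1x) GGAA promoter signature
#'
#' Genes whose promoter overlaps a downregulated monomeric peak (GGAA run
#' exactly `run_eq`, log2 fold < `fc_lt`), intersected with genes
#' significantly downregulated upon FLI1 knockdown in the supplied
#' differential-expression table.
#'
#' @inheritParams build_10x_promoter
#' @param de_sifli1 DE table with columns `gene`, `log2FC`, `adj_p`.
#' @param run_eq exact GGAA unit count (default 1).
#' @param fc_lt log2 fold-change upper bound (default -1).
#' @param de_lfc_lt,de_p_lt DE filter: `log2FC < de_lfc_lt` and
#'   `adj_p < de_p_lt` (defaults 0 and 0.05).
#' @return `gene_signature`, direction `"down"` (down upon STAG2 loss).
#' @export
build_1x_promoter <- function(peak_table, peaks_bed, genes, de_sifli1,
                              run_eq = 1L, fc_lt = -1,
                              de_lfc_lt = 0, de_p_lt = 0.05,
                              promoter_upstream = 1500L,
                              promoter_downstream = 0L) {
  need <- c("gene", "log2FC", "adj_p")
  miss <- setdiff(need, names(de_sifli1))
  if (length(miss)) stopf("DE table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  ok <- peak_table$peak[peak_table$max_run == run_eq &
                          peak_table$log2fc < fc_lt]
  gs <- promoter_overlap_genes(peaks_bed, ok, genes,
                               promoter_upstream, promoter_downstream)
  de_down <- de_sifli1$gene[de_sifli1$log2FC < de_lfc_lt &
                              de_sifli1$adj_p < de_p_lt]
  gene_signature("1x_promoter", intersect(gs, de_down), "down",
                 sig_provenance(list(rule = "promoter_overlap+siFLI1_down",
                                     run_eq = run_eq, fc_lt = fc_lt,
                                     de_lfc_lt = de_lfc_lt, de_p_lt = de_p_lt,
                                     n_qualifying_peaks = length(ok)),
                                peak_table = peak_table, genes = genes,
                                de = de_sifli1))
}

#' Enhancer signatures through consensus loops
#'
#' `class = "10x"`: genes looped (via consensus Hi-C loops) to an
#' upregulated multimeric peak (`max_run >= min_run`, `log2fc > fc_gt`),
#' no DE filter.  `class = "1x"`: genes looped to a downregulated monomeric
#' peak (`max_run == 1`, `log2fc < fc_lt`), then restricted to genes
#' downregulated upon FLI1 knockdown.
#'
#' @param annotated [annotate_anchors()] output.
#' @param peak_table differential peaks with profiles joined.
#' @param class `"10x"` or `"1x"`.
#' @param de_sifli1 DE table (required for `"1x"`).
#' @param min_run multimeric threshold (default 10; set 5 for the broader
#'   >=5x multimeric convention).
#' @param fc_gt,fc_lt log2 thresholds (defaults 0.5 / -1).
#' @param de_lfc_lt,de_p_lt DE filter for the 1x class.
#' @return `gene_signature` (`10x_enhancer` up / `1x_enhancer` down).
#' @export
build_enhancer_signature <- function(annotated, peak_table,
                                     class = c("10x", "1x"),
                                     de_sifli1 = NULL,
                                     min_run = 10L, fc_gt = 0.5, fc_lt = -1,
                                     de_lfc_lt = 0, de_p_lt = 0.05) {
  class <- match.arg(class)
  if (class == "10x") {
    pred <- function(pt) pt$max_run >= min_run & pt$log2fc > fc_gt
    map <- enhancer_gene_map(annotated, peak_table, pred)
    return(gene_signature("10x_enhancer", map$gene, "up",
                          sig_provenance(list(rule = "loop_to_multimeric_up",
                                              min_run = min_run, fc_gt = fc_gt,
                                              n_loops = sum(map$n_loops)),
                                         annotated = annotated,
                                         peak_table = peak_table)))
  }
  if (is.null(de_sifli1)) stopf("1x enhancer signature requires de_sifli1")
  pred <- function(pt) pt$max_run == 1L & pt$log2fc < fc_lt
  map <- enhancer_gene_map(annotated, peak_table, pred)
  de_down <- de_sifli1$gene[de_sifli1$log2FC < de_lfc_lt &
                              de_sifli1$adj_p < de_p_lt]
  gene_signature("1x_enhancer", intersect(map$gene, de_down), "down",
                 sig_provenance(list(rule = "loop_to_monomeric_down+siFLI1",
                                     fc_lt = fc_lt, de_lfc_lt = de_lfc_lt,
                                     de_p_lt = de_p_lt,
                                     n_loops = sum(map$n_loops)),
                                annotated = annotated,
                                peak_table = peak_table, de = de_sifli1))
}

#' Univariate Cox screen across genes
#'
#' Fits a proportional-hazards model per gene on z-scored expression
#' (Efron tie handling).  Genes with (near-)constant expression are flagged
#' and excluded; non-converged fits are flagged.
#'
#' @param expression genes x samples matrix; column names are sample ids.
#' @param surv data.frame `sample`, `time`, `event` (0 censored / 1 death).
#' @param ties tie method passed to [survival::coxph()].
#' @return data.frame `gene`, `coef`, `se`, `z`, `p_value`, `score_chisq`,
#'   `converged` (constant genes appear with NA coefficients and
#'   `converged = FALSE`).
#' @export
cox_screen <- function(expression, surv, ties = "efron") {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  shared <- intersect(colnames(expression), surv$sample)
  if (length(shared) < 10) stopf("need >= 10 samples with expression + survival")
  surv <- surv[match(shared, surv$sample), ]
  if (sum(surv$event) < 1) stopf("no events in survival table")
  expression <- expression[, shared, drop = FALSE]
  ss <- survival::Surv(surv$time, surv$event)
  res <- lapply(rownames(expression), function(g) {
    x <- as.numeric(expression[g, ])
    if (sd(x) == 0) {
      return(data.frame(gene = g, coef = NA_real_, se = NA_real_,
                        z = NA_real_, p_value = NA_real_,
                        score_chisq = NA_real_, converged = FALSE))
    }
    x <- (x - mean(x)) / sd(x)
    fit <- tryCatch(survival::coxph(ss ~ x, ties = ties),
                    error = function(e) NULL, warning = function(w) {
                      suppressWarnings(survival::coxph(ss ~ x, ties = ties))
                    })
    if (is.null(fit)) {
      return(data.frame(gene = g, coef = NA_real_, se = NA_real_,
                        z = NA_real_, p_value = NA_real_,
                        score_chisq = NA_real_, converged = FALSE))
    }
    sm <- summary(fit)
    data.frame(gene = g, coef = unname(stats::coef(fit)),
               se = sm$coefficients[1, "se(coef)"],
               z = sm$coefficients[1, "z"],
               p_value = sm$coefficients[1, "Pr(>|z|)"],
               score_chisq = unname(sm$sctest["test"]),
               converged = is.finite(stats::coef(fit)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Prognostic refinement of a signature
#'
#' Intersects a signature with genes showing a positive Cox coefficient for
#' overall survival (the sign-only filter used for the compact prognostic
#' set; an optional Wald-p threshold is off by default).
#'
#' @param signature `gene_signature`.
#' @param cox_results [cox_screen()] output.
#' @param coef_gt coefficient lower bound (default 0).
#' @param p_lt optional Wald p threshold (default `NULL`, no p filter).
#' @return refined `gene_signature` named `prognostic_<name>`.  Signature
#'   genes absent from the Cox results are dropped with a warning.
#' @export
refine_prognostic <- function(signature, cox_results, coef_gt = 0,
                              p_lt = NULL) {
  stopifnot(inherits(signature, "gene_signature"))
  missing <- setdiff(signature$genes, cox_results$gene)
  if (length(missing))
    warnf("%d signature gene(s) absent from Cox results; dropped",
          length(missing))
  cx <- cox_results[match(intersect(signature$genes, cox_results$gene),
                          cox_results$gene), ]
  keep <- !is.na(cx$coef) & cx$coef > coef_gt
  if (!is.null(p_lt)) keep <- keep & !is.na(cx$p_value) & cx$p_value < p_lt
  gene_signature(paste0("prognostic_", signature$name),
                 cx$gene[keep], signature$direction,
                 sig_provenance(list(rule = "cox_coefficient_positive",
                                     coef_gt = coef_gt, p_lt = p_lt),
                                signature = signature$genes,
                                cox = cox_results))
}

#' STAG2-inactivation activity signature
#'
#' Genes significantly differential in every supplied model-system DE table
#' (>= 2 tables, e.g. STAG2-silenced A673 and TC-71 contrasts) with
#' concordant direction across all of them.
#'
#' @param de_tables named list of >= 2 DE tables (`gene`, `log2FC`,
#'   `adj_p`).
#' @param adj_p_lt significance threshold applied in each table.
#' @return list of two `gene_signature`s: `up` (up upon STAG2 loss) and
#'   `down`.
#' @export
build_activity_signature <- function(de_tables, adj_p_lt = 0.05) {
  if (length(de_tables) < 2) stopf("need >= 2 model-system DE tables")
  per <- lapply(de_tables, function(d) {
    sig <- d[d$adj_p < adj_p_lt, c("gene", "log2FC")]
    setNames(sign(sig$log2FC), sig$gene)
  })
  shared <- Reduce(intersect, lapply(per, names))
  if (length(shared)) {
    signs <- sapply(per, function(v) v[shared])
    if (length(shared) == 1L) signs <- matrix(signs, nrow = 1)
    conc <- apply(signs, 1, function(s) all(s == s[1]) && s[1] != 0)
    shared <- shared[conc]
    dirn <- sapply(per[[1]][shared], identity)
  } else dirn <- numeric(0)
  prov <- sig_provenance(list(rule = "concordant_significant_all_systems",
                              adj_p_lt = adj_p_lt,
                              n_systems = length(de_tables)),
                         de_tables = de_tables)
  list(up = gene_signature("stag2_inactivation_up",
                           shared[dirn > 0], "up", prov),
       down = gene_signature("stag2_inactivation_down",
                             shared[dirn < 0], "down", prov))
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' @param signatures list of `gene_signature` (or named list of character
#'   vectors).
#' @param path file path.
#' @return `read_gmt`: named list of character vectors; `write_gmt`:
#'   `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    if (inherits(s, "gene_signature")) {
      paste(c(s$name, s$direction, s$genes), collapse = "\t")
    } else paste(c("set", "na", s), collapse = "\t")
  }, character(1))
  if (!is.null(names(signatures))) {
    lines <- mapply(function(nm, s) {
      g <- if (inherits(s, "gene_signature")) s$genes else s
      d <- if (inherits(s, "gene_signature")) s$direction else "na"
      paste(c(nm, d, g), collapse = "\t")
    }, names(signatures), signatures)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}
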