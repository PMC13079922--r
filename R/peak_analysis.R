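# Per-peak signal normalization, condition fold-changes, lost/retained/gained
# partitioning and repeat-class stratification of the cistrome.

#' Fold-change threshold presets
#'
#' Two threshold sets appear in the source analyses and are never mixed:
#' the figure preset (`lost < -2`, `gained > 1.25`, log2 scale) used for the
#' high-confidence lost/gained enhancer scatter, and the methods preset
#' (`lost < -1`, `gained > 0.5`) used by the signature-definition rules.
#' All folds in this package are log2.
#'
#' @param preset `"figure"` or `"methods"`.
#' @return list with `lost_lt` and `gained_gt` (log2 thresholds).
#' @export
fc_thresholds <- function(preset = c("figure", "methods")) {
  preset <- match.arg(preset)
  switch(preset,
         figure = list(lost_lt = -2, gained_gt = 1.25),
         methods = list(lost_lt = -1, gained_gt = 0.5))
}

#' Depth-normalize a peak-signal count table
#'
#' Scales raw per-peak counts to a common sequencing depth
#' (`count * target_depth / library_size`); the default target is 16 million
#' reads.
#'
#' @param counts numeric matrix, peaks x samples.
#' @param lib_sizes named numeric vector of library sizes (reads) covering
#'   every column of `counts`.
#' @param target_depth target depth in reads (default 16e6).
#' @return normalized numeric matrix, same dimensions.
#' @export
normalize_signal <- function(counts, lib_sizes, target_depth = 16e6) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(colnames(counts)))
  miss <- setdiff(colnames(counts), names(lib_sizes))
  if (length(miss)) stopf("library size missing for sample(s): %s",
                          paste(miss, collapse = ", "))
  ls <- lib_sizes[colnames(counts)]
  if (any(ls <= 0)) stopf("library sizes must be positive")
  sweep(counts, 2, target_depth / ls, `*`)
}

#' Per-peak log2 fold-change between conditions
#'
#' `log2((mean_treatment + c) / (mean_control + c))` on the normalized
#' scale; the pseudocount (default 1) guards against empty peaks.
#'
#' @param normalized normalized signal matrix (peaks x samples).
#' @param control_ids,treatment_ids column names of the two groups.
#' @param pseudocount added to both group means.
#' @return named numeric vector of log2 fold-changes.
#' @export
peak_log2fc <- function(normalized, control_ids, treatment_ids,
                        pseudocount = 1) {
  stopifnot(length(control_ids) >= 1, length(treatment_ids) >= 1)
  mc <- rowMeans(normalized[, control_ids, drop = FALSE])
  mt <- rowMeans(normalized[, treatment_ids, drop = FALSE])
  log2((mt + pseudocount) / (mc + pseudocount))
}

#' Build a differential-peak table
#'
#' Joins per-peak normalized means, log2 fold-change and a
#' lost/retained/gained status call under a threshold preset, optionally
#' joined with repeat profiles.
#'
#' @param normalized normalized signal matrix with peak ids as rownames.
#' @param control_ids,treatment_ids sample groups.
#' @param thresholds list from [fc_thresholds()] or explicit
#'   `list(lost_lt=, gained_gt=)`.
#' @param profiles optional [profile_intervals()] output joined on peak id.
#' @param pseudocount see [peak_log2fc()].
#' @return data.frame: `peak`, `mean_control`, `mean_treatment`, `log2fc`,
#'   `status`, and when profiles are given `max_run`, `repeat_class`.
#' @export
differential_peaks <- function(normalized, control_ids, treatment_ids,
                               thresholds = fc_thresholds("figure"),
                               profiles = NULL, pseudocount = 1) {
  lfc <- peak_log2fc(normalized, control_ids, treatment_ids, pseudocount)
  out <- data.frame(
    peak = rownames(normalized),
    mean_control = rowMeans(normalized[, control_ids, drop = FALSE]),
    mean_treatment = rowMeans(normalized[, treatment_ids, drop = FALSE]),
    log2fc = unname(lfc))
  out$status <- ifelse(out$log2fc < thresholds$lost_lt, "lost",
                       ifelse(out$log2fc > thresholds$gained_gt,
                              "gained", "retained"))
  if (!is.null(profiles)) {
    j <- match(out$peak, profiles$peak)
    if (anyNA(j)) stopf("peak(s) missing from profiles: %s",
                        paste(head(out$peak[is.na(j)]), collapse = ", "))
    out$max_run <- profiles$max_run[j]
    out$repeat_class <- profiles$repeat_class[j]
  }
  rownames(out) <- NULL
  out
}

#' Venn partition of two peak sets
#'
#' Presence/absence overlap of two called peak sets (distinct from the
#' fold-change status call): a peak is shared when it reciprocally overlaps
#' a peak of the other set by at least `min_overlap` bp.
#'
#' @param peaks_a,peaks_b interval tables.
#' @param min_overlap minimum overlap bp.
#' @return list with `counts` (`shared_a`, `shared_b`, `a_only`, `b_only`)
#'   and `fractions` (`lost_fraction` = a_only / |a|), plus the per-set hit
#'   vectors.
#' @export
venn_partition <- function(peaks_a, peaks_b, min_overlap = 1L) {
  ha <- intersect_intervals(peaks_a, peaks_b, min_overlap)$a_hit
  hb <- intersect_intervals(peaks_b, peaks_a, min_overlap)$a_hit
  counts <- c(shared_a = sum(ha), shared_b = sum(hb),
              a_only = sum(!ha), b_only = sum(!hb))
  fr <- if (nrow(peaks_a)) unname(counts["a_only"]) / nrow(peaks_a) else NA_real_
  list(counts = counts, fractions = c(lost_fraction = fr),
       a_hit = ha, b_hit = hb)
}

#' Stratify differential peaks by repeat class
#'
#' Cross-tabulates lost/retained/gained status against repeat class and
#' summarizes the per-class log2 fold-change distribution; optionally runs a
#' two-sided Welch t test between two named classes.
#'
#' @param diff_peaks [differential_peaks()] output carrying `repeat_class`.
#' @param test_classes optional length-2 character vector of classes to
#'   compare by two-sided t test on log2fc.
#' @return list with `contingency` (status x class counts), `proportions`
#'   (within-status class proportions), `class_stats` (per-class n, mean,
#'   median, sd of log2fc) and optional `test`.
#' @export
stratify_by_class <- function(diff_peaks, test_classes = NULL) {
  stopifnot(all(c("status", "repeat_class", "log2fc") %in% names(diff_peaks)))
  tab <- table(status = diff_peaks$status, class = diff_peaks$repeat_class)
  props <- prop.table(tab, margin = 1)
  sp <- split(diff_peaks$log2fc, diff_peaks$repeat_class)
  class_stats <- data.frame(
    repeat_class = names(sp),
    n = lengths(sp),
    mean_log2fc = vapply(sp, mean, numeric(1)),
    median_log2fc = vapply(sp, stats::median, numeric(1)),
    sd_log2fc = vapply(sp, sd, numeric(1)))
  rownames(class_stats) <- NULL
  out <- list(contingency = tab, proportions = props, class_stats = class_stats)
  if (!is.null(test_classes)) {
    stopifnot(length(test_classes) == 2)
    x <- sp[[test_classes[1]]]; y <- sp[[test_classes[2]]]
    if (length(x) >= 2 && length(y) >= 2) {
      tt <- stats::t.test(x, y)
      out$test <- list(classes = test_classes, statistic = unname(tt$statistic),
                       p_value = tt$p.value)
    }
  }
  out
}

#' Signal profile matrix around anchor points
#'
#' Mean signal in fixed-width bins around each anchor midpoint from a
#' bedGraph-like track; column means give the aggregate profile curve
#' (metaplot) used to visualize binding centered on GGAA microsatellites.
#'
#' @param track data.frame `chrom`, `start`, `end`, `value`, non-overlapping
#'   within a sample.
#' @param anchors interval table; midpoints are used.
#' @param half_width bp on each side of the anchor midpoint.
#' @param bin bin width in bp (must divide 2*half_width).
#' @return list with `matrix` (anchors x bins; NA where the window leaves
#'   the covered genome/chromosome edge) and `profile` (column means,
#'   NA-removed).
#' @export
signal_profile_matrix <- function(track, anchors, half_width = 2000L,
                                  bin = 50L) {
  stopifnot(half_width > 0, bin > 0, (2 * half_width) %% bin == 0)
  nb <- as.integer(2 * half_width / bin)
  mid <- floor((anchors$start + anchors$end) / 2)
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = nb)
  offs <- seq(0L, nb - 1L) * bin - half_width
  tr_by_chrom <- if (nrow(track)) split(track, track$chrom) else list()
  for (i in seq_len(nrow(anchors))) {
    tr <- tr_by_chrom[[anchors$chrom[i]]]
    if (is.null(tr)) next
    bs <- mid[i] + offs
    if (bs[1] < 0) next   # too near the chromosome edge: row stays NA
    be <- bs + bin
    # mean of track value over each bin (uncovered bases count as NA)
    for (j in seq_len(nb)) {
      sel <- tr$start < be[j] & tr$end > bs[j]
      if (!any(sel)) next
      ov <- pmin(tr$end[sel], be[j]) - pmax(tr$start[sel], bs[j])
      covered <- sum(ov)
      if (covered >= bin) {
        mat[i, j] <- sum(tr$value[sel] * ov) / covered
      } else {
        mat[i, j] <- sum(tr$value[sel] * ov) / bin
      }
    }
  }
  list(matrix = mat,
       profile = colMeans(mat, na.rm = TRUE),
       bin_offsets = offs + bin / 2)
}

#' Pearson correlation of two fold-change vectors
#'
#' @param log2fc_x,log2fc_y named numeric vectors over shared peaks (matched
#'   by name when names are present, by position otherwise).
#' @return list `r`, `p_value`, `n`.
#' @export
fc_correlation <- function(log2fc_x, log2fc_y) {
  if (!is.null(names(log2fc_x)) && !is.null(names(log2fc_y))) {
    shared <- intersect(names(log2fc_x), names(log2fc_y))
    log2fc_x <- log2fc_x[shared]; log2fc_y <- log2fc_y[shared]
  }
  if (length(log2fc_x) < 3) stopf("need at least 3 shared peaks")
  if (sd(log2fc_x) == 0 || sd(log2fc_y) == 0)
    stopf("zero variance in fold-change vector")
  ct <- stats::cor.test(log2fc_x, log2fc_y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(log2fc_x))
}

#' Surrogate differential-expression test
#'
#' Per-gene Welch t test on `log2(normalized + 1)` with Benjamini-Hochberg
#' correction.  Used to turn synthetic count matrices into the
#' differential-expression tables the signature rules consume; it stands in
#' for the count-model fits applied to the real cohorts, which are consumed
#' as pre-computed tables.
#'
#' @param normalized normalized expression matrix (genes x samples).
#' @param groups named character/factor over samples with exactly 2 levels;
#'   log2FC is level2 vs level1.
#' @return data.frame `gene`, `log2FC`, `statistic`, `p_value`, `adj_p`.
#' @export
surrogate_de <- function(normalized, groups) {
  groups <- as.factor(groups[colnames(normalized)])
  lv <- levels(droplevels(groups))
  stopifnot(length(lv) == 2)
  if (any(table(groups) < 2)) stopf("need >=2 samples per group")
  lx <- log2(normalized + 1)
  g1 <- lx[, groups == lv[1], drop = FALSE]
  g2 <- lx[, groups == lv[2], drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, var); v2 <- apply(g2, 1, var)
  n1 <- ncol(g1); n2 <- ncol(g2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[is.na(p)] <- 1   # zero-variance null genes
  tstat[is.na(tstat)] <- 0
  data.frame(gene = rownames(normalized),
             log2FC = unname(m2 - m1),
             statistic = unname(tstat),
             p_value = unname(p),
             adj_p = p.adjust(p, "BH"),
             row.names = NULL)
}
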