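# Minimal interval algebra over BED-style (0-based, half-open) tables.
# All user-facing coordinates are 0-based half-open; IRanges (1-based closed)
# is used internally.

#' Validate a BED-style interval table
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open); optional `name`, `score`, `strand`.
#' @param chrom_sizes optional named vector of chromosome lengths (bp); when
#'   supplied, every interval must lie within its chromosome.
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("interval table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(x)) {
    bad <- which(!(x$start >= 0 & x$start < x$end))
    if (length(bad)) stopf("invalid interval at row %d: start=%s end=%s",
                           bad[1], x$start[bad[1]], x$end[bad[1]])
    if (!is.null(chrom_sizes)) {
      unk <- setdiff(unique(x$chrom), names(chrom_sizes))
      if (length(unk)) stopf("chromosome(s) absent from size table: %s",
                             paste(unk, collapse = ", "))
      over <- which(x$end > chrom_sizes[x$chrom])
      if (length(over)) stopf("interval at row %d exceeds chromosome bounds",
                              over[1])
    }
  }
  invisible(x)
}

# split a BED table into a per-chromosome IRanges list (1-based closed)
as_iranges_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) {
    list(idx = i, ir = IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i]))
  })
}

#' Sort and merge intervals
#'
#' Intervals closer than `merge_distance` bp (gap strictly less than the
#' distance) are merged into one spanning interval.  With the default
#' distance 0 only genuinely overlapping intervals merge: half-open abutting
#' intervals (`[10,20)`, `[20,30)`) are kept separate.
#'
#' @param x interval table (see [validate_intervals()]).
#' @param merge_distance non-negative merge distance in bp.
#' @return sorted, pairwise non-overlapping interval table with columns
#'   `chrom`, `start`, `end`, `n_merged`.
#' @export
sort_merge <- function(x, merge_distance = 0L) {
  validate_intervals(x)
  stopifnot(merge_distance >= 0)
  if (!nrow(x)) return(data.frame(chrom = character(), start = integer(),
                                  end = integer(), n_merged = integer()))
  out <- lapply(split(x, x$chrom), function(xx) {
    ir <- IRanges::IRanges(xx$start + 1L, xx$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_distance, with.revmap = TRUE)
    data.frame(chrom = xx$chrom[1],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               n_merged = lengths(S4Vectors::mcols(red)$revmap))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Widen intervals symmetrically (bedtools slop)
#'
#' @param x interval table.
#' @param flank bp added on each side.
#' @param chrom_sizes named vector of chromosome lengths; intervals are
#'   clipped to `[0, size)`.
#' @return widened interval table (other columns preserved).
#' @export
slop <- function(x, flank, chrom_sizes) {
  validate_intervals(x)
  stopifnot(flank >= 0, !is.null(chrom_sizes))
  unk <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(unk)) stopf("unknown chromosome(s): %s", paste(unk, collapse = ", "))
  x$start <- pmax(0L, as.integer(x$start - flank))
  x$end <- pmin(as.integer(chrom_sizes[x$chrom]), as.integer(x$end + flank))
  x
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals from `a` and `b` overlapping by at least
#' `min_overlap` bp, plus a per-`a` hit indicator.
#'
#' @param a,b interval tables.
#' @param min_overlap minimum overlap in bp (default 1, the bedtools
#'   convention).
#' @return list with `pairs` (data.frame `a_idx`, `b_idx`, `overlap_bp`,
#'   row indices into `a` and `b`) and `a_hit` (logical over rows of `a`).
#' @export
intersect_intervals <- function(a, b, min_overlap = 1L) {
  validate_intervals(a); validate_intervals(b)
  stopifnot(min_overlap >= 1)
  pairs <- data.frame(a_idx = integer(), b_idx = integer(), overlap_bp = integer())
  if (nrow(a) && nrow(b)) {
    bl <- as_iranges_by_chrom(b)
    res <- lapply(split(seq_len(nrow(a)), a$chrom), function(ai) {
      chrom <- a$chrom[ai[1]]
      bb <- bl[[chrom]]
      if (is.null(bb)) return(NULL)
      ira <- IRanges::IRanges(a$start[ai] + 1L, a$end[ai])
      hits <- IRanges::findOverlaps(ira, bb$ir, minoverlap = min_overlap)
      if (!length(hits)) return(NULL)
      qi <- ai[S4Vectors::queryHits(hits)]
      si <- bb$idx[S4Vectors::subjectHits(hits)]
      ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
      data.frame(a_idx = qi, b_idx = si, overlap_bp = as.integer(ov))
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res)) pairs <- do.call(rbind, res)
    pairs <- pairs[order(pairs$a_idx, pairs$b_idx), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  a_hit <- logical(nrow(a))
  a_hit[unique(pairs$a_idx)] <- TRUE
  list(pairs = pairs, a_hit = a_hit)
}

#' Fisher exact test of overlap co-occurrence
#'
#' Tests association between two binary annotations over a shared universe of
#' regions (e.g. cohesin co-binding across peak classes).  The 2x2 table is
#' `(a&b, a&!b, !a&b, !a&!b)`; p is the two-sided exact p obtained by summing
#' hypergeometric probabilities not exceeding that of the observed table.
#'
#' @param a_hits,b_hits logical vectors over the same universe.
#' @return list with `table` (2x2 matrix), `odds_ratio` (conditional MLE;
#'   `NaN` with a warning when a margin is zero) and `p_value`.
#' @export
overlap_fisher <- function(a_hits, b_hits) {
  stopifnot(is.logical(a_hits), is.logical(b_hits),
            length(a_hits) == length(b_hits))
  if (!length(a_hits)) stopf("empty universe: no regions to test")
  tab <- matrix(c(sum(a_hits & b_hits), sum(a_hits & !b_hits),
                  sum(!a_hits & b_hits), sum(!a_hits & !b_hits)),
                nrow = 2, byrow = TRUE,
                dimnames = list(a = c("a", "not_a"), b = c("b", "not_b")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warnf("a margin of the 2x2 table is zero; odds ratio undefined")
    return(list(table = tab, odds_ratio = NaN, p_value = 1))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Read / write BED
#'
#' BED6(+1): `chrom start end name score strand [extra]`.  Coordinates are
#' 0-based half-open, as in the format.
#' @param path file path.
#' @param x interval table with at least `chrom`, `start`, `end`.
#' @return `read_bed`: interval data.frame; `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "extra")
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  names(x) <- cols[seq_len(ncol(x))]
  validate_intervals(x)
  x
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
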