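# Maximal tandem GGAA-run scanner and per-peak repeat profiling.
#
# EWS-FLI1 binds GGAA microsatellites; the number of consecutive GGAA units
# ("n x GGAA") defines the enhancer class used throughout the pipeline.

IUPAC_CHARS <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]

#' Scan a nucleotide sequence for maximal tandem GGAA runs
#'
#' Finds every maximal run of consecutive `GGAA` units on the plus strand
#' and, when `strands = "both"`, every maximal `TTCC` run reported as a
#' minus-strand GGAA block.  A run is maximal when it cannot be extended by
#' one unit on either side; runs on opposite strands may overlap and are
#' reported independently.  Matching is case-insensitive; `N` never matches.
#'
#' @param seq single nucleotide string over the IUPAC alphabet.
#' @param strands `"plus_only"` (default, the published procedure matched the
#'   plus-strand genome string) or `"both"`.
#' @return data.frame of repeat blocks: `start`, `end` (0-based half-open),
#'   `strand`, `unit_count`, sorted by `start`.  `end - start == 4 *
#'   unit_count` always holds.
#' @export
scan_sequence <- function(seq, strands = c("plus_only", "both")) {
  strands <- match.arg(strands)
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), s)
  if (bad > 0) stopf("non-IUPAC character '%s' at position %d",
                     substr(s, bad, bad), bad)
  blocks <- find_unit_runs(s, "GGAA", "+")
  if (strands == "both") {
    blocks <- rbind(blocks, find_unit_runs(s, "TTCC", "-"))
  }
  blocks <- blocks[order(blocks$start, blocks$strand), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

# all maximal tandem runs of a 4-mer unit: locate unit occurrences, then
# chain occurrences spaced exactly one unit apart into runs
find_unit_runs <- function(s, unit, strand_label) {
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), unit_count = integer())
  m <- gregexpr(unit, s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)                      # 1-based
  w <- nchar(unit)
  new_run <- c(TRUE, diff(starts) != w)
  run_id <- cumsum(new_run)
  first <- starts[new_run]
  count <- as.integer(tabulate(run_id))
  data.frame(start = first - 1L,
             end = first - 1L + w * count,
             strand = strand_label,
             unit_count = count)
}

#' Scan a FASTA file for GGAA repeat blocks
#'
#' Records are scanned one at a time so arbitrarily large genomes need not be
#' resident in full.
#'
#' @param path FASTA file.
#' @param strands see [scan_sequence()].
#' @param chrom_subset optional character vector restricting which records
#'   are scanned; a name absent from the file is an error.
#' @return data.frame of blocks with a leading `chrom` column.
#' @export
scan_fasta <- function(path, strands = c("plus_only", "both"),
                       chrom_subset = NULL) {
  strands <- match.arg(strands)
  idx <- Biostrings::fasta.index(path)
  recnames <- sub("\\s.*$", "", idx$desc)
  if (!is.null(chrom_subset)) {
    miss <- setdiff(chrom_subset, recnames)
    if (length(miss)) stopf("chromosome(s) not in FASTA: %s",
                            paste(miss, collapse = ", "))
    idx <- idx[match(chrom_subset, recnames), , drop = FALSE]
    recnames <- chrom_subset
  }
  out <- lapply(seq_len(nrow(idx)), function(i) {
    sq <- as.character(Biostrings::readDNAStringSet(idx[i, , drop = FALSE]))[[1]]
    if (!nchar(sq)) return(NULL)
    bl <- scan_sequence(sq, strands)
    if (!nrow(bl)) return(NULL)
    cbind(chrom = recnames[i], bl)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), unit_count = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize GGAA repeat content of genomic intervals
#'
#' For each interval, counts the repeat blocks whose span intersects the
#' evaluation window (the full interval by default, or a fixed window around
#' the interval midpoint).  A block partially overlapping the window
#' contributes its full unit count: repeat units are treated as atomic.
#' Disconnected blocks are never merged; each maximal run counts separately.
#'
#' @param intervals interval table; a `name` column supplies peak ids
#'   (defaults to `peak_<row>`).
#' @param blocks repeat-block table from [scan_fasta()].
#' @param window_mode `"full_interval"` or `"center_window"`.
#' @param center_halfwidth half-width w (bp) of the `center_window` mode
#'   (window is midpoint +/- w); must be positive in that mode.
#' @param thresholds unit-count thresholds k for the `n_blocks_ge_<k>`
#'   columns (number of disconnected blocks with at least k units).
#' @param bin_edges passed to [classify_repeat_class()].
#' @return data.frame: `peak`, `max_run`, `n_blocks_total`,
#'   `n_blocks_ge_<k>`..., `total_units`, `repeat_class`.
#' @export
profile_intervals <- function(intervals, blocks,
                              window_mode = c("full_interval", "center_window"),
                              center_halfwidth = NULL,
                              thresholds = c(1L, 5L, 10L),
                              bin_edges = c(1L, 5L, 10L)) {
  window_mode <- match.arg(window_mode)
  validate_intervals(intervals)
  ids <- intervals$name %||% sprintf("peak_%04d", seq_len(nrow(intervals)))
  win <- intervals[, c("chrom", "start", "end")]
  if (window_mode == "center_window") {
    if (is.null(center_halfwidth) || center_halfwidth <= 0)
      stopf("center_window mode requires a positive center_halfwidth")
    mid <- floor((win$start + win$end) / 2)
    win$start <- pmax(0, mid - center_halfwidth)
    win$end <- mid + center_halfwidth
  }
  n <- nrow(intervals)
  prof <- data.frame(peak = ids, max_run = 0L, n_blocks_total = 0L)
  for (k in thresholds) prof[[sprintf("n_blocks_ge_%d", k)]] <- 0L
  prof$total_units <- 0L
  if (nrow(blocks) && n) {
    ov <- intersect_intervals(win, blocks[, c("chrom", "start", "end")],
                              min_overlap = 1L)$pairs
    if (nrow(ov)) {
      uc <- blocks$unit_count[ov$b_idx]
      agg <- split(uc, ov$a_idx)
      rows <- as.integer(names(agg))
      prof$max_run[rows] <- vapply(agg, max, integer(1))
      prof$n_blocks_total[rows] <- lengths(agg)
      prof$total_units[rows] <- vapply(agg, function(u) sum(u), integer(1))
      for (k in thresholds) {
        prof[[sprintf("n_blocks_ge_%d", k)]][rows] <-
          vapply(agg, function(u) sum(u >= k), integer(1))
      }
    }
  }
  prof$repeat_class <- classify_repeat_class(prof$max_run, bin_edges)
  prof
}

#' Classify a repeat profile into repeat-number bins
#'
#' Default bins follow the published stratification: `0x` (no repeat),
#' `1-4x`, `5-9x`, `>=10x` on the largest run in the window.  An alternative
#' two-class scheme (`bin_edges = c(1, 2, 10)` with custom labels, or the
#' `paper_extremes` preset) separates the monomeric `1x` and multimeric
#' `10x` site classes.
#'
#' @param max_run integer vector of largest unit counts.
#' @param bin_edges strictly increasing positive integers; bin k spans
#'   `[edge_k, edge_{k+1})`, the final bin is open-ended, and values below
#'   the first edge map to `0x`.
#' @param labels optional labels for the bins above `0x` (auto-generated
#'   otherwise).
#' @return character vector of class labels.
#' @export
classify_repeat_class <- function(max_run, bin_edges = c(1L, 5L, 10L),
                                  labels = NULL) {
  stopifnot(length(bin_edges) >= 1, all(diff(bin_edges) > 0),
            all(bin_edges >= 1))
  if (is.null(labels)) {
    upper <- c(bin_edges[-1] - 1L, NA)
    labels <- ifelse(is.na(upper), sprintf(">=%dx", bin_edges),
                     ifelse(upper == bin_edges, sprintf("%dx", bin_edges),
                            sprintf("%d-%dx", bin_edges, upper)))
  }
  stopifnot(length(labels) == length(bin_edges))
  idx <- findInterval(max_run, bin_edges)
  out <- c("0x", labels)[idx + 1L]
  out
}

#' Default repeat-class bin schemes
#'
#' `"stratified"`: `0x / 1-4x / 5-9x / >=10x` (the histogram bins);
#' `"extremes"`: the monomeric-vs-multimeric site scheme used for signature
#' definition, labelling `max_run == 1` as `1x` and `max_run >= 10` as
#' `10x` (everything else keeps an interior label that signature rules
#' ignore).
#' @param scheme one of `"stratified"`, `"extremes"`.
#' @return list with `bin_edges` and `labels`.
#' @export
repeat_class_scheme <- function(scheme = c("stratified", "extremes")) {
  scheme <- match.arg(scheme)
  if (scheme == "stratified") {
    list(bin_edges = c(1L, 5L, 10L), labels = c("1-4x", "5-9x", ">=10x"))
  } else {
    list(bin_edges = c(1L, 2L, 10L), labels = c("1x", "2-9x", "10x"))
  }
}
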