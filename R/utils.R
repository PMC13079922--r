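# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable digest of an R object
#'
#' MD5 of a version-3 serialization; used to record provenance of derived
#' gene signatures so that re-derivation can be verified.
#' @param x any R object
#' @return character(1) md5 hex digest
#' @keywords internal
digest_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 3, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

read_tsv0 <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#", ...)
}

write_tsv0 <- function(x, path, col.names = TRUE) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = col.names)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic child seeds so that independent generator stages do not share
# random streams; kept well below .Machine$integer.max
child_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k) * 1009L) %% 2147483587L
}
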