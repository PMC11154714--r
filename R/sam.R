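#' Write a toy SAM file of single-end reads
#'
#' Emits a minimal, valid SAM file from a table of read placements, for
#' exercising [count_reads()] on constructed examples.  This is a test
#' utility, not a sequencing simulator: sequences are runs of `A` matching
#' the CIGAR query length and base qualities are omitted.
#'
#' @param reads tibble with columns `chrom`, `pos` (1-based leftmost
#'   mapped position) and optionally `cigar` (default `"50M"`), `mapq`
#'   (default 60), `strand` (`"+"`/`"-"`, default `"+"`), `qname`.
#' @param path output `.sam` path.
#' @param chrom_lengths named integer vector of reference lengths for the
#'   header; defaults to generous bounds inferred from the reads.
#' @return `path`, invisibly.  Convert with [Rsamtools::asBam()] to
#'   obtain a sorted, indexed BAM.
#' @export
write_toy_sam <- function(reads, path, chrom_lengths = NULL) {
  check_columns(reads, c("chrom", "pos"), "`reads`")
  reads <- as_tibble(reads)
  n <- nrow(reads)
  if (!"cigar" %in% names(reads)) reads$cigar <- "50M"
  if (!"mapq" %in% names(reads)) reads$mapq <- 60L
  if (!"strand" %in% names(reads)) reads$strand <- "+"
  if (!"qname" %in% names(reads)) reads$qname <- sprintf("read%04d", seq_len(n))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(reads$pos + 10000L, reads$chrom, max)
  }
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths))
  )
  qlen <- vapply(reads$cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIS=X]", cg)[[1]]
    if (ops[1] == -1) return(1L)
    pieces <- regmatches(cg, gregexpr("[0-9]+[MIS=X]", cg))[[1]]
    sum(as.integer(sub("[MIS=X]$", "", pieces)))
  }, integer(1))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, flag, reads$chrom, as.integer(reads$pos),
                  as.integer(reads$mapq), reads$cigar,
                  strrep("A", qlen))
  writeLines(c(header, body), path)
  invisible(path)
}
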