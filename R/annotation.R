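#' Length of a 1-based inclusive genomic interval
#'
#' All coordinates in irsplit are 1-based and inclusive at both ends (the
#' convention of genome-browser text and PCR product coordinates), so an
#' interval covers `end - start + 1` bases.
#'
#' @param start,end integer vectors of interval bounds (both inclusive).
#' @return integer vector of interval lengths in bp.
#' @export
#' @examples
#' interval_length(201, 300) # 100
interval_length <- function(start, end) {
  if (length(start) != length(end)) {
    abort("`start` and `end` must have the same length.")
  }
  bad <- which(end < start)
  if (length(bad)) {
    abort(sprintf("Invalid interval: end < start at position(s) %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  as.integer(end - start + 1)
}

#' Build per-transcript exonic/intronic/span features from exon records
#'
#' Overlapping or book-ended exon records within one transcript are unioned
#' before introns are derived, so introns are exactly the gaps between the
#' merged exons (`intron start = previous exon end + 1`,
#' `intron end = next exon start - 1`).  A single-exon transcript therefore
#' has zero introns.  Each transcript also receives a `transcript` feature
#' spanning the whole locus, so that per transcript
#' exonic length + intronic length = span length.
#'
#' @param exons data frame of exon records with columns `transcript_id`,
#'   `chrom`, `start`, `end` and optionally `strand`, `gene_id`,
#'   `gene_symbol`.  Coordinates are 1-based inclusive.
#' @param mask_exons if `TRUE`, intronic positions that overlap an exon of
#'   *any* transcript in `exons` are removed (a stricter intron definition
#'   used by some IR tools); the default keeps each transcript's introns as
#'   plain inter-exon gaps.
#' @return a tibble of genomic features, one row per feature, with columns
#'   `transcript_id`, `gene_id`, `gene_symbol`, `chrom`, `strand`,
#'   `feature_class` (`"exonic"`, `"intronic"` or `"transcript"`),
#'   `ordinal` (1-based within transcript and class, in coordinate order),
#'   `start`, `end`, `length` and `feature_id`
#'   (`transcript_id|feature_class|ordinal`).  Rows are ordered by
#'   (chrom, transcript start, transcript_id).
#' @export
transcript_models <- function(exons, mask_exons = FALSE) {
  check_columns(exons, c("transcript_id", "chrom", "start", "end"), "`exons`")
  exons <- as_tibble(exons)
  if (!"strand" %in% names(exons)) exons$strand <- "*"
  if (!"gene_id" %in% names(exons)) exons$gene_id <- exons$transcript_id
  if (!"gene_symbol" %in% names(exons)) exons$gene_symbol <- NA_character_
  exons$strand <- as.character(exons$strand)
  exons$strand[is.na(exons$strand) | !exons$strand %in% c("+", "-")] <- "*"
  if (nrow(exons) == 0L) return(empty_features())
  if (any(exons$end < exons$start)) abort("Exon record with end < start.")

  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand
  )
  by_tx <- GenomicRanges::split(gr, exons$transcript_id)
  merged <- GenomicRanges::reduce(by_tx)           # union per transcript
  spans <- unlist(range(merged), use.names = FALSE)
  names(spans) <- names(merged)
  introns_l <- GenomicRanges::psetdiff(spans, merged)

  flat_introns <- unlist(introns_l, use.names = FALSE)
  intron_tx <- rep(names(introns_l), S4Vectors::elementNROWS(introns_l))
  if (mask_exons && length(flat_introns)) {
    all_exons <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    GenomicRanges::strand(all_exons) <- "*"
    keep_strand <- as.character(GenomicRanges::strand(flat_introns))
    us <- flat_introns
    GenomicRanges::strand(us) <- "*"
    hits <- GenomicRanges::findOverlaps(us, all_exons)
    ex_by_intron <- IRanges::extractList(all_exons,
                                         methods::as(hits, "IntegerList"))
    masked <- GenomicRanges::psetdiff(us, ex_by_intron)
    piece_n <- S4Vectors::elementNROWS(masked)
    new_tx <- rep(intron_tx, piece_n)
    new_strand <- rep(keep_strand, piece_n)
    flat_introns <- unlist(masked, use.names = FALSE)
    GenomicRanges::strand(flat_introns) <- new_strand
    intron_tx <- new_tx
  }

  meta <- exons |>
    distinct(.data$transcript_id, .keep_all = TRUE) |>
    select("transcript_id", "gene_id", "gene_symbol")

  gr_to_tbl <- function(g, tx, class) {
    if (!length(g)) return(NULL)
    tibble(
      transcript_id = tx,
      chrom = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(GenomicRanges::strand(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g),
      feature_class = class
    )
  }
  flat_exons <- unlist(merged, use.names = FALSE)
  exon_tx <- rep(names(merged), S4Vectors::elementNROWS(merged))
  feats <- bind_rows(
    gr_to_tbl(flat_exons, exon_tx, "exonic"),
    gr_to_tbl(flat_introns, intron_tx, "intronic"),
    gr_to_tbl(spans, names(spans), "transcript")
  )

  span_tbl <- feats |>
    filter(.data$feature_class == "transcript") |>
    select("transcript_id", tx_start = "start")
  feats |>
    left_join(meta, by = "transcript_id") |>
    left_join(span_tbl, by = "transcript_id") |>
    arrange(.data$chrom, .data$tx_start, .data$transcript_id,
            .data$feature_class, .data$start) |>
    group_by(.data$transcript_id, .data$feature_class) |>
    mutate(ordinal = row_number()) |>
    ungroup() |>
    mutate(
      length = interval_length(.data$start, .data$end),
      feature_id = paste(.data$transcript_id, .data$feature_class,
                         .data$ordinal, sep = "|")
    ) |>
    select("transcript_id", "gene_id", "gene_symbol", "chrom", "strand",
           "feature_class", "ordinal", "start", "end", "length", "feature_id")
}

empty_features <- function() {
  tibble(
    transcript_id = character(), gene_id = character(),
    gene_symbol = character(), chrom = character(), strand = character(),
    feature_class = character(), ordinal = integer(),
    start = integer(), end = integer(), length = integer(),
    feature_id = character()
  )
}

#' Parse a GTF/GFF transcript annotation into per-transcript features
#'
#' Reads exon records from a GTF2.2 or GFF3 file (format auto-detected from
#' the extension by [rtracklayer::import()]), groups them by transcript, and
#' derives merged exons, introns and the transcript span via
#' [transcript_models()].
#'
#' @param path path to a GTF or GFF3 file.
#' @param mask_exons see [transcript_models()].
#' @return a feature tibble as documented in [transcript_models()].
#' @details Transcript identity is taken from the `transcript_id` attribute
#'   (GTF) or the `Parent` attribute (GFF3).  `transcript`/`mRNA` records
#'   without any exon child are skipped; a warning reports how many.
#' @export
read_transcript_models <- function(path, mask_exons = FALSE) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  types <- tolower(as.character(mc$type %||% rep("exon", length(gr))))
  is_exon <- types == "exon"

  tx_of <- function(idx) {
    if (!is.null(mc$transcript_id)) {
      as.character(mc$transcript_id[idx])
    } else if (!is.null(mc$Parent)) {
      as.character(unlist(mc$Parent[idx]))
    } else {
      abort("Cannot determine transcript ids: no transcript_id or Parent attribute.")
    }
  }

  exon_idx <- which(is_exon)
  tx_ids <- tx_of(exon_idx)
  # transcripts declared but without exon children
  declared <- character()
  if (any(types %in% c("transcript", "mrna"))) {
    didx <- which(types %in% c("transcript", "mrna"))
    declared <- if (!is.null(mc$transcript_id)) {
      as.character(mc$transcript_id[didx])
    } else if (!is.null(mc$ID)) as.character(mc$ID[didx]) else character()
    # GFF3 Parent of exons refers to the transcript ID attribute
  }
  orphans <- setdiff(declared, unique(tx_ids))
  if (length(orphans)) {
    warn(sprintf("Skipped %d transcript record(s) with zero exon records.",
                 length(orphans)))
  }
  if (!length(exon_idx)) {
    warn("No exon records found in annotation.")
    return(empty_features())
  }
  g <- gr[exon_idx]
  gene_id <- if (!is.null(mc$gene_id)) as.character(mc$gene_id[exon_idx]) else tx_ids
  sym <- if (!is.null(mc$gene_name)) {
    as.character(mc$gene_name[exon_idx])
  } else NA_character_
  exons <- tibble(
    transcript_id = tx_ids,
    gene_id = gene_id,
    gene_symbol = sym,
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g)
  )
  transcript_models(exons, mask_exons = mask_exons)
}

#' Drop transcripts without introns
#'
#' Intron-less (single-exon) transcripts carry no information about intron
#' retention and are removed before quantification.
#'
#' @param features feature tibble from [transcript_models()].
#' @return the feature tibble restricted to transcripts with at least one
#'   intron, with attributes `n_removed` and `n_retained`.  Emits a message
#'   with the counts, and a warning if nothing is retained.
#' @export
filter_intronless <- function(features) {
  check_columns(features, c("transcript_id", "feature_class"), "`features`")
  with_intron <- features |>
    filter(.data$feature_class == "intronic") |>
    pull(.data$transcript_id) |>
    unique()
  all_tx <- unique(features$transcript_id)
  out <- features |> filter(.data$transcript_id %in% with_intron)
  n_removed <- length(all_tx) - length(with_intron)
  inform(sprintf("filter_intronless: retained %d transcript(s), removed %d intron-less.",
                 length(with_intron), n_removed))
  if (!length(with_intron)) {
    warn("All transcripts are intron-less; the feature set is empty.")
  }
  attr(out, "n_removed") <- n_removed
  attr(out, "n_retained") <- length(with_intron)
  out
}

#' Export features as BED6
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` is decremented on export.  The BED name field is the
#' `feature_id` (`transcript_id|feature_class|ordinal`), allowing a lossless
#' round trip through [import_regions()].
#'
#' @param features feature tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_regions <- function(features, path) {
  header <- "# BED6: chrom start0 end name(transcript_id|feature_class|ordinal) score strand"
  if (nrow(features) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  strand_out <- ifelse(features$strand %in% c("+", "-"), features$strand, ".")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   features$chrom, features$start - 1L, features$end,
                   features$feature_id, strand_out)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Re-import a BED6 region file written by [export_regions()]
#'
#' @param path BED file path.
#' @return feature tibble (without gene annotations, which BED cannot carry).
#' @export
import_regions <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_features())
  bed <- readr::read_tsv(
    I(lines),
    col_names = c("chrom", "start0", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  tibble(
    transcript_id = map_chr(parts, 1),
    gene_id = map_chr(parts, 1),
    gene_symbol = NA_character_,
    chrom = bed$chrom,
    strand = if_else(bed$strand %in% c("+", "-"), bed$strand, "*"),
    feature_class = map_chr(parts, 2),
    ordinal = as.integer(map_chr(parts, 3)),
    start = as.integer(bed$start0 + 1L),
    end = as.integer(bed$end),
  ) |>
    mutate(
      length = interval_length(.data$start, .data$end),
      feature_id = bed$name
    )
}
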