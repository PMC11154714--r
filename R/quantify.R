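#' Count aligned reads over exonic/intronic/transcript features
#'
#' Overlap counting is union-style: a read increments every feature it
#' overlaps by at least `min_overlap` aligned bases, so a read straddling an
#' exon/intron junction counts toward both features — such junction reads
#' are precisely the signal intron-retention detection relies on.  Reads
#' below the mapping-quality cutoff are skipped (multi-mappers typically
#' carry MAPQ 0).  Counting is deterministic and independent of read order.
#'
#' @param features feature tibble from [transcript_models()] /
#'   [filter_intronless()].
#' @param bam_files character vector of BAM paths; names are used as sample
#'   ids (default: file name without extension).  Whole files are streamed,
#'   so a BAM index is not required.
#' @param min_overlap minimum overlapping bases for a read to count (bp).
#' @param mapq minimum mapping quality; reads with lower MAPQ (or missing
#'   MAPQ) are discarded.  Default 1 drops typical multi-mapped reads.
#' @param fragments if `TRUE`, read pairs are counted once per fragment
#'   (a feature overlapped by either mate is incremented once).
#' @param stranded `"no"` (default), `"fr"` (read strand must match feature
#'   strand) or `"rf"` (opposite).
#' @param chr_normalize reconcile `"chr"` prefixes between BAM and
#'   annotation automatically.
#' @return a long counts tibble: `feature_id`, `transcript_id`,
#'   `feature_class`, `length`, `sample`, `count` — one row per feature per
#'   sample, suitable for [compute_tpm()].
#' @export
count_reads <- function(features, bam_files, min_overlap = 1, mapq = 1,
                        fragments = FALSE,
                        stranded = c("no", "fr", "rf"),
                        chr_normalize = TRUE) {
  stranded <- match.arg(stranded)
  if (nrow(features) == 0L) abort("Empty feature set; nothing to count.")
  if (is.null(names(bam_files)) || any(!nzchar(names(bam_files)))) {
    names(bam_files) <- sub("\\.bam$", "", basename(bam_files))
  }
  feat_gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
  names(feat_gr) <- features$feature_id

  count_one <- function(path) {
    if (!file.exists(path)) abort(sprintf("BAM file not found: %s", path))
    param <- Rsamtools::ScanBamParam(
      mapqFilter = if (mapq > 0) as.integer(mapq) else NA_integer_
    )
    reads <- if (fragments) {
      GenomicAlignments::grglist(
        GenomicAlignments::readGAlignmentPairs(path, param = param)
      )
    } else {
      GenomicAlignments::grglist(
        GenomicAlignments::readGAlignments(path, param = param)
      )
    }
    if (!length(reads)) {
      warn(sprintf("No reads passed filters in %s; counts are all zero.",
                   basename(path)))
      return(setNames(integer(nrow(features)), features$feature_id))
    }
    if (chr_normalize) {
      feat_chr <- unique(features$chrom)
      read_chr <- GenomeInfoDb::seqlevels(reads)
      if (!any(read_chr %in% feat_chr)) {
        if (all(startsWith(feat_chr, "chr"))) {
          GenomeInfoDb::seqlevels(reads) <- paste0("chr", read_chr)
        } else {
          GenomeInfoDb::seqlevels(reads) <- sub("^chr", "", read_chr)
        }
      }
    }
    if (stranded == "rf") {
      reads <- GenomicRanges::invertStrand(reads)
    }
    GenomicRanges::countOverlaps(
      feat_gr, reads,
      minoverlap = min_overlap,
      ignore.strand = (stranded == "no")
    )
  }

  counts <- map(bam_files, count_one)
  base <- features |>
    select("feature_id", "transcript_id", "feature_class", "length")
  imap(counts, function(cnt, sample_id) {
    base |> mutate(sample = sample_id, count = as.integer(cnt[base$feature_id]))
  }) |>
    list_rbind()
}

#' Convert counts to TPM
#'
#' TPM for feature f in a sample is the length-normalised read rate scaled
#' to sum to one million over the normalisation universe:
#' \deqn{TPM_f = 10^6 \, (r_f/L_f) \Big/ \sum_g (r_g/L_g)}
#' with \eqn{r_f} the read count and \eqn{L_f} the feature length in bp.
#' By default each feature class (exonic / intronic / transcript) is
#' normalised over its own universe, so exonic TPMs sum to 1e6 over exonic
#' features, and likewise for the other classes; `universe = "shared"`
#' normalises over all features in the table instead (a sensitivity-analysis
#' variant).
#'
#' @param counts long counts tibble (`feature_id`, `feature_class`,
#'   `length`, `sample`, `count`), as from [count_reads()] or
#'   [ingest_matrix()].
#' @param universe `"class"` (default) or `"shared"`.
#' @return the tibble with `count` replaced by `tpm`.  Samples with an
#'   all-zero universe keep TPM 0 throughout (no division by zero).
#' @export
compute_tpm <- function(counts, universe = c("class", "shared")) {
  universe <- match.arg(universe)
  check_columns(counts, c("feature_id", "feature_class", "length", "sample",
                          "count"), "`counts`")
  if (any(counts$count < 0)) abort("Negative counts are not allowed.")
  if (any(counts$length < 1)) abort("Feature lengths must be >= 1 bp.")
  grouping <- if (universe == "class") c("sample", "feature_class") else "sample"
  out <- counts |>
    mutate(.rate = .data$count / .data$length) |>
    group_by(across(dplyr::all_of(grouping))) |>
    mutate(
      .tot = sum(.data$.rate),
      tpm = if_else(.data$.tot > 0, .data$.rate / .data$.tot * 1e6, 0)
    ) |>
    ungroup() |>
    select(-".rate", -".tot", -"count")
  attr(out, "normalization_universe") <- universe
  out
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expected layout: a `feature_id` column, a `length` column (bp; required
#' for counts, optional for TPM), and one numeric column per sample.
#' Feature ids of the form `transcript_id|feature_class|ordinal` (as written
#' by [write_matrix()] and [export_regions()]) are decomposed; otherwise the
#' id is taken as the transcript id with the class given by `feature_class`.
#'
#' @param path TSV path.
#' @param type `"counts"` or `"tpm"` — what the numeric cells are.
#' @param feature_class class label used when ids carry none.
#' @return long tibble with columns `feature_id`, `transcript_id`,
#'   `feature_class`, (`length`,) `sample` and `count` or `tpm`.
#' @export
ingest_matrix <- function(path, type = c("counts", "tpm"),
                          feature_class = "transcript") {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("Matrix file not found: %s", path))
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(wide, "feature_id", sprintf("matrix '%s'", path))
  if (anyDuplicated(wide$feature_id)) {
    dup <- wide$feature_id[duplicated(wide$feature_id)][1]
    abort(sprintf("Duplicate feature key '%s' in %s.", dup, path))
  }
  has_len <- "length" %in% names(wide)
  if (type == "counts" && !has_len) {
    abort("Counts matrix must carry a `length` column (bp).")
  }
  sample_cols <- setdiff(names(wide), c("feature_id", "length"))
  if (!length(sample_cols)) {
    if (nrow(wide) == 0L) { # legitimately empty matrix
      out <- tibble(feature_id = character(), transcript_id = character(),
                    feature_class = character(), sample = character())
      if (has_len) out$length <- integer()
      out[[if (type == "counts") "count" else "tpm"]] <- numeric()
      return(out)
    }
    abort("No sample columns found.")
  }
  for (cc in sample_cols) {
    v <- wide[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("Non-numeric cell in column '%s', row %d of %s.",
                    cc, bad %||% 1L, path))
    }
    if (anyNA(v)) {
      abort(sprintf("Missing value in column '%s', row %d of %s.",
                    cc, which(is.na(v))[1], path))
    }
    if (any(v < 0)) {
      abort(sprintf("Negative value in column '%s', row %d of %s.",
                    cc, which(v < 0)[1], path))
    }
  }
  long <- wide |>
    pivot_longer(dplyr::all_of(sample_cols), names_to = "sample",
                 values_to = if (type == "counts") "count" else "tpm")
  split_ok <- grepl("^[^|]+\\|[^|]+\\|[0-9]+$", long$feature_id)
  if (all(split_ok)) {
    parts <- strsplit(long$feature_id, "|", fixed = TRUE)
    long$transcript_id <- map_chr(parts, 1)
    long$feature_class <- map_chr(parts, 2)
  } else {
    long$transcript_id <- long$feature_id
    long$feature_class <- feature_class
  }
  if (type == "counts") long$count <- as.integer(round(long$count))
  long |>
    relocate("feature_id", "transcript_id", "feature_class")
}

#' Write a long counts/TPM tibble as a wide TSV matrix
#'
#' @param x long tibble with `feature_id`, `sample` and a `count` or `tpm`
#'   value column (plus `length` for counts, carried through).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  value_col <- intersect(c("count", "tpm"), names(x))[1]
  if (is.na(value_col)) abort("`x` must have a `count` or `tpm` column.")
  id_cols <- intersect(c("feature_id", "length"), names(x))
  wide <- x |>
    select(dplyr::all_of(c(id_cols, "sample", value_col))) |>
    pivot_wider(names_from = "sample", values_from = dplyr::all_of(value_col))
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
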