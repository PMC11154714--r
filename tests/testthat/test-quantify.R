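make_counts <- function(counts, lengths, samples = "s1",
                        feature_class = "transcript") {
  tibble::tibble(
    feature_id = rep(sprintf("f%d", seq_along(lengths)), length(samples)),
    transcript_id = rep(sprintf("f%d", seq_along(lengths)), length(samples)),
    feature_class = feature_class,
    length = rep(lengths, length(samples)),
    sample = rep(samples, each = length(lengths)),
    count = as.vector(counts)
  )
}

test_that("TPM normalisation follows the rate formula", {
  # a single feature takes the whole million regardless of count/length
  one <- compute_tpm(make_counts(7L, 500L))
  expect_equal(one$tpm, 1e6)
  # equal rates split the million equally
  eq <- compute_tpm(make_counts(c(10L, 20L, 30L), c(1000L, 2000L, 3000L)))
  expect_equal(eq$tpm, rep(1e6 / 3, 3))
  # all-zero sample stays zero
  z <- compute_tpm(make_counts(c(0L, 0L), c(100L, 200L)))
  expect_equal(z$tpm, c(0, 0))
})

test_that("TPM columns sum to 1e6 per feature class and are scale-invariant", {
  set.seed(11)
  for (i in 1:10) {
    nf <- sample(3:20, 1)
    counts <- dplyr::bind_rows(
      make_counts(matrix(rpois(nf * 3, 50), nf), sample(100:5000, nf),
                  samples = c("s1", "s2", "s3"), feature_class = "exonic"),
      make_counts(matrix(rpois(nf * 3, 10), nf), sample(100:5000, nf),
                  samples = c("s1", "s2", "s3"), feature_class = "intronic") |>
        dplyr::mutate(feature_id = paste0("i_", feature_id))
    )
    tpm <- compute_tpm(counts)
    sums <- tpm |>
      dplyr::group_by(sample, feature_class) |>
      dplyr::summarise(s = sum(tpm), .groups = "drop")
    nonzero <- sums$s[sums$s > 0]
    expect_equal(nonzero, rep(1e6, length(nonzero)), tolerance = 1e-9)
    # scaling one sample's counts leaves its TPM unchanged
    scaled <- counts |>
      dplyr::mutate(count = ifelse(sample == "s2", count * 7L, count))
    expect_equal(compute_tpm(scaled)$tpm, tpm$tpm, tolerance = 1e-12)
  }
})

test_that("shared-universe normalisation sums to 1e6 over all features", {
  counts <- dplyr::bind_rows(
    make_counts(c(5L, 5L), c(100L, 100L), feature_class = "exonic"),
    make_counts(c(3L, 2L), c(100L, 100L), feature_class = "intronic") |>
      dplyr::mutate(feature_id = paste0("i_", feature_id))
  )
  tpm <- compute_tpm(counts, universe = "shared")
  expect_equal(sum(tpm$tpm), 1e6)
})

test_that("matrix TSV round trip preserves values and schema errors are caught", {
  set.seed(5)
  counts <- make_counts(matrix(rpois(8, 30), 4), c(150L, 700L, 90L, 1200L),
                        samples = c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(counts, path)
  back <- ingest_matrix(path, type = "counts")
  expect_equal(
    dplyr::arrange(back, feature_id, sample)$count,
    dplyr::arrange(counts, feature_id, sample)$count)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlength\ts1", "f1\t100\t-3"), bad)
  expect_error(ingest_matrix(bad, type = "counts"), "Negative")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlength\ts1", "f1\t100\t3", "f1\t100\t4"), dup)
  expect_error(ingest_matrix(dup, type = "counts"), "Duplicate")
  chr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlength\ts1", "f1\t100\tx"), chr)
  expect_error(ingest_matrix(chr, type = "counts"), "Non-numeric|Missing")
})

test_that("read counting matches manual overlap enumeration", {
  skip_if_not_installed("Rsamtools")
  f <- suppressMessages(filter_intronless(transcript_models(tiny_exons())))
  sam <- withr::local_tempfile(fileext = ".sam")
  # 3 reads fully inside t1 exon1 (100-200), 1 read straddling the
  # exon/intron boundary at 200|201, 1 low-MAPQ read inside the intron
  reads <- tibble::tibble(
    chrom = "chr1",
    pos = c(120L, 130L, 140L, 180L, 250L),
    cigar = c("30M", "30M", "30M", "50M", "20M"),
    mapq = c(60L, 60L, 60L, 60L, 0L)
  )
  write_toy_sam(reads, sam, chrom_lengths = c(chr1 = 10000L, chr2 = 1000L))
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  cm <- count_reads(f, c(samp1 = bam))
  get <- function(id) cm$count[cm$feature_id == id & cm$sample == "samp1"]
  expect_equal(get("t1|exonic|1"), 4L)    # 3 inside + 1 straddling
  expect_equal(get("t1|intronic|1"), 1L)  # straddler only; MAPQ-0 skipped
  expect_equal(get("t1|exonic|2"), 0L)
  expect_equal(get("t2|exonic|1"), 0L)

  # permutation invariance: shuffled read order gives identical counts
  sam2 <- withr::local_tempfile(fileext = ".sam")
  write_toy_sam(reads[c(4, 1, 5, 3, 2), ], sam2,
                chrom_lengths = c(chr1 = 10000L, chr2 = 1000L))
  bam2 <- Rsamtools::asBam(sam2, withr::local_tempfile(), overwrite = TRUE)
  cm2 <- count_reads(f, c(samp1 = bam2))
  expect_equal(cm2$count, cm$count)

  # empty BAM: all-zero matrix with a warning
  sam0 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:10000",
               "@SQ\tSN:chr2\tLN:1000"), sam0)
  bam0 <- Rsamtools::asBam(sam0, withr::local_tempfile(), overwrite = TRUE)
  expect_warning(cm0 <- count_reads(f, c(s0 = bam0)), "No reads")
  expect_true(all(cm0$count == 0L))
})

test_that("min_overlap controls boundary-read counting", {
  f <- suppressMessages(filter_intronless(transcript_models(tiny_exons())))
  sam <- withr::local_tempfile(fileext = ".sam")
  # read 196-215: 5 bases on the exon, 15 on the intron
  write_toy_sam(tibble::tibble(chrom = "chr1", pos = 196L, cigar = "20M"),
                sam, chrom_lengths = c(chr1 = 10000L, chr2 = 1000L))
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE)
  cm1 <- count_reads(f, c(s = bam), min_overlap = 1)
  cm10 <- count_reads(f, c(s = bam), min_overlap = 10)
  g <- function(cm, id) cm$count[cm$feature_id == id]
  expect_equal(g(cm1, "t1|exonic|1"), 1L)
  expect_equal(g(cm1, "t1|intronic|1"), 1L)
  expect_equal(g(cm10, "t1|exonic|1"), 0L)   # only 5 bases overlap
  expect_equal(g(cm10, "t1|intronic|1"), 1L)
})
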