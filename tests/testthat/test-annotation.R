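test_that("introns are the gaps between merged exons", {
  f <- transcript_models(tiny_exons())
  t1_introns <- f[f$transcript_id == "t1" & f$feature_class == "intronic", ]
  expect_equal(t1_introns$start, 201L)
  expect_equal(t1_introns$end, 300L)
  t2_introns <- f[f$transcript_id == "t2" & f$feature_class == "intronic", ]
  expect_equal(t2_introns$start, c(1101L, 1301L))
  expect_equal(t2_introns$end, c(1200L, 1400L))
  # single-exon transcript has zero introns
  expect_equal(sum(f$transcript_id == "t3" & f$feature_class == "intronic"), 0L)
})

test_that("overlapping exon records are unioned before intron derivation", {
  # oracle: union of covered integer positions
  ex <- tibble::tibble(transcript_id = "tA", chrom = "chr1",
                       start = c(100L, 150L), end = c(200L, 250L))
  covered <- sort(unique(c(100:200, 150:250)))
  f <- transcript_models(ex)
  exonic <- f[f$feature_class == "exonic", ]
  expect_equal(exonic$start, min(covered))
  expect_equal(exonic$end, max(covered))
  expect_equal(sum(f$feature_class == "intronic"), 0L)

  # random fixtures: merged exons reproduce the position-set union and
  # exon + intron lengths always tile the span
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    starts <- sort(sample(1:500, n))
    ends <- starts + sample(10:80, n, replace = TRUE)
    fx <- transcript_models(tibble::tibble(
      transcript_id = "tx", chrom = "c", start = starts, end = ends))
    pos_union <- sort(unique(unlist(Map(seq, starts, ends))))
    exonic <- fx[fx$feature_class == "exonic", ]
    expect_equal(
      sort(unlist(Map(seq, exonic$start, exonic$end))), pos_union)
    span <- fx[fx$feature_class == "transcript", ]
    expect_equal(sum(exonic$length) +
                   sum(fx$length[fx$feature_class == "intronic"]),
                 span$length)
    # no overlapping exons, no intron shorter than 1 bp
    if (nrow(exonic) > 1) {
      expect_true(all(exonic$start[-1] > exonic$end[-nrow(exonic)] + 1))
    }
    expect_true(all(fx$length >= 1))
  }
})

test_that("interval lengths follow the 1-based inclusive convention", {
  expect_equal(interval_length(201, 300), 100L)
  expect_equal(interval_length(5, 5), 1L)       # single base
  expect_error(interval_length(10, 9), "end < start")
})

test_that("intron-less transcripts are removed with counts reported", {
  f <- transcript_models(tiny_exons())
  expect_message(ff <- filter_intronless(f), "retained 2.*removed 1")
  expect_setequal(unique(ff$transcript_id), c("t1", "t2"))
  expect_equal(attr(ff, "n_removed"), 1L)
  expect_equal(attr(ff, "n_retained"), 2L)
  # all single-exon: empty result plus warning
  single <- tibble::tibble(transcript_id = "s1", chrom = "c",
                           start = 1L, end = 10L)
  expect_warning(
    expect_message(empty <- filter_intronless(transcript_models(single))),
    "intron-less")
  expect_equal(nrow(empty), 0L)
})

test_that("feature index covers all three classes after filtering", {
  ff <- suppressMessages(filter_intronless(transcript_models(tiny_exons())))
  cls <- table(ff$feature_class)
  expect_equal(unname(cls["transcript"]), 2L)
  expect_gte(unname(cls["exonic"]), 2L)
  expect_gte(unname(cls["intronic"]), 2L)
})

test_that("BED export round-trips losslessly and converts coordinates", {
  f <- transcript_models(tiny_exons())
  bed <- withr::local_tempfile(fileext = ".bed")
  export_regions(f, bed)
  lines <- readLines(bed)
  expect_true(startsWith(lines[1], "#"))
  # 1-based inclusive 201-300 becomes BED 200,300
  intron_line <- grep("t1\\|intronic\\|1", lines, value = TRUE)
  expect_equal(strsplit(intron_line, "\t")[[1]][2:3], c("200", "300"))
  back <- import_regions(bed)
  cols <- c("transcript_id", "chrom", "strand", "feature_class", "ordinal",
            "start", "end", "length", "feature_id")
  expect_equal(as.data.frame(back[, cols]), as.data.frame(f[, cols]))
  # empty set gives a header-only file
  empty_bed <- withr::local_tempfile(fileext = ".bed")
  export_regions(transcript_models(tiny_exons()[0, ]), empty_bed)
  expect_true(startsWith(readLines(empty_bed), "#"))
  expect_equal(nrow(import_regions(empty_bed)), 0L)
})

test_that("re-parsing exported exons reconstructs the same introns", {
  f <- transcript_models(tiny_exons())
  bed <- withr::local_tempfile(fileext = ".bed")
  export_regions(f[f$feature_class == "exonic", ], bed)
  rebuilt <- transcript_models(import_regions(bed))
  expect_equal(
    as.data.frame(rebuilt[rebuilt$feature_class == "intronic",
                          c("transcript_id", "start", "end")]),
    as.data.frame(f[f$feature_class == "intronic",
                    c("transcript_id", "start", "end")]))
})

test_that("GTF parsing extracts exons and derives introns", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ttest\ttranscript\t100\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\ttest\ttranscript\t500\t600\t.\t+\t.\tgene_id "g2"; transcript_id "t_orphan";'
  ), gtf)
  expect_warning(f <- read_transcript_models(gtf), "zero exon")
  expect_equal(f$start[f$feature_class == "intronic"], 201L)
  expect_equal(f$end[f$feature_class == "intronic"], 300L)
  expect_false("t_orphan" %in% f$transcript_id)
})

test_that("exon masking removes intronic positions covered by other transcripts", {
  ex <- tibble::tibble(
    transcript_id = c("tB", "tB", "tC"), chrom = "chr1",
    start = c(100L, 400L, 180L), end = c(150L, 450L, 250L))
  unmasked <- transcript_models(ex)
  masked <- transcript_models(ex, mask_exons = TRUE)
  iu <- unmasked[unmasked$transcript_id == "tB" &
                   unmasked$feature_class == "intronic", ]
  im <- masked[masked$transcript_id == "tB" &
                 masked$feature_class == "intronic", ]
  expect_equal(iu$start, 151L); expect_equal(iu$end, 399L)
  expect_equal(im$start, c(151L, 251L))
  expect_equal(im$end, c(179L, 399L))
})
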