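#' Run the full exon-intron split IR analysis
#'
#' Orchestrates the pipeline stages on abundance matrices: quantify
#' (counts are TPM-normalised if needed) -> expression filter -> IR ratio
#' -> directional screens -> six-set classification -> contingency ->
#' association tables (top-N ranking, Z-score heatmap matrices, volcano,
#' quadrant counts) -> optional over-representation analysis.  Any stage
#' failure is re-raised with the stage name prefixed.  All stages are
#' deterministic, so identical inputs and parameters reproduce identical
#' outputs.
#'
#' @param exonic,intronic,transcript long abundance tibbles (with `tpm`,
#'   or `count` + `length` columns), e.g. from [generate_cohort()],
#'   [count_reads()] or [ingest_matrix()].
#' @param metadata tibble with `sample`, `group` and optionally
#'   `subgroup`.
#' @param group1 label of the disease-like group (numerator of ratios);
#'   default: the larger group.
#' @param params list overriding the default thresholds:
#'   `detection_threshold` (0.60), `alpha` (0.05), `fdr_level` (0.05),
#'   `epsilon` (0.01), `top_n` (200), `top_fraction` (0.25),
#'   `top_source` ("set-I"), `expr_adjust` ("fdr"),
#'   `summary_fun` ("median").
#' @param gene_sets optional named list of gene sets (see
#'   [read_gene_sets()]) to run [ora_test()] on the top IR fraction.
#' @param tx2gene optional `transcript_id` -> `gene_symbol` mapping
#'   (required for enrichment).
#' @param out_dir optional directory; when given, stage outputs are
#'   written as TSV/JSON and listed in the manifest.
#' @return an `ir_run` list: `filter`, `ir`, `screen`, `sets`,
#'   `contingency` (NULL when a set is empty), `top`, `heatmap_intron`,
#'   `heatmap_transcript`, `volcano`, `quadrants`, `enrichment` (NULL
#'   unless requested), `params` and `manifest` (tool version, parameters,
#'   stage timings, output files with md5 digests).
#' @export
run_ir_pipeline <- function(exonic, intronic, transcript, metadata,
                            group1 = NULL, params = list(),
                            gene_sets = NULL, tx2gene = NULL,
                            out_dir = NULL) {
  defaults <- list(
    detection_threshold = 0.60, alpha = 0.05, fdr_level = 0.05,
    epsilon = 0.01, top_n = 200, top_fraction = 0.25,
    top_source = "set-I", expr_adjust = "fdr", summary_fun = "median"
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  p <- modifyList(defaults, params)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  if (is.null(group1)) {
    sizes <- table(metadata$group)
    group1 <- names(sizes)[which.max(sizes)]
  }
  gt <- as_group_tbl(metadata[, intersect(c("sample", "group"),
                                          names(metadata))], group1 = group1)

  as_tpm <- function(x, what) {
    if ("tpm" %in% names(x)) return(x)
    if (!"count" %in% names(x)) {
      abort(sprintf("`%s` must carry a `tpm` or `count` column.", what))
    }
    compute_tpm(x)
  }
  tpms <- stage("quantify", list(
    exonic = as_tpm(exonic, "exonic"),
    intronic = as_tpm(intronic, "intronic"),
    transcript = as_tpm(transcript, "transcript")
  ))

  filt <- stage("filter", filter_expressed(
    tpms$transcript, gt, threshold = p$detection_threshold))
  kept <- filt$transcript_id[filt$retained]
  if (!length(kept)) abort("[stage filter] No transcript passed the detection filter.")

  ir <- stage("ir", compute_ir(
    tpms$exonic |> filter(.data$transcript_id %in% kept),
    tpms$intronic |> filter(.data$transcript_id %in% kept),
    gt, epsilon = p$epsilon, summary_fun = p$summary_fun))

  screen <- stage("screen", ir_screen(
    tpms$intronic, tpms$transcript, gt, transcripts = kept,
    fdr_level = p$fdr_level))

  sets <- stage("classify", classify_sets(
    screen, alpha = p$alpha, fdr_level = p$fdr_level,
    expr_adjust = p$expr_adjust))

  cont <- NULL
  if (all(c("set-I", "set-II") %in% sets$ir_set) &&
      nrow(dplyr::filter(sets, .data$ir_set != "none",
                         .data$expr_subset %in% c("A", "B", "C"))) > 0) {
    cont <- stage("contingency", tryCatch(contingency(sets),
                                          error = function(e) NULL))
  }

  assoc <- stage("association", {
    top <- select_top_n(screen, sets, ir, source_set = p$top_source,
                        n = p$top_n)
    ord <- sample_block_order(metadata, control = setdiff(group_levels(gt),
                                                          group1))
    hm_i <- hm_t <- NULL
    if (nrow(top) > 0) {
      hm_i <- zscore_rows(tpms$intronic, top$transcript_id, ord)
      hm_t <- zscore_rows(tpms$transcript, top$transcript_id, ord)
    }
    list(top = top, heatmap_intron = hm_i, heatmap_transcript = hm_t,
         volcano = volcano_table(ir, screen, tpms$transcript),
         quadrants = quadrant_counts(ir))
  })

  enr <- NULL
  if (!is.null(gene_sets)) {
    enr <- stage("enrichment", {
      if (is.null(tx2gene)) abort("Enrichment requires `tx2gene`.")
      ranked <- select_top_n(screen, sets, ir, source_set = p$top_source,
                             n = Inf)
      query <- select_top_fraction(ranked, tx2gene,
                                   fraction = p$top_fraction)
      universe <- unique(tx2gene$gene_symbol[
        match(kept, tx2gene$transcript_id)])
      universe <- universe[!is.na(universe)]
      ora_test(query, gene_sets, universe)
    })
  }

  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      if (is.null(x)) return()
      path <- file.path(out_dir, name)
      readr::write_tsv(x, path, progress = FALSE)
      outputs <<- c(outputs, path)
    }
    wr(screen, "screen.tsv")
    wr(sets, "sets.tsv")
    wr(ir$summary, "ir_summary.tsv")
    wr(assoc$volcano, "volcano.tsv")
    wr(assoc$top, "top_transcripts.tsv")
    wr(assoc$heatmap_intron, "heatmap_intron_z.tsv")
    wr(assoc$heatmap_transcript, "heatmap_transcript_z.tsv")
    if (!is.null(enr)) wr(enr, "enrichment.tsv")
    summary_json <- list(
      n_filtered = length(kept),
      set_sizes = as.list(table(sets$ir_set)),
      quadrants = as.list(assoc$quadrants)
    )
    if (!is.null(cont)) {
      summary_json <- c(summary_json, list(
        chi2_stat = cont$chi2_stat, chi2_p = cont$chi2_p,
        odds_ratio = cont$odds_ratio, fisher_p = cont$fisher_p,
        percentages = cont$percentages
      ))
    }
    spath <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary_json, spath, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, spath)
  }

  manifest <- list(
    tool = "irsplit",
    version = as.character(packageVersion("irsplit")),
    group1 = group1,
    params = p,
    n_samples = nrow(metadata),
    n_transcripts_in = dplyr::n_distinct(transcript$transcript_id),
    n_transcripts_filtered = length(kept),
    stage_seconds = as.list(timings),
    outputs = if (length(outputs)) {
      lapply(outputs, function(f) list(path = f,
                                       md5 = unname(tools::md5sum(f))))
    } else list()
  )
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(filter = filt, ir = ir, screen = screen, sets = sets,
         contingency = cont, top = assoc$top,
         heatmap_intron = assoc$heatmap_intron,
         heatmap_transcript = assoc$heatmap_transcript,
         volcano = assoc$volcano, quadrants = assoc$quadrants,
         enrichment = enr, params = p, manifest = manifest),
    class = "ir_run"
  )
}

#' @export
print.ir_run <- function(x, ...) {
  cat(sprintf("<ir_run> %d transcripts screened; sets: %s\n",
              nrow(x$screen),
              paste(names(table(x$sets$ir_set)), table(x$sets$ir_set),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @rdname run_ir_pipeline
#' @param x an `ir_run`.
#' @param ... unused.
#' @export
glance.ir_run <- function(x, ...) {
  tibble(
    n_screened = nrow(x$screen),
    n_set1 = sum(x$sets$ir_set == "set-I"),
    n_set2 = sum(x$sets$ir_set == "set-II"),
    odds_ratio = if (!is.null(x$contingency)) x$contingency$odds_ratio else NA_real_,
    chi2_p = if (!is.null(x$contingency)) x$contingency$chi2_p else NA_real_
  )
}
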