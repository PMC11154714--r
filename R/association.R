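#' Select the top-ranked transcripts of an IR set
#'
#' Members of `source_set` are ranked by the ascending p-value of that
#' set's own directional intronic screen (set-I uses the group1 > group2
#' p, set-II the reverse).  Ties are broken by larger absolute
#' `log2_ratio`, then lexicographic transcript id, so the ranking is fully
#' deterministic.
#'
#' @param screen `screen_result` tibble from [ir_screen()].
#' @param sets classification tibble from [classify_sets()].
#' @param ir an `ir_table` from [compute_ir()] (supplies `log2_ratio` for
#'   tie-breaking), or its `summary` tibble.
#' @param source_set `"set-I"` (default), `"set-II"`, or a subset label
#'   such as `"set-IA"`.
#' @param n number of transcripts to return; if fewer are available, all
#'   are returned.
#' @return ranked tibble: `transcript_id`, `p`, `log2_ratio`, `rank`.
#' @export
select_top_n <- function(screen, sets, ir, source_set = "set-I", n = 200) {
  summary <- if (inherits(ir, "ir_table")) ir$summary else ir
  check_columns(summary, c("transcript_id", "log2_ratio"), "`ir` summary")
  base_set <- if (startsWith(source_set, "set-II")) "set-II" else "set-I"
  subset <- sub("^set-I{1,2}", "", source_set)
  members <- sets |> filter(.data$ir_set == base_set)
  if (nzchar(subset)) members <- members |> filter(.data$expr_subset == subset)
  if (nrow(members) == 0L) {
    warn(sprintf("Source set '%s' is empty.", source_set))
    return(tibble(transcript_id = character(), p = numeric(),
                  log2_ratio = numeric(), rank = integer()))
  }
  p_col <- if (base_set == "set-I") "p_ir_g1_gt_g2" else "p_ir_g2_gt_g1"
  members |>
    inner_join(screen[, c("transcript_id", p_col)], by = "transcript_id") |>
    inner_join(summary[, c("transcript_id", "log2_ratio")],
               by = "transcript_id") |>
    rename(p = dplyr::all_of(p_col)) |>
    arrange(.data$p, desc(abs(.data$log2_ratio)), .data$transcript_id) |>
    mutate(rank = row_number()) |>
    slice_head(n = n) |>
    select("transcript_id", "p", "log2_ratio", "rank")
}

#' Sample ordering in control / low-risk / high-risk blocks
#'
#' Returns sample ids ordered for heatmap display: the control group first,
#' then group-1 samples of the low-risk subgroup, then the high-risk
#' subgroup; original order is kept within blocks.
#'
#' @param metadata tibble with columns `sample`, `group` and optionally
#'   `subgroup`; `control` names the control group level (default: the
#'   smaller group), `subgroup_order` the within-group1 block order.
#' @param control control group label.
#' @param subgroup_order character vector giving the block order of
#'   subgroup levels.
#' @return character vector of sample ids.
#' @export
sample_block_order <- function(metadata, control = NULL,
                               subgroup_order = NULL) {
  check_columns(metadata, c("sample", "group"), "`metadata`")
  groups <- unique(as.character(metadata$group))
  if (is.null(control)) {
    sizes <- table(metadata$group)
    control <- names(sizes)[which.min(sizes)]
  }
  ctrl <- metadata$sample[metadata$group == control]
  rest <- metadata[metadata$group != control, ]
  if ("subgroup" %in% names(metadata) && !all(is.na(rest$subgroup))) {
    if (is.null(subgroup_order)) subgroup_order <- sort(unique(rest$subgroup))
    rest <- rest[order(match(rest$subgroup, subgroup_order)), ]
  }
  c(ctrl, rest$sample)
}

#' Row-wise Z scores for heatmap display
#'
#' Standardises each transcript's TPM row to mean 0 and sample (n-1)
#' standard deviation 1 across the given samples; constant rows become
#' all-zero.  Columns follow `sample_order` exactly, regardless of input
#' order.
#'
#' @param tpm long TPM tibble (`transcript_id`, `sample`, `tpm`; summed
#'   per transcript if several features).
#' @param transcripts character vector of row ids, in display (rank) order.
#' @param sample_order character vector of column ids, in display order
#'   (see [sample_block_order()]).
#' @return wide tibble: `transcript_id` then one column per sample, rows
#'   and columns in the requested order.
#' @export
zscore_rows <- function(tpm, transcripts, sample_order) {
  check_columns(tpm, c("transcript_id", "sample", "tpm"), "`tpm`")
  missing_s <- setdiff(sample_order, unique(tpm$sample))
  if (length(missing_s)) {
    abort(sprintf("Unknown sample(s) in `sample_order`: %s",
                  paste(head(missing_s, 5), collapse = ", ")))
  }
  missing_t <- setdiff(transcripts, unique(tpm$transcript_id))
  if (length(missing_t)) {
    abort(sprintf("Unknown transcript(s): %s",
                  paste(head(missing_t, 5), collapse = ", ")))
  }
  long <- tpm |>
    filter(.data$transcript_id %in% transcripts,
           .data$sample %in% sample_order) |>
    group_by(.data$transcript_id, .data$sample) |>
    summarise(tpm = sum(.data$tpm), .groups = "drop") |>
    group_by(.data$transcript_id) |>
    mutate(z = {
      s <- sd(.data$tpm)
      if (is.na(s) || s == 0) rep(0, length(.data$tpm))
      else (.data$tpm - mean(.data$tpm)) / s
    }) |>
    ungroup()
  wide <- long |>
    select("transcript_id", "sample", "z") |>
    pivot_wider(names_from = "sample", values_from = "z")
  wide <- wide[match(transcripts, wide$transcript_id),
               c("transcript_id", sample_order)]
  wide
}

#' Volcano-plot data table
#'
#' Per transcript: `x` is the between-group log2 fold change of the
#' intron/exon TPM ratio (from [compute_ir()]); `y_p` is `-log10` of the
#' two-sided intronic-screen p-value; `y_expr` is the log10 between-group
#' fold change of transcript-level expression (group summary of TPM, with
#' the same pseudocount).  The quadrant label combines the signs of `x`
#' and `y_expr`: the upper-right quadrant holds transcripts with more IR
#' and more expression in group 1.
#'
#' @param ir `ir_table` from [compute_ir()].
#' @param screen `screen_result` from [ir_screen()].
#' @param tpm_transcript long transcript-level TPM tibble.
#' @return tibble: `transcript_id`, `x`, `y_p`, `y_expr`, `quadrant`.
#' @export
volcano_table <- function(ir, screen, tpm_transcript) {
  stopifnot(inherits(ir, "ir_table"))
  gt <- ir$groups
  lev <- group_levels(gt)
  eps <- ir$epsilon
  sfun <- if (ir$summary_fun == "median") median else mean
  expr_sum <- tpm_transcript |>
    inner_join(gt[, c("sample", "group")], by = "sample") |>
    group_by(.data$transcript_id) |>
    summarise(
      expr_g1 = sfun(.data$tpm[.data$group == lev[1]]),
      expr_g2 = sfun(.data$tpm[.data$group == lev[2]]),
      .groups = "drop"
    ) |>
    mutate(y_expr = log10((.data$expr_g1 + eps) / (.data$expr_g2 + eps)))

  ir$summary |>
    select("transcript_id", x = "log2_ratio") |>
    inner_join(screen[, c("transcript_id", "p_ir_two_sided")],
               by = "transcript_id") |>
    inner_join(expr_sum[, c("transcript_id", "y_expr")],
               by = "transcript_id") |>
    mutate(
      y_p = -log10(pmax(.data$p_ir_two_sided, .Machine$double.xmin)),
      quadrant = dplyr::case_when(
        .data$x > 0 & .data$y_expr > 0 ~ "more IR, higher expression in group1",
        .data$x > 0 & .data$y_expr < 0 ~ "more IR, lower expression in group1",
        .data$x < 0 & .data$y_expr > 0 ~ "less IR, higher expression in group1",
        .data$x < 0 & .data$y_expr < 0 ~ "less IR, lower expression in group1",
        .default = "boundary"
      )
    ) |>
    select("transcript_id", "x", "y_p", "y_expr", "quadrant")
}

#' Counts relative to the identity line of group IR summaries
#'
#' Compares each transcript's group-1 and group-2 summary intron/exon
#' ratios: `above` counts transcripts with a strictly larger group-1
#' summary (more IR in group 1), `below` the converse, `on` exact
#' equality.  Percentages are of the above + below total, the off-diagonal
#' transcripts.
#'
#' @param ir `ir_table` from [compute_ir()].
#' @return one-row tibble: `above`, `on`, `below`, `pct_above`,
#'   `pct_below`, `n`.
#' @export
quadrant_counts <- function(ir) {
  stopifnot(inherits(ir, "ir_table"))
  s <- ir$summary
  above <- sum(s$summary_g1 > s$summary_g2)
  below <- sum(s$summary_g1 < s$summary_g2)
  on_line <- sum(s$summary_g1 == s$summary_g2)
  off <- above + below
  tibble(
    above = above, on = on_line, below = below,
    pct_above = if (off > 0) round_half_up(100 * above / off) else NA_real_,
    pct_below = if (off > 0) round_half_up(100 * below / off) else NA_real_,
    n = nrow(s)
  )
}

#' Volcano plot of differential intron retention
#'
#' @param volcano tibble from [volcano_table()].
#' @param alpha significance level drawn as a horizontal reference.
#' @return a ggplot object.
#' @export
plot_volcano <- function(volcano, alpha = 0.05) {
  ggplot2::ggplot(volcano, ggplot2::aes(x = .data$x, y = .data$y_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$quadrant),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "log2 fold change, intron/exon TPM ratio",
                  y = "-log10 p (intronic screen, two-sided)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Heatmap of row-standardised TPM
#'
#' @param zmat wide Z-score tibble from [zscore_rows()].
#' @return a ggplot object (tiles; rows in ranked order, columns in block
#'   order).
#' @export
plot_ir_heatmap <- function(zmat) {
  long <- zmat |>
    pivot_longer(-"transcript_id", names_to = "sample", values_to = "z") |>
    mutate(
      transcript_id = factor(.data$transcript_id,
                             levels = rev(zmat$transcript_id)),
      sample = factor(.data$sample, levels = setdiff(names(zmat),
                                                     "transcript_id"))
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                     y = .data$transcript_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
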