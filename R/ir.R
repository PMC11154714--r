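#' Per-transcript intron/exon TPM ratio and between-group summary
#'
#' For each transcript and sample, intronic and exonic TPMs are summed over
#' that transcript's features and the intron-retention statistic is the
#' pseudocounted ratio
#' \deqn{R = (TPM_{intron} + \epsilon) / (TPM_{exon} + \epsilon).}
#' Per group, `R` is summarised (median by default — robust to the heavy
#' right tail of TPM), and the between-group statistic is
#' `log2_ratio = log2(summary_R_group1 / summary_R_group2)`, which is
#' antisymmetric under swapping the groups.
#'
#' @param tpm_exonic,tpm_intronic long TPM tibbles (columns
#'   `transcript_id`, `sample`, `tpm`; extra columns ignored) for the
#'   exonic and intronic feature universes.
#' @param groups sample-to-group mapping: a data frame with columns
#'   `sample`, `group` or a named vector.  Exactly two groups.
#' @param group1 optional name of the group to treat as group 1 (the
#'   numerator / disease-like group); defaults to the first level
#'   encountered.
#' @param epsilon pseudocount added to both numerator and denominator (TPM
#'   units).  With `epsilon > 0` the ratio is finite and positive even when
#'   the exonic TPM is zero.
#' @param summary_fun `"median"` (default) or `"mean"` group summary.
#' @param zero_exon_flag_fraction transcripts whose exonic TPM is zero in
#'   more than this fraction of samples are flagged (`flag_zero_exon`).
#' @return an object of class `ir_table`: a list with
#'   \describe{
#'     \item{ratios}{tibble per transcript x sample: `tpm_intron`,
#'       `tpm_exon`, `ratio`.}
#'     \item{summary}{tibble per transcript: per-group summary ratios
#'       (`summary_g1`, `summary_g2`), `log2_ratio`, `flag_zero_exon`.}
#'     \item{groups, epsilon, summary_fun}{the parameters used.}
#'   }
#'   `tidy()` returns the summary tibble; `autoplot()` draws the group
#'   summary scatter with the identity line.
#' @export
compute_ir <- function(tpm_exonic, tpm_intronic, groups, group1 = NULL,
                       epsilon = 0.01,
                       summary_fun = c("median", "mean"),
                       zero_exon_flag_fraction = 0.4) {
  summary_fun <- match.arg(summary_fun)
  check_columns(tpm_exonic, c("transcript_id", "sample", "tpm"), "`tpm_exonic`")
  check_columns(tpm_intronic, c("transcript_id", "sample", "tpm"), "`tpm_intronic`")
  if (epsilon < 0) abort("`epsilon` must be >= 0.")
  gt <- as_group_tbl(groups, group1 = group1)

  sum_by_tx <- function(x) {
    x |>
      group_by(.data$transcript_id, .data$sample) |>
      summarise(tpm = sum(.data$tpm), .groups = "drop")
  }
  ex <- sum_by_tx(tpm_exonic)
  intr <- sum_by_tx(tpm_intronic)

  only_ex <- setdiff(unique(ex$transcript_id), unique(intr$transcript_id))
  only_in <- setdiff(unique(intr$transcript_id), unique(ex$transcript_id))
  if (length(only_ex) || length(only_in)) {
    warn(sprintf(
      "Excluded %d transcript(s) present in only one of the two matrices.",
      length(only_ex) + length(only_in)))
  }

  ratios <- inner_join(
    rename(ex, tpm_exon = "tpm"),
    rename(intr, tpm_intron = "tpm"),
    by = c("transcript_id", "sample")
  ) |>
    inner_join(gt[, c("sample", "group")], by = "sample") |>
    mutate(ratio = (.data$tpm_intron + epsilon) / (.data$tpm_exon + epsilon))

  if (!all(is.finite(ratios$ratio))) {
    abort("Non-finite intron/exon ratio; use epsilon > 0 when exonic TPM can be zero.")
  }

  sfun <- if (summary_fun == "median") median else mean
  lev <- group_levels(gt)
  summary <- ratios |>
    group_by(.data$transcript_id) |>
    summarise(
      summary_g1 = sfun(.data$ratio[.data$group == lev[1]]),
      summary_g2 = sfun(.data$ratio[.data$group == lev[2]]),
      flag_zero_exon = mean(.data$tpm_exon == 0) > zero_exon_flag_fraction,
      .groups = "drop"
    ) |>
    mutate(log2_ratio = log2(.data$summary_g1 / .data$summary_g2))

  structure(
    list(
      ratios = select(ratios, -"group"),
      summary = summary,
      groups = gt,
      epsilon = epsilon,
      summary_fun = summary_fun
    ),
    class = "ir_table"
  )
}

#' @export
print.ir_table <- function(x, ...) {
  lev <- group_levels(x$groups)
  cat(sprintf(
    "<ir_table> %d transcripts, %d samples (%s: %d, %s: %d), epsilon = %g, %s summary\n",
    nrow(x$summary), nrow(x$groups),
    lev[1], sum(x$groups$group == lev[1]),
    lev[2], sum(x$groups$group == lev[2]),
    x$epsilon, x$summary_fun))
  print(x$summary, ...)
  invisible(x)
}

#' @rdname compute_ir
#' @param x an `ir_table`.
#' @param ... unused.
#' @export
tidy.ir_table <- function(x, ...) x$summary

#' @rdname compute_ir
#' @export
glance.ir_table <- function(x, ...) {
  tibble(
    n_transcripts = nrow(x$summary),
    n_samples = nrow(x$groups),
    epsilon = x$epsilon,
    summary_fun = x$summary_fun,
    n_flag_zero_exon = sum(x$summary$flag_zero_exon)
  )
}

#' @rdname compute_ir
#' @param object an `ir_table`.
#' @export
autoplot.ir_table <- function(object, ...) {
  lev <- group_levels(object$groups)
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$summary_g2, y = .data$summary_g1)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = sprintf("intron/exon TPM ratio, %s (%s)", object$summary_fun, lev[2]),
      y = sprintf("intron/exon TPM ratio, %s (%s)", object$summary_fun, lev[1])
    ) +
    ggplot2::theme_minimal()
}
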