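#' Six-set differential IR/expression classification
#'
#' Transcripts whose directional intronic screen rejects under BH form
#' set-I (higher intron usage in group 1) or set-II (higher in group 2);
#' the two directional screens cannot both reject at any reasonable level,
#' so the sets are disjoint.  Within a set, the transcript-level expression
#' screens assign subsets relative to the set's own group:
#' \describe{
#'   \item{A}{over-expressed in the set's group (directional expression
#'     screen rejects in the same direction as the IR call);}
#'   \item{B}{under-expressed in the set's group (opposite direction
#'     rejects);}
#'   \item{C}{non-differentially expressed: two-sided expression p >
#'     `alpha` (raw, unadjusted — an intentionally asymmetric rule);}
#'   \item{unassigned}{an IR screen rejected but none of the A/B/C rules
#'     applies (reported, never silently forced into C).}
#' }
#'
#' @param screen a `screen_result` tibble from [ir_screen()].
#' @param alpha raw-p threshold for the set-C two-sided rule.
#' @param fdr_level BH level for the directional screens.
#' @param expr_adjust `"fdr"` (default) uses BH-adjusted q-values for the
#'   A/B expression screens; `"raw"` thresholds the raw p at `alpha`.
#' @return tibble per transcript: `ir_set` (`"set-I"`, `"set-II"`,
#'   `"none"`), `expr_subset` (`"A"`, `"B"`, `"C"`, `"unassigned"`, or
#'   `NA` when `ir_set` is `"none"`), and `set_label` (e.g. `"set-IA"`).
#' @export
classify_sets <- function(screen, alpha = 0.05, fdr_level = 0.05,
                          expr_adjust = c("fdr", "raw")) {
  expr_adjust <- match.arg(expr_adjust)
  check_columns(screen,
                c("transcript_id", "q_ir_g1_gt_g2", "q_ir_g2_gt_g1",
                  "p_expr_g1_gt_g2", "p_expr_g2_gt_g1", "p_expr_two_sided",
                  "q_expr_g1_gt_g2", "q_expr_g2_gt_g1"),
                "`screen`")
  in_set1 <- screen$q_ir_g1_gt_g2 <= fdr_level
  in_set2 <- screen$q_ir_g2_gt_g1 <= fdr_level
  both <- in_set1 & in_set2
  if (any(both)) {
    warn(sprintf("%d transcript(s) reject both directional IR screens; left in 'none'.",
                 sum(both)))
    in_set1[both] <- FALSE
    in_set2[both] <- FALSE
  }
  ir_set <- dplyr::case_when(in_set1 ~ "set-I", in_set2 ~ "set-II",
                             .default = "none")

  expr_up_g1 <- if (expr_adjust == "fdr") {
    screen$q_expr_g1_gt_g2 <= fdr_level
  } else screen$p_expr_g1_gt_g2 < alpha
  expr_up_g2 <- if (expr_adjust == "fdr") {
    screen$q_expr_g2_gt_g1 <= fdr_level
  } else screen$p_expr_g2_gt_g1 < alpha
  non_diff <- screen$p_expr_two_sided > alpha

  # "over-expressed" is relative to the set's own group
  own_up <- if_else(ir_set == "set-I", expr_up_g1, expr_up_g2)
  other_up <- if_else(ir_set == "set-I", expr_up_g2, expr_up_g1)
  expr_subset <- dplyr::case_when(
    ir_set == "none" ~ NA_character_,
    own_up ~ "A",
    other_up ~ "B",
    non_diff ~ "C",
    .default = "unassigned"
  )
  tibble(
    transcript_id = screen$transcript_id,
    ir_set = ir_set,
    expr_subset = expr_subset,
    set_label = if_else(
      ir_set == "none", "none",
      paste0(ir_set, if_else(expr_subset == "unassigned", " (unassigned)",
                             expr_subset))
    )
  )
}

#' Summarise set/subset counts with reported-style percentages
#'
#' Given per-set (and optionally per-subset) transcript counts, computes
#' each set's share of the grand total and each subset's share within its
#' set, with percentages rounded half-up to whole numbers, the convention
#' used when such splits are reported.
#'
#' @param counts data frame with columns `ir_set`, `n`, and optionally
#'   `expr_subset`.
#' @return the input with added columns `set_total` (transcripts in the
#'   set), `total` (grand total) and, when subsets are given,
#'   `pct_within_set`; plus `pct_of_total` per set.
#' @export
#' @examples
#' summarize_set_counts(tibble::tibble(
#'   ir_set = "set-I", expr_subset = c("A", "B", "C"),
#'   n = c(10436, 188, 1345)
#' ))
summarize_set_counts <- function(counts) {
  check_columns(counts, c("ir_set", "n"), "`counts`")
  out <- counts |>
    group_by(.data$ir_set) |>
    mutate(set_total = sum(.data$n)) |>
    ungroup() |>
    mutate(
      total = sum(.data$n),
      pct_of_total = round_half_up(100 * .data$set_total / .data$total)
    )
  if ("expr_subset" %in% names(counts)) {
    out <- out |>
      mutate(pct_within_set = round_half_up(100 * .data$n / .data$set_total))
  }
  out
}

#' Contingency analysis of IR set vs expression subset
#'
#' Builds the 2 x 3 table of {set-I, set-II} x {A, B, C} (unassigned
#' transcripts are excluded) and applies Pearson's chi-square test without
#' continuity correction; on the 2 x 2 {A, B} subtable it computes the
#' sample odds ratio `ad/bc` and Fisher's exact p-value.  A zero cell in
#' the 2 x 2 table triggers the Haldane-Anscombe +0.5 correction for the
#' odds ratio (flagged).
#'
#' @param sets classification tibble from [classify_sets()].
#' @return an `ir_contingency` object with elements `table_2x3`,
#'   `chi2_stat`, `chi2_df`, `chi2_p`, `table_2x2`, `odds_ratio`,
#'   `haldane`, `fisher_p` and `percentages` (via
#'   [summarize_set_counts()]).  `tidy()` returns the cell counts,
#'   `glance()` the test statistics.
#' @export
contingency <- function(sets) {
  check_columns(sets, c("ir_set", "expr_subset"), "`sets`")
  used <- sets |>
    filter(.data$ir_set %in% c("set-I", "set-II"),
           .data$expr_subset %in% c("A", "B", "C"))
  if (!all(c("set-I", "set-II") %in% used$ir_set)) {
    abort("Both set-I and set-II must be non-empty for the contingency analysis.")
  }
  tab <- table(
    factor(used$ir_set, levels = c("set-I", "set-II")),
    factor(used$expr_subset, levels = c("A", "B", "C"))
  )
  tab_m <- matrix(as.integer(tab), nrow = 2,
                  dimnames = list(ir_set = c("set-I", "set-II"),
                                  expr_subset = c("A", "B", "C")))
  chi <- suppressWarnings(chisq.test(tab_m, correct = FALSE))

  tab22 <- tab_m[, c("A", "B")]
  haldane <- any(tab22 == 0)
  t22 <- if (haldane) tab22 + 0.5 else tab22
  or <- (t22[1, 1] * t22[2, 2]) / (t22[1, 2] * t22[2, 1])
  fish <- fisher.test(tab22)

  pct <- sets |>
    filter(.data$ir_set %in% c("set-I", "set-II"), !is.na(.data$expr_subset)) |>
    count(.data$ir_set, .data$expr_subset) |>
    summarize_set_counts()

  structure(
    list(
      table_2x3 = tab_m,
      chi2_stat = unname(chi$statistic),
      chi2_df = unname(chi$parameter),
      chi2_p = chi$p.value,
      table_2x2 = tab22,
      odds_ratio = unname(or),
      haldane = haldane,
      fisher_p = fish$p.value,
      percentages = pct
    ),
    class = "ir_contingency"
  )
}

#' @export
print.ir_contingency <- function(x, ...) {
  cat("<ir_contingency>\n2 x 3 table (IR set x expression subset):\n")
  print(x$table_2x3)
  cat(sprintf("chi-square = %.4g (df = %d), p = %.3g\n",
              x$chi2_stat, x$chi2_df, x$chi2_p))
  cat(sprintf("2 x 2 {A,B}: odds ratio = %.4g%s, Fisher p = %.3g\n",
              x$odds_ratio, if (x$haldane) " (Haldane-corrected)" else "",
              x$fisher_p))
  invisible(x)
}

#' @rdname contingency
#' @param x,object an `ir_contingency`.
#' @param ... unused.
#' @export
tidy.ir_contingency <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table_2x3))) |>
    setNames(c("ir_set", "expr_subset", "n"))
}

#' @rdname contingency
#' @export
glance.ir_contingency <- function(x, ...) {
  tibble(
    chi2_stat = x$chi2_stat,
    chi2_df = x$chi2_df,
    chi2_p = x$chi2_p,
    odds_ratio = x$odds_ratio,
    haldane = x$haldane,
    fisher_p = x$fisher_p,
    n = sum(x$table_2x3)
  )
}
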