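#' Filter transcripts by detection rate in both groups
#'
#' A transcript is retained when its TPM is positive in at least
#' `threshold` of the samples of *each* group separately (inclusive bound),
#' ensuring it is expressed in the large majority of both conditions before
#' differential screening.
#'
#' @param tpm_transcript long transcript-level TPM tibble
#'   (`transcript_id`, `sample`, `tpm`).
#' @param groups sample-to-group mapping (see [compute_ir()]).
#' @param group1 optional group-1 label.
#' @param threshold detection fraction in (0, 1]; default 0.60.
#' @return tibble per transcript: `frac_g1`, `frac_g2`, `retained`.
#' @export
filter_expressed <- function(tpm_transcript, groups, group1 = NULL,
                             threshold = 0.60) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  check_columns(tpm_transcript, c("transcript_id", "sample", "tpm"),
                "`tpm_transcript`")
  gt <- as_group_tbl(groups, group1 = group1)
  lev <- group_levels(gt)
  tpm_transcript |>
    inner_join(gt[, c("sample", "group")], by = "sample") |>
    group_by(.data$transcript_id) |>
    summarise(
      frac_g1 = mean(.data$tpm[.data$group == lev[1]] > 0),
      frac_g2 = mean(.data$tpm[.data$group == lev[2]] > 0),
      .groups = "drop"
    ) |>
    mutate(retained = .data$frac_g1 >= threshold & .data$frac_g2 >= threshold)
}

#' One-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney test of `H1: a > b` (or `a < b`).  For `length(a) +
#' length(b) <= 12` without ties the exact null distribution is used;
#' otherwise the normal approximation with mid-rank tie correction and
#' continuity correction.  When every value in both samples is identical
#' there is no directional evidence and the p-value is 1 (flagged via the
#' `"degenerate"` attribute).
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @param direction `"greater"` tests a > b, `"less"` tests a < b.
#' @return a single p-value.
#' @export
#' @examples
#' rank_test_one_sided(c(3, 4, 5), c(1, 2), "greater") # 0.1
rank_test_one_sided <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 observations.")
  }
  vals <- c(a, b)
  if (length(unique(vals)) == 1L) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  n <- length(vals)
  use_exact <- n <= 12 && !any(duplicated(vals))
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = direction, exact = use_exact,
                correct = TRUE)
  )
  unname(res$p.value)
}

# Vectorized directional Mann-Whitney over matrix rows (transcripts x
# samples), normal approximation with tie and continuity correction --
# identical formulas to stats::wilcox.test(exact = FALSE, correct = TRUE).
# Returns a tibble with p_greater (g1 > g2), p_less (g2 > g1),
# p_two_sided and a degenerate flag (constant rows get p = 1).
mw_screen <- function(M, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  M <- M[, c(idx1, idx2), drop = FALSE]
  N <- n1 + n2
  ranks <- matrixStats::rowRanks(M, ties.method = "average")
  W <- rowSums(ranks[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
  # tie correction: only rows with tied values need the t^3 - t sum
  rmin <- matrixStats::rowRanks(M, ties.method = "min")
  has_ties <- rowSums(ranks != rmin) > 0
  tie_term <- numeric(nrow(M))
  if (any(has_ties)) {
    tie_term[has_ties] <- apply(M[has_ties, , drop = FALSE], 1L, function(x) {
      cnt <- rle(sort(x))$lengths
      sum(cnt^3 - cnt)
    })
  }
  sigma <- sqrt((n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1))))
  mu <- n1 * n2 / 2
  degenerate <- sigma == 0
  s <- ifelse(degenerate, 1, sigma)
  z <- W - mu
  p_greater <- pnorm((z - 0.5) / s, lower.tail = FALSE)
  p_less <- pnorm((z + 0.5) / s)
  z2 <- (z - sign(z) * 0.5) / s
  p_two <- 2 * pmin(pnorm(z2), pnorm(z2, lower.tail = FALSE))
  p_two <- pmin(p_two, 1)
  tibble(
    p_greater = ifelse(degenerate, 1, p_greater),
    p_less = ifelse(degenerate, 1, p_less),
    p_two_sided = ifelse(degenerate, 1, p_two),
    degenerate = degenerate
  )
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Step-up BH q-values (via [stats::p.adjust()]) with rejection at
#' `q <= level`; rejections are always a subset of `{p <= level}`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param level FDR level (default 0.05).
#' @return tibble with columns `p`, `q`, `reject` (empty input gives an
#'   empty tibble).
#' @export
bh_adjust <- function(p, level = 0.05) {
  if (length(p) == 0L) {
    return(tibble(p = numeric(), q = numeric(), reject = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, reject = q <= level)
}

#' Directional IR and expression screens
#'
#' Runs, per transcript, two one-sided Wilcoxon rank-sum tests on the
#' summed intronic TPM (group1 > group2 and group2 > group1) and the same
#' two directional tests plus the two-sided test on transcript-level TPM.
#' Each directional screen is Benjamini-Hochberg adjusted across all tested
#' transcripts at `fdr_level`.  Group sizes here are typically large and
#' unbalanced (e.g. 97 vs 9), so the screens use the normal approximation
#' with tie and continuity correction throughout.
#'
#' @param tpm_intronic long intronic TPM tibble (`transcript_id`,
#'   `sample`, `tpm`; summed per transcript if several introns).
#' @param tpm_transcript long transcript-level TPM tibble.
#' @param groups sample-to-group mapping; `group1` optionally names the
#'   disease-like group.
#' @param group1 optional group-1 label.
#' @param transcripts optional character vector restricting the screen
#'   (e.g. the [filter_expressed()] survivors).
#' @param fdr_level BH level for the q-value rejection flags.
#' @return a `screen_result` tibble, one row per transcript, with columns
#'   `p_ir_g1_gt_g2`, `p_ir_g2_gt_g1`, `p_ir_two_sided`,
#'   `p_expr_g1_gt_g2`, `p_expr_g2_gt_g1`, `p_expr_two_sided`, matching
#'   `q_*` columns for the four directional screens, and `n_g1`, `n_g2`.
#' @export
ir_screen <- function(tpm_intronic, tpm_transcript, groups, group1 = NULL,
                      transcripts = NULL, fdr_level = 0.05) {
  check_columns(tpm_intronic, c("transcript_id", "sample", "tpm"),
                "`tpm_intronic`")
  check_columns(tpm_transcript, c("transcript_id", "sample", "tpm"),
                "`tpm_transcript`")
  gt <- as_group_tbl(groups, group1 = group1)
  lev <- group_levels(gt)

  to_matrix <- function(x) {
    wide <- x |>
      group_by(.data$transcript_id, .data$sample) |>
      summarise(tpm = sum(.data$tpm), .groups = "drop") |>
      pivot_wider(names_from = "sample", values_from = "tpm", values_fill = 0)
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$transcript_id
    m
  }
  m_intr <- to_matrix(tpm_intronic)
  m_expr <- to_matrix(tpm_transcript)
  common <- intersect(rownames(m_intr), rownames(m_expr))
  if (!is.null(transcripts)) common <- intersect(common, transcripts)
  if (!length(common)) abort("No transcripts shared by the two matrices.")
  samples <- intersect(colnames(m_intr), gt$sample)
  g1 <- which(samples %in% gt$sample[gt$group == lev[1]])
  g2 <- which(samples %in% gt$sample[gt$group == lev[2]])
  if (length(g1) < 2 || length(g2) < 2) {
    abort("Each group needs at least 2 samples present in the matrices.")
  }
  m_intr <- m_intr[common, samples, drop = FALSE]
  m_expr <- m_expr[common, samples, drop = FALSE]

  ir <- mw_screen(m_intr, g1, g2)
  expr <- mw_screen(m_expr, g1, g2)

  tibble(
    transcript_id = common,
    p_ir_g1_gt_g2 = ir$p_greater,
    p_ir_g2_gt_g1 = ir$p_less,
    p_ir_two_sided = ir$p_two_sided,
    p_expr_g1_gt_g2 = expr$p_greater,
    p_expr_g2_gt_g1 = expr$p_less,
    p_expr_two_sided = expr$p_two_sided,
    q_ir_g1_gt_g2 = bh_adjust(ir$p_greater, fdr_level)$q,
    q_ir_g2_gt_g1 = bh_adjust(ir$p_less, fdr_level)$q,
    q_expr_g1_gt_g2 = bh_adjust(expr$p_greater, fdr_level)$q,
    q_expr_g2_gt_g1 = bh_adjust(expr$p_less, fdr_level)$q,
    n_g1 = length(g1),
    n_g2 = length(g2)
  )
}
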