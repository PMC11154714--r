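#' Null calibration of the directional IR screens
#'
#' Generates complete-null synthetic cohorts (no planted effects),
#' runs both directional intronic screens with BH control, classifies
#' sets, and records the per-cohort false-discovery proportion of the
#' combined set-I and set-II calls: `FDP = false calls / max(calls, 1)`,
#' where a call is false when the cohort's truth table labels the
#' transcript `"none"`.  Under a complete null every call is false, so
#' the mean FDP equals the fraction of cohorts with at least one call.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param config a [cohort_config()]; the set fractions are forced to
#'   zero so no effects are planted.
#' @param fdr_level BH level for the screens.
#' @param seeds integer vector of per-cohort seeds (length `n_cohorts`);
#'   default `1:n_cohorts`.
#' @return tibble with one row per cohort: `seed`, `n_calls`,
#'   `n_false`, `fdp`; the mean FDP is the quantity to compare against
#'   the nominal level.
#' @export
null_calibration <- function(n_cohorts = 200,
                             config = cohort_config(n_transcripts = 2000),
                             fdr_level = 0.05,
                             seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_cohorts)
  if (length(seeds) != n_cohorts) {
    abort("`seeds` must have length `n_cohorts`.")
  }
  cfg <- config
  cfg$fraction_setI <- 0
  cfg$fraction_setII <- 0
  map(seeds, function(s) {
    drawn <- draw_cohort(cfg, seed = s)
    g1 <- which(drawn$metadata$group == "CLL")
    g2 <- which(drawn$metadata$group == "NBC")
    scr <- mw_screen(drawn$intronic, g1, g2)
    in_set1 <- bh_adjust(scr$p_greater, fdr_level)$reject
    in_set2 <- bh_adjust(scr$p_less, fdr_level)$reject
    # union of the two set calls; double rejections fall back to 'none'
    called <- xor(in_set1, in_set2)
    is_false <- called & drawn$truth$ir_set == "none"
    tibble(
      seed = s,
      n_calls = sum(called),
      n_false = sum(is_false),
      fdp = sum(is_false) / max(sum(called), 1)
    )
  }) |>
    list_rbind()
}
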