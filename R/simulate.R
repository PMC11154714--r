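#' Configuration for a synthetic two-group IR cohort
#'
#' Defaults emulate the unbalanced study design the package targets: 97
#' disease (CLL-like) samples — 41 high-risk (IGHV-unmutated-like) and 56
#' low-risk (mutated-like) — against 9 normal B-cell-like controls.
#' Baseline transcript abundance is log-normal (reproducing the heavy
#' right tail of TPM), the baseline intron/exon abundance ratio is
#' log-normal around `intron_ratio`, and all planted effects are
#' multiplicative, matching the ratio-based IR statistic:
#' set-I transcripts have intronic abundance multiplied by `delta_ir` in
#' group 1 (set-II: in group 2), and A/B-subset transcripts have
#' exonic/transcript abundance multiplied/divided by `delta_expr` in the
#' set's own group.  Per-cell noise is multiplicative log-normal with
#' log-sd `sigma`.
#'
#' @param n_group1,n_group2 sample counts (disease, control).
#' @param subgroup_split named integer vector splitting group 1 into
#'   display blocks; must sum to `n_group1`.
#' @param n_transcripts number of transcripts.
#' @param fraction_setI,fraction_setII fractions of transcripts planted
#'   with elevated intron usage in group 1 / group 2
#'   (`fraction_setI + fraction_setII <= 1`).
#' @param subset_props proportions of A (over-expressed), B
#'   (under-expressed) and C (non-differential) within each planted set;
#'   must sum to 1.
#' @param delta_ir,delta_expr multiplicative effect sizes (> 0; 1 plants
#'   no effect).
#' @param sigma log-normal noise sd on the log scale.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance
#'   parameters.
#' @param intron_ratio median baseline intron/exon abundance ratio.
#' @param intron_ratio_sdlog log-sd of the baseline intron/exon ratio.
#' @param epsilon pseudocount to use downstream (recorded, not applied
#'   here).
#' @param mode `"tpm"` emits column-normalised TPM matrices; `"counts"`
#'   emits negative-binomial read counts with matched means.
#' @param nb_dispersion negative-binomial dispersion (counts mode);
#'   variance = mu + dispersion * mu^2.
#' @param lib_size expected reads per sample and feature class (counts
#'   mode).
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_group1 = 97, n_group2 = 9,
                          subgroup_split = c("U-CLL" = 41, "M-CLL" = 56),
                          n_transcripts = 2000,
                          fraction_setI = 0.15, fraction_setII = 0.10,
                          subset_props = c(A = 0.5, B = 0.2, C = 0.3),
                          delta_ir = 4, delta_expr = 3,
                          sigma = 0.5,
                          baseline_meanlog = 3, baseline_sdlog = 1.5,
                          intron_ratio = 0.1, intron_ratio_sdlog = 0.5,
                          epsilon = 0.01,
                          mode = c("tpm", "counts"),
                          nb_dispersion = 0.3, lib_size = 5e6) {
  mode <- match.arg(mode)
  cfg <- list(
    n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
    subgroup_split = subgroup_split,
    n_transcripts = as.integer(n_transcripts),
    fraction_setI = fraction_setI, fraction_setII = fraction_setII,
    subset_props = subset_props,
    delta_ir = delta_ir, delta_expr = delta_expr,
    sigma = sigma,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    intron_ratio = intron_ratio, intron_ratio_sdlog = intron_ratio_sdlog,
    epsilon = epsilon, mode = mode,
    nb_dispersion = nb_dispersion, lib_size = lib_size
  )
  if (cfg$n_group1 < 2 || cfg$n_group2 < 2) {
    abort("Each group needs at least 2 samples.")
  }
  if (!is.null(cfg$subgroup_split) &&
      sum(cfg$subgroup_split) != cfg$n_group1) {
    abort("`subgroup_split` must sum to `n_group1`.")
  }
  if (cfg$n_transcripts < 0) abort("`n_transcripts` must be >= 0.")
  fr <- c(cfg$fraction_setI, cfg$fraction_setII)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    abort("Set fractions must lie in [0, 1] and sum to at most 1.")
  }
  if (any(cfg$subset_props < 0) || abs(sum(cfg$subset_props) - 1) > 1e-8 ||
      !setequal(names(cfg$subset_props), c("A", "B", "C"))) {
    abort("`subset_props` must be named A/B/C, non-negative, and sum to 1.")
  }
  if (cfg$delta_ir <= 0 || cfg$delta_expr <= 0) {
    abort("Effect sizes must be > 0.")
  }
  if (cfg$sigma < 0) abort("`sigma` must be >= 0.")
  structure(cfg, class = "cohort_config")
}

# split n into named A/B/C counts matching props exactly (cumulative rounding)
split_counts <- function(n, props) {
  cum <- round(cumsum(props) * n)
  counts <- diff(c(0, cum))
  setNames(as.integer(counts), names(props))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws paired exonic / intronic / transcript abundance matrices under
#' the model described in [cohort_config()], plus sample metadata and a
#' per-transcript truth table.  Output is bitwise-reproducible given
#' (`config`, `seed`).  Effect sizes of exactly 1 plant no effect, so the
#' recorded truth labels reflect *realized* effects: with `delta_ir = 1`
#' (or zero set fractions) the truth contains no set-I/set-II transcripts.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @return an `ir_cohort` list: `exonic`, `intronic`, `transcript` (long
#'   tibbles with `feature_id`, `transcript_id`, `feature_class`,
#'   `sample`, and `tpm` or `count` + `length`), `metadata` (`sample`,
#'   `group`, `subgroup`), `truth` (`transcript_id`, `ir_set`,
#'   `expr_subset`, `ir_multiplier`, `expr_multiplier`), `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  drawn <- draw_cohort(config, seed)
  metadata <- drawn$metadata
  tx <- drawn$truth$transcript_id
  ntx <- config$n_transcripts
  mat_to_long <- function(m, class, value_col, lengths = NULL) {
    if (ntx == 0) {
      out <- tibble(feature_id = character(), transcript_id = character(),
                    feature_class = character(), sample = character())
      out[[value_col]] <- numeric()
      if (!is.null(lengths)) out$length <- integer()
      return(out)
    }
    out <- as_tibble(m, rownames = "transcript_id") |>
      pivot_longer(-"transcript_id", names_to = "sample",
                   values_to = value_col) |>
      mutate(
        feature_class = class,
        feature_id = paste(.data$transcript_id, class, 1L, sep = "|")
      )
    if (!is.null(lengths)) {
      out$length <- lengths[match(out$transcript_id, tx)]
    }
    relocate(out, "feature_id", "transcript_id", "feature_class")
  }
  value_col <- if (config$mode == "tpm") "tpm" else "count"
  out <- list(
    exonic = mat_to_long(drawn$exonic, "exonic", value_col,
                         drawn$lengths$exonic),
    intronic = mat_to_long(drawn$intronic, "intronic", value_col,
                           drawn$lengths$intronic),
    transcript = mat_to_long(drawn$transcript, "transcript", value_col,
                             drawn$lengths$transcript)
  )
  structure(
    c(out, list(metadata = metadata, truth = drawn$truth, config = config,
                seed = as.integer(seed))),
    class = "ir_cohort"
  )
}

# Matrix-level cohort draw shared by generate_cohort() and
# null_calibration(): returns feature-class matrices (transcripts x
# samples, dimnames set) plus metadata and truth.  All randomness happens
# here, in a fixed order, so (config, seed) fully determines the output.
draw_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  n1 <- config$n_group1; n2 <- config$n_group2
  ntx <- config$n_transcripts
  samples1 <- sprintf("CLL%03d", seq_len(n1))
  samples2 <- sprintf("NBC%02d", seq_len(n2))
  subgroup <- if (!is.null(config$subgroup_split)) {
    rep(names(config$subgroup_split), config$subgroup_split)
  } else rep(NA_character_, n1)
  metadata <- tibble(
    sample = c(samples1, samples2),
    group = c(rep("CLL", n1), rep("NBC", n2)),
    subgroup = c(subgroup, rep(NA_character_, n2))
  )
  tx <- if (ntx > 0) sprintf("TX%05d", seq_len(ntx)) else character()

  # planted labels
  n_set1 <- round(config$fraction_setI * ntx)
  n_set2 <- round(config$fraction_setII * ntx)
  ir_set <- rep("none", ntx)
  if (n_set1 > 0) ir_set[seq_len(n_set1)] <- "set-I"
  if (n_set2 > 0) ir_set[n_set1 + seq_len(n_set2)] <- "set-II"
  expr_subset <- rep(NA_character_, ntx)
  for (s in c("set-I", "set-II")) {
    idx <- which(ir_set == s)
    if (length(idx)) {
      cnt <- split_counts(length(idx), config$subset_props)
      expr_subset[idx] <- rep(names(cnt), cnt)
    }
  }

  # realized multipliers (1 = no effect)
  ir_mult <- ifelse(ir_set == "none", 1, config$delta_ir)
  expr_mult <- dplyr::case_when(
    is.na(expr_subset) | expr_subset == "C" ~ 1,
    expr_subset == "A" ~ config$delta_expr,
    expr_subset == "B" ~ 1 / config$delta_expr
  )
  # labels reflect realized effects, not intent
  ir_set[ir_mult == 1] <- "none"
  expr_subset[ir_set == "none"] <- NA_character_
  realized_subset <- expr_subset
  realized_subset[!is.na(expr_subset) & expr_mult == 1] <- "C"

  truth <- tibble(
    transcript_id = tx,
    ir_set = ir_set,
    expr_subset = realized_subset,
    ir_multiplier = ifelse(ir_set == "none", 1, ir_mult),
    expr_multiplier = ifelse(ir_set == "none", 1, expr_mult)
  )

  ns <- n1 + n2
  in_g1 <- c(rep(TRUE, n1), rep(FALSE, n2))
  baseline <- rlnorm(ntx, config$baseline_meanlog, config$baseline_sdlog)
  rho <- rlnorm(ntx, log(config$intron_ratio), config$intron_ratio_sdlog)

  # per-(transcript, sample) effect factors
  g1_cols <- matrix(rep(in_g1, each = ntx), nrow = ntx, ncol = ns)
  ir_boost_g1 <- truth$ir_set == "set-I"
  ir_boost_g2 <- truth$ir_set == "set-II"
  ir_factor <- matrix(1, ntx, ns)
  ir_factor[ir_boost_g1, ] <- ifelse(g1_cols[ir_boost_g1, , drop = FALSE],
                                     config$delta_ir, 1)
  ir_factor[ir_boost_g2, ] <- ifelse(g1_cols[ir_boost_g2, , drop = FALSE],
                                     1, config$delta_ir)
  # expression effect acts in the set's own group
  e_g1 <- rep(1, ntx); e_g2 <- rep(1, ntx)
  e_g1[ir_boost_g1] <- truth$expr_multiplier[ir_boost_g1]
  e_g2[ir_boost_g2] <- truth$expr_multiplier[ir_boost_g2]
  expr_factor <- matrix(rep(e_g2, ns), nrow = ntx, ncol = ns)
  expr_factor[, in_g1] <- matrix(rep(e_g1, n1), nrow = ntx, ncol = n1)

  noise <- function() {
    if (ntx == 0) return(matrix(numeric(), 0, ns))
    matrix(exp(rnorm(ntx * ns, 0, config$sigma)), ntx, ns)
  }
  # Expression effects act on the transcript-level matrix only; the
  # intronic matrix carries the IR effect alone.  The directional IR
  # screens test intronic abundance directly, so coupling expression into
  # the intronic signal would conflate the two planted effects.
  exon_ab <- baseline * noise()
  intron_ab <- (baseline * rho) * ir_factor * noise()
  tx_ab <- baseline * expr_factor * noise()

  name_mat <- function(m) {
    if (ntx > 0) dimnames(m) <- list(tx, metadata$sample)
    m
  }
  lengths <- list(exonic = NULL, intronic = NULL, transcript = NULL)
  if (config$mode == "tpm") {
    to_tpm <- function(m) {
      if (ntx == 0) return(m)
      cs <- colSums(m)
      sweep(m, 2, ifelse(cs > 0, cs, 1), "/") * 1e6
    }
    mats <- list(exonic = to_tpm(exon_ab), intronic = to_tpm(intron_ab),
                 transcript = to_tpm(tx_ab))
  } else {
    exon_len <- pmax(100L, as.integer(round(rlnorm(ntx, log(1500), 0.6))))
    intron_len <- pmax(100L, as.integer(round(rlnorm(ntx, log(5000), 0.8))))
    tx_len <- exon_len + intron_len
    to_counts <- function(m, len) {
      if (ntx == 0) return(m)
      mass <- m * len
      cs <- colSums(mass)
      mu <- sweep(mass, 2, ifelse(cs > 0, cs, 1), "/") * config$lib_size
      matrix(rnbinom(ntx * ncol(m), mu = mu, size = 1 / config$nb_dispersion),
             ntx, ncol(m))
    }
    mats <- list(exonic = to_counts(exon_ab, exon_len),
                 intronic = to_counts(intron_ab, intron_len),
                 transcript = to_counts(tx_ab, tx_len))
    lengths <- list(exonic = exon_len, intronic = intron_len,
                    transcript = tx_len)
  }
  list(
    exonic = name_mat(mats$exonic),
    intronic = name_mat(mats$intronic),
    transcript = name_mat(mats$transcript),
    lengths = lengths,
    metadata = metadata,
    truth = truth
  )
}

#' @export
print.ir_cohort <- function(x, ...) {
  cat(sprintf(
    "<ir_cohort> %d transcripts x %d samples (%d %s), mode = %s, seed = %d\n",
    x$config$n_transcripts, nrow(x$metadata),
    x$config$n_group1, x$metadata$group[1], x$config$mode, x$seed))
  planted <- table(x$truth$ir_set)
  cat("planted:", paste(names(planted), planted, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a cohort fixture directory
#'
#' Writes the three abundance matrices as wide TSVs (via
#' [write_matrix()]), sample metadata and truth as TSVs, and the
#' configuration as JSON, such that [read_cohort()] reconstructs an
#' equivalent cohort object and [ingest_matrix()] can re-ingest each
#' matrix on its own.
#'
#' @param cohort an `ir_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ir_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in c("exonic", "intronic", "transcript")) {
    write_matrix(cohort[[cls]], file.path(dir, paste0(cls, ".tsv")))
  }
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  cfg <- unclass(cohort$config)
  # keep names through JSON: atomic vectors serialize nameless
  cfg$subset_props <- as.list(cfg$subset_props)
  if (!is.null(cfg$subgroup_split)) {
    cfg$subgroup_split <- as.list(cfg$subgroup_split)
  }
  cfg$seed <- cohort$seed
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) abort(sprintf("No config.json in %s", dir))
  raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  seed <- raw$seed %||% NA_integer_
  raw$seed <- NULL
  sgs <- unlist(raw$subgroup_split)
  raw$subset_props <- unlist(raw$subset_props)
  raw["subgroup_split"] <- list(sgs) # keep the slot even when NULL
  config <- do.call(cohort_config, raw)
  type <- if (config$mode == "tpm") "tpm" else "counts"
  mats <- lapply(c("exonic", "intronic", "transcript"), function(cls) {
    ingest_matrix(file.path(dir, paste0(cls, ".tsv")), type = type,
                  feature_class = cls)
  })
  names(mats) <- c("exonic", "intronic", "transcript")
  truth_cols <- readr::cols(
    transcript_id = readr::col_character(),
    ir_set = readr::col_character(),
    expr_subset = readr::col_character(),
    ir_multiplier = readr::col_double(),
    expr_multiplier = readr::col_double()
  )
  structure(
    c(mats, list(
      metadata = readr::read_tsv(file.path(dir, "metadata.tsv"),
                                 col_types = "ccc", progress = FALSE),
      truth = readr::read_tsv(file.path(dir, "truth.tsv"),
                              col_types = truth_cols, progress = FALSE),
      config = config,
      seed = as.integer(seed)
    )),
    class = "ir_cohort"
  )
}
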