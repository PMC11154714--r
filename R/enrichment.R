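#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, member
#'   genes).
#' @return named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  fgsea::gmtPathways(path)
}

#' Map the top fraction of a ranked transcript list to gene symbols
#'
#' Takes the first `ceiling(fraction * n)` transcripts of a ranked list
#' (e.g. the set-I transcripts ranked by screen p-value) and collapses
#' them to unique gene symbols.  Transcripts without a symbol mapping are
#' dropped; their count is reported via the `"n_unmapped"` attribute and a
#' warning.
#'
#' @param ranked ranked tibble with a `transcript_id` column, best first
#'   (e.g. from [select_top_n()] with `n = Inf`).
#' @param tx2gene data frame mapping `transcript_id` to `gene_symbol`.
#' @param fraction fraction of the list to keep, in (0, 1].
#' @return character vector of unique gene symbols.
#' @export
select_top_fraction <- function(ranked, tx2gene, fraction = 0.25) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1].")
  }
  check_columns(ranked, "transcript_id", "`ranked`")
  check_columns(tx2gene, c("transcript_id", "gene_symbol"), "`tx2gene`")
  n_keep <- ceiling(fraction * nrow(ranked))
  top <- ranked$transcript_id[seq_len(n_keep)]
  mapped <- tx2gene$gene_symbol[match(top, tx2gene$transcript_id)]
  n_unmapped <- sum(is.na(mapped))
  if (n_unmapped > 0) {
    warn(sprintf("%d transcript(s) had no gene-symbol mapping and were dropped.",
                 n_unmapped))
  }
  out <- unique(mapped[!is.na(mapped)])
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under uniform sampling from the universe: the one-sided
#' hypergeometric tail \eqn{P(X \ge k)} with `k` the overlap, `m` the set
#' size, `n` the query size and `N` the universe size, all after
#' restricting sets and query to the universe.  P-values are
#' Bonferroni-adjusted over the number of sets actually tested.  The
#' background universe should match the tested population (e.g. all genes
#' surviving the expression filter), not the whole annotation.
#'
#' @param query character vector of gene symbols; members outside
#'   `universe` are dropped with a warning.
#' @param gene_sets named list of gene-symbol vectors (see
#'   [read_gene_sets()]); sets are restricted to the universe and empty
#'   sets dropped.
#' @param universe character vector of background gene symbols.
#' @return tibble sorted by adjusted p: `set`, `k` (overlap), `m` (set
#'   size), `n` (query size), `N` (universe size), `p`, `p_bonferroni`,
#'   `fold_enrichment` = (k/n)/(m/N), `genes` (overlap, comma-separated).
#' @export
ora_test <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) abort("`universe` is empty.")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe were dropped.",
                 length(outside)))
  }
  query <- unique(intersect(query, universe))
  n <- length(query)
  if (n == 0L) {
    warn("Empty query after restriction to the universe.")
    return(tibble(set = character(), k = integer(), m = integer(),
                  n = integer(), N = integer(), p = numeric(),
                  p_bonferroni = numeric(), fold_enrichment = numeric(),
                  genes = character()))
  }
  restricted <- map(gene_sets, intersect, universe)
  keep <- lengths(restricted) > 0
  if (any(!keep)) {
    warn(sprintf("%d gene set(s) empty after restriction were dropped.",
                 sum(!keep)))
  }
  restricted <- restricted[keep]
  n_sets <- length(restricted)
  if (n_sets == 0L) abort("No gene sets left after restriction to the universe.")

  res <- imap(restricted, function(members, name) {
    m <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    tibble(
      set = name, k = k, m = m, n = n, N = N, p = p,
      fold_enrichment = (k / n) / (m / N),
      genes = paste(sort(hit), collapse = ",")
    )
  }) |>
    list_rbind() |>
    mutate(p_bonferroni = pmin(1, .data$p * n_sets)) |>
    relocate("p_bonferroni", .after = "p") |>
    arrange(.data$p_bonferroni, .data$p, .data$set)
  res
}
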