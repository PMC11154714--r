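# Shared fixtures and independent oracles used across test files.

# three-transcript annotation: t1 (2 exons), t2 (3 exons), t3 (1 exon)
tiny_exons <- function() {
  tibble::tribble(
    ~transcript_id, ~gene_id, ~gene_symbol, ~chrom, ~start, ~end, ~strand,
    "t1", "g1", "G1", "chr1", 100L, 200L, "+",
    "t1", "g1", "G1", "chr1", 301L, 400L, "+",
    "t2", "g2", "G2", "chr1", 1000L, 1100L, "-",
    "t2", "g2", "G2", "chr1", 1201L, 1300L, "-",
    "t2", "g2", "G2", "chr1", 1401L, 1500L, "-",
    "t3", "g3", "G3", "chr2", 50L, 150L, "+"
  )
}

# long TPM tibble from a named matrix (rows transcripts, cols samples)
mat_to_tpm <- function(m, feature_class = "transcript") {
  tibble::as_tibble(m, rownames = "transcript_id") |>
    tidyr::pivot_longer(-transcript_id, names_to = "sample",
                        values_to = "tpm") |>
    dplyr::mutate(
      feature_class = feature_class,
      feature_id = paste(transcript_id, feature_class, 1L, sep = "|")
    )
}

two_group_map <- function(n1 = 4, n2 = 3, g1 = "CLL", g2 = "NBC") {
  tibble::tibble(
    sample = c(sprintf("A%d", seq_len(n1)), sprintf("B%d", seq_len(n2))),
    group = c(rep(g1, n1), rep(g2, n2))
  )
}

# --- independent oracles -------------------------------------------------

# exact one-sided rank-sum p by enumerating all group labelings
perm_rank_p <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  if (direction == "greater") mean(stats >= obs) else mean(stats <= obs)
}

# two-sided Fisher p by hypergeometric enumeration over fixed margins
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ORA tail p by enumerating every size-n draw from a universe of size N
ora_enum_p <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(m) # wlog the set is the first m elements
  mean(apply(draws, 2, function(d) sum(d %in% in_set)) >= k)
}
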