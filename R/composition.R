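#' Base composition of an alignment
#'
#' Frequencies of the four bases pooled over every unambiguous A/C/G/T
#' character in the alignment. `g_R` and `g_Y` are the purine and pyrimidine
#' totals used by the TN93 correction.
#'
#' @param aln An `skt_alignment`.
#' @param deletion `"pairwise"` (default; counts every unambiguous character)
#'   or `"complete"` (first drops columns containing any gap or ambiguity in
#'   any sequence).
#' @return A one-row tibble with columns `freq_A`, `freq_C`, `freq_G`,
#'   `freq_T`, `g_R`, `g_Y` and `counted_sites`.
#' @export
base_composition <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- seq_matrix(aln)
  if (deletion == "complete") {
    keep <- !apply(m, 2, function(col) any(!col %in% DNA_BASES))
    m <- m[, keep, drop = FALSE]
  }
  chars <- as.vector(m)
  chars <- chars[chars %in% DNA_BASES]
  if (length(chars) == 0) {
    abort_input("alignment contains no unambiguous A/C/G/T characters")
  }
  counts <- table(factor(chars, levels = DNA_BASES))
  f <- as.numeric(counts) / sum(counts)
  names(f) <- DNA_BASES
  tibble::tibble(
    freq_A = f[["A"]], freq_C = f[["C"]], freq_G = f[["G"]], freq_T = f[["T"]],
    g_R = f[["A"]] + f[["G"]], g_Y = f[["C"]] + f[["T"]],
    counted_sites = length(chars)
  )
}

#' Chi-square test of base-composition homogeneity among sequences
#'
#' Contingency chi-square of the per-sequence A/C/G/T counts against the
#' expectation from the pooled frequencies, with `df = 3 * (N - 1)` for `N`
#' sequences. A large p-value supports compositional homogeneity, an
#' assumption of the distance corrections used here.
#'
#' @param aln An `skt_alignment` with at least two sequences.
#' @return A one-row tibble with `statistic`, `df` and `p_value` (upper tail
#'   of the chi-square distribution).
#' @export
composition_homogeneity_test <- function(aln) {
  if (nrow(aln) < 2) {
    abort_input("homogeneity test needs at least two sequences")
  }
  m <- seq_matrix(aln)
  obs <- t(apply(m, 1, function(row) {
    table(factor(row[row %in% DNA_BASES], levels = DNA_BASES))
  }))
  totals <- rowSums(obs)
  if (any(totals == 0)) {
    bad <- aln$id[totals == 0][[1]]
    abort_input(paste0("sequence '", bad, "' has no countable A/C/G/T characters"))
  }
  pooled <- colSums(obs) / sum(obs)
  expd <- outer(totals, pooled)
  use <- expd > 0
  statistic <- sum((obs[use] - expd[use])^2 / expd[use])
  df <- 3 * (nrow(aln) - 1)
  tibble::tibble(
    statistic = statistic,
    df = df,
    p_value = pchisq(statistic, df, lower.tail = FALSE)
  )
}

#' Variable and parsimony-informative site counts
#'
#' A column is variable when at least two unambiguous states are observed,
#' and parsimony informative when at least two states are each present in at
#' least two sequences. Gaps and ambiguity codes are ignored within a column.
#'
#' @param aln An `skt_alignment`.
#' @return A one-row tibble with `total_sites`, `variable_sites`,
#'   `parsimony_informative_sites` and the corresponding proportions.
#' @export
site_summary <- function(aln) {
  m <- seq_matrix(aln)
  cls <- apply(m, 2, function(col) {
    counts <- table(col[col %in% DNA_BASES])
    c(variable = sum(counts > 0) >= 2,
      informative = sum(counts >= 2) >= 2)
  })
  total <- ncol(m)
  v <- sum(cls["variable", ])
  pi <- sum(cls["informative", ])
  tibble::tibble(
    total_sites = total,
    variable_sites = v,
    parsimony_informative_sites = pi,
    prop_variable = v / total,
    prop_informative = pi / total
  )
}
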