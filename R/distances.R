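#' Count transition and transversion proportions between two sequences
#'
#' Compares two aligned sequences site by site under pairwise deletion:
#' any site where either character is not an unambiguous A/C/G/T is
#' excluded. `P1` is the proportion of purine transitions (A<->G), `P2` the
#' proportion of pyrimidine transitions (C<->T) and `Q` the proportion of
#' transversions, all relative to the number of compared sites.
#'
#' @param a,b Aligned nucleotide sequences (single strings of equal length).
#' @return A one-row tibble with `P1`, `P2`, `Q` and `compared_sites`.
#' @examples
#' count_site_patterns("AG", "GG")
#' @export
count_site_patterns <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (nchar(a) != nchar(b)) {
    abort_alignment("sequences have unequal lengths")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  n <- sum(ok)
  if (n == 0) {
    abort_input("no comparable unambiguous sites between the two sequences")
  }
  ca <- ca[ok]
  cb <- cb[ok]
  diff <- ca != cb
  pair <- paste0(pmin(ca[diff], cb[diff]), pmax(ca[diff], cb[diff]))
  tibble::tibble(
    P1 = sum(pair == "AG") / n,
    P2 = sum(pair == "CT") / n,
    Q = sum(!pair %in% c("AG", "CT")) / n,
    compared_sites = n
  )
}

#' Jukes-Cantor corrected distance
#'
#' @param p Observed proportion of differing sites.
#' @return A one-row tibble with `distance` (substitutions/site) and `flag`
#'   (`"ok"` or `"saturated"` when the correction is undefined).
#' @export
jc_distance <- function(p) {
  if (p < 0 || p > 1) abort_input("`p` must be in [0, 1]")
  arg <- 1 - 4 * p / 3
  if (arg <= 0) {
    return(tibble::tibble(distance = NA_real_, flag = "saturated"))
  }
  tibble::tibble(distance = -0.75 * log(arg), flag = "ok")
}

#' Kimura two-parameter corrected distance
#'
#' @param P Observed proportion of transitions.
#' @param Q Observed proportion of transversions.
#' @return A one-row tibble with `distance` and `flag` as in [jc_distance()].
#' @export
k2p_distance <- function(P, Q) {
  if (P < 0 || Q < 0 || P + Q > 1) {
    abort_input("`P` and `Q` must be non-negative with P + Q <= 1")
  }
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) {
    return(tibble::tibble(distance = NA_real_, flag = "saturated"))
  }
  tibble::tibble(distance = -0.5 * log(a1) - 0.25 * log(a2), flag = "ok")
}

#' Tamura-Nei (TN93) corrected distance
#'
#' Corrects observed transition/transversion proportions for multiple hits
#' allowing unequal base frequencies and distinct purine vs pyrimidine
#' transition rates:
#' \deqn{d = -k_1 \ln w_1 - k_2 \ln w_2 - k_3 \ln w_3}
#' with \eqn{k_1 = 2 g_A g_G / g_R}, \eqn{k_2 = 2 g_T g_C / g_Y},
#' \eqn{k_3 = 2 (g_R g_Y - g_A g_G g_Y / g_R - g_T g_C g_R / g_Y)},
#' \eqn{w_1 = 1 - P_1 g_R / (2 g_A g_G) - Q / (2 g_R)},
#' \eqn{w_2 = 1 - P_2 g_Y / (2 g_T g_C) - Q / (2 g_Y)} and
#' \eqn{w_3 = 1 - Q / (2 g_R g_Y)}.
#'
#' When a base frequency required by a term is zero, the term is evaluated
#' only if its observed proportion is also zero (the term then contributes
#' nothing); otherwise the composition is degenerate and an error is raised.
#' If any log argument is non-positive the pair is flagged `"saturated"` and
#' the distance is undefined.
#'
#' @param counts A one-row tibble from [count_site_patterns()].
#' @param comp A one-row tibble from [base_composition()].
#' @return A one-row tibble with `distance` and `flag`.
#' @export
trn_distance <- function(counts, comp) {
  P1 <- counts$P1[[1]]; P2 <- counts$P2[[1]]; Q <- counts$Q[[1]]
  gA <- comp$freq_A[[1]]; gC <- comp$freq_C[[1]]
  gG <- comp$freq_G[[1]]; gT <- comp$freq_T[[1]]
  gR <- gA + gG
  gY <- gC + gT
  d <- 0
  if (gA * gG > 0) {
    k1 <- 2 * gA * gG / gR
    w1 <- 1 - P1 * gR / (2 * gA * gG) - Q / (2 * gR)
    if (w1 <= 0) {
      return(tibble::tibble(distance = NA_real_, flag = "saturated"))
    }
    d <- d - k1 * log(w1)
  } else if (P1 > 0) {
    abort_input("degenerate composition: purine transitions observed but freq_A * freq_G = 0")
  }
  if (gT * gC > 0) {
    k2 <- 2 * gT * gC / gY
    w2 <- 1 - P2 * gY / (2 * gT * gC) - Q / (2 * gY)
    if (w2 <= 0) {
      return(tibble::tibble(distance = NA_real_, flag = "saturated"))
    }
    d <- d - k2 * log(w2)
  } else if (P2 > 0) {
    abort_input("degenerate composition: pyrimidine transitions observed but freq_C * freq_T = 0")
  }
  if (gR > 0 && gY > 0) {
    k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (w3 <= 0) {
      return(tibble::tibble(distance = NA_real_, flag = "saturated"))
    }
    d <- d - k3 * log(w3)
  } else if (Q > 0) {
    abort_input("degenerate composition: transversions observed but g_R * g_Y = 0")
  }
  tibble::tibble(distance = d, flag = "ok")
}

# distance between two sequences under a named model
model_distance <- function(counts, model, comp = NULL) {
  switch(model,
    p = tibble::tibble(distance = counts$P1 + counts$P2 + counts$Q, flag = "ok"),
    jc = jc_distance(counts$P1 + counts$P2 + counts$Q),
    k2p = k2p_distance(counts$P1 + counts$P2, counts$Q),
    tn93 = trn_distance(counts, comp),
    abort_config(paste0("unknown distance model '", model, "'"))
  )
}

#' Pairwise distance matrix over haplotypes
#'
#' Symmetric, zero-diagonal matrix of corrected genetic distances. Pairs for
#' which the correction is undefined are flagged `"saturated"` (value `NA`)
#' rather than aborting; downstream consumers such as [build_nj_tree()]
#' refuse saturated input explicitly.
#'
#' @param x An `skt_haplotypes` table or `skt_alignment`.
#' @param model One of `"tn93"` (default), `"p"`, `"jc"`, `"k2p"`.
#' @param composition_scope For `tn93`: `"pooled"` (one composition for the
#'   whole set, the default) or `"per-pair"` (composition recomputed from
#'   each pair of sequences).
#' @param deletion `"pairwise"` (default) excludes gap/ambiguous sites per
#'   pair; `"complete"` drops such columns once for the whole set.
#' @return An object of class `skt_dist`: list with `labels`, `values`
#'   (numeric matrix), `flags` (character matrix) and `model`.
#' @export
distance_matrix <- function(x, model = c("tn93", "p", "jc", "k2p"),
                            composition_scope = c("pooled", "per-pair"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  composition_scope <- match.arg(composition_scope)
  deletion <- match.arg(deletion)
  aln <- as_labelled_alignment(x)
  if (nrow(aln) < 2) {
    abort_input("distance matrix needs at least two haplotypes")
  }
  if (deletion == "complete") {
    m <- seq_matrix(aln)
    keep <- !apply(m, 2, function(col) any(!col %in% DNA_BASES))
    if (!any(keep)) abort_input("complete deletion removed every site")
    aln <- alignment(aln$id, apply(m[, keep, drop = FALSE], 1, paste0,
                                   collapse = ""))
  }
  n <- nrow(aln)
  labels <- aln$id
  comp_pooled <- if (model == "tn93") base_composition(aln) else NULL
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  flags <- matrix("ok", n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      counts <- count_site_patterns(aln$seq[[i]], aln$seq[[j]])
      comp <- comp_pooled
      if (model == "tn93" && composition_scope == "per-pair") {
        comp <- base_composition(alignment(c("a", "b"),
                                           c(aln$seq[[i]], aln$seq[[j]])))
      }
      res <- model_distance(counts, model, comp)
      values[i, j] <- values[j, i] <- res$distance[[1]]
      flags[i, j] <- flags[j, i] <- res$flag[[1]]
    }
  }
  structure(
    list(labels = labels, values = values, flags = flags, model = model),
    class = "skt_dist"
  )
}

#' Wrap a plain numeric matrix as a distance matrix object
#'
#' @param m Symmetric numeric matrix with row/column names.
#' @param model Label recorded for provenance (default `"user"`).
#' @return An `skt_dist` object.
#' @export
as_dist_matrix <- function(m, model = "user") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  }
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12) {
    abort_input("`m` must be a symmetric square matrix")
  }
  structure(
    list(labels = rownames(m), values = m,
         flags = matrix("ok", nrow(m), ncol(m),
                        dimnames = dimnames(m)),
         model = model),
    class = "skt_dist"
  )
}

#' @export
print.skt_dist <- function(x, ...) {
  cat("<skt_dist> ", length(x$labels), " labels, model ", x$model,
      ", ", sum(x$flags[upper.tri(x$flags)] == "saturated"),
      " saturated pair(s)\n", sep = "")
  print(round(x$values, 6))
  invisible(x)
}

#' Write a distance matrix as square tab-delimited text
#'
#' Header row of labels, then one row per label with the label in the first
#' column. Saturated cells are written as `NA`.
#'
#' @param dm An `skt_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(label = dm$labels, dm$values, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a distance matrix from delimited text
#'
#' Accepts the square tab-delimited format written by
#' [write_distance_matrix()] and PHYLIP-style square matrices (first line a
#' taxon count).
#'
#' @param path Input path.
#' @return An `skt_dist` with flags reconstructed from `NA` cells.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  first <- readLines(path, n = 1)
  if (grepl("^\\s*\\d+\\s*$", first)) {
    n <- as.integer(trimws(first))
    body <- utils::read.table(path, skip = 1, header = FALSE,
                              stringsAsFactors = FALSE)
    labels <- as.character(body[[1]])
    m <- as.matrix(body[, -1, drop = FALSE])
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    labels <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  flags <- ifelse(is.na(m), "saturated", "ok")
  diag(flags) <- "ok"
  structure(list(labels = labels, values = m, flags = flags, model = "file"),
            class = "skt_dist")
}

#' @method tidy skt_dist
#' @export
tidy.skt_dist <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    item1 = x$labels[idx[, 1]],
    item2 = x$labels[idx[, 2]],
    distance = x$values[idx],
    flag = x$flags[idx]
  )
}
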