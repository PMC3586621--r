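#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the rate-corrected Q criterion
#' \eqn{Q_{ij} = (m - 2) d_{ij} - R_i - R_j}. Ties in the Q minimisation are
#' broken by the lexicographically smallest (row, column) pair in current
#' matrix order, so the result is deterministic for a fixed input matrix.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the adjacent branch of the same join; the raw (unclamped) lengths are
#' retained in the `"raw_lengths"` attribute. Saturated pairs are refused
#' with an error listing the offending pairs, because silently substituting
#' an arbitrary large distance would corrupt the tree.
#'
#' @param dm An `skt_dist` with at least three labels and no saturated pairs.
#' @return An unrooted `ape::phylo` tree (basal trichotomy; internal nodes
#'   of degree three) with branch lengths in substitutions/site.
#' @examples
#' m <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' build_nj_tree(as_dist_matrix(m))
#' @export
build_nj_tree <- function(dm) {
  if (!inherits(dm, "skt_dist")) abort_input("`dm` must be an skt_dist")
  n <- length(dm$labels)
  if (n < 3) abort_input("neighbour joining needs at least 3 labels")
  sat <- which(dm$flags == "saturated" & upper.tri(dm$flags), arr.ind = TRUE)
  if (nrow(sat) > 0) {
    pairs <- paste0(dm$labels[sat[, 1]], "-", dm$labels[sat[, 2]])
    abort_saturation(
      paste0("distance matrix contains saturated pair(s): ",
             paste(pairs, collapse = ", ")),
      pairs = pairs
    )
  }
  bad <- dm$labels[grepl("[();,:'\\s\"]", dm$labels, perl = TRUE)]
  if (length(bad) > 0) {
    abort_input(paste0("labels contain newick-reserved characters: ",
                       paste(bad, collapse = ", ")))
  }

  M <- dm$values
  frag <- dm$labels
  raw <- list()
  fmt <- function(x) sprintf("%.12g", x)

  clamp_pair <- function(bi, bj) {
    ri <- bi; rj <- bj
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    list(bi = bi, bj = bj, raw_i = ri, raw_j = rj)
  }

  while (length(frag) > 3) {
    m <- length(frag)
    R <- rowSums(M)
    best_i <- 1L; best_j <- 2L
    best_q <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        q <- (m - 2) * M[i, j] - R[i] - R[j]
        if (q < best_q) {
          best_q <- q; best_i <- i; best_j <- j
        }
      }
    }
    i <- best_i; j <- best_j
    bi <- 0.5 * M[i, j] + (R[i] - R[j]) / (2 * (m - 2))
    bj <- M[i, j] - bi
    cl <- clamp_pair(bi, bj)
    raw[[length(raw) + 1]] <- tibble::tibble(
      step = length(raw) + 1L, member = c(frag[i], frag[j]),
      raw_length = c(cl$raw_i, cl$raw_j), length = c(cl$bi, cl$bj)
    )
    new_frag <- paste0("(", frag[i], ":", fmt(cl$bi), ",",
                       frag[j], ":", fmt(cl$bj), ")")
    others <- setdiff(seq_len(m), c(i, j))
    d_new <- 0.5 * (M[i, others] + M[j, others] - M[i, j])
    M <- rbind(cbind(M[others, others, drop = FALSE], d_new),
               c(d_new, 0))
    frag <- c(frag[others], new_frag)
  }

  # final three-way join closes the unrooted tree
  a <- 0.5 * (M[1, 2] + M[1, 3] - M[2, 3])
  b <- 0.5 * (M[1, 2] + M[2, 3] - M[1, 3])
  c3 <- 0.5 * (M[1, 3] + M[2, 3] - M[1, 2])
  lens <- c(a, b, c3)
  raw_final <- lens
  if (any(lens < 0)) {
    for (k in which(lens < 0)) {
      deficit <- lens[k]
      lens[k] <- 0
      donor <- setdiff(order(lens, decreasing = TRUE), k)[1]
      lens[donor] <- max(lens[donor] + deficit, 0)
    }
  }
  raw[[length(raw) + 1]] <- tibble::tibble(
    step = length(raw) + 1L, member = frag,
    raw_length = raw_final, length = lens
  )
  nwk <- paste0("(", frag[1], ":", fmt(lens[1]), ",",
                frag[2], ":", fmt(lens[2]), ",",
                frag[3], ":", fmt(lens[3]), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "raw_lengths") <- dplyr::bind_rows(raw)
  tree
}

#' Write a tree as newick text
#'
#' @param tree An `ape::phylo` tree.
#' @param precision Number of significant digits for branch lengths
#'   (default 6).
#' @return A newick string with trailing semicolon.
#' @export
to_newick <- function(tree, precision = 6) {
  ape::write.tree(tree, digits = precision)
}

#' Parse newick text into a tree
#'
#' @param text A newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1
    if (chars[pos] == ")") {
      depth <- depth - 1
      if (depth < 0) {
        abort_parse(paste0("unbalanced ')' at position ", pos))
      }
    }
  }
  if (depth != 0) {
    abort_parse(paste0("unbalanced '(' (", depth,
                       " unclosed) by position ", length(chars)))
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) abort_parse(paste0("cannot parse newick: ",
                                           conditionMessage(e)))
  )
  if (is.null(tree)) abort_parse("cannot parse newick text")
  tree
}

#' Per-clade monophyly report
#'
#' For each clade label, reports whether its leaves form a connected subtree
#' excluding all other clades, i.e. whether the leaf set (or its complement)
#' is a bipartition of the unrooted tree. Single leaves and the full leaf
#' set are trivially monophyletic.
#'
#' @param tree An `ape::phylo` tree.
#' @param clades A data frame with columns `label` and `clade`, or a named
#'   character vector (names = leaf labels, values = clades). Every leaf
#'   must be labelled.
#' @return A tibble with columns `clade`, `n_leaves`, `monophyletic`.
#' @export
leaf_clusters <- function(tree, clades) {
  if (is.data.frame(clades)) {
    map <- setNames(as.character(clades$clade), clades$label)
  } else {
    map <- setNames(as.character(clades), names(clades))
  }
  missing <- setdiff(tree$tip.label, names(map))
  if (length(missing) > 0) {
    abort_input(paste0("no clade label for leaf/leaves: ",
                       paste(missing, collapse = ", ")))
  }
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  splits <- lapply(parts, as.integer)
  tip_clade <- map[tree$tip.label]
  out <- purrr::map_dfr(unique(unname(tip_clade)), function(cl) {
    idx <- which(tip_clade == cl)
    mono <- length(idx) %in% c(1L, n) ||
      any(vapply(splits, function(s) {
        setequal(s, idx) || setequal(s, setdiff(seq_len(n), idx))
      }, logical(1)))
    tibble::tibble(clade = cl, n_leaves = length(idx), monophyletic = mono)
  })
  out
}
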