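# shared fixture builders: everything is generated in code, nothing binary

rand_seq <- function(L, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(freqs), L, replace = TRUE, prob = freqs), collapse = "")
}

# replace the characters at `sites` with `to` (recycled)
mutate_at <- function(seq, sites, to) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[sites] <- rep_len(to, length(sites))
  paste(chars, collapse = "")
}

# substitute each site with a different base than the current one
mutate_random <- function(seq, sites) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (s in sites) {
    chars[[s]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[s]]), 1)
  }
  paste(chars, collapse = "")
}

# hand-built panel: three clades separated by disjoint 20-site blocks
# (pairwise clade divergence 40/L), localities one extra substitution apart,
# six established haplotypes within one substitution of the source founder
make_test_panel <- function(L = 1000, seed = 42) {
  set.seed(seed)
  root <- rand_seq(L)
  clade_anc <- lapply(1:3, function(i) {
    sites <- ((i - 1) * 25 + 1):((i - 1) * 25 + 20)
    mutate_random(root, sites)
  })
  native <- list()
  founders <- list()
  k <- 0
  for (i in 1:3) {
    for (j in 1:2) {
      founder <- mutate_random(clade_anc[[i]], 200 + 10 * (j - 1) + i)
      k <- k + 1
      native[[k]] <- tibble::tibble(
        label = sprintf("REF%02d", k), seq = founder,
        locality = sprintf("Clade%d-Loc%d", i, j),
        clade = sprintf("clade%d", i)
      )
      if (i == 1 && j == 1) founders$source <- founder
    }
  }
  est <- c(founders$source,
           vapply(1:5, function(k) {
             mutate_random(founders$source, 280 + k)
           }, character(1)))
  reference_panel(
    native = dplyr::bind_rows(native),
    established = tibble::tibble(label = sprintf("EST%02d", 1:6), seq = est),
    established_localities = c("Range-A", "Range-B"),
    source_region_label = "Clade1-Loc1"
  )
}

# TN93 oracle: expected transition/transversion proportions at divergence t
# from the matrix exponential of the scaled rate matrix (independent of the
# closed-form inversion under test)
tn93_expected <- function(freqs, a1, a2, b, t) {
  bases <- c("A", "C", "G", "T")
  rate <- function(i, j) {
    pr <- sort(c(i, j))
    if (identical(pr, c("A", "G"))) return(a1)
    if (identical(pr, c("C", "T"))) return(a2)
    b
  }
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) {
    if (i != j) Q[i, j] <- rate(i, j) * freqs[[j]]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs[bases] * diag(Q))
  P <- as.matrix(Matrix::expm(Q / mu * t))
  prop <- function(i, j) freqs[[i]] * P[i, j] + freqs[[j]] * P[j, i]
  tv <- prop("A", "C") + prop("A", "T") + prop("C", "G") + prop("G", "T")
  list(
    counts = tibble::tibble(P1 = prop("A", "G"), P2 = prop("C", "T"),
                            Q = tv, compared_sites = 10000L),
    comp = tibble::tibble(freq_A = freqs[["A"]], freq_C = freqs[["C"]],
                          freq_G = freqs[["G"]], freq_T = freqs[["T"]],
                          g_R = freqs[["A"]] + freqs[["G"]],
                          g_Y = freqs[["C"]] + freqs[["T"]],
                          counted_sites = 10000L)
  )
}

# random draw of an unsaturated TN93 regime (composition, rates, divergence)
random_tn93_case <- function() {
  f <- runif(4, 0.5, 1.5)
  f <- f / sum(f)
  names(f) <- c("A", "C", "G", "T")
  list(freqs = f,
       a1 = runif(1, 2, 20), a2 = runif(1, 2, 20), b = 1,
       t = runif(1, 0.01, 0.5))
}

# random unrooted binary tree with additive metric
random_additive_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  tr
}

# tip-to-tip path-length matrix in a fixed label order
path_dists <- function(tree, labels = sort(tree$tip.label)) {
  m <- ape::cophenetic.phylo(tree)
  m[labels, labels]
}

cli_script <- function() {
  system.file("cli", "skinktrace.R", package = "skinktrace")
}

rscript_bin <- function() {
  file.path(R.home("bin"), "Rscript")
}

# view a haplotype table as an alignment of its representative sequences
haplotype_alignment_for_test <- function(h) {
  alignment(h$label, h$seq)
}
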