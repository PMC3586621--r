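test_that("base composition matches a brute-force character tally", {
  expect_equal(base_composition(alignment("s", "ACGT"))$freq_A, 0.25)
  two <- base_composition(alignment(c("a", "b"), c("AAAA", "GGGG")))
  expect_equal(two$freq_A, 0.5)
  expect_equal(two$freq_G, 0.5)
  expect_equal(two$freq_C, 0)

  set.seed(31)
  aln <- alignment(sprintf("s%03d", 1:100),
                   replicate(100, rand_seq(50, c(A = .4, C = .3, G = .2, T = .1))))
  comp <- base_composition(aln)
  tally <- table(factor(unlist(strsplit(aln$seq, "")), levels = c("A", "C", "G", "T")))
  expect_equal(c(comp$freq_A, comp$freq_C, comp$freq_G, comp$freq_T),
               as.numeric(tally / sum(tally)))
  expect_equal(comp$g_R + comp$g_Y, 1)
  expect_equal(comp$counted_sites, 100L * 50L)

  expect_error(base_composition(alignment("gap", "----")),
               class = "skt_error_input")
})

test_that("composition homogeneity test matches a hand-built contingency oracle", {
  # identical sequences: exact homogeneity
  aln <- alignment(paste0("s", 1:5), rep("ACGTACGT", 5))
  res <- composition_homogeneity_test(aln)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 3 * 4)

  # df formula: N = 195 sequences gives df = 582
  set.seed(8)
  big <- alignment(sprintf("q%03d", 1:195), replicate(195, rand_seq(20)))
  expect_equal(composition_homogeneity_test(big)$df, 582)

  # statistic equals stats::chisq.test on the 5 x 4 count table
  set.seed(9)
  aln <- alignment(paste0("r", 1:5), replicate(5, rand_seq(60)))
  counts <- t(sapply(strsplit(aln$seq, ""), function(ch) {
    table(factor(ch, levels = c("A", "C", "G", "T")))
  }))
  oracle <- suppressWarnings(stats::chisq.test(counts))
  mine <- composition_homogeneity_test(aln)
  expect_equal(mine$statistic, unname(oracle$statistic))
  expect_equal(mine$df, unname(oracle$parameter))
  expect_equal(mine$p_value, unname(oracle$p.value))

  # invariant under sequence reordering
  expect_equal(composition_homogeneity_test(aln[c(3, 1, 5, 2, 4), ])$statistic,
               mine$statistic)
})

test_that("site-pattern counting classifies columns like a per-column oracle", {
  same <- count_site_patterns("ACGTACGT", "ACGTACGT")
  expect_equal(c(same$P1, same$P2, same$Q), c(0, 0, 0))

  one <- count_site_patterns("AG", "GG")
  expect_equal(one$P1, 0.5)
  expect_equal(one$Q, 0)
  expect_equal(one$compared_sites, 2L)

  # columns: A/G transition, C/T transition, G/G, T/T; gap and N excluded
  mixed <- count_site_patterns("ACGT-N", "GTGTAC")
  expect_equal(mixed$compared_sites, 4L)
  expect_equal(mixed$P1, 0.25)
  expect_equal(mixed$P2, 0.25)
  expect_equal(mixed$Q, 0)

  # random case against an exhaustive per-column classification
  set.seed(12)
  a <- rand_seq(200)
  b <- mutate_random(a, sample(200, 40))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  is_ts <- function(x, y) paste0(pmin(x, y), pmax(x, y)) %in% c("AG", "CT")
  diff <- ca != cb
  oracle_p1 <- sum(diff & paste0(pmin(ca, cb), pmax(ca, cb)) == "AG") / 200
  oracle_p2 <- sum(diff & paste0(pmin(ca, cb), pmax(ca, cb)) == "CT") / 200
  oracle_q <- sum(diff & !is_ts(ca, cb)) / 200
  got <- count_site_patterns(a, b)
  expect_equal(c(got$P1, got$P2, got$Q), c(oracle_p1, oracle_p2, oracle_q))

  expect_error(count_site_patterns("AC", "ACG"), class = "skt_error_alignment")
  expect_error(count_site_patterns("NN", "AC"), class = "skt_error_input")
})

test_that("JC and K2P closed forms evaluate correctly and flag saturation", {
  expect_equal(jc_distance(0)$distance, 0)
  expect_equal(k2p_distance(0, 0)$distance, 0)
  expect_equal(jc_distance(0.3)$distance, -0.75 * log(1 - 0.4))
  expect_equal(jc_distance(0.8)$flag, "saturated")
  expect_equal(k2p_distance(0.45, 0.2)$flag, "saturated")
})

test_that("TN93 reduces to K2P under uniform composition and inverts the model", {
  uniform <- tibble::tibble(freq_A = .25, freq_C = .25, freq_G = .25,
                            freq_T = .25, g_R = .5, g_Y = .5,
                            counted_sites = 1000L)
  cts <- tibble::tibble(P1 = 0.05, P2 = 0.05, Q = 0.06, compared_sites = 1000L)
  expect_equal(trn_distance(cts, uniform)$distance,
               k2p_distance(0.10, 0.06)$distance, tolerance = 1e-13)

  zero <- tibble::tibble(P1 = 0, P2 = 0, Q = 0, compared_sites = 10L)
  expect_equal(trn_distance(zero, uniform)$distance, 0)

  # w3 <= 0 marks the saturation boundary
  sat <- tibble::tibble(P1 = 0, P2 = 0, Q = 0.6, compared_sites = 10L)
  expect_equal(trn_distance(sat, uniform)$flag, "saturated")

  # matrix-exponential oracle: distance recovers the generating divergence
  set.seed(21)
  errs <- replicate(30, {
    cs <- random_tn93_case()
    e <- tn93_expected(cs$freqs, cs$a1, cs$a2, cs$b, cs$t)
    abs(trn_distance(e$counts, e$comp)$distance - cs$t)
  })
  expect_lt(max(errs), 1e-9)
})

test_that("correction never shrinks the observed distance", {
  set.seed(23)
  for (i in 1:25) {
    a <- rand_seq(300, c(A = .326, C = .310, G = .120, T = .244))
    b <- mutate_random(a, sample(300, sample(5:60, 1)))
    cts <- count_site_patterns(a, b)
    comp <- base_composition(alignment(c("a", "b"), c(a, b)))
    d <- trn_distance(cts, comp)
    if (d$flag == "ok") {
      expect_gte(d$distance, cts$P1 + cts$P2 + cts$Q)
    }
  }
})

test_that("distance matrix is symmetric, zero-diagonal and pairwise-consistent", {
  set.seed(25)
  base <- rand_seq(400)
  seqs <- c(base, vapply(1:4, function(i) mutate_random(base, sample(400, 15 * i)),
                         character(1)))
  haps <- collapse_haplotypes(alignment(paste0("h", 1:5), seqs), "H")
  dm <- distance_matrix(haps, model = "tn93")
  expect_equal(dm$values, t(dm$values))
  expect_equal(unname(diag(dm$values)), rep(0, 5))

  # every cell equals a per-pair recomputation through the scalar path
  comp <- base_composition(alignment(paste0("h", 1:5), seqs))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      cts <- count_site_patterns(seqs[[i]], seqs[[j]])
      expect_equal(dm$values[i, j], trn_distance(cts, comp)$distance)
    }
  }

  # identical sequences under distinct labels give zero off-diagonal
  dup <- distance_matrix(alignment(c("u", "v"), c(base, base)), model = "p")
  expect_equal(dup$values["u", "v"], 0)
})

test_that("TN93 distances agree with an independent implementation", {
  set.seed(26)
  base <- rand_seq(600, c(A = .3, C = .3, G = .2, T = .2))
  seqs <- c(base, vapply(1:5, function(i) mutate_random(base, sample(600, 10 * i)),
                         character(1)))
  aln <- alignment(paste0("s", 1:6), seqs)
  dm <- distance_matrix(aln, model = "tn93")
  bin <- ape::as.DNAbin(t(vapply(strsplit(tolower(aln$seq), ""), identity,
                                 character(600))))
  rownames(bin) <- aln$id
  ref <- as.matrix(ape::dist.dna(bin, model = "TN93"))
  expect_lt(max(abs(dm$values - ref[dm$labels, dm$labels])), 1e-12)
})

test_that("distance matrices round-trip through delimited text", {
  set.seed(27)
  base <- rand_seq(200)
  aln <- alignment(c("A", "B", "C"),
                   c(base, mutate_random(base, 1:10), mutate_random(base, 20:35)))
  dm <- distance_matrix(aln, model = "k2p")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, path)
  back <- read_distance_matrix(path)
  expect_equal(back$labels, dm$labels)
  expect_equal(back$values, dm$values)

  # PHYLIP-style square format is also accepted
  phy <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("3", paste("A", paste(dm$values[1, ], collapse = " ")),
               paste("B", paste(dm$values[2, ], collapse = " ")),
               paste("C", paste(dm$values[3, ], collapse = " "))), phy)
  back2 <- read_distance_matrix(phy)
  expect_equal(back2$values, dm$values, tolerance = 1e-12)
})

test_that("site summary matches exhaustive column classification", {
  aln <- alignment(paste0("s", 1:4), rep("ACGTACGT", 4))
  ss <- site_summary(aln)
  expect_equal(ss$variable_sites, 0L)
  expect_equal(ss$parsimony_informative_sites, 0L)

  # column patterns AAAT (variable, not informative) and AATT (informative)
  aln <- alignment(paste0("s", 1:4), c("AA", "AA", "AT", "TT"))
  ss <- site_summary(aln)
  expect_equal(ss$variable_sites, 2L)
  expect_equal(ss$parsimony_informative_sites, 1L)

  set.seed(29)
  m <- matrix(sample(c("A", "C", "G", "T", "N"), 10 * 50, replace = TRUE,
                     prob = c(.24, .24, .24, .24, .04)), 10, 50)
  aln <- alignment(paste0("s", 1:10), apply(m, 1, paste0, collapse = ""))
  ss <- site_summary(aln)
  oracle <- apply(m, 2, function(col) {
    counts <- table(col[col %in% c("A", "C", "G", "T")])
    c(sum(counts > 0) >= 2, sum(counts >= 2) >= 2)
  })
  expect_equal(ss$variable_sites, sum(oracle[1, ]))
  expect_equal(ss$parsimony_informative_sites, sum(oracle[2, ]))
  expect_lte(ss$parsimony_informative_sites, ss$variable_sites)
})
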