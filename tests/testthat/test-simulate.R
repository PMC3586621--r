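test_that("the simulator is deterministic per seed", {
  cfg <- simulation_config(seed = 7, n_clades = 3, seq_length = 400)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$native, p2$native)
  expect_identical(p1$established, p2$established)
  d1 <- simulate_detections(p1, cfg)
  d2 <- simulate_detections(p2, cfg)
  expect_identical(d1, d2)

  other <- simulate_reference_panel(simulation_config(seed = 8, n_clades = 3,
                                                      seq_length = 400))
  expect_false(identical(p1$native$seq, other$native$seq))
})

test_that("simulated panels respect the configured divergence bands", {
  cfg <- simulation_config(seed = 13, n_clades = 5, localities_per_clade = 2,
                           seq_length = 800)
  panel <- simulate_reference_panel(cfg)
  expect_false(any(duplicated(panel$native$seq)))
  expect_false(any(duplicated(panel$established$seq)))

  dm <- distance_matrix(tibble::tibble(label = panel$native$label,
                                       seq = panel$native$seq), model = "tn93")
  td <- tidy(dm)
  clade_of <- setNames(panel$native$clade, panel$native$label)
  between <- td[clade_of[td$item1] != clade_of[td$item2], ]
  within <- td[clade_of[td$item1] == clade_of[td$item2], ]
  # 20% sampling slack around the configured bands
  expect_true(all(between$distance >= cfg$inter_clade_range[1] * 0.8))
  expect_true(all(between$distance <= cfg$inter_clade_range[2] * 1.2))
  expect_true(all(within$distance <= cfg$intra_region_range[2] * 2 * 1.2))

  # established haplotypes sit within the intra-region band of each other
  dme <- distance_matrix(tibble::tibble(label = panel$established$label,
                                        seq = panel$established$seq),
                         model = "p")
  expect_true(all(tidy(dme)$distance <= cfg$intra_region_range[2]))
})

test_that("generated alignments pass sequence validation and degenerate configs work", {
  cfg <- simulation_config(seed = 3, n_clades = 1, localities_per_clade = 4,
                           seq_length = 500)
  panel <- simulate_reference_panel(cfg)
  aln <- alignment(panel$native$label, panel$native$seq)  # validates
  expect_equal(n_sites(aln), 500)
  expect_equal(unique(panel$native$clade), "clade1")

  expect_error(simulation_config(seed = 1, inter_clade_range = c(0.9, 1.2)),
               class = "skt_error_config")
  expect_error(simulation_config(seed = 1, detection_mix = c(local = 1)),
               class = "skt_error_config")
  expect_error(simulation_config(seed = 1, base_freqs = c(A = 1, C = 0,
                                                          G = 0, T = 0)),
               class = "skt_error_config")
})

test_that("detection batches carry correct bookkeeping", {
  cfg <- simulation_config(seed = 17, n_clades = 3, seq_length = 400,
                           detection_mix = c(local = 5, movement = 5,
                                             arrival = 5))
  panel <- simulate_reference_panel(cfg)
  det <- simulate_detections(panel, cfg)
  expect_equal(nrow(det), 15)
  expect_equal(unname(table(det$true_category)[c("local-resident",
                                                 "new-arrival",
                                                 "within-country-movement")]),
               c(5L, 5L, 5L), ignore_attr = TRUE)
  expect_true(all(det$locality[det$true_category == "local-resident"] %in%
                    panel$established_localities))
  expect_false(any(det$locality[det$true_category == "within-country-movement"] %in%
                     panel$established_localities))

  none <- simulate_detections(panel, simulation_config(
    seed = 17, n_clades = 3, seq_length = 400,
    detection_mix = c(local = 0, movement = 0, arrival = 0)))
  expect_equal(nrow(none), 0)
})

test_that("zero prediction error yields perfect recorded predictions; half does not", {
  cfg0 <- simulation_config(seed = 23, n_clades = 4, seq_length = 400,
                            detection_mix = c(local = 0, movement = 0,
                                              arrival = 30),
                            prediction_error_rate = 0)
  panel <- simulate_reference_panel(cfg0)
  det <- simulate_detections(panel, cfg0)
  expect_true(all(det$predicted_origin == det$true_source))

  cfg5 <- simulation_config(seed = 23, n_clades = 4, seq_length = 400,
                            detection_mix = c(local = 0, movement = 0,
                                              arrival = 200),
                            prediction_error_rate = 0.5)
  det5 <- simulate_detections(simulate_reference_panel(cfg5), cfg5)
  hits <- sum(det5$predicted_origin == det5$true_source)
  # binomial 99% interval for p = 0.5, n = 200: roughly [82, 118]
  bounds <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(hits, bounds[[1]])
  expect_lte(hits, bounds[[2]])
})

test_that("recovery experiments are perfect in the separated regime and degrade past it", {
  cfg <- simulation_config(seed = 29, n_clades = 4, localities_per_clade = 2,
                           seq_length = 600,
                           detection_mix = c(local = 10, movement = 10,
                                             arrival = 20))
  rec <- recovery_experiment(cfg)
  expect_equal(glance(rec)$category_accuracy, 1)
  expect_equal(glance(rec)$source_accuracy, 1)
  conf <- tidy(rec)
  expect_true(all(conf$true_category == conf$category))

  # intra-region variation beyond close_tol breaks tier-2 containment
  wide <- simulation_config(seed = 29, n_clades = 4, localities_per_clade = 2,
                            seq_length = 600,
                            intra_region_range = c(0.01, 0.015),
                            detection_mix = c(local = 20, movement = 0,
                                              arrival = 0))
  # established set now spreads wider than close_tol: simulate queries from
  # the same source region that straddle the boundary
  panel_w <- simulate_reference_panel(wide)
  straddle <- mutate_random(panel_w$established$seq[[1]],
                            sample(600, 6))  # ~1% away
  res <- classify_detection(straddle, "NZ-Range-1", panel_w)
  expect_equal(res$category, "new-arrival")

  # zero detections: empty confusion matrix
  none <- recovery_experiment(simulation_config(
    seed = 29, n_clades = 3, seq_length = 400,
    detection_mix = c(local = 0, movement = 0, arrival = 0)))
  expect_equal(nrow(tidy(none)), 0)
  expect_equal(glance(none)$n, 0L)
})
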