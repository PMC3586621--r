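#' Simulation configuration
#'
#' Defines the statistical structure the assignment pipeline assumes: a
#' native range partitioned into geographically non-overlapping clades with
#' inter-clade corrected divergence in `inter_clade_range` (default
#' 1.8-8.3\%), within-region divergence in `intra_region_range` (default
#' 0-0.3\%), an established-population haplotype subset drawn from one
#' source clade, and detection batches of the three true categories.
#' Defaults mirror the empirical mitochondrial alignment: 1221 bp, nine
#' clades, six established haplotypes and base frequencies
#' A = 0.326, C = 0.310, G = 0.120, T = 0.244, with purine/pyrimidine
#' transition biases typical of skink mtDNA.
#'
#' @param seed Integer seed; every simulator function derives its
#'   randomness from it.
#' @param seq_length Alignment length in bp.
#' @param n_clades Number of native-range clades.
#' @param localities_per_clade Sampled localities per clade.
#' @param haplotypes_per_locality Haplotypes per locality.
#' @param n_established Haplotypes in the established invaded-range set.
#' @param established_clade Index of the clade acting as source region.
#' @param base_freqs Named vector of A/C/G/T frequencies (sums to 1).
#' @param kappa1,kappa2 Purine (A<->G) and pyrimidine (C<->T) transition
#'   rate multipliers relative to transversions.
#' @param inter_clade_range Target range of between-clade distances
#'   (substitutions/site).
#' @param intra_region_range Target range of within-region distances.
#' @param detection_mix Named counts `c(local = , movement = , arrival = )`.
#' @param prediction_error_rate Probability that a simulated recorded
#'   prediction names the wrong source locality.
#' @param n_established_localities,n_outside_localities Number of
#'   invaded-range locality names inside/outside the established range.
#' @return A list of class `skt_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              seq_length = 1221,
                              n_clades = 9,
                              localities_per_clade = 3,
                              haplotypes_per_locality = 1,
                              n_established = 6,
                              established_clade = 1,
                              base_freqs = c(A = 0.326, C = 0.310,
                                             G = 0.120, T = 0.244),
                              kappa1 = 8,
                              kappa2 = 4,
                              inter_clade_range = c(0.018, 0.083),
                              intra_region_range = c(0, 0.003),
                              detection_mix = c(local = 5, movement = 5,
                                                arrival = 5),
                              prediction_error_rate = 0,
                              n_established_localities = 3,
                              n_outside_localities = 3) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort_config("`seed` must be a single integer")
  }
  if (seq_length < 10) abort_config("`seq_length` too short")
  if (n_clades < 1) abort_config("`n_clades` must be >= 1")
  if (is.null(names(base_freqs)) ||
      !setequal(names(base_freqs), DNA_BASES) ||
      abs(sum(base_freqs) - 1) > 1e-8 || any(base_freqs <= 0)) {
    abort_config("`base_freqs` must be positive A/C/G/T frequencies summing to 1")
  }
  check_range <- function(r, nm) {
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      abort_config(paste0("`", nm, "` must be an ordered non-negative range"))
    }
  }
  check_range(inter_clade_range, "inter_clade_range")
  check_range(intra_region_range, "intra_region_range")
  if (inter_clade_range[2] > 0.6) {
    abort_config("`inter_clade_range` upper bound implies saturated distances")
  }
  if (is.null(detection_mix) || length(detection_mix) == 0) {
    abort_config("`detection_mix` must be a named count vector")
  }
  if (!all(c("local", "movement", "arrival") %in% names(detection_mix)) ||
      any(detection_mix < 0)) {
    abort_config("`detection_mix` needs non-negative counts named local, movement, arrival")
  }
  if (established_clade < 1 || established_clade > n_clades) {
    abort_config("`established_clade` out of range")
  }
  if (prediction_error_rate < 0 || prediction_error_rate > 1) {
    abort_config("`prediction_error_rate` must be in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), seq_length = as.integer(seq_length),
         n_clades = as.integer(n_clades),
         localities_per_clade = as.integer(localities_per_clade),
         haplotypes_per_locality = as.integer(haplotypes_per_locality),
         n_established = as.integer(n_established),
         established_clade = as.integer(established_clade),
         base_freqs = base_freqs[DNA_BASES],
         kappa1 = kappa1, kappa2 = kappa2,
         inter_clade_range = inter_clade_range,
         intra_region_range = intra_region_range,
         detection_mix = detection_mix,
         prediction_error_rate = prediction_error_rate,
         n_established_localities = as.integer(n_established_localities),
         n_outside_localities = as.integer(n_outside_localities)),
    class = "skt_sim_config"
  )
}

# one discrete substitution at each of `sites`, with replacement base drawn
# proportionally to TN93 rates away from the current base
mutate_sites <- function(chars, sites, freqs, kappa1, kappa2) {
  transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
  for (s in sites) {
    cur <- chars[[s]]
    others <- setdiff(DNA_BASES, cur)
    w <- freqs[others]
    partner <- transition_partner[[cur]]
    kap <- if (cur %in% c("A", "G")) kappa1 else kappa2
    w[partner] <- w[partner] * kap
    chars[[s]] <- sample(others, 1, prob = w)
  }
  chars
}

# child at exactly round(target * L) substituted sites relative to `parent`
evolve_to <- function(parent, target, cfg, min_mut = 0) {
  L <- cfg$seq_length
  n_mut <- max(min_mut, round(target * L))
  if (n_mut == 0) return(parent)
  if (n_mut > 0.7 * L) {
    abort_config("divergence target implies saturation; lower the range")
  }
  sites <- sample.int(L, n_mut)
  mutate_sites(parent, sites, cfg$base_freqs, cfg$kappa1, cfg$kappa2)
}

#' Simulate a clade-structured reference panel
#'
#' Draws a root sequence from the configured base composition, evolves one
#' ancestor per clade to a depth placing between-clade distances inside
#' `inter_clade_range`, then places locality founders and haplotypes within
#' `intra_region_range` of their clade ancestor. The established haplotype
#' set is drawn from the first locality of the source clade, each within
#' one substitution of the founder. All panel haplotypes are pairwise
#' distinct. Deterministic for a fixed seed.
#'
#' @param cfg An [simulation_config()].
#' @return An [reference_panel()] whose `native` table carries the true
#'   locality and clade of every haplotype; the out-of-range locality names
#'   are stored in the `"outside_localities"` attribute.
#' @export
simulate_reference_panel <- function(cfg) {
  if (!inherits(cfg, "skt_sim_config")) abort_config("`cfg` must be a simulation_config")
  with_seed(cfg$seed, {
    L <- cfg$seq_length
    lo_u <- 0.60 * cfg$inter_clade_range[1]
    hi_u <- 0.48 * cfg$inter_clade_range[2]
    if (round(hi_u * L) < 1) {
      abort_config("inter-clade range too small for this sequence length")
    }
    depths <- if (cfg$n_clades == 1) {
      mean(c(lo_u, hi_u))
    } else {
      seq(lo_u, hi_u, length.out = cfg$n_clades)
    }
    root <- sample(DNA_BASES, L, replace = TRUE, prob = cfg$base_freqs)
    max_intra_mut <- max(1, floor(cfg$intra_region_range[2] * L))
    seen <- character()
    draw_unique <- function(parent, n_mut_choices) {
      for (try in 1:50) {
        n_mut <- if (length(n_mut_choices) == 1) n_mut_choices
                 else sample(n_mut_choices, 1)
        child <- if (n_mut == 0) parent
                 else mutate_sites(parent, sample.int(L, n_mut),
                                   cfg$base_freqs, cfg$kappa1, cfg$kappa2)
        key <- paste(child, collapse = "")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          return(child)
        }
      }
      abort_config("could not draw a distinct haplotype; widen the ranges")
    }
    native <- list()
    counter <- 0
    established <- NULL
    source_label <- NULL
    for (ci in seq_len(cfg$n_clades)) {
      ancestor <- evolve_to(root, depths[[ci]], cfg, min_mut = 1)
      for (lj in seq_len(cfg$localities_per_clade)) {
        founder <- draw_unique(ancestor, seq_len(max_intra_mut))
        for (hk in seq_len(cfg$haplotypes_per_locality)) {
          hap <- if (hk == 1) founder else draw_unique(founder, 1)
          counter <- counter + 1
          native[[counter]] <- tibble::tibble(
            label = sprintf("REF%03d", counter),
            seq = paste(hap, collapse = ""),
            locality = sprintf("Clade%d-Loc%d", ci, lj),
            clade = sprintf("clade%d", ci)
          )
        }
        if (ci == cfg$established_clade && lj == 1) {
          est_sites <- sample.int(L, max(0, cfg$n_established - 1))
          est <- list(founder)
          for (k in seq_len(cfg$n_established - 1)) {
            est[[k + 1]] <- mutate_sites(founder, est_sites[[k]],
                                         cfg$base_freqs, cfg$kappa1,
                                         cfg$kappa2)
          }
          established <- tibble::tibble(
            label = sprintf("EST%02d", seq_len(cfg$n_established)),
            seq = vapply(est, paste, character(1), collapse = "")
          )
          source_label <- sprintf("Clade%d-Loc1", ci)
        }
      }
    }
    panel <- reference_panel(
      native = dplyr::bind_rows(native),
      established = established,
      established_localities = sprintf("NZ-Range-%d",
                                       seq_len(cfg$n_established_localities)),
      source_region_label = source_label
    )
    attr(panel, "outside_localities") <-
      sprintf("NZ-Beyond-%d", seq_len(cfg$n_outside_localities))
    attr(panel, "config") <- cfg
    panel
  })
}

#' Simulate a detection batch against a simulated panel
#'
#' Local residents carry established haplotypes at in-range localities;
#' within-country movements carry established haplotypes at out-of-range
#' localities; new arrivals carry native haplotypes from non-source clades
#' at any invaded-range locality. Simulated recorded predictions name the
#' true source locality, replaced by a wrong locality with probability
#' `prediction_error_rate`.
#'
#' @param panel A panel from [simulate_reference_panel()].
#' @param cfg The same [simulation_config()].
#' @return A tibble with `id`, `seq`, `locality`, `predicted_origin`,
#'   `true_category`, `true_source`.
#' @export
simulate_detections <- function(panel, cfg) {
  if (!inherits(cfg, "skt_sim_config")) abort_config("`cfg` must be a simulation_config")
  with_seed(cfg$seed + 1L, {
    in_range <- panel$established_localities
    out_range <- attr(panel, "outside_localities") %||% "Beyond-1"
    mix <- cfg$detection_mix
    arrivals_pool <- panel$native[panel$native$clade !=
                                    sprintf("clade%d", cfg$established_clade), ]
    if (mix[["arrival"]] > 0 && nrow(arrivals_pool) == 0) {
      abort_config("no non-source clades to draw new arrivals from")
    }
    sample_vec <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
    rows <- list()
    if (mix[["local"]] > 0) {
      k <- sample.int(nrow(panel$established), mix[["local"]], replace = TRUE)
      rows$local <- tibble::tibble(
        seq = panel$established$seq[k],
        locality = sample_vec(in_range, mix[["local"]]),
        true_category = "local-resident",
        true_source = NA_character_,
        predicted_origin = NA_character_
      )
    }
    if (mix[["movement"]] > 0) {
      k <- sample.int(nrow(panel$established), mix[["movement"]], replace = TRUE)
      rows$movement <- tibble::tibble(
        seq = panel$established$seq[k],
        locality = sample_vec(out_range, mix[["movement"]]),
        true_category = "within-country-movement",
        true_source = NA_character_,
        predicted_origin = NA_character_
      )
    }
    if (mix[["arrival"]] > 0) {
      k <- sample.int(nrow(arrivals_pool), mix[["arrival"]], replace = TRUE)
      truth <- arrivals_pool$locality[k]
      wrong <- stats::runif(mix[["arrival"]]) < cfg$prediction_error_rate
      all_locs <- unique(panel$native$locality)
      predicted <- truth
      for (i in which(wrong)) {
        predicted[[i]] <- sample(setdiff(all_locs, truth[[i]]), 1)
      }
      rows$arrival <- tibble::tibble(
        seq = arrivals_pool$seq[k],
        locality = sample_vec(c(in_range, out_range), mix[["arrival"]]),
        true_category = "new-arrival",
        true_source = truth,
        predicted_origin = predicted
      )
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0) {
      return(tibble::tibble(id = character(), seq = character(),
                            locality = character(),
                            predicted_origin = character(),
                            true_category = character(),
                            true_source = character()))
    }
    out$id <- sprintf("DET%03d", seq_len(nrow(out)))
    dplyr::select(out, "id", "seq", "locality", "predicted_origin",
                  "true_category", "true_source")
  })
}

#' Parameter-recovery experiment for the assignment cascade
#'
#' Simulates a panel and a detection batch, classifies the batch with
#' [batch_classify()], and reports the confusion matrix over true vs
#' inferred categories together with category and source-locality accuracy.
#' Per-row classification errors are carried through, never aborting the
#' experiment.
#'
#' @param cfg An [simulation_config()].
#' @param thresholds An [assignment_thresholds()].
#' @param model Distance model (default `"tn93"`).
#' @return A list of class `skt_recovery` with elements `confusion`
#'   (tibble of true vs inferred counts), `summary` (one-row tibble with
#'   `n`, `category_accuracy`, `source_accuracy`) and `results` (the full
#'   classification table with truth columns).
#' @export
recovery_experiment <- function(cfg, thresholds = assignment_thresholds(),
                                model = "tn93") {
  panel <- simulate_reference_panel(cfg)
  det <- simulate_detections(panel, cfg)
  if (nrow(det) == 0) {
    return(structure(
      list(confusion = tibble::tibble(true_category = character(),
                                      category = character(), n = integer()),
           summary = tibble::tibble(n = 0L, category_accuracy = NA_real_,
                                    source_accuracy = NA_real_),
           results = tibble::tibble()),
      class = "skt_recovery"
    ))
  }
  cls <- batch_classify(det, panel, thresholds = thresholds, model = model)
  res <- dplyr::bind_cols(
    cls,
    det[, c("true_category", "true_source")]
  )
  confusion <- dplyr::count(res, .data$true_category, .data$category)
  cat_acc <- mean(res$category == res$true_category, na.rm = FALSE)
  arr <- res[res$true_category == "new-arrival", ]
  src_acc <- if (nrow(arr) == 0) NA_real_ else {
    mean(vapply(seq_len(nrow(arr)), function(i) {
      !is.na(arr$inferred_source[[i]]) &&
        arr$true_source[[i]] %in%
          strsplit(arr$inferred_source[[i]], "|", fixed = TRUE)[[1]]
    }, logical(1)))
  }
  structure(
    list(confusion = confusion,
         summary = tibble::tibble(n = nrow(res),
                                  category_accuracy = cat_acc,
                                  source_accuracy = src_acc),
         results = res),
    class = "skt_recovery"
  )
}

#' @method glance skt_recovery
#' @export
glance.skt_recovery <- function(x, ...) {
  x$summary
}

#' @method tidy skt_recovery
#' @export
tidy.skt_recovery <- function(x, ...) {
  x$confusion
}

#' @export
print.skt_recovery <- function(x, ...) {
  cat("<skt_recovery> n =", x$summary$n, "\n")
  print(x$confusion)
  print(x$summary)
  invisible(x)
}
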