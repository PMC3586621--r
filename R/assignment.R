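#' Classification thresholds for the assignment cascade
#'
#' `identical_tol` bounds tier 1 (haplotype already known from the
#' established invaded-range populations); `close_tol` bounds tier 2
#' (previously undetected haplotype from the same source region, the
#' "closely related" band). Distances above `close_tol` are new arrivals.
#'
#' @param identical_tol Distance at or below which a query is treated as an
#'   established haplotype (default 0).
#' @param close_tol Distance at or below which a query is treated as a
#'   previously undetected source-region haplotype (default 0.003, i.e.
#'   0.3\% corrected divergence).
#' @return A list of class `skt_thresholds`.
#' @export
assignment_thresholds <- function(identical_tol = 0, close_tol = 0.003) {
  if (!is.numeric(identical_tol) || !is.numeric(close_tol) ||
      identical_tol < 0 || identical_tol > close_tol) {
    abort_config("need 0 <= identical_tol <= close_tol")
  }
  structure(list(identical_tol = identical_tol, close_tol = close_tol),
            class = "skt_thresholds")
}

#' Build a reference panel
#'
#' The panel couples the native-range haplotypes (with locality and clade
#' labels) with the haplotypes known from the established invaded-range
#' populations and the list of localities constituting the established
#' range.
#'
#' @param native Data frame with columns `label`, `seq`, `locality`, `clade`.
#' @param established Data frame with columns `label`, `seq`.
#' @param established_localities Character vector of locality names forming
#'   the established invaded range.
#' @param source_region_label Optional name of the native source region of
#'   the established populations.
#' @return A list of class `skt_panel`.
#' @export
reference_panel <- function(native, established, established_localities,
                            source_region_label = NULL) {
  need <- c("label", "seq", "locality", "clade")
  if (!all(need %in% names(native))) {
    abort_input(paste0("`native` needs columns: ", paste(need, collapse = ", ")))
  }
  if (!all(c("label", "seq") %in% names(established))) {
    abort_input("`established` needs columns label, seq")
  }
  if (length(established_localities) == 0) {
    abort_input("`established_localities` must be non-empty")
  }
  native <- tibble::as_tibble(native)
  established <- tibble::as_tibble(established)
  native$seq <- toupper(native$seq)
  established$seq <- toupper(established$seq)
  labs <- c(native$label, established$label)
  dup <- unique(labs[duplicated(labs)])
  if (length(dup) > 0) {
    abort_input(paste0("duplicate panel label(s): ", paste(dup, collapse = ", ")))
  }
  lens <- unique(nchar(c(native$seq, established$seq)))
  if (length(lens) != 1) {
    abort_alignment("panel sequences are not all the same length")
  }
  structure(
    list(native = native, established = established,
         established_localities = as.character(established_localities),
         source_region_label = source_region_label),
    class = "skt_panel"
  )
}

#' @export
print.skt_panel <- function(x, ...) {
  cat("<skt_panel> ", nrow(x$native), " native haplotypes (",
      length(unique(x$native$clade)), " clades, ",
      length(unique(x$native$locality)), " localities), ",
      nrow(x$established), " established haplotypes, ",
      length(x$established_localities), " established-range localities\n",
      sep = "")
  invisible(x)
}

# pooled base composition over all panel sequences
panel_composition <- function(panel) {
  base_composition(alignment(
    c(panel$native$label, panel$established$label),
    c(panel$native$seq, panel$established$seq)
  ))
}

# distance of a query to one reference sequence under a model
query_distance <- function(query, ref, model, comp) {
  counts <- count_site_patterns(query, ref)
  model_distance(counts, model, comp)
}

#' Rank native-range references by distance to a query
#'
#' @param query Query sequence (aligned to the panel length).
#' @param panel An [reference_panel()].
#' @param model Distance model (default `"tn93"` with the panel's pooled
#'   composition).
#' @return A tibble `label`, `locality`, `clade`, `distance`, `is_min`
#'   sorted ascending by distance (ties at the minimum all flagged
#'   `is_min`). Saturated references are dropped; if every reference is
#'   saturated the query is unassignable and an error is raised.
#' @export
nearest_reference <- function(query, panel, model = "tn93") {
  query <- toupper(as.character(query))
  if (nchar(query) != nchar(panel$native$seq[[1]])) {
    abort_alignment("query length does not match panel alignment length")
  }
  comp <- if (model == "tn93") panel_composition(panel) else NULL
  res <- purrr::map_dfr(seq_len(nrow(panel$native)), function(i) {
    d <- query_distance(query, panel$native$seq[[i]], model, comp)
    tibble::tibble(label = panel$native$label[[i]],
                   locality = panel$native$locality[[i]],
                   clade = panel$native$clade[[i]],
                   distance = d$distance[[1]], flag = d$flag[[1]])
  })
  ok <- res[res$flag == "ok", ]
  if (nrow(ok) == 0) {
    abort_saturation("query is saturated against every reference; unassignable")
  }
  ok <- dplyr::arrange(ok, .data$distance, .data$label)
  ok$is_min <- ok$distance <= min(ok$distance) + 1e-12
  ok$flag <- NULL
  ok
}

#' Classify one detection
#'
#' Decision cascade: (1) minimum distance to the established haplotype set
#' at or below `identical_tol` means the animal carries a known
#' invaded-range haplotype; (2) at or below `close_tol` means a previously
#' undetected haplotype from the same source region; in both cases the
#' animal is of local origin and is a `local-resident` if detected inside
#' the established range, otherwise a `within-country-movement` (jump
#' dispersal). (3) Anything more divergent is a `new-arrival`, whose source
#' is the locality (or tied localities) of the nearest native-range
#' haplotype.
#'
#' Because mitochondrial data cannot distinguish a resident from a fresh
#' arrival out of the same source region, tier 1/2 results carry the caveat
#' `local-or-same-source` rather than resolving the ambiguity.
#'
#' @param query Query sequence.
#' @param detection_locality Locality of the detection.
#' @param panel An [reference_panel()].
#' @param thresholds An [assignment_thresholds()].
#' @param model Distance model (default `"tn93"`).
#' @param known_localities Optional character vector of resolvable locality
#'   names outside the established range; when supplied, a locality in
#'   neither list raises a locality-resolution error.
#' @return A one-row tibble: `category`, `tier`, `matched_haplotypes`,
#'   `min_distance`, `inferred_source`, `ties`, `caveat`.
#' @export
classify_detection <- function(query, detection_locality, panel,
                               thresholds = assignment_thresholds(),
                               model = "tn93", known_localities = NULL) {
  query <- toupper(as.character(query))
  loc_norm <- norm_full(detection_locality)
  in_range <- loc_norm %in% norm_full(panel$established_localities)
  if (!in_range && !is.null(known_localities) &&
      !loc_norm %in% norm_full(known_localities)) {
    abort_locality(paste0("cannot resolve detection locality '",
                          detection_locality, "'"))
  }
  comp <- if (model == "tn93") panel_composition(panel) else NULL
  est <- purrr::map_dfr(seq_len(nrow(panel$established)), function(i) {
    d <- query_distance(query, panel$established$seq[[i]], model, comp)
    tibble::tibble(label = panel$established$label[[i]],
                   distance = ifelse(d$flag[[1]] == "ok", d$distance[[1]], Inf))
  })
  min_est <- min(est$distance)
  tier <- if (min_est <= thresholds$identical_tol) 1L
          else if (min_est <= thresholds$close_tol) 2L
          else 3L
  if (tier < 3L) {
    matched <- est$label[est$distance <= min_est + 1e-12]
    category <- if (in_range) "local-resident" else "within-country-movement"
    tibble::tibble(
      category = category,
      tier = tier,
      matched_haplotypes = paste(matched, collapse = "|"),
      min_distance = min_est,
      inferred_source = if (in_range) NA_character_ else "established-range",
      ties = NA_character_,
      caveat = "local-or-same-source"
    )
  } else {
    nr <- nearest_reference(query, panel, model = model)
    top <- nr[nr$is_min, ]
    tibble::tibble(
      category = "new-arrival",
      tier = 3L,
      matched_haplotypes = paste(top$label, collapse = "|"),
      min_distance = min(top$distance),
      inferred_source = paste(unique(top$locality), collapse = "|"),
      ties = if (nrow(top) > 1) paste(top$label, collapse = "|") else NA_character_,
      caveat = NA_character_
    )
  }
}

#' Classify a batch of detections
#'
#' Applies [classify_detection()] row by row; per-row errors are captured in
#' an `error` column and the batch continues. When the detections carry a
#' `predicted_origin` column and an equivalence table is supplied, new
#' arrivals are also scored against the prediction.
#'
#' @param detections Tibble with columns `id`, `seq`, `locality` and
#'   optionally `predicted_origin`.
#' @param panel An [reference_panel()].
#' @param thresholds An [assignment_thresholds()].
#' @param eq Optional [read_region_equivalence()] table for prediction
#'   scoring.
#' @param model Distance model.
#' @param known_localities Passed to [classify_detection()].
#' @return A tibble of class `skt_classification`, one row per detection.
#' @export
batch_classify <- function(detections, panel,
                           thresholds = assignment_thresholds(),
                           eq = NULL, model = "tn93",
                           known_localities = NULL) {
  need <- c("id", "seq", "locality")
  if (!all(need %in% names(detections))) {
    abort_input(paste0("`detections` needs columns: ",
                       paste(need, collapse = ", ")))
  }
  empty_row <- tibble::tibble(
    category = NA_character_, tier = NA_integer_,
    matched_haplotypes = NA_character_, min_distance = NA_real_,
    inferred_source = NA_character_, ties = NA_character_,
    caveat = NA_character_
  )
  rows <- purrr::map_dfr(seq_len(nrow(detections)), function(i) {
    res <- tryCatch(
      cbind(classify_detection(detections$seq[[i]], detections$locality[[i]],
                               panel, thresholds, model, known_localities),
            error = NA_character_),
      error = function(e) cbind(empty_row, error = conditionMessage(e))
    )
    tibble::as_tibble(cbind(
      tibble::tibble(id = detections$id[[i]],
                     locality = detections$locality[[i]]),
      res
    ))
  })
  if ("predicted_origin" %in% names(detections)) {
    rows$predicted_origin <- detections$predicted_origin
    rows$prediction_tier <- ifelse(
      rows$category == "new-arrival" & !is.na(rows$category),
      score_prediction(rows$predicted_origin, rows$inferred_source, eq),
      NA_character_
    )
  }
  class(rows) <- c("skt_classification", class(rows))
  attr(rows, "thresholds") <- thresholds
  attr(rows, "model") <- model
  rows
}

#' @method glance skt_classification
#' @export
glance.skt_classification <- function(x, ...) {
  ok <- x[is.na(x$error), ]
  tibble::tibble(
    n = nrow(x),
    n_local_resident = sum(ok$category == "local-resident"),
    n_within_country_movement = sum(ok$category == "within-country-movement"),
    n_new_arrival = sum(ok$category == "new-arrival"),
    n_error = sum(!is.na(x$error))
  )
}
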