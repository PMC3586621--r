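# locality-name normalization: case-insensitive, punctuation-stripped,
# parenthetical qualifiers retained as sub-regions

norm_clean <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[.,?'\"]", "", x)
  gsub("\\s+", " ", x)
}

norm_full <- function(x) {
  norm_clean(x)
}

# base name with any trailing parenthetical qualifier removed
norm_base <- function(x) {
  trimws(gsub("\\s*\\([^)]*\\)\\s*$", "", norm_clean(x)))
}

# qualifier inside a trailing parenthetical, NA when absent
norm_qualifier <- function(x) {
  x <- norm_clean(x)
  has <- grepl("\\(([^)]*)\\)\\s*$", x)
  out <- rep(NA_character_, length(x))
  out[has] <- trimws(sub(".*\\(([^)]*)\\)\\s*$", "\\1", x[has]))
  out
}

# unordered normalized pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

#' Read a region-equivalence table
#'
#' Delimited text with columns `locality_a`, `locality_b`, `tier`
#' (`exact` or `near`). Exact pairs are locality names treated as the same
#' region; near pairs are "broad region" matches (localities roughly within
#' 100 km of each other). Pairs are symmetric, and the same pair may not
#' appear in both tiers.
#'
#' @param path Path to a CSV file; defaults to the bundled table encoding
#'   the study-region pairings.
#' @return A tibble of class `skt_equiv`.
#' @export
read_region_equivalence <- function(path = NULL) {
  path <- path %||% system.file("extdata", "region_equivalence.csv",
                                package = "skinktrace", mustWork = TRUE)
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("locality_a", "locality_b", "tier")
  if (!all(need %in% names(df))) {
    abort_input(paste0("equivalence table needs columns: ",
                       paste(need, collapse = ", ")))
  }
  if (!all(df$tier %in% c("exact", "near"))) {
    abort_input("equivalence tier must be 'exact' or 'near'")
  }
  keys <- pair_key(norm_full(df$locality_a), norm_full(df$locality_b))
  both <- intersect(keys[df$tier == "exact"], keys[df$tier == "near"])
  if (length(both) > 0) {
    abort_input("a locality pair appears in both the exact and near tiers")
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("skt_equiv", class(out))
  out
}

# normalized pair-key set for one tier; table names are matched as
# written (the query side is probed in both full and base form, so listing
# a bare name covers its sub-regions without over-matching siblings)
equiv_keys <- function(eq, which_tier) {
  if (is.null(eq)) return(character())
  sub <- eq[eq$tier == which_tier, ]
  unique(pair_key(norm_full(sub$locality_a), norm_full(sub$locality_b)))
}

# tier of a single predicted/confirmed name pair
match_tier_one <- function(pred, conf, exact_keys, near_keys) {
  pf <- norm_full(pred); cf <- norm_full(conf)
  pb <- norm_base(pred); cb <- norm_base(conf)
  pq <- norm_qualifier(pred); cq <- norm_qualifier(conf)
  combos <- c(pair_key(pf, cf), pair_key(pf, cb),
              pair_key(pb, cf), pair_key(pb, cb))
  same_base <- !is.na(pb) && !is.na(cb) && pb == cb && nzchar(pb)
  exact <- pf == cf ||
    (same_base && (is.na(pq) || is.na(cq) || pq == cq)) ||
    any(combos %in% exact_keys)
  if (exact) return("exact")
  near <- same_base || any(combos %in% near_keys)
  if (near) return("near")
  "far"
}

#' Score a recorded origin prediction against the confirmed origin
#'
#' Tiered matching of locality names: `exact` when the names agree after
#' normalization (a bare name matches any of its parenthetical sub-regions)
#' or the pair is listed as exact-equivalent; `near` when the base names
#' agree but the sub-regions differ, or the pair is listed as a broad-region
#' match; otherwise `far`. A missing or `Unknown` prediction scores
#' `no-prediction`. Predictions may list alternatives separated by `" or "`
#' and confirmations may carry ties separated by `"|"`; the best tier over
#' all combinations is returned.
#'
#' @param predicted Character vector of recorded predictions.
#' @param confirmed Character vector of molecularly confirmed origins.
#' @param eq An `skt_equiv` table (or `NULL` for name matching only).
#' @return Character vector over
#'   `{"exact", "near", "far", "no-prediction"}`.
#' @examples
#' eq <- read_region_equivalence()
#' score_prediction("Caboolture", "Brisbane (North)", eq)
#' @export
score_prediction <- function(predicted, confirmed, eq = NULL) {
  exact_keys <- equiv_keys(eq, "exact")
  near_keys <- equiv_keys(eq, "near")
  order_tier <- c(exact = 1, near = 2, far = 3)
  purrr::map2_chr(predicted, confirmed, function(p, conf) {
    if (is.na(p) || norm_full(p) %in% c("", "unknown", "na")) {
      return("no-prediction")
    }
    if (is.na(conf) || !nzchar(trimws(conf))) {
      return("no-prediction")
    }
    p_alts <- trimws(strsplit(p, "\\s+or\\s+")[[1]])
    c_alts <- trimws(strsplit(conf, "|", fixed = TRUE)[[1]])
    tiers <- vapply(p_alts, function(pa) {
      vapply(c_alts, function(ca) {
        match_tier_one(pa, ca, exact_keys, near_keys)
      }, character(1))
    }, character(length(c_alts)))
    tiers <- as.character(tiers)
    names(order_tier)[min(order_tier[tiers])]
  })
}

#' Read the established-range locality list
#'
#' One locality name per line; lines starting with `#` are comments.
#'
#' @param path Path to a plain-text file; defaults to the bundled list of
#'   localities in the established invaded range (the northern North
#'   Island).
#' @return Character vector of locality names.
#' @export
read_established_localities <- function(path = NULL) {
  path <- path %||% system.file("extdata", "established_localities.txt",
                                package = "skinktrace", mustWork = TRUE)
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) abort_input("established-locality list is empty")
  x
}
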