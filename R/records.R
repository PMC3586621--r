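TRANSPORT_LEVELS <- c("air", "sea", "truck", "rail", "truck-or-rail",
                      "rail-or-sea", "unknown")

#' Load interception records from delimited text
#'
#' Reads a CSV of biosecurity interception records into a validated tibble.
#' Required columns: `sample_code`, `location`, `month`. Recognised optional
#' columns: `transport`, `stage`, `cargo` (or `cargo_type` +
#' `cargo_contents`), `svl_mm`, `adult`, `alive`, `predicted_origin`,
#' `confirmed_origin`, `haplotype`, `group_size`, `note`. The three bundled
#' fixtures transcribe the study's interception tables cell for cell:
#' `table1_delicata_new_arrivals.csv` (13 new arrivals direct from
#' Australia), `table2_delicata_within_nz.csv` (24 within-country
#' movements) and `table3_guichenoti.csv` (4 congener interceptions, one of
#' which was a group of eight).
#'
#' @param path Path to a CSV file, or one of the fixture names above (with
#'   or without `.csv`).
#' @param species Optional species tag stored on every record.
#' @param record_class Optional class tag (`new-arrival`, `within-nz`,
#'   `local`).
#' @return A tibble of class `skt_records`.
#' @examples
#' t1 <- load_records("table1_delicata_new_arrivals")
#' nrow(t1)
#' @export
load_records <- function(path, species = NA_character_,
                         record_class = NA_character_) {
  if (!file.exists(path)) {
    candidate <- system.file("extdata",
                             paste0(sub("\\.csv$", "", path), ".csv"),
                             package = "skinktrace")
    if (nzchar(candidate)) path <- candidate
  }
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_code", "location", "month")
  if (!all(need %in% names(df))) {
    abort_input(paste0("record file needs columns: ",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  }
  n <- nrow(df)
  get_col <- function(nm, default = NA_character_) {
    if (nm %in% names(df)) df[[nm]] else rep(default, n)
  }
  month <- df$month
  bad_month <- which(!tolower(month) %in% tolower(month.name))
  if (length(bad_month) > 0) {
    abort_input(paste0("row ", bad_month[[1]], ": invalid month '",
                       month[[bad_month[[1]]]], "'"))
  }
  month <- month.name[match(tolower(month), tolower(month.name))]
  transport <- tolower(gsub("\\s+", "-", trimws(get_col("transport", "unknown"))))
  transport[is.na(transport)] <- "unknown"
  bad_tr <- which(!transport %in% TRANSPORT_LEVELS)
  if (length(bad_tr) > 0) {
    abort_input(paste0("row ", bad_tr[[1]], ": invalid transport '",
                       transport[[bad_tr[[1]]]], "'"))
  }
  stage <- tolower(trimws(get_col("stage")))
  stage[is.na(stage) | stage == ""] <- "n/a"
  bad_st <- which(!stage %in% c("border", "post-border", "n/a"))
  if (length(bad_st) > 0) {
    abort_input(paste0("row ", bad_st[[1]], ": invalid stage '",
                       stage[[bad_st[[1]]]], "'"))
  }
  cargo <- get_col("cargo")
  if (all(is.na(cargo)) && "cargo_type" %in% names(df)) {
    contents <- get_col("cargo_contents")
    cargo <- ifelse(is.na(contents) | contents == "",
                    df$cargo_type,
                    paste0(df$cargo_type, " (", contents, ")"))
  }
  svl <- suppressWarnings(as.numeric(get_col("svl_mm")))
  bad_svl <- which(!is.na(get_col("svl_mm")) & (is.na(svl) | svl <= 0))
  if (length(bad_svl) > 0) {
    abort_input(paste0("row ", bad_svl[[1]], ": invalid svl_mm '",
                       get_col("svl_mm")[[bad_svl[[1]]]], "'"))
  }
  adult <- toupper(trimws(get_col("adult")))
  bad_ad <- which(!is.na(adult) & !adult %in% c("Y", "N"))
  if (length(bad_ad) > 0) {
    abort_input(paste0("row ", bad_ad[[1]], ": invalid adult flag '",
                       adult[[bad_ad[[1]]]], "'"))
  }
  alive <- tolower(trimws(get_col("alive")))
  bad_al <- which(!is.na(alive) & !alive %in% c("alive", "dead"))
  if (length(bad_al) > 0) {
    abort_input(paste0("row ", bad_al[[1]], ": invalid alive flag '",
                       alive[[bad_al[[1]]]], "'"))
  }
  gs <- suppressWarnings(as.integer(get_col("group_size", "1")))
  gs[is.na(gs)] <- 1L
  if (any(gs < 1)) {
    abort_input(paste0("row ", which(gs < 1)[[1]], ": group_size must be >= 1"))
  }
  out <- tibble::tibble(
    sample_code = df$sample_code,
    species = rep(as.character(species), n),
    record_class = rep(as.character(record_class), n),
    location = df$location,
    month = month,
    transport = transport,
    stage = stage,
    cargo = cargo,
    svl_mm = svl,
    adult = adult,
    alive = alive,
    predicted_origin = get_col("predicted_origin"),
    confirmed_origin = get_col("confirmed_origin"),
    haplotype = get_col("haplotype"),
    group_size = gs,
    note = get_col("note")
  )
  class(out) <- c("skt_records", class(out))
  out
}

#' Season of a calendar month (austral convention)
#'
#' Southern-hemisphere mapping: Dec-Feb summer, Mar-May autumn, Jun-Aug
#' winter, Sep-Nov spring — the convention relevant to trans-Tasman
#' interception records.
#'
#' @param month Month names (full or abbreviated, any case) or integers
#'   1-12.
#' @return Factor with levels `summer`, `autumn`, `winter`, `spring`.
#' @examples
#' season_of(c("June", "December"))
#' @export
season_of <- function(month) {
  if (is.numeric(month)) {
    idx <- as.integer(month)
  } else {
    idx <- match(tolower(substr(month, 1, 3)), tolower(month.abb))
  }
  if (any(is.na(idx) | idx < 1 | idx > 12)) {
    abort_input("invalid month")
  }
  seasons <- c("summer", "summer", "autumn", "autumn", "autumn",
               "winter", "winter", "winter", "spring", "spring",
               "spring", "summer")
  factor(seasons[idx], levels = c("summer", "autumn", "winter", "spring"))
}

transport_class <- function(transport) {
  dplyr::case_match(
    transport,
    "air" ~ "air",
    "sea" ~ "sea",
    c("truck", "rail", "truck-or-rail") ~ "land",
    "rail-or-sea" ~ "land-or-sea",
    .default = "unknown"
  )
}

#' Summarise interception records along one dimension
#'
#' Counts and integer-rounded percentages (half away from zero) of records
#' per level. The denominator counts detection events (records), matching
#' the per-interception percentages of the source tables.
#'
#' @param records An `skt_records` tibble.
#' @param dimension One of `"season"`, `"transport-class"`, `"stage"`,
#'   `"alive"`, `"adult"`, `"location"`, `"origin"`.
#' @return A tibble of class `skt_summary` with columns `dimension`,
#'   `level`, `n`, `fraction`, `percent`.
#' @examples
#' t1 <- load_records("table1_delicata_new_arrivals")
#' summarize_records(t1, "season")
#' @export
summarize_records <- function(records,
                              dimension = c("season", "transport-class",
                                            "stage", "alive", "adult",
                                            "location", "origin")) {
  dimension <- match.arg(dimension)
  if (nrow(records) == 0) abort_input("no records to summarise")
  level <- switch(dimension,
    "season" = as.character(season_of(records$month)),
    "transport-class" = transport_class(records$transport),
    "stage" = records$stage,
    "alive" = records$alive,
    "adult" = records$adult,
    "location" = records$location,
    "origin" = ifelse(is.na(records$predicted_origin), "Unknown",
                      records$predicted_origin)
  )
  levels_order <- if (dimension == "season") {
    c("summer", "autumn", "winter", "spring")
  } else {
    unique(level)
  }
  out <- tibble::tibble(level = factor(level, levels = levels_order)) |>
    dplyr::count(.data$level, .drop = FALSE) |>
    dplyr::mutate(
      dimension = dimension,
      level = as.character(.data$level),
      fraction = .data$n / sum(.data$n),
      percent = round_half_up(100 * .data$fraction)
    ) |>
    dplyr::select("dimension", "level", "n", "fraction", "percent")
  class(out) <- c("skt_summary", class(out))
  out
}

#' Prediction accuracy of recorded origins
#'
#' Scores each record's predicted origin against its molecularly confirmed
#' origin with [score_prediction()] and aggregates: the exact-tier share
#' (reported to one decimal) and the exact-or-near share (integer percent).
#' Records without a prediction count in the denominator as unmatched.
#'
#' @param records An `skt_records` tibble with `predicted_origin` and
#'   `confirmed_origin` columns; records lacking a confirmed origin are
#'   dropped.
#' @param eq An `skt_equiv` equivalence table.
#' @return A one-row tibble with `n`, `n_exact`, `n_near`, `n_far`,
#'   `n_no_prediction`, `exact_pct`, `exact_or_near_pct`. Per-record tiers
#'   are available via [tidy()] (attribute `"tiers"`).
#' @export
prediction_accuracy <- function(records, eq = NULL) {
  sub <- records[!is.na(records$confirmed_origin) &
                   nzchar(trimws(records$confirmed_origin)), ]
  if (nrow(sub) == 0) {
    out <- tibble::tibble(n = 0L, n_exact = 0L, n_near = 0L, n_far = 0L,
                          n_no_prediction = 0L, exact_pct = NA_real_,
                          exact_or_near_pct = NA_real_)
    attr(out, "tiers") <- tibble::tibble(sample_code = character(),
                                         predicted_origin = character(),
                                         confirmed_origin = character(),
                                         tier = character())
    class(out) <- c("skt_accuracy", class(out))
    return(out)
  }
  tier <- score_prediction(sub$predicted_origin, sub$confirmed_origin, eq)
  n <- nrow(sub)
  out <- tibble::tibble(
    n = n,
    n_exact = sum(tier == "exact"),
    n_near = sum(tier == "near"),
    n_far = sum(tier == "far"),
    n_no_prediction = sum(tier == "no-prediction"),
    exact_pct = round(100 * sum(tier == "exact") / n, 1),
    exact_or_near_pct = round_half_up(100 * sum(tier %in% c("exact", "near")) / n)
  )
  attr(out, "tiers") <- tibble::tibble(
    sample_code = sub$sample_code,
    predicted_origin = sub$predicted_origin,
    confirmed_origin = sub$confirmed_origin,
    tier = tier
  )
  class(out) <- c("skt_accuracy", class(out))
  out
}

#' @method tidy skt_accuracy
#' @export
tidy.skt_accuracy <- function(x, ...) {
  attr(x, "tiers")
}

#' Origin and destination counts with an established-range split
#'
#' Counts records by recorded freight origin and by interception location,
#' and splits locations into inside/outside the established range.
#' Locations that are missing are reported under `unresolved` rather than
#' dropped.
#'
#' @param records An `skt_records` tibble.
#' @param established_localities Character vector of established-range
#'   locality names (see [read_established_localities()]).
#' @return A list of class `skt_odc` with tibbles `origins`, `destinations`
#'   and `range_split` (columns `status`, `n`, `fraction`, `percent`).
#' @export
origin_and_destination_counts <- function(records, established_localities) {
  if (length(established_localities) == 0) {
    abort_input("`established_localities` must be supplied")
  }
  origin <- ifelse(is.na(records$predicted_origin) |
                     !nzchar(trimws(records$predicted_origin)),
                   "Unknown", records$predicted_origin)
  origins <- tibble::tibble(origin = origin) |>
    dplyr::count(.data$origin, sort = TRUE)
  destinations <- tibble::tibble(location = records$location) |>
    dplyr::count(.data$location, sort = TRUE)
  est_norm <- norm_full(established_localities)
  status <- dplyr::case_when(
    is.na(records$location) | !nzchar(trimws(records$location)) ~ "unresolved",
    norm_full(records$location) %in% est_norm ~ "inside-range",
    .default = "outside-range"
  )
  range_split <- tibble::tibble(
    status = factor(status, levels = c("inside-range", "outside-range",
                                       "unresolved"))
  ) |>
    dplyr::count(.data$status, .drop = FALSE) |>
    dplyr::mutate(status = as.character(.data$status),
                  fraction = .data$n / sum(.data$n),
                  percent = round_half_up(100 * .data$fraction))
  structure(list(origins = origins, destinations = destinations,
                 range_split = range_split),
            class = "skt_odc")
}

#' @export
print.skt_odc <- function(x, ...) {
  cat("<skt_odc>\nOrigins:\n")
  print(x$origins)
  cat("Destinations:\n")
  print(x$destinations)
  cat("Range split:\n")
  print(x$range_split)
  invisible(x)
}
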