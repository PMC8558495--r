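#' Occurrence-record preparation
#'
#' Point records arrive as a tibble with columns `id`, `lon`, `lat`, `year`
#' and at least one of `admixture` (proportion of invasive alleles, in
#' \[0, 1\], with optional `n_individuals`) or `presence` (logical). The
#' functions in this module turn raw records into a thinned,
#' catchment-aggregated modelling table.
#'
#' @name occurrence_prep
NULL

#' Preparation configuration
#'
#' @param admixture_absent_threshold records with admixture strictly below
#'   this proportion are classified absent (default 0.10).
#' @param thinning_radius_m minimum allowed distance (metres, haversine)
#'   between two retained records of the same year (default 500).
#' @param min_year records from earlier calendar years are dropped
#'   (default 2002, matching the availability of the satellite record).
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(admixture_absent_threshold = 0.10,
                        thinning_radius_m = 500,
                        min_year = 2002) {
  if (admixture_absent_threshold <= 0 || admixture_absent_threshold >= 1) {
    abort("admixture_absent_threshold must be in (0, 1)")
  }
  if (thinning_radius_m <= 0) abort("thinning_radius_m must be positive")
  structure(
    list(
      admixture_absent_threshold = admixture_absent_threshold,
      thinning_radius_m = thinning_radius_m,
      min_year = min_year
    ),
    class = "prep_config"
  )
}

#' Classify presence from genetic admixture
#'
#' A record with admixture strictly below the threshold is classified
#' absent; at or above it, present. Records carrying only a `presence`
#' flag pass through unchanged; when both are given, admixture is
#' authoritative and presence is recomputed. Admixture values are retained.
#'
#' @param records occurrence tibble (see [occurrence_prep]).
#' @param cfg a [prep_config()].
#' @return The records tibble with `presence` filled; row count unchanged.
#' @export
classify_presence <- function(records, cfg = prep_config()) {
  records <- tibble::as_tibble(records)
  if (!"presence" %in% names(records)) records$presence <- NA
  if (!"admixture" %in% names(records)) records$admixture <- NA_real_
  bad_adm <- which(!is.na(records$admixture) &
    (records$admixture < 0 | records$admixture > 1))
  if (length(bad_adm)) {
    abort(paste0(
      "admixture outside [0, 1] for record(s): ",
      paste(records$id[bad_adm], collapse = ", ")
    ))
  }
  neither <- which(is.na(records$admixture) & is.na(records$presence))
  if (length(neither)) {
    abort(paste0(
      "record(s) with neither admixture nor presence: ",
      paste(records$id[neither], collapse = ", ")
    ))
  }
  has_adm <- !is.na(records$admixture)
  records$presence[has_adm] <-
    records$admixture[has_adm] >= cfg$admixture_absent_threshold
  records$presence <- as.logical(records$presence)
  records
}

#' Spatially thin records within year strata
#'
#' Greedy minimum-distance subsampling: records are shuffled with the given
#' seed, then visited in order; a record is retained iff its great-circle
#' distance to every already-retained record of the same year exceeds the
#' thinning radius. The retained set is maximal (no dropped record could be
#' reinserted) and deterministic given the seed. Records before
#' `cfg$min_year` are dropped first.
#'
#' @inheritParams classify_presence
#' @param seed integer seed controlling the visit order.
#' @return The retained subset of `records`.
#' @export
thin_points <- function(records, cfg = prep_config(), seed = 1L) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  stopifnot(all(is.finite(records$lon)), all(is.finite(records$lat)))
  records <- records[records$year >= cfg$min_year, , drop = FALSE]
  if (nrow(records) == 0) return(records)
  ord <- withr::with_seed(as.integer(seed), sample.int(nrow(records)))
  records <- records[ord, , drop = FALSE]
  keep_rows <- integer(0)
  for (yr in unique(records$year)) {
    idx <- which(records$year == yr)
    kept <- integer(0)
    for (i in idx) {
      if (length(kept)) {
        d <- geosphere::distHaversine(
          cbind(records$lon[kept], records$lat[kept]),
          c(records$lon[i], records$lat[i]),
          r = EARTH_RADIUS_M
        )
        if (any(d <= cfg$thinning_radius_m)) next
      }
      kept <- c(kept, i)
    }
    keep_rows <- c(keep_rows, kept)
  }
  records[sort(keep_rows), , drop = FALSE]
}

#' Aggregate records to catchment-year observations
#'
#' Each (catchment, year) pair is treated as an independent observation.
#' In `"occurrence"` mode a catchment-year is suitable iff it contains at
#' least one presence record. In `"admixture"` mode the response is the
#' weighted mean admixture, weighted by `n_individuals` (a missing sample
#' size counts as one individual and is reported). Records falling inside
#' no catchment are dropped and counted in the report attached as
#' `attr(, "report")`.
#'
#' @inheritParams classify_presence
#' @param catch a [catchments()] tibble.
#' @param mode `"occurrence"` or `"admixture"`.
#' @return A tibble keyed by (`huc_id`, `year`) with a `presence` or
#'   `admixture` column plus `n_records`; report in `attr(, "report")`.
#' @export
aggregate_to_catchments <- function(records, catch,
                                    mode = c("occurrence", "admixture")) {
  mode <- match.arg(mode)
  records <- tibble::as_tibble(records)
  records$huc_id <- assign_catchment(records$lon, records$lat, catch)
  outside <- sum(is.na(records$huc_id))
  if (outside > 0) {
    inform(paste0(outside, " record(s) outside all catchments were dropped"))
  }
  records <- records[!is.na(records$huc_id), , drop = FALSE]
  report <- list(n_outside = outside, n_used = nrow(records))
  if (mode == "occurrence") {
    if (!"presence" %in% names(records) || anyNA(records$presence)) {
      abort("occurrence mode requires a complete presence column; run classify_presence() first")
    }
    out <- records |>
      dplyr::group_by(.data$huc_id, .data$year) |>
      dplyr::summarise(
        presence = any(.data$presence),
        n_records = dplyr::n(),
        .groups = "drop"
      )
  } else {
    if (!"admixture" %in% names(records) || anyNA(records$admixture)) {
      abort("admixture mode requires a complete admixture column")
    }
    if (!"n_individuals" %in% names(records)) records$n_individuals <- NA_real_
    n_missing <- sum(is.na(records$n_individuals))
    if (n_missing > 0) {
      inform(paste0(n_missing, " record(s) missing n_individuals; treated as n = 1"))
    }
    report$n_missing_sample_size <- n_missing
    records$n_individuals[is.na(records$n_individuals)] <- 1
    out <- records |>
      dplyr::group_by(.data$huc_id, .data$year) |>
      dplyr::summarise(
        admixture = sum(.data$admixture * .data$n_individuals) /
          sum(.data$n_individuals),
        n_records = dplyr::n(),
        .groups = "drop"
      )
  }
  out <- dplyr::arrange(out, .data$huc_id, .data$year)
  attr(out, "report") <- report
  out
}

#' Read occurrence records from CSV
#'
#' Columns: `id, lon, lat, year, admixture, n_individuals, presence`;
#' empty cells are allowed for the optional fields.
#'
#' @param path CSV path.
#' @return An occurrence tibble.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat", "year")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0("occurrence CSV missing column(s): ", paste(miss, collapse = ", ")))
  }
  df$id <- as.character(df$id)
  if ("presence" %in% names(df)) df$presence <- as.logical(df$presence)
  tibble::as_tibble(df)
}
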