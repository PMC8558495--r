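#' Composite and zonally average every covariate of a landscape
#'
#' Applies each covariate's compositing rule (from the configuration's
#' composite catalogue) to its raster stack and averages the result over
#' catchments, yielding the long-form covariate table.
#'
#' @param landscape an [make_landscape()] result (or any list with
#'   `$stacks`, `$catchments` and a `$config$composites` catalogue).
#' @return Long tibble `(huc_id, year, variable, value)`; static variables
#'   have `NA` year.
#' @export
compose_landscape <- function(landscape) {
  cat_spec <- landscape$config$composites
  out <- vector("list", nrow(cat_spec))
  for (i in seq_len(nrow(cat_spec))) {
    cs <- cat_spec[i, ]
    comp <- temporal_composite(
      landscape$stacks[[cs$stack]],
      reducer = cs$reducer, window = cs$window
    )
    comp$variable <- cs$variable
    out[[i]] <- zonal_mean(comp, landscape$catchments)
  }
  dplyr::bind_rows(out)
}

#' Per-catchment mean covariates over a window of years
#'
#' Collapses the long zonal table to one row per catchment: dynamic
#' variables are averaged over the window's years, static variables pass
#' through; used to build the decadal prediction windows.
#'
#' @param zonal long tibble from [compose_landscape()] / [zonal_mean()].
#' @param years years included in the window.
#' @param label optional window label stored as an attribute.
#' @return Wide tibble: `huc_id` plus one column per variable.
#' @export
window_covariates <- function(zonal, years, label = NULL) {
  w <- zonal |>
    dplyr::filter(is.na(.data$year) | .data$year %in% years) |>
    dplyr::group_by(.data$huc_id, .data$variable) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    dplyr::arrange(.data$huc_id)
  attr(w, "window") <- label
  w
}

#' Run the synthetic study end to end up to the design tables
#'
#' Generates the landscape and records, classifies presence from
#' admixture, spatially thins the records, aggregates them to
#' catchment-year responses, composites and zonally averages every
#' covariate, and assembles the occurrence and admixture design tables.
#'
#' @param cfg a [synth_config()].
#' @return List: `landscape`, `records` (raw), `thinned`, `zonal`,
#'   `design_occurrence`, `design_admixture`, `truth`.
#' @export
synth_pipeline <- function(cfg = synth_config()) {
  landscape <- make_landscape(cfg)
  occ <- make_occurrences(cfg, landscape)
  prep <- prep_config(min_year = min(cfg$years))
  records <- classify_presence(occ$records, prep)
  thinned <- thin_points(records, prep, seed = cfg$seed + 2L)
  resp_occ <- aggregate_to_catchments(thinned, landscape$catchments, "occurrence")
  resp_adm <- aggregate_to_catchments(thinned, landscape$catchments, "admixture")
  zonal <- compose_landscape(landscape)
  list(
    landscape = landscape,
    records = records,
    thinned = thinned,
    zonal = zonal,
    design_occurrence = build_design_table(zonal, resp_occ),
    design_admixture = build_design_table(zonal, resp_adm),
    truth = occ$truth
  )
}
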