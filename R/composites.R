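#' Temporal compositing of covariate raster time-series
#'
#' Reduces the slices of a [raster_stack()] to one composite slice per year
#' following the product-specific rules used for freshwater suitability
#' covariates: maximum annual land-surface temperature, seasonal
#' precipitation sums, annual standard deviation of surface-water extent
#' ("flashiness"), annual sums of gross primary productivity, annual mean
#' vegetation indices. Static layers pass through unchanged.
#'
#' @param stack a [raster_stack()].
#' @param reducer one of `"max"`, `"sum"`, `"mean"`, `"std"`. `"std"` is the
#'   sample standard deviation; pixels with fewer than two unmasked
#'   observations in a window are masked (a single observation carries no
#'   information about variability).
#' @param window `"annual"`, a season code (`"MAM"`, `"JJA"`, `"SON"`,
#'   `"DJF"`; December is assigned to the following year's DJF window), or
#'   `list(start =, end =)` dates for a single custom window.
#' @return A [raster_stack()] with one slice per year (dates are the
#'   January 1st of each composite year), or the input unchanged if static.
#' @export
temporal_composite <- function(stack, reducer = c("max", "sum", "mean", "std"),
                               window = "annual") {
  if (is_static(stack)) return(stack)
  reducer <- match.arg(reducer)
  d <- dim(stack$values)
  mth <- as.integer(format(stack$dates, "%m"))
  yr <- as.integer(format(stack$dates, "%Y"))
  if (is.list(window)) {
    sel <- stack$dates >= as.Date(window$start) & stack$dates <= as.Date(window$end)
    if (!any(sel)) {
      abort(sprintf("empty composite window %s..%s", window$start, window$end))
    }
    groups <- list(custom = which(sel))
    out_dates <- as.Date(window$start)
  } else if (identical(window, "annual")) {
    groups <- split(seq_len(d[3]), yr)
    out_dates <- as.Date(sprintf("%s-01-01", names(groups)))
  } else if (window %in% c("MAM", "JJA", "SON", "DJF")) {
    season_months <- list(
      MAM = 3:5, JJA = 6:8, SON = 9:11, DJF = c(12L, 1L, 2L)
    )[[window]]
    sel <- mth %in% season_months
    if (!any(sel)) abort(sprintf("empty composite window '%s'", window))
    # December belongs to the DJF window labelled with the following year
    season_year <- yr + (window == "DJF") * (mth == 12L)
    groups <- split(which(sel), season_year[sel])
    out_dates <- as.Date(sprintf("%s-01-01", names(groups)))
  } else {
    abort(paste0("unknown composite window: ", format(window)))
  }
  npix <- d[1] * d[2]
  flat <- matrix(stack$values, nrow = npix, ncol = d[3])
  out <- array(NA_real_, c(d[1], d[2], length(groups)))
  for (g in seq_along(groups)) {
    m <- flat[, groups[[g]], drop = FALSE]
    nobs <- rowSums(!is.na(m))
    val <- switch(reducer,
      sum = rowSums(m, na.rm = TRUE),
      mean = rowSums(m, na.rm = TRUE) / nobs,
      max = {
        v <- m[, 1]
        for (j in seq_len(ncol(m))[-1]) v <- pmax(v, m[, j], na.rm = TRUE)
        v
      },
      std = {
        mu <- rowSums(m, na.rm = TRUE) / nobs
        ss <- rowSums((m - mu)^2, na.rm = TRUE)
        sqrt(ss / (nobs - 1))
      }
    )
    val[nobs == 0] <- NA_real_
    if (reducer == "std") val[nobs < 2] <- NA_real_
    out[, , g] <- val
  }
  raster_stack(out, stack$origin, stack$pixel,
    dates = out_dates, variable = stack$variable
  )
}

#' Zonal mean of a composited raster over catchments
#'
#' Averages pixel values over each catchment polygon. A pixel belongs to a
#' catchment iff its centre falls inside the polygon (no area weighting);
#' masked pixels are excluded. Catchments covering no unmasked pixel centre
#' get `NA` and are listed in the report attribute.
#'
#' @param stack a (typically composited) [raster_stack()].
#' @param catch a [catchments()] tibble in the same geographic coordinates.
#' @return A tibble `(huc_id, year, variable, value)`; for static layers
#'   `year` is `NA`. Report in `attr(, "report")`.
#' @export
zonal_mean <- function(stack, catch) {
  d <- dim(stack$values)
  ctr <- pixel_centers(stack)
  assignment <- assign_catchment(ctr$lon, ctr$lat, catch)
  if (all(is.na(assignment))) {
    abort("raster and catchments do not overlap: no pixel centre falls in any catchment")
  }
  years <- if (is_static(stack)) NA_integer_ else
    as.integer(format(stack$dates, "%Y"))
  res <- vector("list", d[3])
  for (s in seq_len(d[3])) {
    v <- as.vector(stack$values[, , s])
    ok <- !is.na(assignment) & !is.na(v)
    means <- tapply(v[ok], assignment[ok], mean)
    res[[s]] <- tibble::tibble(
      huc_id = catch$huc_id,
      year = years[s],
      variable = stack$variable,
      value = as.numeric(means[catch$huc_id])
    )
  }
  out <- dplyr::bind_rows(res)
  empty <- unique(out$huc_id[is.na(out$value)])
  if (length(empty)) {
    inform(paste0(
      "catchment(s) with no unmasked pixel centre in at least one slice: ",
      paste(empty, collapse = ", ")
    ))
  }
  attr(out, "report") <- list(empty_catchments = empty)
  out
}

#' Assemble the catchment-year design table
#'
#' Joins per-variable zonal tables to the response table on
#' (`huc_id`, `year`), treating each catchment-year pair as an independent
#' observation. Static variables (zonal rows with `NA` year) are broadcast
#' across years. Rows with any missing covariate are dropped and counted.
#'
#' @param zonal long tibble `(huc_id, year, variable, value)`, e.g. rows
#'   from [zonal_mean()] bound together.
#' @param response tibble keyed by (`huc_id`, `year`) with a `presence` or
#'   `admixture` column (see [aggregate_to_catchments()]).
#' @return A wide tibble: `huc_id`, `year`, the response column(s), then
#'   covariates in alphabetical order. Drop counts in `attr(, "report")`.
#' @export
build_design_table <- function(zonal, response) {
  dup <- zonal |>
    dplyr::count(.data$huc_id, .data$year, .data$variable) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0(
      "duplicate (huc_id, year) in zonal input for: ",
      paste(sprintf(
        "%s/%s/%s", dup$variable, dup$huc_id, dup$year
      ), collapse = ", ")
    ))
  }
  dupr <- response |> dplyr::count(.data$huc_id, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dupr)) {
    abort(paste0(
      "duplicate (huc_id, year) in response table for: ",
      paste(sprintf("%s/%s", dupr$huc_id, dupr$year), collapse = ", ")
    ))
  }
  dynamic <- zonal |> dplyr::filter(!is.na(.data$year))
  static <- zonal |> dplyr::filter(is.na(.data$year))
  wide <- NULL
  if (nrow(dynamic)) {
    wide <- tidyr::pivot_wider(dynamic,
      names_from = "variable", values_from = "value"
    )
  }
  out <- tibble::as_tibble(response)
  if (!is.null(wide)) out <- dplyr::inner_join(out, wide, by = c("huc_id", "year"))
  if (nrow(static)) {
    swide <- static |> dplyr::select(-"year") |>
      tidyr::pivot_wider(names_from = "variable", values_from = "value")
    out <- dplyr::inner_join(out, swide, by = "huc_id")
  }
  covars <- sort(unique(zonal$variable))
  keep <- complete.cases(out[, covars, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " row(s) dropped for missing covariate values"))
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("design table is empty (no overlapping huc_id/year keys)")
  out <- out[, c(setdiff(names(out), covars), covars), drop = FALSE]
  out <- dplyr::arrange(out, .data$huc_id, .data$year)
  attr(out, "report") <- list(n_dropped_missing = n_dropped)
  out
}
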