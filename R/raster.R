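#' Raster time-series stacks
#'
#' A `raster_stack` holds a covariate's gridded time series as a
#' rows x cols x slices array in geographic coordinates (WGS84), with the
#' first row at the top (north). `NA` cells are masked and excluded from
#' every reduction. The geotransform is `origin = c(xmin, ymax)` plus
#' positive pixel sizes `pixel = c(dx, dy)`; the centre of cell
#' (r, c) is at `(xmin + (c - 0.5) dx, ymax - (r - 0.5) dy)`.
#'
#' Static covariates (e.g. topographic diversity) are single-slice stacks
#' with `dates = NULL`.
#'
#' @param values numeric array (rows x cols x slices) or matrix (one slice).
#' @param origin numeric `c(xmin, ymax)` of the grid's top-left corner.
#' @param pixel numeric `c(dx, dy)` pixel sizes in degrees (both positive).
#' @param dates `Date` vector, one per slice, or `NULL` for a static layer.
#' @param variable covariate name.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(values, origin, pixel, dates = NULL,
                         variable = "layer") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    if (length(dates) != dim(values)[3]) {
      abort("length(dates) must equal the number of slices")
    }
    o <- order(dates)
    dates <- dates[o]
    values <- values[, , o, drop = FALSE]
  }
  stopifnot(length(origin) == 2, length(pixel) == 2, all(pixel > 0))
  structure(
    list(
      variable = variable, values = values,
      origin = as.numeric(origin), pixel = as.numeric(pixel),
      dates = dates
    ),
    class = "raster_stack"
  )
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<raster_stack '%s'> %d x %d pixels, %d slice(s)%s\n",
    x$variable, d[1], d[2], d[3],
    if (is.null(x$dates)) " (static)" else
      sprintf(", %s..%s", min(x$dates), max(x$dates))
  ))
  invisible(x)
}

is_static <- function(stack) is.null(stack$dates)

# Longitude/latitude of every pixel centre, row-major over the grid.
pixel_centers <- function(stack) {
  d <- dim(stack$values)
  rows <- seq_len(d[1])
  cols <- seq_len(d[2])
  lon <- stack$origin[1] + (cols - 0.5) * stack$pixel[1]
  lat <- stack$origin[2] - (rows - 0.5) * stack$pixel[2]
  list(
    lon = rep(lon, each = d[1]), lat = rep(lat, times = d[2]),
    row = rep(rows, times = d[2]), col = rep(cols, each = d[1])
  )
}

# Index of the pixel containing a lon/lat point (NA outside the grid).
pixel_index <- function(stack, lon, lat) {
  d <- dim(stack$values)
  col <- floor((lon - stack$origin[1]) / stack$pixel[1]) + 1
  row <- floor((stack$origin[2] - lat) / stack$pixel[2]) + 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Write / read a single raster slice as an ESRI ASCII grid
#'
#' Plain-text raster interchange: the standard ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows of values, north row first). Requires square pixels.
#'
#' @param stack a single-slice [raster_stack()].
#' @param path file path.
#' @return `write_ascii_grid()`: `path` invisibly; `read_ascii_grid()`: a
#'   single-slice [raster_stack()].
#' @export
write_ascii_grid <- function(stack, path) {
  d <- dim(stack$values)
  if (d[3] != 1) abort("write_ascii_grid() takes a single-slice stack")
  if (abs(stack$pixel[1] - stack$pixel[2]) > 1e-12) {
    abort("ESRI ASCII grids require square pixels")
  }
  v <- stack$values[, , 1]
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", d[2]), paste("nrows", d[1]),
    paste("xllcorner", format(stack$origin[1], digits = 15)),
    paste("yllcorner", format(stack$origin[2] - d[1] * stack$pixel[2], digits = 15)),
    paste("cellsize", format(stack$pixel[1], digits = 15)),
    "NODATA_value -9999"
  ), con)
  utils::write.table(v, con,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param variable covariate name for the stack read back.
#' @param date optional slice date.
#' @export
read_ascii_grid <- function(path, variable = "layer", date = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == vals[["nodata_value"]]] <- NA
  raster_stack(
    v,
    origin = c(
      vals[["xllcorner"]],
      vals[["yllcorner"]] + vals[["nrows"]] * vals[["cellsize"]]
    ),
    pixel = rep(vals[["cellsize"]], 2),
    dates = if (!is.null(date)) as.Date(date),
    variable = variable
  )
}
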