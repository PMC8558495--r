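#' Synthetic study-system configuration
#'
#' Defines a synthetic landscape emulating the shape of a catchment-scale
#' trout-invasion study: a ~1 degree x 0.6 degree montane study area near
#' 48 N tiled into 100 sub-watershed catchments, a 14-year record
#' (2002-2015), twelve base environmental covariates (two of which drive
#' the true suitability) plus two planted collinear covariates for the
#' screening stage, and clustered point sampling with near-duplicate
#' records to exercise spatial thinning.
#'
#' The ground truth is a logistic suitability function on standardized
#' composited covariate values: logit(mu) = beta0 + sum(beta_v * z_v).
#' With slopes `c(lst = 4, surface_water = 2)` the landscape is strongly
#' separable; the intercept 2.2 is calibrated (once, numerically, against
#' the default landscape's standardized catchment-year covariate
#' distribution) so that the expected presence fraction among sampled
#' sites is ~323/490.
#' Admixture values are Beta-distributed around suitability with
#' concentration 8, giving the right skew typical of heavily invaded
#' populations when suitability is high.
#'
#' Temporal noise is deliberately comparable in size to the persistent
#' spatial pattern (sd 0.8 vs 1 for the dynamic covariates), and seasonal
#' precipitation uses independent per-season fields: both keep the
#' covariates from being mutually predictable through shared structure, so
#' the screening stage removes the planted collinear pair and not the
#' independent base covariates.
#'
#' @param seed master seed; it fully determines the landscape and records.
#' @param grid_dim pixels `c(rows, cols)`.
#' @param catchment_tiles catchment grid `c(rows, cols)` of tiled
#'   rectangles.
#' @param years study years.
#' @param n_sites number of sampled catchment-year cells (base records).
#' @param cluster_rate fraction of extra near-duplicate records (< 500 m
#'   from an existing same-year point) added to exercise thinning.
#' @param beta0,beta logistic truth: intercept and named slopes on
#'   standardized composited covariates.
#' @param admixture_concentration Beta concentration around suitability.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 42L,
                         grid_dim = c(80, 80),
                         catchment_tiles = c(20, 20),
                         years = 2002:2015,
                         n_sites = 490L,
                         cluster_rate = 0.25,
                         beta0 = 2.2,
                         beta = c(lst = 4, surface_water = 2),
                         admixture_concentration = 8) {
  stacks <- tibble::tribble(
    ~name,            ~static, ~autocorr_length, ~temporal_sd, ~offset, ~scale, ~cadence,
    "lst",            FALSE,   25,               0.8,          300,     8,      "seasonal",
    "tree_cover",     FALSE,   12,               0.8,          50,      15,     "seasonal",
    "flashiness",     FALSE,   8,                0.8,          3,       1,      "seasonal",
    "gpp",            FALSE,   12,               0.8,          200,     50,     "seasonal",
    "evi",            FALSE,   12,               0.8,          0.4,     0.12,   "seasonal",
    "precip",         FALSE,   20,               0.8,          30,      10,     "monthly",
    "surface_water",  TRUE,    25,               0,            20,      10,     "static",
    "heat_load",      TRUE,    10,               0,            0.6,     0.2,    "static",
    "topo_diversity", TRUE,    5,                0,            0.5,     0.2,    "static"
  )
  composites <- tibble::tribble(
    ~variable,         ~stack,            ~reducer, ~window,
    "lst",             "lst",             "max",    "annual",
    "tree_cover",      "tree_cover",      "mean",   "annual",
    "flashiness",      "flashiness",      "std",    "annual",
    "gpp",             "gpp",             "sum",    "annual",
    "evi",             "evi",             "mean",   "annual",
    "ndvi",            "ndvi",            "mean",   "annual",
    "precip_spring",   "precip",          "sum",    "MAM",
    "precip_summer",   "precip",          "sum",    "JJA",
    "precip_fall",     "precip",          "sum",    "SON",
    "precip_winter",   "precip",          "sum",    "DJF",
    "surface_water",   "surface_water",   "mean",   "annual",
    "heat_load",       "heat_load",       "mean",   "annual",
    "topo_diversity",  "topo_diversity",  "mean",   "annual",
    "radiation_index", "radiation_index", "mean",   "annual"
  )
  # kernel lengths are defined relative to the default 80-pixel grid and
  # scale with smaller test grids
  stacks$autocorr_length <- pmax(
    1, round(stacks$autocorr_length * min(grid_dim) / 80)
  )
  collinear <- tibble::tribble(
    ~source,     ~derived,          ~transform, ~weight, ~noise_sd,
    "evi",       "ndvi",            "linear",   0.95,    NA,
    "heat_load", "radiation_index", "square",   NA,      0.05
  )
  if (!all(names(beta) %in% composites$variable)) {
    abort("truth covariates must be generated composite variables")
  }
  structure(
    list(
      seed = as.integer(seed),
      grid_dim = as.integer(grid_dim),
      origin = c(-114.6, 48.6),
      pixel = c(1 / 60, 0.01),
      catchment_tiles = as.integer(catchment_tiles),
      years = as.integer(years),
      n_sites = as.integer(n_sites),
      cluster_rate = cluster_rate,
      beta0 = beta0, beta = beta,
      admixture_concentration = admixture_concentration,
      stacks = stacks, composites = composites, collinear = collinear
    ),
    class = "synth_config"
  )
}

# Standardized spatially autocorrelated field: smoothed white noise
# (separable box moving average of the given length), rescaled to mean 0,
# sd 1. length 1 degenerates to white noise.
smooth_field <- function(dim, autocorr_length) {
  if (autocorr_length >= min(dim)) {
    abort("autocorrelation length must be smaller than the grid")
  }
  m <- matrix(rnorm(prod(dim)), dim[1], dim[2])
  m <- box_smooth(m, autocorr_length)
  (m - mean(m)) / sd(m)
}

# Truncated box moving average applied along rows then columns.
box_smooth <- function(m, L) {
  if (L <= 1) return(m)
  h <- floor(L / 2)
  avg1d <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, avg1d)
  t(apply(m, 1, avg1d))
}

slice_dates <- function(years, cadence) {
  switch(cadence,
    seasonal = as.Date(vapply(years, function(y) {
      sprintf("%d-%s-15", y, c("01", "04", "07", "10"))
    }, character(4))),
    monthly = as.Date(vapply(years, function(y) {
      sprintf("%d-%02d-15", y, 1:12)
    }, character(12))),
    abort(paste0("unknown cadence: ", cadence))
  )
}

#' Generate the synthetic landscape
#'
#' Builds, per covariate, a spatially autocorrelated base field plus
#' smoothed year- and slice-level noise (scaled by the covariate's
#' temporal sd), maps them onto physical offsets/scales, derives the
#' planted collinear covariates, and tiles the study area into rectangular
#' catchments with unique hierarchical ids.
#'
#' @param cfg a [synth_config()].
#' @return A list of class `aqrisk_landscape`: `$stacks` (named list of
#'   [raster_stack()]), `$catchments`, `$config`.
#' @export
make_landscape <- function(cfg = synth_config()) {
  withr::with_seed(cfg$seed, {
    dims <- cfg$grid_dim
    z_fields <- list()
    stacks <- list()
    for (i in seq_len(nrow(cfg$stacks))) {
      s <- cfg$stacks[i, ]
      base <- smooth_field(dims, s$autocorr_length)
      if (s$static) {
        z <- array(base, c(dims, 1L))
        dates <- NULL
      } else if (s$cadence == "monthly") {
        # independent per-season persistent fields (winter and summer
        # precipitation patterns differ), plus season-year and month noise
        dates <- slice_dates(cfg$years, s$cadence)
        season_of <- function(m) c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)[m]
        season_base <- replicate(4, smooth_field(dims, s$autocorr_length),
          simplify = FALSE
        )
        z <- array(NA_real_, c(dims, length(dates)))
        for (yi in seq_along(cfg$years)) {
          yf <- replicate(4, smooth_field(dims, s$autocorr_length),
            simplify = FALSE
          )
          for (m in 1:12) {
            sf <- smooth_field(dims, s$autocorr_length)
            si <- season_of(m)
            z[, , (yi - 1) * 12 + m] <-
              season_base[[si]] + s$temporal_sd * yf[[si]] +
              0.5 * s$temporal_sd * sf
          }
        }
      } else {
        dates <- slice_dates(cfg$years, s$cadence)
        nsl <- length(dates)
        per_year <- nsl / length(cfg$years)
        z <- array(NA_real_, c(dims, nsl))
        for (yi in seq_along(cfg$years)) {
          yf <- smooth_field(dims, s$autocorr_length)
          for (k in seq_len(per_year)) {
            sf <- smooth_field(dims, s$autocorr_length)
            z[, , (yi - 1) * per_year + k] <-
              base + s$temporal_sd * yf + 0.5 * s$temporal_sd * sf
          }
        }
      }
      z_fields[[s$name]] <- z
      stacks[[s$name]] <- raster_stack(
        s$offset + s$scale * z, cfg$origin, cfg$pixel,
        dates = dates, variable = s$name
      )
    }
    for (i in seq_len(nrow(cfg$collinear))) {
      cl <- cfg$collinear[i, ]
      src <- z_fields[[cl$source]]
      src_stack <- stacks[[cl$source]]
      if (cl$transform == "linear") {
        w <- cl$weight
        noise <- array(rnorm(length(src)), dim(src))
        for (k in seq_len(dim(src)[3])) noise[, , k] <- box_smooth(noise[, , k], 8)
        noise <- (noise - mean(noise)) / sd(noise)
        z <- w * src + sqrt(1 - w^2) * noise
      } else {
        noise <- box_smooth(matrix(rnorm(prod(dims)), dims[1], dims[2]), 8)
        noise <- (noise - mean(noise)) / sd(noise)
        z <- (src^2 - 1) / sqrt(2) + cl$noise_sd * array(noise, dim(src))
      }
      stacks[[cl$derived]] <- raster_stack(
        z, cfg$origin, cfg$pixel,
        dates = src_stack$dates, variable = cl$derived
      )
    }
    tiles <- cfg$catchment_tiles
    px_per_tile <- dims / tiles
    ids <- character(0)
    geoms <- list()
    for (ti in seq_len(tiles[1])) {
      for (tj in seq_len(tiles[2])) {
        xmin <- cfg$origin[1] + (tj - 1) * px_per_tile[2] * cfg$pixel[1]
        xmax <- cfg$origin[1] + tj * px_per_tile[2] * cfg$pixel[1]
        ymax <- cfg$origin[2] - (ti - 1) * px_per_tile[1] * cfg$pixel[2]
        ymin <- cfg$origin[2] - ti * px_per_tile[1] * cfg$pixel[2]
        ids <- c(ids, sprintf("H17%02d%02d", ti, tj))
        geoms <- c(geoms, list(cbind(
          c(xmin, xmax, xmax, xmin, xmin),
          c(ymin, ymin, ymax, ymax, ymin)
        )))
      }
    }
    structure(
      list(stacks = stacks, catchments = catchments(ids, geoms), config = cfg),
      class = "aqrisk_landscape"
    )
  })
}

# Standardized per-catchment-year values of the causal composited
# covariates: the suitability truth operates at the catchment scale, the
# modelling unit of the workflow. Returns a tibble keyed by (huc_id, year)
# with one standardized column z_<variable> per causal covariate.
causal_zonal <- function(landscape) {
  cfg <- landscape$config
  out <- tidyr::expand_grid(
    huc_id = landscape$catchments$huc_id, year = cfg$years
  )
  for (v in names(cfg$beta)) {
    spec <- cfg$composites[cfg$composites$variable == v, ]
    comp <- temporal_composite(
      landscape$stacks[[spec$stack]],
      reducer = spec$reducer, window = spec$window
    )
    zt <- zonal_mean(comp, landscape$catchments)
    if (all(is.na(zt$year))) {
      vals <- zt$value[match(out$huc_id, zt$huc_id)]
    } else {
      vals <- zt$value[match(
        paste(out$huc_id, out$year),
        paste(zt$huc_id, zt$year)
      )]
    }
    out[[paste0("z_", v)]] <- (vals - mean(vals, na.rm = TRUE)) /
      sd(vals, na.rm = TRUE)
  }
  out
}

#' Sample synthetic occurrence and admixture records
#'
#' Samples catchment-year cells, places one point per cell (enforcing
#' > 500 m spacing between same-year points so that, at cluster rate 0,
#' thinning removes nothing), draws presence from the logistic truth on
#' the local composited covariate values and admixture from a Beta
#' distribution centred on the same suitability, then adds near-duplicate
#' cluster points (< 500 m, same year) to exercise thinning.
#'
#' @param cfg a [synth_config()].
#' @param landscape the matching [make_landscape()] result.
#' @return List: `$records` (occurrence tibble with `id, lon, lat, year,
#'   admixture, n_individuals`), `$truth` (per-record suitability and true
#'   standardized causal values).
#' @export
make_occurrences <- function(cfg = synth_config(), landscape = make_landscape(cfg)) {
  catch <- landscape$catchments
  if (nrow(catch) == 0) abort("landscape has no catchments")
  causal <- causal_zonal(landscape)
  withr::with_seed(cfg$seed + 1L, {
    cells <- expand.grid(
      ci = seq_len(nrow(catch)), year = cfg$years,
      KEEP.OUT.ATTRS = FALSE
    )
    pick <- cells[sample(nrow(cells), cfg$n_sites), ]
    lon <- numeric(0); lat <- numeric(0); yr <- integer(0); huc <- character(0)
    for (r in seq_len(nrow(pick))) {
      g <- catch$geometry[[pick$ci[r]]]
      for (try in 1:50) {
        px <- runif(1, min(g[, 1]) + 1e-6, max(g[, 1]) - 1e-6)
        py <- runif(1, min(g[, 2]) + 1e-6, max(g[, 2]) - 1e-6)
        same_year <- which(yr == pick$year[r])
        if (!length(same_year)) break
        d <- geosphere::distHaversine(
          cbind(lon[same_year], lat[same_year]), c(px, py),
          r = EARTH_RADIUS_M
        )
        if (all(d > 500)) break
      }
      lon <- c(lon, px); lat <- c(lat, py)
      yr <- c(yr, pick$year[r]); huc <- c(huc, catch$huc_id[pick$ci[r]])
    }
    n_extra <- floor(cfg$cluster_rate * cfg$n_sites)
    if (n_extra > 0) {
      src <- sample(length(lon), n_extra, replace = TRUE)
      dest <- geosphere::destPoint(
        cbind(lon[src], lat[src]),
        b = runif(n_extra, 0, 360), d = runif(n_extra, 50, 450),
        r = EARTH_RADIUS_M
      )
      lon <- c(lon, dest[, 1]); lat <- c(lat, dest[, 2])
      yr <- c(yr, yr[src]); huc <- c(huc, huc[src])
    }
    # a record's suitability is driven by its catchment-year environment
    # (the modelling unit of the workflow); cluster points inherit the
    # catchment of their source point
    ci <- match(paste(huc, yr), paste(causal$huc_id, causal$year))
    lp <- rep(cfg$beta0, length(lon))
    zvals <- matrix(NA_real_, length(lon), length(cfg$beta),
      dimnames = list(NULL, names(cfg$beta))
    )
    for (v in names(cfg$beta)) {
      z <- causal[[paste0("z_", v)]][ci]
      zvals[, v] <- z
      lp <- lp + cfg$beta[[v]] * z
    }
    suit <- plogis(lp)
    presence <- rbinom(length(suit), 1, suit) == 1
    mu <- pmin(pmax(suit, 0.01), 0.99)
    adm_raw <- rbeta(
      length(mu),
      mu * cfg$admixture_concentration,
      (1 - mu) * cfg$admixture_concentration
    )
    # keep admixture consistent with the 10% classification rule: present
    # records carry >= 0.10 admixture, absent ones < 0.10, both shaped by
    # the same Beta(suitability) draw
    admixture <- ifelse(presence, 0.1 + 0.9 * adm_raw, 0.1 * adm_raw)
    n_individuals <- sample(5:40, length(mu), replace = TRUE)
    ids <- sprintf("rec%04d", seq_along(lon))
    records <- tibble::tibble(
      id = ids, lon = lon, lat = lat, year = yr,
      admixture = admixture, n_individuals = n_individuals
    )
    truth <- tibble::tibble(
      id = ids, huc_id = huc, year = yr,
      suitability = suit, presence = presence
    )
    for (v in colnames(zvals)) truth[[paste0("z_", v)]] <- zvals[, v]
    list(records = records, truth = truth)
  })
}
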