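test_that("reducers reproduce the hand-worked pixel series", {
  mk <- function(vals) {
    raster_stack(
      array(rep(vals, each = 1), c(1, 1, length(vals))),
      origin = c(0, 1), pixel = c(0.01, 0.01),
      dates = as.Date("2005-01-01") + seq_along(vals) * 30
    )
  }
  expect_equal(temporal_composite(mk(c(300, 310, 305)), "max")$values[1, 1, 1], 310)
  expect_equal(temporal_composite(mk(c(2, 2, 2)), "std")$values[1, 1, 1], 0)
  s <- mk(c(1, 2, 3, 4))
  s$values[1, 1, 3] <- NA
  expect_equal(temporal_composite(s, "sum")$values[1, 1, 1], 7)
})

test_that("every reducer equals the naive per-pixel loop oracle on masked stacks", {
  for (s in 1:6) {
    stk <- withr::with_seed(s, random_stack(
      nr = sample(2:10, 1), nc = sample(2:10, 1), ns = sample(3:12, 1)
    ))
    yr <- as.integer(format(stk$dates, "%Y"))
    for (reducer in c("max", "sum", "mean", "std")) {
      got <- temporal_composite(stk, reducer, "annual")
      for (g in seq_along(unique(yr))) {
        want <- oracle_composite(stk, reducer, which(yr == sort(unique(yr))[g]))
        if (reducer %in% c("max", "sum")) {
          expect_identical(got$values[, , g], want)
        } else {
          expect_equal(got$values[, , g], want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("a pixel-year with no unmasked observation is masked, std needs two", {
  v <- array(c(5, NA, NA, NA), c(1, 1, 4))
  stk <- raster_stack(v, c(0, 1), c(0.01, 0.01),
    dates = as.Date("2005-03-01") + (0:3) * 30
  )
  expect_equal(temporal_composite(stk, "sum")$values[1, 1, 1], 5)
  expect_true(is.na(temporal_composite(stk, "std")$values[1, 1, 1]))
})

test_that("seasonal windows select calendar months and DJF rolls December forward", {
  dates <- seq(as.Date("2004-12-15"), as.Date("2005-11-15"), by = "month")
  v <- array(rep(1:12, each = 1), c(1, 1, 12))
  stk <- raster_stack(v, c(0, 1), c(0.01, 0.01), dates = dates)
  mam <- temporal_composite(stk, "sum", "MAM")
  # months Mar-May 2005 carry values 4, 5, 6
  expect_equal(as.vector(mam$values), 15)
  expect_equal(format(mam$dates, "%Y"), "2005")
  djf <- temporal_composite(stk, "sum", "DJF")
  # Dec 2004 (1) + Jan 2005 (2) + Feb 2005 (3), labelled 2005
  expect_equal(as.vector(djf$values), 6)
  expect_equal(format(djf$dates, "%Y"), "2005")
})

test_that("a season sum equals the sum of its monthly sum-composites", {
  for (s in 1:3) {
    stk <- withr::with_seed(s, random_stack(4, 4, 24, year_span = 1))
    season <- temporal_composite(stk, "sum", "JJA")
    if (dim(season$values)[3] == 0) next
    months <- as.integer(format(stk$dates, "%m"))
    manual <- array(0, dim(season$values)[1:2])
    any_obs <- array(FALSE, dim(season$values)[1:2])
    for (m in 6:8) {
      sel <- which(months == m)
      if (!length(sel)) next
      sl <- stk$values[, , sel, drop = FALSE]
      manual <- manual + apply(sl, c(1, 2), function(x) sum(x, na.rm = TRUE))
      any_obs <- any_obs | apply(!is.na(sl), c(1, 2), any)
    }
    manual[!any_obs] <- NA
    expect_equal(season$values[, , 1], manual, tolerance = 1e-12)
  }
})

test_that("static stacks pass through and bad windows error", {
  static <- raster_stack(matrix(1:4, 2), c(0, 1), c(0.01, 0.01))
  expect_identical(temporal_composite(static, "max"), static)
  stk <- random_stack(2, 2, 4)
  expect_error(temporal_composite(stk, "sum",
    window = list(start = "1990-01-01", end = "1990-02-01")
  ), "empty")
  expect_error(temporal_composite(stk, "median"), "arg")
})

test_that("zonal mean of a uniform raster is that value", {
  catch <- two_rect_catchments()
  stk <- raster_stack(matrix(5, 10, 20), c(0, 0.1), c(0.01, 0.01),
    dates = as.Date("2005-01-01")
  )
  out <- zonal_mean(stk, catch)
  expect_equal(out$value, c(5, 5))
  expect_equal(out$year, c(2005L, 2005L))
})

test_that("zonal mean matches the pixel-center-in-polygon oracle on a 2x2 grid", {
  # 2x2 raster over [0,0.2]x[0,0.2]; values row-wise 1 2 / 3 4
  stk <- raster_stack(matrix(c(1, 3, 2, 4), 2, 2), c(0, 0.2), c(0.1, 0.1),
    dates = as.Date("2005-01-01")
  )
  # polygon covering exactly the top row's pixel centers (y = 0.15)
  top <- catchments("T", list(cbind(
    c(-0.01, 0.21, 0.21, -0.01, -0.01), c(0.12, 0.12, 0.18, 0.18, 0.12)
  )))
  expect_equal(zonal_mean(stk, top)$value, 1.5)
})

test_that("zonal mean excludes masked pixels and reports empty catchments", {
  catch <- two_rect_catchments()
  m <- matrix(rnorm(200), 10, 20)
  m[, 11:20] <- NA # mask all of HB
  stk <- raster_stack(m, c(0, 0.1), c(0.01, 0.01), dates = as.Date("2005-01-01"))
  expect_message(out <- zonal_mean(stk, catch), "HB")
  expect_equal(out$value[out$huc_id == "HA"], mean(m[, 1:10]))
  expect_true(is.na(out$value[out$huc_id == "HB"]))
  expect_equal(attr(out, "report")$empty_catchments, "HB")
})

test_that("zonal mean ignores values outside the polygon entirely", {
  catch <- catchments("HA", list(cbind(
    c(0, 0.1, 0.1, 0, 0), c(0, 0, 0.1, 0.1, 0)
  )))
  base <- withr::with_seed(1, matrix(rnorm(200), 10, 20))
  stk <- raster_stack(base, c(0, 0.1), c(0.01, 0.01), dates = as.Date("2005-01-01"))
  v1 <- zonal_mean(stk, catch)$value
  shuffled <- base
  shuffled[, 11:20] <- withr::with_seed(2, matrix(rnorm(100), 10, 10))
  stk2 <- raster_stack(shuffled, c(0, 0.1), c(0.01, 0.01), dates = as.Date("2005-01-01"))
  expect_identical(zonal_mean(stk2, catch)$value, v1)
})

test_that("zonal mean with no overlap at all errors", {
  catch <- catchments("HZ", list(cbind(c(5, 6, 6, 5, 5), c(5, 5, 6, 6, 5))))
  stk <- raster_stack(matrix(1, 4, 4), c(0, 0.1), c(0.01, 0.01),
    dates = as.Date("2005-01-01")
  )
  expect_error(zonal_mean(stk, catch), "overlap")
})

test_that("the design table joins covariates and response on catchment-year keys", {
  zonal <- tidyr::expand_grid(
    huc_id = c("HA", "HB"), year = 2004:2008,
    variable = c("a", "b", "c")
  )
  zonal$value <- seq_len(nrow(zonal)) / 10
  response <- tidyr::expand_grid(huc_id = c("HA", "HB"), year = 2004:2008)
  response$presence <- rep(c(TRUE, FALSE), 5)
  out <- build_design_table(zonal, response)
  expect_equal(nrow(out), 10)
  expect_equal(names(out), c("huc_id", "year", "presence", "a", "b", "c"))

  # one missing covariate value drops exactly that row
  zonal2 <- zonal[!(zonal$huc_id == "HA" & zonal$year == 2004 & zonal$variable == "b"), ]
  expect_message(out2 <- build_design_table(zonal2, response), "dropped")
  expect_equal(nrow(out2), 9)
  expect_equal(attr(out2, "report")$n_dropped_missing, 1)
})

test_that("static variables broadcast across years", {
  zonal <- dplyr::bind_rows(
    tibble::tibble(huc_id = "HA", year = 2004:2005, variable = "dyn", value = c(1, 2)),
    tibble::tibble(huc_id = "HA", year = NA_integer_, variable = "stat", value = 9)
  )
  response <- tibble::tibble(huc_id = "HA", year = 2004:2005, presence = c(TRUE, FALSE))
  out <- build_design_table(zonal, response)
  expect_equal(out$stat, c(9, 9))
  expect_equal(out$dyn, c(1, 2))
})

test_that("disjoint year ranges give an empty table with a warning", {
  zonal <- tibble::tibble(huc_id = "HA", year = 2004L, variable = "a", value = 1)
  response <- tibble::tibble(huc_id = "HA", year = 2010L, presence = TRUE)
  expect_warning(out <- build_design_table(zonal, response), "empty")
  expect_equal(nrow(out), 0)
})

test_that("duplicate catchment-year keys are rejected by name", {
  zonal <- tibble::tibble(
    huc_id = c("HA", "HA"), year = 2004L, variable = "a", value = 1:2
  )
  response <- tibble::tibble(huc_id = "HA", year = 2004L, presence = TRUE)
  expect_error(build_design_table(zonal, response), "a/HA/2004")
  zon <- tibble::tibble(huc_id = "HA", year = 2004L, variable = "a", value = 1)
  resp2 <- tibble::tibble(huc_id = c("HA", "HA"), year = 2004L, presence = TRUE)
  expect_error(build_design_table(zon, resp2), "HA/2004")
})

test_that("catchment GeoJSON and ASCII grids round-trip", {
  catch <- two_rect_catchments()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_catchments(catch, path, properties = data.frame(huc_id = "HA", prob = 0.7))
  back <- read_catchments(path)
  expect_equal(back$huc_id, catch$huc_id)
  expect_equal(back$geometry[[2]][1:4, ], unname(catch$geometry[[2]][1:4, ]),
    ignore_attr = TRUE
  )

  stk <- raster_stack(matrix(c(1, NA, 3, 4), 2), c(0, 1), c(0.5, 0.5),
    dates = as.Date("2005-01-01"), variable = "v"
  )
  gpath <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(stk, gpath)
  back2 <- read_ascii_grid(gpath, variable = "v", date = "2005-01-01")
  expect_equal(back2$values, stk$values)
  expect_equal(back2$origin, stk$origin)
  expect_equal(back2$pixel, stk$pixel)
})
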