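# Shared fixtures, built in code at test time.

# Occurrence tibble from vectors, with defaults filled.
occ_tbl <- function(lon, lat, year, admixture = NULL, presence = NULL,
                    n_individuals = NULL) {
  n <- length(lon)
  tibble::tibble(
    id = sprintf("r%03d", seq_len(n)),
    lon = lon, lat = lat, year = year,
    admixture = admixture %||% rep(NA_real_, n),
    n_individuals = n_individuals %||% rep(NA_real_, n),
    presence = presence %||% rep(NA, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two rectangular catchments side by side, sharing the lon = 0.1 edge.
two_rect_catchments <- function() {
  catchments(
    c("HA", "HB"),
    list(
      cbind(c(0, 0.1, 0.1, 0, 0), c(0, 0, 0.1, 0.1, 0)),
      cbind(c(0.1, 0.2, 0.2, 0.1, 0.1), c(0, 0, 0.1, 0.1, 0))
    )
  )
}

# Random masked integer stack for composite oracle checks.
random_stack <- function(nr, nc, ns, year_span = 1, mask_rate = 0.2,
                         integer_values = TRUE) {
  v <- array(
    if (integer_values) {
      as.numeric(sample(0:50, nr * nc * ns, replace = TRUE))
    } else {
      rnorm(nr * nc * ns)
    },
    c(nr, nc, ns)
  )
  v[runif(length(v)) < mask_rate] <- NA
  dates <- sort(sample(
    seq(as.Date("2005-01-01"), by = "day", length.out = 365 * year_span),
    ns
  ))
  raster_stack(v, origin = c(0, 1), pixel = c(0.01, 0.01),
    dates = dates, variable = "x"
  )
}

# Naive per-pixel composite oracle: explicit loops over unmasked slices.
oracle_composite <- function(stack, reducer, slices) {
  d <- dim(stack$values)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- stack$values[i, j, slices]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      out[i, j] <- switch(reducer,
        max = max(x),
        sum = sum(x),
        mean = sum(x) / length(x),
        std = if (length(x) < 2) NA_real_ else {
          mu <- sum(x) / length(x)
          sqrt(sum((x - mu)^2) / (length(x) - 1))
        }
      )
    }
  }
  out
}

# Brute-force MESS oracle: literal four-branch formula, one value at a time.
oracle_mess <- function(reference, query, covars) {
  n <- nrow(query)
  smat <- matrix(NA_real_, n, length(covars), dimnames = list(NULL, covars))
  for (v in covars) {
    ref <- reference[[v]]
    m <- min(ref)
    M <- max(ref)
    for (i in seq_len(n)) {
      p <- query[[v]][i]
      if (M == m) {
        smat[i, v] <- if (p == m) 0 else -Inf
        next
      }
      f <- sum(ref < p) / length(ref)
      smat[i, v] <- if (f == 0) {
        100 * (p - m) / (M - m)
      } else if (f <= 0.5) {
        200 * f
      } else if (f < 1) {
        200 * (1 - f)
      } else {
        100 * (M - p) / (M - m)
      }
    }
  }
  smat
}

# Separable classification table: presence fully determined by x1.
separable_table <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    x1 <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
    tibble::tibble(
      presence = x1 > 0,
      x1 = x1, x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n)
    )
  })
}

# Default-condition pipeline, built once per test run and cached.
default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pipe <- suppressMessages(synth_pipeline(synth_config()))
      scr <- suppressWarnings(screen_covariates(pipe$design_occurrence))
      cache <<- list(pipe = pipe, screening = scr)
    }
    cache
  }
})

fast_specs <- function(task = "classification", seed = 1) {
  model_specs(task, members = c("GLM", "CTA", "RF"), seed = seed)
}
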