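#' Tri-method importance tally of environmental drivers
#'
#' For every retained ensemble member, ranks the covariates by three
#' importance techniques and tallies how often each covariate lands in a
#' top-3 list; each (member, method) pair contributes exactly three tally
#' increments.
#'
#' * Permutation importance: each covariate's holdout values are shuffled
#'   `n_permutations` times; the mean drop in holdout skill (classification
#'   accuracy, or MAE rise for regression) ranks the covariates.
#' * Recursive feature elimination (RFE): the covariate with the smallest
#'   per-step importance (model-native where the member provides one,
#'   otherwise a single permutation drop) is removed and the member refit,
#'   until one remains; elimination order gives the ranking.
#' * Backwards elimination: each covariate is removed in turn, the member
#'   refit without it, and the holdout skill drop (AUC drop or MAE rise)
#'   ranks the covariates.
#'
#' Ranking ties are broken alphabetically.
#'
#' @param ensemble an [fit_members()] result (its stored training split and
#'   holdout are reused so all three methods share one skill currency).
#' @param seed seed for the permutation shuffles.
#' @param n_permutations shuffles per covariate (default 10).
#' @return An object of class `aqrisk_importance`: `$tally` tibble
#'   `(covariate, count)` and `$audit` tibble
#'   `(member, method, rank, covariate, score)`.
#' @export
importance_ensemble <- function(ensemble, seed = 1L, n_permutations = 10) {
  covars <- ensemble$covariates
  if (length(covars) < 3) abort("top-3 tally undefined for fewer than 3 covariates")
  if (length(covars) < 4) {
    warn("fewer than 4 covariates: every covariate will appear in every top-3 list")
  }
  mem <- retained_members(ensemble)
  hold_x <- ensemble$data[ensemble$holdout_idx, covars, drop = FALSE]
  hold_y <- response_vector(ensemble)[ensemble$holdout_idx]
  train_x <- as.data.frame(ensemble$data[ensemble$train_idx, covars, drop = FALSE])
  train_y <- response_vector(ensemble)[ensemble$train_idx]
  audit <- list()
  for (i in seq_len(nrow(mem))) {
    member <- mem$fit[[i]]
    spec <- list(
      name = member$name, task = ensemble$task,
      params = member$params %||% list(), seed = member$seed
    )
    scores <- list(
      permutation = permutation_scores(
        member, hold_x, hold_y, ensemble$threshold,
        seed = as.integer(seed) + i, n_permutations = n_permutations
      ),
      rfe = rfe_scores(spec, train_x, train_y, hold_x, hold_y,
        threshold = ensemble$threshold, seed = as.integer(seed) + i
      ),
      backwards = backwards_scores(spec, train_x, train_y, hold_x, hold_y)
    )
    for (method in names(scores)) {
      s <- scores[[method]]
      ranking <- names(s)[order(-s, names(s))]
      audit[[length(audit) + 1]] <- tibble::tibble(
        member = member$name, method = method,
        rank = seq_along(ranking), covariate = ranking,
        score = unname(s[ranking])
      )
    }
  }
  audit <- dplyr::bind_rows(audit)
  tally <- audit |>
    dplyr::filter(.data$rank <= 3) |>
    dplyr::count(.data$covariate, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$covariate)
  structure(
    list(tally = tally, audit = audit,
         n_members = nrow(mem), n_methods = 3L),
    class = "aqrisk_importance"
  )
}

response_vector <- function(ensemble) {
  y <- ensemble$data[[ensemble$response]]
  if (ensemble$task == "classification") as.logical(y) else as.numeric(y)
}

holdout_metric <- function(task, pred, y, threshold) {
  if (task == "classification") mean((pred >= threshold) == y) else mean(abs(pred - y))
}

# Mean drop in holdout metric over shuffles of one covariate at a time.
permutation_scores <- function(member, hold_x, hold_y, threshold,
                               seed, n_permutations) {
  task <- member$task
  base <- holdout_metric(task, predict_member(member, hold_x), hold_y, threshold)
  covars <- names(hold_x)
  withr::with_seed(as.integer(seed), {
    vapply(setNames(covars, covars), function(v) {
      drops <- vapply(seq_len(n_permutations), function(p) {
        shuffled <- hold_x
        shuffled[[v]] <- sample(shuffled[[v]])
        m <- holdout_metric(task, predict_member(member, shuffled), hold_y, threshold)
        if (task == "classification") base - m else m - base
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
}

# Native per-step importance used inside RFE; falls back to a single
# permutation pass for members without native importances (ANN).
native_importance <- function(spec, x, y, hold_x, hold_y, threshold, seed) {
  covars <- names(x)
  zeros <- setNames(rep(0, length(covars)), covars)
  if (spec$name == "RF") {
    fit <- withr::with_seed(spec$seed, ranger::ranger(
      x = x,
      y = if (spec$task == "classification") factor(y, levels = c(FALSE, TRUE)) else y,
      probability = spec$task == "classification",
      importance = "impurity", seed = spec$seed, num.threads = 1
    ))
    imp <- fit$variable.importance
    zeros[names(imp)] <- imp
    zeros
  } else if (spec$name %in% c("GBM", "XGB")) {
    member <- fit_member(spec, x, y)
    imp <- xgboost::xgb.importance(model = xgboost::xgb.load.raw(member$fit$raw))
    zeros[imp$Feature] <- imp$Gain
    zeros
  } else if (spec$name == "CTA") {
    member <- fit_member(spec, x, y)
    imp <- member$fit$variable.importance
    if (!is.null(imp)) zeros[names(imp)] <- imp
    zeros
  } else if (spec$name == "GLM") {
    member <- fit_member(spec, x, y)
    z <- summary(member$fit)$coefficients
    rows <- intersect(rownames(z), covars)
    zeros[rows] <- abs(z[rows, 3])
    zeros
  } else {
    member <- fit_member(spec, x, y)
    permutation_scores(member, hold_x[, covars, drop = FALSE], hold_y,
      threshold,
      seed = seed, n_permutations = 1
    )
  }
}

# RFE ranking score: covariates eliminated later score higher.
rfe_scores <- function(spec, x, y, hold_x, hold_y, threshold, seed) {
  covars <- names(x)
  remaining <- covars
  elim_order <- character(0)
  while (length(remaining) > 1) {
    imp <- native_importance(
      spec, x[, remaining, drop = FALSE], y,
      hold_x, hold_y, threshold, seed
    )
    weakest <- sort(names(imp)[imp == min(imp)])[1]
    elim_order <- c(elim_order, weakest)
    remaining <- setdiff(remaining, weakest)
  }
  elim_order <- c(elim_order, remaining)
  setNames(seq_along(elim_order), elim_order)
}

# Skill drop from refitting the member without each covariate in turn.
backwards_scores <- function(spec, x, y, hold_x, hold_y) {
  full <- fit_member(spec, x, y)
  base <- member_skill(full, hold_x, hold_y)
  covars <- names(x)
  vapply(setNames(covars, covars), function(v) {
    reduced <- fit_member(spec, x[, setdiff(covars, v), drop = FALSE], y)
    s <- member_skill(reduced, hold_x, hold_y)
    if (spec$task == "classification") base - s else s - base
  }, numeric(1))
}

#' @export
print.aqrisk_importance <- function(x, ...) {
  cat(sprintf(
    "<aqrisk_importance> %d member(s) x %d methods (tally mass %d)\n",
    x$n_members, x$n_methods, sum(x$tally$count)
  ))
  print(x$tally)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aqrisk_importance <- function(x, ...) x$tally

#' Partial-dependence curve
#'
#' Evaluates the mean prediction over all training rows while a single
#' covariate is swept along a quantile-based grid (robust to skewed
#' covariates); other covariates keep their observed values. For an
#' ensemble the curve is the weighted average of member curves.
#'
#' @param object an `aqrisk_ensemble` or a single fitted member.
#' @param table rows over which predictions are averaged; defaults to the
#'   ensemble's training table.
#' @param covariate covariate name.
#' @param grid_size number of quantile grid points (default 20).
#' @return A tibble of class `aqrisk_pdp`: `(covariate, grid, response)`.
#' @export
pdp <- function(object, covariate, table = NULL, grid_size = 20) {
  if (inherits(object, "aqrisk_ensemble")) {
    table <- tibble::as_tibble(table %||% object$data)
    mem <- retained_members(object)
    fits <- mem$fit
    weights <- mem$weight
  } else if (inherits(object, "aqrisk_member")) {
    if (is.null(table)) abort("a single member needs an explicit table")
    table <- tibble::as_tibble(table)
    fits <- list(object)
    weights <- 1
  } else {
    abort("object must be an aqrisk_ensemble or aqrisk_member")
  }
  if (!covariate %in% names(table)) {
    abort(paste0("covariate '", covariate, "' not in table"))
  }
  vals <- table[[covariate]]
  grid <- sort(unique(quantile(vals,
    probs = seq(0, 1, length.out = grid_size), names = FALSE
  )))
  if (length(grid) == 1) {
    warn(paste0("covariate '", covariate, "' is constant; single-point curve"))
  }
  resp <- vapply(grid, function(g) {
    sweep_tbl <- table
    sweep_tbl[[covariate]] <- g
    preds <- vapply(fits, function(f) mean(predict_member(f, sweep_tbl)),
      numeric(1)
    )
    sum(preds * weights)
  }, numeric(1))
  out <- tibble::tibble(covariate = covariate, grid = grid, response = resp)
  class(out) <- c("aqrisk_pdp", class(out))
  out
}

#' Multivariate environmental similarity (MESS)
#'
#' Scores how similar each query unit's covariates are to a reference
#' (training) table, per the standard similarity formula. For covariate v
#' with reference minimum m, maximum M and f the fraction of reference
#' values strictly less than the query value p:
#' f = 0 gives S = 100 (p - m) / (M - m); 0 < f <= 0.5 gives S = 200 f;
#' 0.5 < f < 1 gives S = 200 (1 - f); f = 1 gives S = 100 (M - p) / (M - m).
#' The MESS value is the minimum S over covariates; negative values flag
#' extrapolation outside the reference range. A constant reference
#' covariate scores 0 where the query matches it and -Inf otherwise
#' (reported, and excluded from the minimum unless it is the only
#' covariate).
#'
#' @param reference reference tibble (training covariates).
#' @param query query tibble with the same covariate columns.
#' @param covariates optional explicit covariate names; defaults to the
#'   shared numeric covariate columns.
#' @return A tibble of class `aqrisk_mess`, one row per query row:
#'   `mess`, `most_dissimilar`, and per-covariate columns `S_<name>`.
#' @export
mess <- function(reference, query, covariates = NULL) {
  covars <- covariates %||%
    intersect(covariate_names(reference), covariate_names(query))
  if (!length(covars)) abort("no shared covariate columns")
  if (nrow(reference) == 0) abort("empty reference table")
  miss <- setdiff(covars, names(query))
  if (length(miss)) {
    abort(paste0("query lacks covariate(s): ", paste(miss, collapse = ", ")))
  }
  smat <- vapply(covars, function(v) {
    ref <- reference[[v]]
    p <- query[[v]]
    m <- min(ref)
    M <- max(ref)
    if (M == m) {
      return(ifelse(p == m, 0, -Inf))
    }
    f <- vapply(p, function(pi) mean(ref < pi), numeric(1))
    s <- numeric(length(p))
    s[f == 0] <- 100 * (p[f == 0] - m) / (M - m)
    b <- f > 0 & f <= 0.5
    s[b] <- 200 * f[b]
    b <- f > 0.5 & f < 1
    s[b] <- 200 * (1 - f[b])
    s[f == 1] <- 100 * (M - p[f == 1]) / (M - m)
    s
  }, numeric(nrow(query)))
  smat <- matrix(as.vector(smat), nrow = nrow(query), ncol = length(covars),
    dimnames = list(NULL, covars)
  )
  finite_cols <- smat
  if (length(covars) > 1) finite_cols[is.infinite(smat)] <- NA
  mess_val <- apply(finite_cols, 1, function(r) {
    if (all(is.na(r))) -Inf else min(r, na.rm = TRUE)
  })
  worst <- apply(smat, 1, function(r) sort(names(r)[r == min(r)])[1])
  out <- tibble::tibble(mess = mess_val, most_dissimilar = worst)
  for (v in covars) out[[paste0("S_", v)]] <- unname(smat[, v])
  if (any(is.infinite(smat))) {
    inform("constant reference covariate mismatched in query (-Inf similarity reported)")
  }
  class(out) <- c("aqrisk_mess", class(out))
  out
}
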