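#' Fit the component models of a weighted ensemble
#'
#' Trains every member on a random 80% of the catchment-year table
#' (stratified by class for classification) and scores each on the withheld
#' 20%: AUC for occurrence classification, mean absolute error for
#' admixture regression. Skill-proportional weights are attached via
#' [compute_weights()].
#'
#' @param table design table with a `presence` (classification) or
#'   `admixture` (regression) response column plus numeric covariates
#'   (key columns `huc_id`, `year`, `n_records` are ignored as predictors).
#' @param task `"classification"` or `"regression"`.
#' @param specs model specifications from [model_specs()]; defaults to all
#'   six members for the given task.
#' @param holdout_fraction fraction withheld for skill scoring (default 0.2).
#' @param seed integer seed: controls the split and all member fits.
#' @param refit_full if `TRUE`, members are refit on the full table after
#'   skills are scored on the 80/20 split, so predictions use every row
#'   while weights remain based on withheld data (used by [cv_accuracy()],
#'   where the fold's held segment provides the unbiased test).
#' @return An object of class `aqrisk_ensemble`: `$members` is a tibble
#'   `(name, fit, skill, weight, status, reason)`; the training table and
#'   split indices are kept for the diagnostics module.
#' @export
fit_members <- function(table, task = c("classification", "regression"),
                        specs = NULL, holdout_fraction = 0.2, seed = 1L,
                        refit_full = FALSE) {
  task <- match.arg(task)
  table <- tibble::as_tibble(table)
  specs <- specs %||% model_specs(task, seed = seed)
  stopifnot(all(vapply(specs, function(s) identical(s$task, task), logical(1))))
  response <- if (task == "classification") "presence" else "admixture"
  if (!response %in% names(table)) {
    abort(paste0("table lacks the '", response, "' response column"))
  }
  if (nrow(table) < 30) abort("need at least 30 rows to fit the ensemble")
  covars <- covariate_names(table)
  if (!length(covars)) abort("no covariate columns found")
  nonfin <- covars[!vapply(table[covars], function(x) all(is.finite(x)), logical(1))]
  if (length(nonfin)) {
    abort(paste0("non-finite covariate(s): ", paste(nonfin, collapse = ", ")))
  }
  y <- table[[response]]
  if (task == "classification") {
    y <- as.logical(y)
    if (length(unique(y)) < 2) abort("single-class training data")
  }
  holdout_idx <- withr::with_seed(as.integer(seed), {
    if (task == "classification") {
      unlist(lapply(split(seq_along(y), y), function(idx) {
        sample(idx, max(1, round(length(idx) * holdout_fraction)))
      }), use.names = FALSE)
    } else {
      sample(seq_along(y), max(1, round(length(y) * holdout_fraction)))
    }
  })
  train_idx <- setdiff(seq_len(nrow(table)), holdout_idx)
  xtr <- as.data.frame(table[train_idx, covars, drop = FALSE])
  ytr <- y[train_idx]
  if (task == "classification" && length(unique(ytr)) < 2) {
    abort("single-class training split")
  }
  members <- lapply(specs, fit_member, x = xtr, y = ytr)
  skill <- vapply(
    members, member_skill,
    numeric(1),
    newdata = table[holdout_idx, covars, drop = FALSE],
    y = y[holdout_idx]
  )
  if (refit_full) {
    members <- lapply(specs, fit_member,
      x = as.data.frame(table[, covars, drop = FALSE]), y = y
    )
  }
  tbl <- tibble::tibble(
    name = vapply(members, `[[`, "", "name"),
    fit = members,
    skill = skill,
    weight = 0,
    status = ifelse(is.na(skill), "culled", "retained"),
    reason = ifelse(is.na(skill), "undefined skill", NA_character_)
  )
  ens <- structure(
    list(
      task = task, response = response, covariates = covars,
      members = tbl, data = table,
      train_idx = train_idx, holdout_idx = holdout_idx,
      threshold = 0.5, seed = as.integer(seed)
    ),
    class = "aqrisk_ensemble"
  )
  reweight(ens)
}

#' Skill-proportional ensemble weights
#'
#' Classification members are weighted proportionally to their AUC;
#' regression members proportionally to inverse MAE (lower error, higher
#' weight). A regression member with zero MAE (a degenerate perfect fit)
#' absorbs all weight, shared equally if several, and is reported.
#'
#' @param skill numeric vector of member skills (AUC or MAE) for the
#'   retained members.
#' @param task `"classification"` or `"regression"`.
#' @return Numeric weights summing to 1.
#' @export
compute_weights <- function(skill, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (!length(skill)) abort("empty ensemble")
  if (anyNA(skill)) abort("every retained member needs a finite skill")
  if (task == "classification") {
    skill / sum(skill)
  } else {
    if (any(skill == 0)) {
      inform("member(s) with zero MAE get all ensemble weight")
      w <- as.numeric(skill == 0)
      w / sum(w)
    } else {
      (1 / skill) / sum(1 / skill)
    }
  }
}

reweight <- function(ensemble) {
  keep <- ensemble$members$status == "retained"
  if (!any(keep)) abort("empty ensemble")
  ensemble$members$weight <- 0
  ensemble$members$weight[keep] <-
    compute_weights(ensemble$members$skill[keep], ensemble$task)
  ensemble
}

retained_members <- function(ensemble) {
  ensemble$members[ensemble$members$status == "retained", , drop = FALSE]
}

#' Cull degenerate ensemble members
#'
#' A classifier is culled iff its predicted class is identical across every
#' unit of every supplied prediction window (it carries no spatial or
#' temporal signal). A regressor is culled iff its predictions are constant
#' across units, or fall outside \[0, 1\] for a proportion-valued response.
#' Weights are recomputed over the survivors.
#'
#' @param ensemble an [fit_members()] result.
#' @param windows list of window covariate tables (see [predict_window()]).
#' @return The ensemble with updated member statuses, reasons and weights.
#' @export
cull_degenerate <- function(ensemble, windows) {
  if (!length(windows)) abort("need at least one prediction window")
  for (i in seq_len(nrow(ensemble$members))) {
    if (ensemble$members$status[i] != "retained") next
    member <- ensemble$members$fit[[i]]
    preds <- unlist(lapply(windows, function(w) predict_member(member, w)))
    if (ensemble$task == "classification") {
      cls <- preds >= ensemble$threshold
      if (length(unique(cls)) == 1) {
        ensemble$members$status[i] <- "culled"
        ensemble$members$reason[i] <- "no variation"
      }
    } else {
      if (diff(range(preds)) < 1e-12) {
        ensemble$members$status[i] <- "culled"
        ensemble$members$reason[i] <- "no variation"
      } else if (any(preds < 0 | preds > 1)) {
        ensemble$members$status[i] <- "culled"
        ensemble$members$reason[i] <- "out of range"
      }
    }
  }
  reweight(ensemble)
}

#' Ensemble prediction over a window covariate table
#'
#' The window table holds one row per catchment with per-unit mean
#' covariates over the window's years. Each retained member predicts a
#' probability (or admixture); the ensemble value is the weight-averaged
#' member prediction and the per-unit uncertainty is the sample standard
#' deviation of the member predictions (0 for a single member).
#'
#' @param ensemble an [fit_members()] result.
#' @param window tibble with `huc_id` plus the training covariates.
#' @param label optional window label (e.g. `"2002-2010"`).
#' @return A tibble of class `aqrisk_map`: `huc_id`, `prob` (or `pred` for
#'   regression), `sd`, `n_members`, and per-member columns `p_<name>`.
#' @export
predict_window <- function(ensemble, window, label = NULL) {
  window <- tibble::as_tibble(window)
  miss <- setdiff(ensemble$covariates, names(window))
  if (length(miss)) {
    abort(paste0("missing covariate column(s): ", paste(miss, collapse = ", ")))
  }
  mem <- retained_members(ensemble)
  pm <- vapply(
    mem$fit, predict_member, numeric(nrow(window)),
    newdata = window[, ensemble$covariates, drop = FALSE]
  )
  pm <- matrix(pm, nrow = nrow(window), ncol = nrow(mem))
  ens_val <- as.numeric(pm %*% mem$weight)
  sdv <- if (ncol(pm) == 1) rep(0, nrow(pm)) else apply(pm, 1, sd)
  out <- tibble::tibble(
    huc_id = window$huc_id,
    value = ens_val, sd = sdv, n_members = ncol(pm)
  )
  names(out)[2] <- if (ensemble$task == "classification") "prob" else "pred"
  for (j in seq_len(ncol(pm))) out[[paste0("p_", mem$name[j])]] <- pm[, j]
  class(out) <- c("aqrisk_map", class(out))
  attr(out, "task") <- ensemble$task
  attr(out, "window") <- label
  out
}

#' Per-catchment suitability change between two windows
#'
#' Raw change is late minus early; normalized change rescales the raw
#' deltas over units to \[-1, 1\] by dividing by the maximum absolute
#' delta (all zeros stay zero).
#'
#' @param map_late,map_early [predict_window()] results on the same units.
#' @return Tibble `(huc_id, delta, delta_norm)`.
#' @export
change_map <- function(map_late, map_early) {
  only_late <- setdiff(map_late$huc_id, map_early$huc_id)
  only_early <- setdiff(map_early$huc_id, map_late$huc_id)
  if (length(only_late) || length(only_early)) {
    abort(paste0(
      "unit sets differ; only in late: {",
      paste(only_late, collapse = ", "), "}; only in early: {",
      paste(only_early, collapse = ", "), "}"
    ))
  }
  vcol <- function(m) if ("prob" %in% names(m)) m$prob else m$pred
  late <- vcol(map_late)
  early <- vcol(map_early)[match(map_late$huc_id, map_early$huc_id)]
  delta <- late - early
  mx <- max(abs(delta))
  tibble::tibble(
    huc_id = map_late$huc_id,
    delta = delta,
    delta_norm = if (mx == 0) rep(0, length(delta)) else delta / mx
  )
}

#' k-fold cross-validated ensemble accuracy
#'
#' Partitions the table into k stratified segments of (near-)equal size.
#' For each fold, all members are fit on the other k - 1 segments (an
#' internal 80/20 split of those segments provides the training-side AUC
#' used for weighting, after which members are refit on all k - 1
#' segments), and the weighted ensemble predicts the held segment at the
#' classification threshold; the fraction of correct predictions is
#' recorded and averaged over folds.
#'
#' @inheritParams fit_members
#' @param k number of folds (default 30).
#' @param threshold classification threshold (default 0.5).
#' @return List of class `aqrisk_cv`: `mean_accuracy`, `fold_accuracy`,
#'   `k`, `n`.
#' @export
cv_accuracy <- function(table, specs = NULL, k = 30, seed = 1L,
                        holdout_fraction = 0.2, threshold = 0.5) {
  table <- tibble::as_tibble(table)
  n <- nrow(table)
  if (k > n) abort(sprintf("k = %d exceeds the %d available rows", k, n))
  y <- as.logical(table$presence)
  folds <- withr::with_seed(as.integer(seed), {
    # deal fold ids cyclically over class-shuffled rows: folds are balanced
    # in size, every fold is non-empty, and classes spread across folds
    ord <- unlist(lapply(split(seq_len(n), y), sample), use.names = FALSE)
    f <- integer(n)
    f[ord] <- rep_len(seq_len(k), n)
    f
  })
  acc <- vapply(seq_len(k), function(fold) {
    tr <- table[folds != fold, , drop = FALSE]
    te <- table[folds == fold, , drop = FALSE]
    ens <- fit_members(tr, "classification",
      specs = specs, holdout_fraction = holdout_fraction,
      seed = as.integer(seed) + fold, refit_full = TRUE
    )
    if (!"huc_id" %in% names(te)) te$huc_id <- as.character(seq_len(nrow(te)))
    p <- predict_window(ens, te)
    mean((p$prob >= threshold) == te$presence)
  }, numeric(1))
  structure(
    list(mean_accuracy = mean(acc), fold_accuracy = acc, k = k, n = n),
    class = "aqrisk_cv"
  )
}

#' @export
print.aqrisk_cv <- function(x, ...) {
  cat(sprintf(
    "<aqrisk_cv> %d-fold accuracy %.3f (fold range %.3f..%.3f, n = %d)\n",
    x$k, x$mean_accuracy, min(x$fold_accuracy), max(x$fold_accuracy), x$n
  ))
  invisible(x)
}

#' @export
print.aqrisk_ensemble <- function(x, ...) {
  cat(sprintf(
    "<aqrisk_ensemble> %s on %d rows, %d covariates\n",
    x$task, nrow(x$data), length(x$covariates)
  ))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aqrisk_ensemble <- function(x, ...) {
  dplyr::select(x$members, "name", "skill", "weight", "status", "reason")
}

#' @exportS3Method generics::glance
glance.aqrisk_ensemble <- function(x, ...) {
  mem <- retained_members(x)
  tibble::tibble(
    task = x$task,
    n_obs = nrow(x$data),
    n_covariates = length(x$covariates),
    n_members = nrow(x$members),
    n_retained = nrow(mem),
    best_member = mem$name[order(
      if (x$task == "classification") -mem$skill else mem$skill
    )][1],
    best_skill = if (x$task == "classification") max(mem$skill) else min(mem$skill)
  )
}
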