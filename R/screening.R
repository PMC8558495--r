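#' Covariate screening configuration
#'
#' @param pearson_threshold pairs with absolute Pearson correlation above
#'   this are collinear; one member is dropped (default 0.7).
#' @param dependence_threshold the dependence-pruning loop stops when every
#'   remaining covariate's feature-dependence score (out-of-bag R-squared of
#'   predicting it from the other covariates) is at or below this value
#'   (default 0.6).
#' @param dependence_trees trees per random-forest dependence fit
#'   (default 200).
#' @param dependence_model_seed seed for the dependence fits (default 1).
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(pearson_threshold = 0.7,
                             dependence_threshold = 0.6,
                             dependence_trees = 200,
                             dependence_model_seed = 1L) {
  stopifnot(
    pearson_threshold > 0, pearson_threshold < 1,
    dependence_threshold > 0, dependence_threshold < 1,
    dependence_trees >= 1
  )
  structure(
    list(
      pearson_threshold = pearson_threshold,
      dependence_threshold = dependence_threshold,
      dependence_trees = as.integer(dependence_trees),
      dependence_model_seed = as.integer(dependence_model_seed)
    ),
    class = "screening_config"
  )
}

# Columns of a design table that act as covariates: numeric, and not a key
# or response column.
covariate_names <- function(table) {
  reserved <- c("huc_id", "year", "presence", "admixture", "n_records", "id")
  nm <- setdiff(names(table), reserved)
  nm[vapply(table[nm], is.numeric, logical(1))]
}

new_screening_report <- function(table, dropped, retained) {
  structure(
    list(table = table, dropped = dropped, retained = retained),
    class = "aqrisk_screening"
  )
}

#' @export
print.aqrisk_screening <- function(x, ...) {
  cat(sprintf(
    "<aqrisk_screening> %d covariate(s) retained, %d dropped\n",
    length(x$retained), nrow(x$dropped)
  ))
  if (nrow(x$dropped)) print(x$dropped)
  invisible(x)
}

drop_log <- function(variable = character(), stage = character(),
                     score = numeric(), partner = character()) {
  tibble::tibble(
    variable = variable, stage = stage,
    score = score, partner = partner
  )
}

#' Stage 1: prune linearly correlated covariates
#'
#' Among each covariate pair with absolute Pearson correlation above the
#' threshold, one member is dropped: pairs are visited in descending |r|,
#' and the member with the larger mean absolute correlation against all
#' other remaining covariates is removed (alphabetical on ties). Constant
#' columns are dropped first with a report entry.
#'
#' @param table design table (see [build_design_table()]); key and response
#'   columns are passed through untouched.
#' @param cfg a [screening_config()].
#' @param covariates optional explicit covariate column names.
#' @return An `aqrisk_screening` report: `$table` (screened), `$dropped`
#'   (ordered log of `(variable, stage, score, partner)`), `$retained`.
#' @export
pearson_prune <- function(table, cfg = screening_config(), covariates = NULL) {
  covars <- covariates %||% covariate_names(table)
  if (length(covars) < 2) abort("pearson_prune() needs at least 2 covariate columns")
  log <- drop_log()
  sds <- vapply(table[covars], sd, numeric(1))
  const <- covars[sds == 0 | is.na(sds)]
  for (v in const) {
    log <- dplyr::bind_rows(log, drop_log(v, "constant", NA_real_, NA_character_))
  }
  retained <- setdiff(covars, const)
  while (length(retained) >= 2) {
    cm <- abs(cor(table[retained]))
    diag(cm) <- 0
    if (max(cm) <= cfg$pearson_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)
    pair <- sort(retained[idx[1, ]])
    # mean |r| of each member against the other remaining covariates
    mean_abs <- rowMeans(cm[pair, , drop = FALSE])
    victim <- if (abs(diff(mean_abs)) < 1e-12) pair[2] else
      pair[which.max(mean_abs)]
    partner <- setdiff(pair, victim)
    log <- dplyr::bind_rows(
      log, drop_log(victim, "pearson", max(cm), partner)
    )
    retained <- setdiff(retained, victim)
  }
  kept_cols <- setdiff(names(table), setdiff(covars, retained))
  new_screening_report(table[, kept_cols, drop = FALSE], log, retained)
}

# Feature-dependence score of each covariate: out-of-bag R-squared of a
# random-forest regression predicting it from the other covariates.
dependence_scores <- function(table, covars, cfg) {
  vapply(covars, function(v) {
    predictors <- setdiff(covars, v)
    fit <- ranger::ranger(
      x = table[, predictors, drop = FALSE],
      y = table[[v]],
      num.trees = cfg$dependence_trees,
      # all predictors considered at every split, as in the regression-forest
      # feature-dependence formulation this score follows
      mtry = length(predictors),
      seed = cfg$dependence_model_seed,
      num.threads = 1
    )
    fit$r.squared
  }, numeric(1))
}

#' Stage 2: prune nonlinearly dependent covariates
#'
#' Iteratively fits a random-forest regression predicting each covariate
#' from the others and records its out-of-bag R-squared as the covariate's
#' feature-dependence score. While the maximum score exceeds the threshold,
#' the single worst offender is dropped (alphabetical on ties) and all
#' scores are recomputed; dropping one covariate per iteration avoids
#' over-pruning mutually dependent groups. Deterministic given the seed.
#'
#' @inheritParams pearson_prune
#' @return An `aqrisk_screening` report (see [pearson_prune()]).
#' @export
dependence_prune <- function(table, cfg = screening_config(),
                             covariates = NULL) {
  covars <- covariates %||% covariate_names(table)
  bad <- covars[!vapply(table[covars], function(x) all(is.finite(x)), logical(1))]
  if (length(bad)) {
    abort(paste0("non-finite values in covariate(s): ", paste(bad, collapse = ", ")))
  }
  if (nrow(table) < 5 * length(covars)) {
    warn(sprintf(
      "only %d rows for %d covariates; dependence scores may be unstable",
      nrow(table), length(covars)
    ))
  }
  log <- drop_log()
  retained <- covars
  while (length(retained) >= 2) {
    scores <- dependence_scores(table, retained, cfg)
    if (max(scores) <= cfg$dependence_threshold) break
    worst <- sort(names(scores)[scores == max(scores)])[1]
    log <- dplyr::bind_rows(
      log, drop_log(worst, "dependence", max(scores), NA_character_)
    )
    retained <- setdiff(retained, worst)
  }
  kept_cols <- setdiff(names(table), setdiff(covars, retained))
  new_screening_report(table[, kept_cols, drop = FALSE], log, retained)
}

#' Run both screening stages
#'
#' Pearson pruning followed by feature-dependence pruning; the combined
#' drop log preserves order across stages.
#'
#' @inheritParams pearson_prune
#' @return An `aqrisk_screening` report with the combined drop log.
#' @export
screen_covariates <- function(table, cfg = screening_config(),
                              covariates = NULL) {
  s1 <- pearson_prune(table, cfg, covariates)
  s2 <- dependence_prune(s1$table, cfg, s1$retained)
  rep <- new_screening_report(
    s2$table, dplyr::bind_rows(s1$dropped, s2$dropped), s2$retained
  )
  attr(rep$table, "screened") <- TRUE
  rep
}

#' @exportS3Method generics::tidy
tidy.aqrisk_screening <- function(x, ...) x$dropped

#' @exportS3Method generics::glance
glance.aqrisk_screening <- function(x, ...) {
  tibble::tibble(
    n_retained = length(x$retained),
    n_dropped = nrow(x$dropped),
    n_dropped_pearson = sum(x$dropped$stage == "pearson"),
    n_dropped_dependence = sum(x$dropped$stage == "dependence"),
    n_dropped_constant = sum(x$dropped$stage == "constant")
  )
}
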