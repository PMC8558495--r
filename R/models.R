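# Component model wrappers.
#
# Six member families, each usable for occurrence classification (predicts
# a probability) or admixture regression (predicts a proportion-scale
# value). Library defaults are used throughout, with no tuning:
#   GLM - logistic / ordinary linear regression (stats)
#   CTA - classification and regression tree (rpart)
#   GBM - gradient boosted trees (xgboost, classic slow-learning profile:
#         eta 0.1, depth 3, 100 rounds)
#   RF  - random forest (ranger, 500 trees)
#   XGB - XGBoost defaults (eta 0.3, depth 6, 100 rounds)
#   ANN - single-hidden-layer neural network (nnet, 5 units, decay 0.01,
#         standardized inputs)

MEMBER_NAMES <- c("GLM", "CTA", "GBM", "RF", "XGB", "ANN")

#' Component model specifications
#'
#' @param task `"classification"` or `"regression"`.
#' @param members subset of `c("GLM", "CTA", "GBM", "RF", "XGB", "ANN")`.
#' @param seed base seed; member i trains with `seed + i`.
#' @param hyperparameters named list (by member) of parameter overrides.
#' @return A list of model specs (name, task, params, seed).
#' @export
model_specs <- function(task = c("classification", "regression"),
                        members = MEMBER_NAMES, seed = 1L,
                        hyperparameters = list()) {
  task <- match.arg(task)
  members <- match.arg(members, MEMBER_NAMES, several.ok = TRUE)
  if (anyDuplicated(members)) abort("member names must be unique")
  lapply(seq_along(members), function(i) {
    list(
      name = members[i], task = task,
      params = hyperparameters[[members[i]]] %||% list(),
      seed = as.integer(seed) + i
    )
  })
}

fit_member <- function(spec, x, y) {
  stopifnot(is.data.frame(x))
  task <- spec$task
  p <- spec$params
  fit <- withr::with_seed(spec$seed, switch(spec$name,
    GLM = {
      df <- cbind(x, .y = as.numeric(y))
      if (task == "classification") {
        suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      } else {
        lm(.y ~ ., data = df)
      }
    },
    CTA = {
      df <- cbind(x, .y = if (task == "classification") {
        factor(y, levels = c(FALSE, TRUE))
      } else {
        as.numeric(y)
      })
      rpart::rpart(.y ~ ., data = df,
        method = if (task == "classification") "class" else "anova"
      )
    },
    RF = ranger::ranger(
      x = x,
      y = if (task == "classification") factor(y, levels = c(FALSE, TRUE)) else y,
      probability = task == "classification",
      num.trees = p$num.trees %||% 500,
      seed = spec$seed, num.threads = 1
    ),
    GBM = xgb_fit(x, y, task,
      eta = p$eta %||% 0.1, max_depth = p$max_depth %||% 3,
      nrounds = p$nrounds %||% 100, seed = spec$seed
    ),
    XGB = xgb_fit(x, y, task,
      eta = p$eta %||% 0.3, max_depth = p$max_depth %||% 6,
      nrounds = p$nrounds %||% 100, seed = spec$seed
    ),
    ANN = {
      ctr <- vapply(x, mean, numeric(1))
      scl <- vapply(x, sd, numeric(1))
      scl[scl == 0] <- 1
      xs <- sweep(sweep(as.matrix(x), 2, ctr), 2, scl, "/")
      net <- suppressWarnings(nnet::nnet(
        xs, as.numeric(y),
        size = p$size %||% 5, decay = p$decay %||% 0.01,
        maxit = p$maxit %||% 200,
        linout = task == "regression",
        entropy = task == "classification",
        trace = FALSE
      ))
      list(net = net, center = ctr, scale = scl)
    },
    abort(paste0("unknown member: ", spec$name))
  ))
  structure(
    list(name = spec$name, task = task, fit = fit, covariates = names(x),
         params = p, seed = spec$seed),
    class = "aqrisk_member"
  )
}

# Boosters are kept as serialized raw bytes and materialized per
# prediction: the live xgb.Booster holds an external pointer that is not
# safe to retain across garbage collections in long-lived member lists.
xgb_fit <- function(x, y, task, eta, max_depth, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = as.numeric(y))
  bst <- xgboost::xgb.train(
    params = list(
      eta = eta, max_depth = max_depth,
      objective = if (task == "classification") {
        "binary:logistic"
      } else {
        "reg:squarederror"
      },
      nthread = 1, seed = seed
    ),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(raw = xgboost::xgb.save.raw(bst)), class = "aqrisk_xgb")
}

xgb_predict <- function(fit, x) {
  bst <- xgboost::xgb.load.raw(fit$raw)
  as.numeric(predict(bst, xgboost::xgb.DMatrix(as.matrix(x))))
}

# Numeric prediction (probability for classification members) on new data;
# columns are matched by name.
predict_member <- function(member, newdata) {
  miss <- setdiff(member$covariates, names(newdata))
  if (length(miss)) {
    abort(paste0("missing covariate column(s): ", paste(miss, collapse = ", ")))
  }
  x <- as.data.frame(newdata)[, member$covariates, drop = FALSE]
  fit <- member$fit
  out <- switch(member$name,
    GLM = if (member$task == "classification") {
      as.numeric(predict(fit, x, type = "response"))
    } else {
      as.numeric(predict(fit, x))
    },
    CTA = if (member$task == "classification") {
      as.numeric(predict(fit, x, type = "prob")[, "TRUE"])
    } else {
      as.numeric(predict(fit, x))
    },
    RF = if (member$task == "classification") {
      as.numeric(predict(fit, data = x, num.threads = 1)$predictions[, "TRUE"])
    } else {
      as.numeric(predict(fit, data = x, num.threads = 1)$predictions)
    },
    GBM = ,
    XGB = xgb_predict(fit, x),
    ANN = {
      xs <- sweep(sweep(as.matrix(x), 2, fit$center), 2, fit$scale, "/")
      as.numeric(predict(fit$net, xs))
    }
  )
  unname(out)
}

# Holdout skill: AUC for classification (larger is better), MAE for
# regression (smaller is better).
member_skill <- function(member, newdata, y) {
  p <- predict_member(member, newdata)
  if (member$task == "classification") {
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(
      response = y, predictor = p,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
    ))
  } else {
    mean(abs(p - y))
  }
}
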