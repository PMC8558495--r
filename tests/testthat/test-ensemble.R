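# Root-only tree member that predicts a constant probability p on any input.
constant_prob_member <- function(p, n = 30) {
  y <- rep(c(TRUE, FALSE), round(c(p, 1 - p) * n))
  x <- data.frame(x1 = seq_along(y) * 0) # constant covariate: root tree
  aqrisk:::fit_member(
    list(name = "CTA", task = "classification", params = list(), seed = 1),
    x, y
  )
}

# Hand-assembled two-member ensemble with known weights.
toy_ensemble <- function(p1, p2, w = c(0.5, 0.5)) {
  m1 <- constant_prob_member(p1)
  m2 <- constant_prob_member(p2)
  structure(
    list(
      task = "classification", response = "presence", covariates = "x1",
      members = tibble::tibble(
        name = c("A", "B"), fit = list(m1, m2), skill = c(0.8, 0.8),
        weight = w, status = "retained", reason = NA_character_
      ),
      threshold = 0.5
    ),
    class = "aqrisk_ensemble"
  )
}

test_that("AUC weights are skill-proportional and inverse-MAE weights favour low error", {
  expect_equal(compute_weights(c(0.8, 0.8), "classification"), c(0.5, 0.5))
  expect_equal(compute_weights(c(0.05, 0.10), "regression"), c(2 / 3, 1 / 3))
  expect_equal(compute_weights(0.9, "classification"), 1)
  expect_equal(compute_weights(0.2, "regression"), 1)
  expect_message(
    w <- compute_weights(c(0, 0.1), "regression"),
    "zero MAE"
  )
  expect_equal(w, c(1, 0))
  expect_error(compute_weights(numeric(0), "classification"), "empty ensemble")
  expect_error(compute_weights(c(0.8, NA), "classification"), "finite")
  # weights of any skill vector sum to one
  for (s in 1:5) {
    sk <- withr::with_seed(s, runif(4, 0.5, 1))
    expect_equal(sum(compute_weights(sk, "classification")), 1)
    expect_equal(sum(compute_weights(sk, "regression")), 1)
  }
})

test_that("perfectly separable data gives every member unit AUC", {
  tbl <- separable_table(60)
  ens <- fit_members(tbl, "classification", seed = 3)
  expect_equal(ens$members$skill, rep(1, 6), tolerance = 1e-9)
  expect_equal(sum(ens$members$weight), 1)
})

test_that("member AUC is at chance when the response is independent of covariates", {
  aucs <- vapply(1:20, function(s) {
    tbl <- withr::with_seed(s, tibble::tibble(
      presence = sample(c(TRUE, FALSE), 400, replace = TRUE),
      x1 = rnorm(400), x2 = rnorm(400), x3 = rnorm(400)
    ))
    ens <- fit_members(tbl, "classification",
      specs = model_specs("classification", c("GLM", "CTA"), seed = s),
      seed = s
    )
    mean(ens$members$skill)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("a random forest beats the untrained mean predictor on y = x", {
  tbl <- withr::with_seed(1, {
    x <- runif(100)
    tibble::tibble(admixture = x, x1 = x, x2 = rnorm(100))
  })
  ens <- fit_members(tbl, "regression",
    specs = model_specs("regression", "RF", seed = 1), seed = 1
  )
  hold <- tbl[ens$holdout_idx, ]
  mae_null <- mean(abs(mean(tbl$admixture[ens$train_idx]) - hold$admixture))
  expect_lt(ens$members$skill, mae_null)
})

test_that("single-class data and non-finite covariates are rejected", {
  tbl <- separable_table(40)
  tbl$presence <- TRUE
  expect_error(fit_members(tbl, "classification"), "single-class")
  tbl2 <- separable_table(40)
  tbl2$x1[3] <- NA
  expect_error(fit_members(tbl2, "classification"), "x1")
})

test_that("fits are deterministic given the seed", {
  tbl <- separable_table(80, seed = 9)
  e1 <- fit_members(tbl, "classification", seed = 5)
  e2 <- fit_members(tbl, "classification", seed = 5)
  w <- tibble::tibble(huc_id = "u", x1 = 0.3, x2 = 0, x3 = 0, x4 = 0)
  expect_identical(predict_window(e1, w), predict_window(e2, w))
})

test_that("a constant-class member is culled with its reason recorded", {
  ens <- toy_ensemble(0.9, 0.5)
  # member A predicts 0.9 everywhere -> always class TRUE -> no variation;
  # member B predicts 0.5 -> also constant class
  tbl1 <- withr::with_seed(1, {
    x1 <- c(rnorm(30, -3), rnorm(30, 3))
    tibble::tibble(presence = x1 > 0, x1 = x1)
  })
  varying <- fit_members(tbl1, "classification",
    specs = model_specs("classification", "GLM", seed = 1), seed = 1
  )$members$fit[[1]]
  ens$members <- dplyr::bind_rows(
    ens$members,
    tibble::tibble(
      name = "C", fit = list(varying), skill = 1, weight = 0,
      status = "retained", reason = NA_character_
    )
  )
  w1 <- tibble::tibble(huc_id = letters[1:5], x1 = c(-4, -2, 0, 2, 4))
  out <- cull_degenerate(ens, list(w1))
  expect_equal(out$members$status, c("culled", "culled", "retained"))
  expect_equal(out$members$reason[1:2], c("no variation", "no variation"))
  expect_equal(out$members$weight, c(0, 0, 1))
})

test_that("regressors are culled when constant or outside the proportion range", {
  mk <- function(y, x) {
    aqrisk:::fit_member(
      list(name = "GLM", task = "regression", params = list(), seed = 1),
      data.frame(x1 = x), y
    )
  }
  x <- seq(0, 1, length.out = 20)
  members <- tibble::tibble(
    name = c("const", "high", "ok"),
    fit = list(
      mk(rep(1.2179, 20), x), # constant, and out of range
      mk(1.1 + 0.2 * x, x),   # varying but above 1
      mk(0.2 + 0.5 * x, x)    # well-behaved
    ),
    skill = c(0.1, 0.1, 0.1), weight = 1 / 3,
    status = "retained", reason = NA_character_
  )
  ens <- structure(
    list(task = "regression", response = "admixture", covariates = "x1",
         members = members, threshold = 0.5),
    class = "aqrisk_ensemble"
  )
  out <- cull_degenerate(ens, list(tibble::tibble(huc_id = letters[1:4], x1 = c(0, 0.3, 0.6, 1))))
  expect_equal(out$members$status, c("culled", "culled", "retained"))
  expect_equal(out$members$reason, c("no variation", "out of range", NA))
  expect_equal(out$members$weight, c(0, 0, 1))
  expect_error(
    cull_degenerate(ens, list()),
    "at least one"
  )
})

test_that("window prediction is the weighted member mean with sample-sd spread", {
  ens <- toy_ensemble(0.2, 0.8)
  w <- tibble::tibble(huc_id = c("u1", "u2"), x1 = c(0, 1))
  out <- predict_window(ens, w, label = "2002-2010")
  expect_equal(out$prob, c(0.5, 0.5))
  expect_equal(out$sd, rep(sd(c(0.2, 0.8)), 2))
  expect_equal(out$sd, rep(0.4242641, 2), tolerance = 1e-6)
  expect_equal(out$n_members, c(2L, 2L))
  expect_equal(attr(out, "window"), "2002-2010")

  # single retained member reproduces that member with zero spread
  ens$members$status[2] <- "culled"
  ens$members$weight <- c(1, 0)
  out1 <- predict_window(ens, w)
  expect_equal(out1$prob, c(0.2, 0.2))
  expect_equal(out1$sd, c(0, 0))
})

test_that("missing window covariates are reported by name", {
  ens <- toy_ensemble(0.2, 0.8)
  expect_error(
    predict_window(ens, tibble::tibble(huc_id = "u", other = 1)),
    "x1"
  )
})

test_that("the ensemble probability is a convex combination of member probabilities", {
  tbl <- separable_table(80, seed = 2)
  ens <- fit_members(tbl, "classification", seed = 2)
  w <- tibble::tibble(
    huc_id = sprintf("u%d", 1:10),
    x1 = seq(-3, 3, length.out = 10), x2 = 0, x3 = 0, x4 = 0
  )
  out <- predict_window(ens, w)
  pm <- as.matrix(out[, grep("^p_", names(out))])
  expect_true(all(out$prob >= apply(pm, 1, min) - 1e-12))
  expect_true(all(out$prob <= apply(pm, 1, max) + 1e-12))
})

test_that("removing a member never changes the others' predictions", {
  tbl <- separable_table(80, seed = 4)
  ens <- fit_members(tbl, "classification", seed = 4)
  w <- tibble::tibble(huc_id = "u", x1 = 0.7, x2 = 0.1, x3 = -0.2, x4 = 0)
  before <- predict_window(ens, w)
  ens$members$status[1] <- "culled"
  ens <- aqrisk:::reweight(ens)
  after <- predict_window(ens, w)
  shared <- intersect(grep("^p_", names(before), value = TRUE),
    grep("^p_", names(after), value = TRUE)
  )
  expect_identical(before[shared], after[shared])
  expect_equal(sum(ens$members$weight), 1)
})

test_that("change maps difference and rescale by the largest absolute delta", {
  m <- function(ids, p) {
    out <- tibble::tibble(huc_id = ids, prob = p, sd = 0, n_members = 1L)
    class(out) <- c("aqrisk_map", class(out))
    out
  }
  same <- change_map(m(c("a", "b"), c(0.4, 0.6)), m(c("a", "b"), c(0.4, 0.6)))
  expect_equal(same$delta, c(0, 0))
  expect_equal(same$delta_norm, c(0, 0))

  ch <- change_map(m(c("a", "b"), c(0.5, 0.1)), m(c("a", "b"), c(0.3, 0.5)))
  expect_equal(ch$delta, c(0.2, -0.4))
  expect_equal(ch$delta_norm, c(0.5, -1))

  one <- change_map(m("a", 0.8), m("a", 0.5))
  expect_equal(one$delta_norm, 1)

  expect_error(
    change_map(m(c("a", "x"), c(0.1, 0.2)), m(c("a", "b"), c(0.1, 0.2))),
    "x.*b"
  )
})

test_that("cross-validated accuracy is perfect on separable data and k is validated", {
  tbl <- separable_table(80, seed = 6)
  cv <- cv_accuracy(tbl, specs = fast_specs(seed = 6), k = 8, seed = 6)
  expect_equal(cv$mean_accuracy, 1)
  expect_length(cv$fold_accuracy, 8)
  expect_error(cv_accuracy(tbl, k = 100, seed = 1), "exceeds")
})

test_that("leave-one-out degenerates to a mean of binary outcomes", {
  tbl <- separable_table(40, seed = 8)
  cv <- cv_accuracy(tbl, specs = model_specs("classification", "GLM", seed = 8),
    k = 40, seed = 8
  )
  expect_true(all(cv$fold_accuracy %in% c(0, 1)))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
})

test_that("tree-based members outrank the linear model on interaction-driven data", {
  wins <- 0
  for (s in 1:10) {
    tbl <- withr::with_seed(s, {
      x1 <- rnorm(300); x2 <- rnorm(300)
      tibble::tibble(
        presence = runif(300) < plogis(3 * x1 * x2),
        x1 = x1, x2 = x2, x3 = rnorm(300)
      )
    })
    ens <- fit_members(tbl, "classification",
      specs = model_specs("classification", c("GLM", "CTA", "RF"), seed = s),
      seed = s
    )
    sk <- setNames(ens$members$skill, ens$members$name)
    if (mean(sk[c("CTA", "RF")]) > sk["GLM"]) wins <- wins + 1
  }
  expect_gte(wins, 6)
})

test_that("tidy and glance summarise the fitted ensemble", {
  ens <- fit_members(separable_table(60), "classification", seed = 1)
  td <- tidy(ens)
  expect_equal(names(td), c("name", "skill", "weight", "status", "reason"))
  g <- glance(ens)
  expect_equal(g$n_members, 6L)
  expect_equal(g$task, "classification")
})
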