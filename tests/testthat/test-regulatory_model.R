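test_that("symmetric null data give a potential near one half", {
  set.seed(1)
  X <- matrix(0, 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0, 1), 20)
  fit <- suppressMessages(fit_logit(X, y)) # constant columns dropped
  expect_equal(fit$alpha, 0, tolerance = 1e-8)
  expect_equal(length(fit$beta), 0L)
  expect_equal(predict_potential(fit, X[1:3, , drop = FALSE]),
               rep(0.5, 3), tolerance = 1e-8)
})

test_that("a saturated binary design recovers the closed-form log odds ratio", {
  # x = 1: 30 cases / 10 controls (odds 3); x = 0: 20 / 20 (odds 1)
  X <- matrix(c(rep(1, 40), rep(0, 40)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 20))
  fit <- fit_logit(X, y)
  expect_equal(unname(fit$beta["x"]), log(3), tolerance = 1e-6)
  expect_equal(fit$alpha, 0, tolerance = 1e-6)
})

test_that("predict_potential evaluates the logistic exactly and checks inputs", {
  model <- structure(list(alpha = 1, beta = c(x = 1), feature_names = "x",
                          scaling = NULL), class = "regpot_logit")
  expect_equal(predict_potential(model, c(x = 1)), 1 / (1 + exp(-2)))
  expect_equal(predict_potential(model, c(x = 0, junk = 9)), 1 / (1 + exp(-1)))
  expect_error(predict_potential(model, c(y = 1)), "missing from input: x")
  # potential decreases monotonically as the intercept goes to -Inf
  pots <- vapply(c(0, -2, -5, -20), function(a) {
    m <- model; m$alpha <- a
    predict_potential(m, c(x = 1))
  }, 0)
  expect_true(all(diff(pots) < 0))
  expect_lt(pots[4], 1e-8)
})

test_that("potential increases in every positively weighted feature", {
  model <- structure(list(alpha = -1, beta = c(u = 0.7, v = 1.3),
                          feature_names = c("u", "v"), scaling = NULL),
                     class = "regpot_logit")
  grid <- seq(0, 5, by = 0.5)
  pu <- vapply(grid, function(g) predict_potential(model, c(u = g, v = 1)), 0)
  pv <- vapply(grid, function(g) predict_potential(model, c(u = 1, v = g)), 0)
  expect_true(all(diff(pu) > 0))
  expect_true(all(diff(pv) > 0))
})

test_that("known coefficients are recovered within 3 SE at n = 5000", {
  fx <- make_logit_fixture(5000, alpha = -0.5,
                           beta = c(h = 0.8, s = -0.6, t = 0.4), seed = 42)
  fit <- fit_logit(fx$X, fx$y)
  est <- coef(fit)
  truth <- c(fx$alpha, fx$beta)
  expect_true(all(abs(est - truth) <= 3 * fit$se))
})

test_that("median coefficient error stays under 2 pooled SE over replicates", {
  errs <- c(); ses <- c()
  for (s in 1:20) {
    fx <- make_logit_fixture(5000, alpha = -0.5,
                             beta = c(h = 0.8, s = -0.6), seed = 400 + s)
    fit <- fit_logit(fx$X, fx$y)
    errs <- c(errs, abs(coef(fit) - c(fx$alpha, fx$beta)))
    ses <- c(ses, fit$se)
  }
  expect_lt(median(errs), 2 * mean(ses))
})

test_that("backward stepwise removes noise, keeps signal, and is deterministic", {
  kept_inf <- 0L; dropped_noise <- 0L
  sel1 <- NULL
  for (s in 1:5) {
    set.seed(500 + s)
    n <- 3000
    X <- cbind(inf1 = rbinom(n, 1, 0.3), inf2 = rnorm(n), inf3 = rnorm(n),
               nz1 = rnorm(n), nz2 = rbinom(n, 1, 0.5), nz3 = rnorm(n))
    y <- rbinom(n, 1, plogis(-1 + 0.8 * X[, 1] + 0.5 * X[, 2] - 0.6 * X[, 3]))
    sw <- stepwise_backward_aic(X, y)
    kept_inf <- kept_inf + sum(c("inf1", "inf2", "inf3") %in% sw$selected)
    dropped_noise <- dropped_noise + sum(!c("nz1", "nz2", "nz3") %in% sw$selected)
    full <- fit_logit(X, y)
    expect_lte(sw$model$aic, full$aic)
    if (s == 1L) {
      sel1 <- sw$selected
      sw_again <- stepwise_backward_aic(X, y)
      expect_identical(sw_again$selected, sel1)
    }
  }
  expect_equal(kept_inf, 15L)
  expect_gte(dropped_noise, 10L)
})

test_that("stepwise agrees with the reference backward stepper on clean data", {
  set.seed(77)
  n <- 2500
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = rnorm(n), d = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.9 * X[, "a"] - 0.8 * X[, "b"]))
  sw <- stepwise_backward_aic(X, y)
  ref <- stats::step(stats::glm(y ~ ., binomial(), data.frame(y = y, X)),
                     direction = "backward", trace = 0)
  expect_setequal(sw$selected, setdiff(names(coef(ref)), "(Intercept)"))
  expect_equal(sw$model$aic, stats::AIC(ref), tolerance = 1e-8)
})

test_that("pure-noise designs collapse toward the intercept-only model", {
  set.seed(88)
  n <- 2000
  X <- cbind(n1 = rnorm(n), n2 = rnorm(n), n3 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.3)
  sw <- stepwise_backward_aic(X, y)
  expect_lte(length(sw$selected), 1L)
  expect_lte(sw$model$aic, fit_logit(X, y)$aic)
})

test_that("shared features are those selected in more than half the studies", {
  studies <- c(
    lapply(1:6, function(i) c("DHS_Hit", "H3K4me1_Hit")),
    lapply(1:5, function(i) c("DHS_Hit", "H3K9ac_Intensity"))
  )
  names(studies) <- paste0("study", 1:11)
  rep_ <- feature_selection_report(studies)
  expect_equal(rep_$occurrence[["DHS_Hit"]], 11L)
  expect_equal(rep_$occurrence[["H3K4me1_Hit"]], 6L)
  # 6 of 11 > 5.5 -> in; 5 of 11 -> out; 11 of 11 -> in
  expect_setequal(rep_$shared, c("DHS_Hit", "H3K4me1_Hit"))
  expect_identical(select_shared_features(studies), rep_$shared)
  expect_error(feature_selection_report(studies[1]), "at least 2")
})

test_that("pooling two identical studies reproduces the single-study fit", {
  fx <- make_logit_fixture(800, alpha = -0.3, beta = c(u = 0.9, v = -0.4),
                           seed = 9)
  single <- fit_logit(fx$X, fx$y)
  pooled <- fit_generalized(list(fx$X, fx$X), list(fx$y, fx$y),
                            shared = c("u", "v"))
  expect_equal(coef(pooled), coef(single), tolerance = 1e-6)
  expect_error(fit_generalized(list(fx$X), list(fx$y), shared = "w"),
               "lacks shared feature")
})

test_that("a generalized model separates held-out informative data", {
  fx_train1 <- make_logit_fixture(1500, -0.5, c(u = 1, v = -0.8), seed = 11)
  fx_train2 <- make_logit_fixture(1500, -0.5, c(u = 1, v = -0.8), seed = 12)
  fx_test <- make_logit_fixture(1500, -0.5, c(u = 1, v = -0.8), seed = 13)
  gen <- fit_generalized(list(fx_train1$X, fx_train2$X),
                         list(fx_train1$y, fx_train2$y), shared = c("u", "v"))
  pot <- predict_potential(gen, fx_test$X)
  # AUROC via the rank-sum identity
  r <- rank(pot)
  n1 <- sum(fx_test$y == 1); n0 <- sum(fx_test$y == 0)
  auroc <- (sum(r[fx_test$y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gt(auroc, 0.6)
})

test_that("separation triggers the ridge fallback instead of aborting", {
  X <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(0, 10), rep(1, 10))
  expect_warning(fit <- fit_logit(X, y), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(coef(fit))))
  expect_gt(unname(fit$beta["x"]), 0)
})

test_that("models serialize to JSON and reload bit-exactly", {
  fx <- make_logit_fixture(400, alpha = 0.2, beta = c(a = 1 / 3, b = -0.77),
                           seed = 3)
  fit <- fit_logit(fx$X, fx$y, meta = list(study = "toy", scheme = "random_tss"))
  f <- withr::local_tempfile(fileext = ".json")
  write_logit_model(fit, f)
  back <- read_logit_model(f)
  expect_identical(back$alpha, fit$alpha)
  expect_identical(back$beta, fit$beta)
  expect_identical(back$se, fit$se)
  expect_identical(back$feature_names, fit$feature_names)
  expect_equal(back$training_meta$study, "toy")
  expect_identical(predict_potential(back, fx$X), predict_potential(fit, fx$X))
})

test_that("wald p values flag informative coefficients", {
  fx <- make_logit_fixture(3000, alpha = -0.5, beta = c(big = 1.2, nil = 0),
                           seed = 22)
  fit <- fit_logit(fx$X, fx$y)
  expect_lt(fit$wald_p[["big"]], 1e-6)
  expect_gt(fit$wald_p[["nil"]], 0.05)
  s <- summary(fit)
  expect_s3_class(s, "summary.regpot_logit")
  expect_equal(nrow(s$table), 3L)
})
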