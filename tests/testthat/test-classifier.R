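test_that("min-max scaling and mean imputation obey their contracts", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_scale(c(5, 5, 5)), c(0, 0, 0))
  expect_error(minmax_scale(c(NA_real_, NA_real_)), "all-missing")
  set.seed(51)
  for (i in 1:50) {
    v <- rnorm(20)
    s <- minmax_scale(v)
    expect_equal(range(s), c(0, 1))
  }
  expect_equal(impute_mean(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(impute_mean(c(1, 2, 3)), c(1, 2, 3))
  v <- c(4, NA, 8, NA, 6)
  expect_equal(mean(impute_mean(v)), mean(v, na.rm = TRUE))
})

test_that("the penalized logistic fit recovers the closed-form MLE as strength -> 0", {
  # 2x2 logistic model: x=1 has 8 pos / 2 neg, x=0 has 2 pos / 8 neg
  X <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  fit <- fit_logistic_l2(X, y, strength = 1e-8)
  expect_equal(unname(fit$coefficients), log(16), tolerance = 1e-4)
  expect_lte(fit$grad_norm, 1e-8)
})

test_that("the penalty keeps one-class and separable problems finite", {
  X <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "x"))
  fit <- fit_logistic_l2(X, rep(1, 20), strength = 1)
  expect_true(all(is.finite(c(fit$coefficients, fit$intercept))))
  expect_true(all(plogis(drop(X %*% fit$coefficients) + fit$intercept) > 0.5))

  Xs <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1, dimnames = list(NULL, "x"))
  ys <- c(rep(0, 10), rep(1, 10))
  fs <- fit_logistic_l2(Xs, ys, strength = 1)
  expect_true(is.finite(fs$coefficients))
})

test_that("the objective is convex: optimum independent of the starting point", {
  set.seed(52)
  X <- matrix(rnorm(200 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(X %*% c(1, -0.5, 0)))
  ref <- fit_logistic_l2(X, y, strength = 0.5)
  for (i in 1:10) {
    alt <- fit_logistic_l2(X, y, strength = 0.5, beta_init = rnorm(4, sd = 3))
    expect_lt(abs(alt$loss - ref$loss), 1e-6)
    expect_equal(alt$coefficients, ref$coefficients, tolerance = 1e-5)
  }
})

test_that("the fit agrees with an independent ridge-logistic implementation", {
  skip_if_not_installed("glmnet")
  set.seed(53)
  n <- 300
  X <- matrix(rnorm(n * 4), ncol = 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(n, 1, plogis(X %*% c(1, -1, 0.5, 0)))
  for (s in c(0.1, 1, 10)) {
    mine <- fit_logistic_l2(X, y, strength = s)
    g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = s / n,
                        standardize = FALSE, thresh = 1e-14)
    expect_equal(unname(mine$coefficients), unname(as.numeric(g$beta)),
                 tolerance = 1e-3)
    expect_equal(mine$intercept, unname(g$a0), tolerance = 1e-3)
  }
})

test_that("stronger regularization weakly shrinks the coefficient norm", {
  set.seed(54)
  X <- matrix(rnorm(150 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(150, 1, plogis(X %*% c(2, -1, 0.5)))
  grid <- 10^seq(-4, 4, length.out = 10)
  norms <- vapply(grid, function(s) {
    sqrt(sum(fit_logistic_l2(X, y, s)$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("CV strength selection prefers heavy penalties on pure noise and is deterministic", {
  set.seed(55)
  spec <- model_spec()
  hits <- 0
  for (i in 1:100) {
    X <- matrix(rnorm(40 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c(0, 1), 20)
    s <- select_strength_cv(X, y, spec, seed = 1000 + i)
    if (s >= spec$l2_grid[6]) hits <- hits + 1
  }
  expect_gte(hits, 80)

  # perfectly informative feature reaches CV accuracy 1 somewhere on the grid
  Xi <- matrix(c(rep(0, 20), rep(1, 20)), ncol = 1, dimnames = list(NULL, "x"))
  yi <- c(rep(0, 20), rep(1, 20))
  s1 <- select_strength_cv(Xi, yi, spec, seed = 9)
  expect_true(s1 %in% spec$l2_grid)
  expect_identical(select_strength_cv(Xi, yi, spec, seed = 9), s1)
})

test_that("a leaked label feature yields perfect repeated-split accuracy", {
  set.seed(56)
  tab <- tibble::tibble(
    tl_id = paste0("t", 1:100),
    leak = rep(c(1, 0), 50),
    noise = rnorm(100),
    label = rep(c("active", "nonactive"), 50)
  )
  m <- evaluate_repeated(tab, model_spec(n_repeats = 10, seed = 2))
  expect_equal(m$mean_accuracy, 1)
  expect_equal(glance(m)$max_accuracy, 1)
})

test_that("label-independent features give chance-level accuracy", {
  set.seed(57)
  tab <- tibble::tibble(
    tl_id = paste0("t", 1:200),
    f1 = rnorm(200), f2 = rnorm(200), f3 = runif(200),
    label = rep(c("active", "nonactive"), 100)
  )
  m <- evaluate_repeated(tab, model_spec(n_repeats = 100, seed = 3))
  # binomial null: pooled test predictions + dataset-level imbalance noise
  se <- sqrt(sd(m$repeats$accuracy)^2 / 100 + 0.25 / 200)
  expect_lt(abs(m$mean_accuracy - 0.5), 3 * se + 1e-9)
})

test_that("repeated evaluation is bit-reproducible from the seed", {
  co <- tiny_cohort(n = 60, seed = 8)
  ft <- features_of(co)
  m1 <- evaluate_repeated(ft, model_spec(n_repeats = 5, seed = 11))
  m2 <- evaluate_repeated(ft, model_spec(n_repeats = 5, seed = 11))
  expect_identical(m1$repeats, m2$repeats)
  expect_identical(m1$coefficients, m2$coefficients)
  m3 <- evaluate_repeated(ft, model_spec(n_repeats = 5, seed = 12))
  expect_false(identical(m1$repeats$accuracy, m3$repeats$accuracy))
})

test_that("leak-safe preprocessing refits imputation and scaling per split", {
  co <- tiny_cohort(n = 60, seed = 9)
  ft <- features_of(co)
  m <- evaluate_repeated(ft, model_spec(n_repeats = 3, seed = 4, leak_safe = TRUE))
  expect_true(all(m$repeats$accuracy >= 0 & m$repeats$accuracy <= 1))
  ms <- evaluate_repeated(ft, model_spec(n_repeats = 3, seed = 4,
                                         stratified_split = TRUE))
  expect_true(all(ms$repeats$accuracy >= 0 & ms$repeats$accuracy <= 1))
})

test_that("a leaked feature gets the smallest attainable permutation p", {
  set.seed(58)
  tab <- tibble::tibble(
    tl_id = paste0("t", 1:60),
    leak = rep(c(1, 0), 30),
    noise = rnorm(60),
    label = rep(c("active", "nonactive"), 30)
  )
  ps <- coefficient_significance(tab, model_spec(), n_perm = 99, seed = 5)
  expect_equal(ps$p_value[ps$term == "leak"], 1 / 100)
  expect_gt(ps$p_value[ps$term == "noise"], 0.05)
})

test_that("permutation p-values are invariant to feature rescaling", {
  co <- tiny_cohort(n = 60, seed = 10)
  ft <- features_of(co) |>
    dplyr::select("tl_id", "gc_content", "has_splice3", "label")
  p1 <- coefficient_significance(ft, model_spec(), n_perm = 49, seed = 6)
  ft2 <- ft |> dplyr::mutate(gc_content = 1000 * .data$gc_content)
  p2 <- coefficient_significance(ft2, model_spec(), n_perm = 49, seed = 6)
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$estimate, p2$estimate, tolerance = 1e-6)
})

test_that("tidy and glance summarize a fitted model", {
  co <- tiny_cohort(n = 60, seed = 12)
  m <- evaluate_repeated(features_of(co), model_spec(n_repeats = 5, seed = 1))
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "sign_consistency") %in% names(td)))
  gl <- glance(m)
  expect_lte(gl$mean_accuracy, gl$max_accuracy)
  expect_s3_class(autoplot(m), "ggplot")
})
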