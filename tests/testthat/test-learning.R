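# Adaptive group-lasso learning: unpenalized fits, weights, prox, FISTA,
# path and cross-validation.

test_that("unpenalized fit reproduces the closed-form M/T rates", {
  str2 <- toy_structure_2()
  tab <- fctbn_coef(str2, m = 0)
  tab <- set_group(tab, "A", "01", ".baseline", log(0.5))
  tab <- set_group(tab, "B", "01", ".baseline", log(0.4))
  tab <- set_group(tab, "B", "01", "A", log(2))
  dat <- small_cohort(str2, tab, 400, seed = 21, horizon = 8,
                      covariates = list())
  # no-parent submodel: node A's fitted rate must equal M/T exactly
  strA <- fctbn_structure(c("A", "B"),
                          parents = list(A = character(0), B = character(0)),
                          progressive = TRUE)
  bt <- fit_unpenalized(strA, dat)
  est <- mle_intensities(sufficient_stats(dat, strA))
  for (nd in c("A", "B")) {
    mt <- est[est$node == nd & est$state == 0, ]
    expect_lt(abs(exp(bt[[nd]][["01"]][1, 1]) - mt$qhat) / mt$qhat, 1e-6)
  }
})

test_that("unpenalized fit recovers known coefficients on a 3-node cohort", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 2000, seed = 11)
  bt <- fit_unpenalized(mod$structure, dat)
  err <- unlist(lapply(mod$structure$nodes, function(nd)
    bt[[nd]][["01"]] - mod$table[[nd]][["01"]]))
  expect_lt(sqrt(mean(err^2)), 0.15)
  # optimality: fitted objective no worse than the truth's
  expect_lte(neg_log_likelihood(bt, mod$structure, dat),
             neg_log_likelihood(mod$table, mod$structure, dat))
  # stationarity: gradient small relative to the objective
  g <- nll_gradient(bt, mod$structure, dat)
  gn <- sqrt(sum(unlist(lapply(g, function(x) unlist(x)))^2))
  expect_lt(gn, 1e-6 * (1 + abs(neg_log_likelihood(bt, mod$structure, dat))))
})

test_that("adaptive weights invert the unpenalized group norms", {
  str2 <- toy_structure_2()
  tab <- fctbn_coef(str2, m = 0)
  tab <- set_group(tab, "B", "01", "A", 2)
  w <- adaptive_weights(tab, str2)
  expect_equal(w[["A->B"]], 0.5)
  # floor rule
  tab0 <- fctbn_coef(str2, m = 0)
  w0 <- adaptive_weights(tab0, str2, floor = 1e-4)
  expect_equal(w0[["A->B"]], 1e4)
  # doubling the estimates halves the weights
  tab2 <- set_group(tab, "B", "01", "A", 4)
  expect_equal(adaptive_weights(tab2, str2)[["A->B"]], w[["A->B"]] / 2)
})

test_that("group soft-thresholding matches its closed form", {
  expect_equal(group_prox(c(3, 4), 5), c(0, 0))
  expect_equal(group_prox(c(3, 4), 2.5), c(1.5, 2))
  v <- c(-1.2, 0.3, 2)
  expect_equal(group_prox(v, 0), v)
  expect_error(group_prox(v, -1), "nonnegative")
})

test_that("group prox minimises its defining objective", {
  withr::with_seed(41, {
    for (i in 1:100) {
      d <- sample(1:5, 1)
      v <- rnorm(d, 0, 2)
      thr <- runif(1, 0, 3)
      prox <- group_prox(v, thr)
      obj <- function(x) 0.5 * sum((x - v)^2) + thr * sqrt(sum(x^2))
      opt <- stats::optim(v / 2, obj, method = "BFGS",
                          control = list(reltol = 1e-14, maxit = 1000))
      expect_lte(obj(prox), opt$value + 1e-6)
    }
  })
})

test_that("lambda = 0 FISTA matches the unpenalized fit", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 300, seed = 13)
  bt <- fit_unpenalized(mod$structure, dat)
  f0 <- fista_fit(mod$structure, dat, 0,
                  opts = fista_opts(tol = 1e-10, patience = 10))
  expect_true(f0$converged)
  expect_lt(abs(f0$objective - neg_log_likelihood(bt, mod$structure, dat)),
            1e-4)
})

test_that("a dominating penalty zeroes every parent group exactly", {
  str2 <- toy_structure_2()
  tab <- fctbn_coef(str2, m = 0)
  tab <- set_group(tab, "A", "01", ".baseline", log(0.5))
  tab <- set_group(tab, "B", "01", ".baseline", log(0.4))
  tab <- set_group(tab, "B", "01", "A", log(2))
  dat <- small_cohort(str2, tab, 300, seed = 14, horizon = 6,
                      covariates = list())
  f <- fista_fit(str2, dat, 1e9)
  expect_length(f$active_groups, 0L)
  expect_true(all(f$coefficients$B[["01"]][, "A"] == 0))
  # baseline rates collapse to the pooled M/T of each node
  est <- mle_intensities(sufficient_stats(
    dat, fctbn_structure(c("A", "B"), parents = "none", progressive = TRUE)))
  for (nd in c("A", "B")) {
    pooled <- est[est$node == nd & est$state == 0, ]
    expect_lt(abs(exp(f$coefficients[[nd]][["01"]][1, 1]) - pooled$qhat) /
                pooled$qhat, 1e-4)
  }
})

test_that("FISTA objective trace is non-increasing (monotone variant)", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 300, seed = 15)
  f <- fista_fit(mod$structure, dat, 5)
  for (tr in f$objective_trace) {
    expect_true(all(diff(tr) <= 1e-9))
    # final objective no worse than the first iterate from zero init
    expect_lte(tr[length(tr)], tr[1])
  }
})

test_that("FISTA recovers true structure on a 3-node cohort via CV", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 5000, seed = 23)
  cv <- cross_validate(mod$structure, dat, k_folds = 3, seed = 23)
  est <- extract_structure(cv$fit$coefficients, mod$structure)
  key <- function(d) paste(d$parent, d$child)
  expect_true(all(key(mod$edges) %in% key(est)))  # both true edges active
  spurious <- setdiff(key(est), key(mod$edges))
  expect_lte(length(spurious), 1L)                # >= 3 of 4 spurious zero
})

test_that("the regularization path reports monotone sparsity", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 400, seed = 16)
  pth <- regularization_path(mod$structure, dat, c(0, 1, 10, 100, 1e4))
  expect_error(regularization_path(mod$structure, dat, c(1, 0)), "ascending")
  s <- pth$summary$sparsity
  expect_true(all(diff(s) >= -1e-12))
  expect_gte(s[length(s)], s[1])
  # single-point grid {0} degenerates to the unpenalized fit
  p0 <- regularization_path(mod$structure, dat, 0)
  expect_equal(nrow(p0$summary), 1L)
  expect_equal(p0$summary$sparsity, 0)
  # coefficients vary continuously along the path
  cf <- vapply(pth$fits, function(f)
    unlist(lapply(f$coefficients_std, function(x) unlist(x))),
    numeric(length(unlist(lapply(pth$fits[[1]]$coefficients_std, unlist)))))
  gaps <- apply(abs(diff(t(cf))), 1, max)
  expect_true(all(gaps < 1.5))
})

test_that("cross-validation is deterministic and uses the default grid", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 200, seed = 18)
  cv1 <- cross_validate(mod$structure, dat, k_folds = 2, seed = 5)
  cv2 <- cross_validate(mod$structure, dat, k_folds = 2, seed = 5)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$best_lambda, cv2$best_lambda)
  expect_equal(cv1$cv_table$lambda, c(0, 10^(0:6)))
})

test_that("CV error approximates training error on duplicated halves", {
  mod <- chain3_model()
  half <- small_cohort(mod$structure, mod$table, 250, seed = 19)
  dup <- bind_data(half, half)
  cv <- cross_validate(mod$structure, dup, lambda_grid = 0, k_folds = 2,
                       seed = 3)
  bt <- fit_unpenalized(mod$structure, dup)
  train_err <- neg_log_likelihood(bt, mod$structure, dup) /
    nrow(dup$records)
  expect_lt(abs(cv$cv_table$cv_error[1] - train_err) / abs(train_err), 0.05)
})
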