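# Functional CTBN model: intensities, likelihood, gradient, counts,
# serialization.

test_that("conditional intensity is the exponential of the summed predictors", {
  str2 <- fctbn_structure(c("A", "B", "C"),
                          parents = list(A = character(0), B = character(0),
                                         C = c("A", "B")),
                          progressive = TRUE)
  tab <- fctbn_coef(str2, m = 0)
  expect_equal(conditional_intensity(tab, "C", "01", character(0)), 1)
  tab <- set_group(tab, "C", "01", ".baseline", log(2))
  expect_equal(conditional_intensity(tab, "C", "01", character(0)), 2)
  # multiplicative parent effects: baseline 1, parent factors 2 and 3
  tab <- set_group(tab, "C", "01", ".baseline", 0)
  tab <- set_group(tab, "C", "01", "A", log(2))
  tab <- set_group(tab, "C", "01", "B", log(3))
  expect_equal(conditional_intensity(tab, "C", "01", c("A", "B")), 6)
  # one active parent multiplies the no-parent rate exactly
  tab <- set_group(tab, "C", "01", ".baseline", 0.4)
  q0 <- conditional_intensity(tab, "C", "01", character(0))
  expect_equal(conditional_intensity(tab, "C", "01", "A"), q0 * 2)
  expect_error(conditional_intensity(tab, "C", "01", "Z"), "unknown parent")
  expect_error(conditional_intensity(tab, "Z", "01", character(0)),
               "unknown node")
})

test_that("covariates enter every active group's predictor", {
  str2 <- toy_structure_2()
  tab <- fctbn_coef(str2, m = 2)
  tab <- set_group(tab, "B", "01", ".baseline", c(0.1, 0.2, -0.3))
  tab <- set_group(tab, "B", "01", "A", c(0.5, -0.1, 0.2))
  z <- c(1.5, -2)
  zt <- c(1, z)
  expect_equal(conditional_intensity(tab, "B", "01", character(0), z),
               exp(sum(zt * c(0.1, 0.2, -0.3))))
  expect_equal(conditional_intensity(tab, "B", "01", "A", z),
               exp(sum(zt * c(0.1, 0.2, -0.3)) + sum(zt * c(0.5, -0.1, 0.2))))
  expect_error(conditional_intensity(tab, "B", "01", "A", 1), "length")
})

test_that("per-subject CIMs have the 2x2 generator form", {
  str2 <- toy_structure_2(progressive = FALSE)
  tab <- fctbn_coef(str2, m = 0)
  tab <- set_group(tab, "A", "01", ".baseline", log(2))
  tab <- set_group(tab, "A", "10", ".baseline", log(0.5))
  cims <- build_subject_cims(str2, tab)
  expect_length(cims$A, 1L)
  expect_equal(unclass(cims$A[[1]]$matrix),
               matrix(c(-2, 2, 0.5, -0.5), 2, byrow = TRUE,
                      dimnames = list(c("0", "1"), c("0", "1"))),
               ignore_attr = "states")
  # node with 2 parents: 4 configurations, all valid generators
  str3 <- fctbn_structure(c("A", "B", "C"),
                          parents = list(A = character(0), B = character(0),
                                         C = c("A", "B")))
  tab3 <- fctbn_coef(str3, m = 0, init = 0.3)
  cims3 <- build_subject_cims(str3, tab3)
  expect_length(cims3$C, 4L)
  for (ci in cims3$C)
    expect_true(validate_intensity(ci$matrix)$valid)
})

test_that("negative log-likelihood matches hand-computed single records", {
  str1 <- toy_structure_1()
  tab <- fctbn_coef(str1, m = 0)   # q = 1
  d <- fctbn_data("A", matrix(numeric(0), 1, 0),
                  make_record("A", 0, 1.0, "A", 1L))
  expect_equal(neg_log_likelihood(tab, str1, d), 1)  # -(log 1 - 1*1)
  tab2 <- set_group(tab, "A", "01", ".baseline", log(2))
  d2 <- fctbn_data("A", matrix(numeric(0), 1, 0), make_record("A", 0, 0.5))
  expect_equal(neg_log_likelihood(tab2, str1, d2), 1)  # exposure only: 2*0.5
  dbad <- d
  dbad$records$t_d <- -1
  expect_error(validate_fctbn_data(dbad), "t_d")
})

test_that("likelihood equals an independent record-by-record sum", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 8, seed = 3)
  tab <- mod$table
  # independent oracle: loop over records; every node accrues exposure at
  # its active exit rate, the transitioning node adds log q
  oracle <- 0
  for (i in seq_len(nrow(dat$records))) {
    r <- dat$records[i, ]
    z <- dat$covariates[r$subject, ]
    for (nd in mod$structure$nodes) {
      if (r[[nd]] == 1) next  # progressive: no exit rate in state 1
      act <- mod$structure$parents[[nd]]
      act <- act[unlist(r[act]) == 1]
      q <- conditional_intensity(tab, nd, "01", act, z)
      oracle <- oracle + q * r$t_d
      if (!r$censored && r$event_node == nd) oracle <- oracle - log(q)
    }
  }
  expect_equal(neg_log_likelihood(tab, mod$structure, dat), oracle)
})

test_that("analytic gradient matches central finite differences", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 10, seed = 4)
  tab <- mod$table
  g <- nll_gradient(tab, mod$structure, dat)
  h <- 1e-6
  for (nd in mod$structure$nodes)
    for (src in colnames(tab[[nd]][["01"]]))
      for (k in 1:2) {
        up <- tab; dn <- tab
        up[[nd]][["01"]][k, src] <- up[[nd]][["01"]][k, src] + h
        dn[[nd]][["01"]][k, src] <- dn[[nd]][["01"]][k, src] - h
        fd <- (neg_log_likelihood(up, mod$structure, dat) -
                 neg_log_likelihood(dn, mod$structure, dat)) / (2 * h)
        expect_lt(abs(g[[nd]][["01"]][k, src] - fd) / max(1, abs(fd)), 1e-5)
      }
})

test_that("gradient vanishes at the closed-form MLE of a plain model", {
  str1 <- toy_structure_1()
  d <- fctbn_data("A", matrix(numeric(0), 2, 0),
                  rbind(make_record("A", 0, 1.0, "A", 1L, 1L),
                        make_record("A", 0, 3.0, "A", 1L, 2L)))
  # M = 2, T = 4 -> qhat = 0.5
  tab <- fctbn_coef(str1, m = 0)
  tab <- set_group(tab, "A", "01", ".baseline", log(0.5))
  g <- nll_gradient(tab, str1, d)
  expect_equal(g$A[["01"]][1, ".baseline"], 0)
  # trivial single-record case: all beta = 0, t_d = 1 -> gradient 0
  tab0 <- fctbn_coef(str1, m = 0)
  d1 <- fctbn_data("A", matrix(numeric(0), 1, 0),
                   make_record("A", 0, 1.0, "A", 1L))
  expect_equal(nll_gradient(tab0, str1, d1)$A[["01"]][1, 1], 0)
})

test_that("negative log-likelihood is convex along random segments", {
  mod <- chain3_model()
  dat <- small_cohort(mod$structure, mod$table, 15, seed = 5)
  withr::with_seed(99, {
    for (rep in 1:100) {
      t1 <- fctbn_coef(mod$structure, m = 1)
      t2 <- fctbn_coef(mod$structure, m = 1)
      for (nd in mod$structure$nodes) {
        t1[[nd]][["01"]][] <- rnorm(length(t1[[nd]][["01"]]), 0, 0.7)
        t2[[nd]][["01"]][] <- rnorm(length(t2[[nd]][["01"]]), 0, 0.7)
      }
      mid <- t1
      for (nd in mod$structure$nodes)
        mid[[nd]][["01"]][] <- (t1[[nd]][["01"]] + t2[[nd]][["01"]]) / 2
      f1 <- neg_log_likelihood(t1, mod$structure, dat)
      f2 <- neg_log_likelihood(t2, mod$structure, dat)
      fm <- neg_log_likelihood(mid, mod$structure, dat)
      expect_lte(fm, (f1 + f2) / 2 + 1e-9)
    }
  })
})

test_that("parameter count follows the closed-form formulas", {
  str5 <- fctbn_structure(paste0("n", 1:5), parents = "all", max_parents = 4)
  expect_equal(parameter_count(str5, 1, "multiplicative"), 100L)
  expect_equal(parameter_count(str5, 1, "full"), 320L)
  str1 <- fctbn_structure("A", parents = "none", max_parents = 0)
  expect_equal(parameter_count(str1, 0, "multiplicative"), 2L)
  expect_equal(parameter_count(str1, 0, "full"), 2L)
})

test_that("model serialization round-trips exactly", {
  mod <- fixture_model("reversible")
  path <- tempfile(fileext = ".json")
  write_fctbn(mod$structure, mod$table, path)
  back <- read_fctbn(path)
  expect_equal(back$structure$nodes, mod$structure$nodes)
  expect_equal(back$structure$parents, mod$structure$parents)
  expect_equal(back$structure$progressive, mod$structure$progressive)
  for (nd in mod$structure$nodes)
    for (d in names(mod$table[[nd]]))
      expect_identical(unname(back$table[[nd]][[d]]),
                       unname(mod$table[[nd]][[d]]))
  # ... and the shipped fixture file equals the in-code definition
  built <- fctbn:::build_fixture_model("reversible")
  for (nd in mod$structure$nodes)
    for (d in names(mod$table[[nd]]))
      expect_identical(mod$table[[nd]][[d]], built$table[[nd]][[d]])
})

test_that("structure construction enforces the schema", {
  expect_error(fctbn_structure(c("A", "A")), "duplicate")
  expect_error(fctbn_structure(c("A", "B"), parents = list(A = "A", B = "A")),
               "own parent")
  expect_error(fctbn_structure(c("A", "B"),
                               parents = list(A = "C", B = character(0))),
               "unknown parent")
  expect_error(fctbn_structure(c("A", "B", "C"), parents = "all",
                               max_parents = 1), "max_parents")
})
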