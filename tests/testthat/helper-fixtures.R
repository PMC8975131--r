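# Shared in-code fixtures for the test suite.

# one binary node, no parents, no covariates
toy_structure_1 <- function(progressive = TRUE)
  fctbn_structure("A", parents = "none", progressive = progressive)

# A -> B, no covariates
toy_structure_2 <- function(progressive = TRUE)
  fctbn_structure(c("A", "B"), parents = list(A = character(0), B = "A"),
                  progressive = progressive)

# build a record row in the canonical column order
make_record <- function(nodes, states, t_d, event_node = NA_character_,
                        event_state = NA_integer_, subject = 1L) {
  rec <- data.frame(subject = subject)
  for (i in seq_along(nodes)) rec[[nodes[i]]] <- as.integer(states[i])
  rec$t_d <- t_d
  rec$event_node <- event_node
  rec$event_state <- as.integer(event_state)
  rec$censored <- is.na(event_node)
  rec
}

# tiny hand-enumerable dataset: 3 subjects on the A -> B network
toy_dataset_3subj <- function() {
  nodes <- c("A", "B")
  rec <- rbind(
    # subject 1: A fires at 2.0, then B fires at 1.5, censored after 0.5
    make_record(nodes, c(0, 0), 2.0, "A", 1L, 1L),
    make_record(nodes, c(1, 0), 1.5, "B", 1L, 1L),
    make_record(nodes, c(1, 1), 0.5, subject = 1L),
    # subject 2: B fires at 1.0, censored after 3.0
    make_record(nodes, c(0, 0), 1.0, "B", 1L, 2L),
    make_record(nodes, c(0, 1), 3.0, subject = 2L),
    # subject 3: fully censored
    make_record(nodes, c(0, 0), 4.0, subject = 3L))
  fctbn_data(nodes, matrix(numeric(0), nrow = 3, ncol = 0), rec)
}

# random small cohort from a given model (uses the current RNG via seed)
small_cohort <- function(structure, table, n, seed, horizon = 10,
                         covariates = list(z1 = list(dist = "normal",
                                                     mean = 0, sd = 1))) {
  generate_cohort(simulation_spec(structure, table,
                                  covariates = covariates,
                                  n_subjects = n, horizon = horizon,
                                  seed = seed))
}

# 3-node chain model with one covariate used by the learning tests:
# true edges A -> B and B -> C among all 6 candidate edges
chain3_model <- function() {
  str3 <- fctbn_structure(c("A", "B", "C"), parents = "all",
                          progressive = TRUE)
  tab <- fctbn_coef(str3, m = 1L)
  tab <- set_group(tab, "A", "01", ".baseline", c(-1.5, 0.3))
  tab <- set_group(tab, "B", "01", ".baseline", c(-2.0, -0.2))
  tab <- set_group(tab, "C", "01", ".baseline", c(-1.8, 0.0))
  tab <- set_group(tab, "B", "01", "A", c(1.0, 0.2))
  tab <- set_group(tab, "C", "01", "B", c(0.9, 0.0))
  list(structure = str3, table = tab,
       edges = data.frame(parent = c("A", "B"), child = c("B", "C")))
}

# cached large fixture cohort shared by the acceptance tests
fixture_cache <- new.env(parent = emptyenv())
fixture_cohort <- function() {
  if (is.null(fixture_cache$dat))
    fixture_cache$dat <- generate_cohort(fixture_spec())
  fixture_cache$dat
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(1, abs(y))), tol)
}
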