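# The reference synthetic network used throughout the tests and
# examples: five chronic conditions (TBI, BaPa, PTSD, Depr, SuAb), one
# covariate ("age score", standard normal), six true edges.  Shipped as
# versioned model files under extdata; build_fixture_model() is the
# in-code source of those files.

fixture_nodes <- c("TBI", "BaPa", "PTSD", "Depr", "SuAb")

# (parent, child, log rate ratio, covariate interaction)
fixture_edges <- data.frame(
  parent = c("TBI", "TBI", "PTSD", "PTSD", "Depr", "BaPa"),
  child = c("PTSD", "Depr", "Depr", "SuAb", "SuAb", "Depr"),
  b0 = c(1.1, 0.7, 0.9, 1.0, 0.8, 0.6),
  b1 = c(0.0, 0.2, 0.0, -0.2, 0.0, 0.0),
  stringsAsFactors = FALSE)

# acquisition baselines: log rate per year at age score 0, and slope
fixture_baselines <- data.frame(
  node = fixture_nodes,
  b0 = c(-2.2, -1.6, -2.5, -2.3, -2.6),
  b1 = c(-0.3, 0.4, 0.2, 0.3, -0.2),
  stringsAsFactors = FALSE)

build_fixture_model <- function(variant = c("progressive", "reversible")) {
  variant <- match.arg(variant)
  str <- fctbn_structure(fixture_nodes, parents = "all", max_parents = 4L,
                         progressive = variant == "progressive")
  tab <- fctbn_coef(str, m = 1L, covariate_names = "age_score")
  for (i in seq_len(nrow(fixture_baselines)))
    tab <- set_group(tab, fixture_baselines$node[i], "01", ".baseline",
                     c(fixture_baselines$b0[i], fixture_baselines$b1[i]))
  for (i in seq_len(nrow(fixture_edges)))
    tab <- set_group(tab, fixture_edges$child[i], "01",
                     fixture_edges$parent[i],
                     c(fixture_edges$b0[i], fixture_edges$b1[i]))
  if (variant == "reversible")
    for (nd in fixture_nodes)
      tab <- set_group(tab, nd, "10", ".baseline", c(-1.9, 0))
  list(structure = str, table = tab)
}

#' Reference synthetic network
#'
#' A five-condition network (TBI, BaPa, PTSD, Depr, SuAb) with one
#' standard-normal covariate ("age score") and six true directed edges,
#' loaded from the versioned model file shipped with the package.  The
#' progressive variant has no remission (1 -> 0 rates are zero); the
#' reversible variant adds a constant remission rate of exp(-1.9) per
#' year to every condition.
#'
#' @param variant \code{"progressive"} (default) or \code{"reversible"}.
#' @return list with \code{structure}, \code{table} (the true
#'   coefficients) and \code{edges} (data.frame of true edges).
#' @export
fixture_model <- function(variant = c("progressive", "reversible")) {
  variant <- match.arg(variant)
  path <- system.file("extdata",
                      paste0("fixture_truth_", variant, "_v1.json"),
                      package = "fctbn")
  mod <- if (nzchar(path)) read_fctbn(path) else build_fixture_model(variant)
  mod$edges <- fixture_edges[, c("parent", "child")]
  mod
}

#' Default simulation spec of the reference network
#'
#' Study conditions used by the recovery experiments: n subjects followed
#' over a 10-year horizon from the no-condition baseline state, one
#' standard-normal covariate.
#'
#' @param n_subjects cohort size (default 5000).
#' @param seed integer seed (default 42).
#' @param horizon follow-up horizon in years (default 10).
#' @param variant fixture variant.
#' @return an \code{fctbn_simspec}.
#' @export
fixture_spec <- function(n_subjects = 5000L, seed = 42L, horizon = 10,
                         variant = "progressive") {
  mod <- fixture_model(variant)
  simulation_spec(mod$structure, mod$table,
                  covariates = list(age_score = list(dist = "normal",
                                                     mean = 0, sd = 1)),
                  n_subjects = n_subjects, horizon = horizon,
                  seed = seed)
}
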