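# Synthetic cohort generator: covariates plus continuous-time trajectories
# sampled from a known functional CTBN by the Gillespie scheme.

#' Specify a simulation
#'
#' @param structure an \code{fctbn_structure} (the true graph).
#' @param truth an \code{fctbn_coef} with the true coefficients.
#' @param covariates named list of per-covariate distributions, each
#'   \code{list(dist = "normal", mean =, sd =)} or
#'   \code{list(dist = "categorical", levels =, probs =)}.
#' @param n_subjects number of subjects.
#' @param horizon right-censoring time (in the dataset time unit).
#' @param initial_state \code{NULL} for the all-zeros joint state, a named
#'   0/1 vector applied to every subject, or
#'   \code{list(states = <matrix>, probs = <vector>)} to sample the
#'   baseline joint state per subject.
#' @param seed integer seed; all randomness flows from it.
#' @param time_unit declarative time unit label.
#' @return object of class \code{"fctbn_simspec"}.
#' @export
simulation_spec <- function(structure, truth, covariates = list(),
                            n_subjects, horizon, initial_state = NULL,
                            seed = 1L, time_unit = "years") {
  stopifnot(inherits(structure, "fctbn_structure"),
            inherits(truth, "fctbn_coef"), horizon > 0, n_subjects >= 0)
  for (cv in covariates) {
    if (!cv$dist %in% c("normal", "categorical"))
      stop("unknown covariate distribution: ", cv$dist)
    if (cv$dist == "categorical" &&
        abs(sum(cv$probs) - 1) > 1e-8)
      stop("categorical probabilities must sum to 1")
  }
  if (is.list(initial_state) && !is.null(initial_state$probs) &&
      abs(sum(initial_state$probs) - 1) > 1e-8)
    stop("initial state probabilities must sum to 1")
  structure(list(structure = structure, truth = truth,
                 covariates = covariates,
                 n_subjects = as.integer(n_subjects), horizon = horizon,
                 initial_state = initial_state, seed = as.integer(seed),
                 time_unit = time_unit),
            class = "fctbn_simspec")
}

#' Draw the covariate table of a cohort
#'
#' @param spec an \code{fctbn_simspec}.
#' @return data.frame with \code{n_subjects} rows; normal covariates are
#'   numeric columns, categorical ones are factors.  Reproducible from the
#'   spec seed.
#' @export
generate_covariates <- function(spec) {
  stopifnot(inherits(spec, "fctbn_simspec"))
  withr::with_seed(spec$seed, generate_covariates_impl(spec))
}

generate_covariates_impl <- function(spec) {
  n <- spec$n_subjects
  cols <- lapply(spec$covariates, function(cv) {
    if (cv$dist == "normal") stats::rnorm(n, cv$mean, cv$sd)
    else factor(sample(cv$levels, n, replace = TRUE, prob = cv$probs),
                levels = cv$levels)
  })
  out <- if (length(cols)) as.data.frame(cols) else
    as.data.frame(matrix(numeric(0), nrow = n, ncol = 0))
  rownames(out) <- if (n) sprintf("s%d", seq_len(n)) else character(0)
  out
}

# active exit rate of every node in joint state s (named 0/1 vector)
node_exit_rates <- function(structure, truth, z, s) {
  vapply(structure$nodes, function(nd) {
    dir <- if (s[[nd]] == 0L) "01" else "10"
    if (dir == "10" && structure$progressive) return(0)
    act <- structure$parents[[nd]][s[structure$parents[[nd]]] == 1L]
    conditional_intensity(truth, nd, dir, act, z)
  }, numeric(1))
}

#' Sample one trajectory from a known model
#'
#' Gillespie scheme on the factored process: in the current joint state
#' each node has one active exit rate; the holding time is exponential
#' with the total rate and the transitioning node is picked with
#' probability proportional to its rate.  Per event exactly two draws are
#' consumed from the current RNG stream, in a fixed order: first the
#' holding-time exponential, then the uniform node pick.  The trajectory
#' is right-censored at \code{horizon}; if every rate is zero a single
#' censored record covering the whole horizon is returned.
#'
#' @param structure,truth the generating model.
#' @param z numeric covariate vector.
#' @param horizon censoring time.
#' @param initial_state named 0/1 vector over the nodes (default all 0).
#' @return data.frame of records (without the \code{subject} column).
#' @export
sample_trajectory <- function(structure, truth, z, horizon,
                              initial_state = NULL) {
  nodes <- structure$nodes
  s <- if (is.null(initial_state))
    setNames(integer(length(nodes)), nodes)
  else {
    stopifnot(setequal(names(initial_state), nodes))
    setNames(as.integer(initial_state[nodes]), nodes)
  }
  t_now <- 0
  recs <- list()
  repeat {
    rates <- node_exit_rates(structure, truth, z, s)
    R <- sum(rates)
    if (R <= 0) {
      recs[[length(recs) + 1L]] <-
        c(as.list(s), list(t_d = horizon - t_now, event_node = NA_character_,
                           event_state = NA_integer_, censored = TRUE))
      break
    }
    dt <- stats::rexp(1L, R)
    u <- stats::runif(1L)
    if (t_now + dt >= horizon) {
      recs[[length(recs) + 1L]] <-
        c(as.list(s), list(t_d = horizon - t_now, event_node = NA_character_,
                           event_state = NA_integer_, censored = TRUE))
      break
    }
    k <- findInterval(u, cumsum(rates) / R, left.open = TRUE) + 1L
    nd <- nodes[k]
    recs[[length(recs) + 1L]] <-
      c(as.list(s), list(t_d = dt, event_node = nd,
                         event_state = 1L - s[[nd]], censored = FALSE))
    s[[nd]] <- 1L - s[[nd]]
    t_now <- t_now + dt
  }
  do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
}

#' Generate a synthetic cohort
#'
#' Draws covariates, encodes them numerically (one-hot for categorical
#' levels beyond the first), samples one trajectory per subject from the
#' true model, and assembles an \code{fctbn_data}.  Fully reproducible
#' from \code{spec$seed}.
#'
#' @param spec an \code{fctbn_simspec}.
#' @return an \code{fctbn_data} cohort.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fctbn_simspec"))
  withr::with_seed(spec$seed, {
    covdf <- generate_covariates_impl(spec)
    Z <- encode_covariates(covdf)
    m_truth <- attr(spec$truth, "m")
    if (ncol(Z) != m_truth)
      stop("truth expects ", m_truth, " covariates, encoded table has ",
           ncol(Z))
    nodes <- spec$structure$nodes
    init <- spec$initial_state
    recs <- vector("list", spec$n_subjects)
    for (p in seq_len(spec$n_subjects)) {
      s0 <- if (is.null(init)) NULL
      else if (is.list(init)) {
        i <- sample.int(length(init$probs), 1L, prob = init$probs)
        setNames(as.integer(init$states[i, nodes]), nodes)
      } else init
      tr <- sample_trajectory(spec$structure, spec$truth, Z[p, ],
                              spec$horizon, s0)
      tr <- cbind(subject = p, tr)
      recs[[p]] <- tr
    }
    records <- if (spec$n_subjects)
      do.call(rbind, recs)
    else {
      records <- data.frame(subject = integer(0))
      for (nd in nodes) records[[nd]] <- integer(0)
      records$t_d <- numeric(0)
      records$event_node <- character(0)
      records$event_state <- integer(0)
      records$censored <- logical(0)
      records
    }
    rownames(records) <- NULL
    fctbn_data(nodes, Z, records, time_unit = spec$time_unit,
               validate = FALSE)
  })
}

# --- discrete views of trajectories ----------------------------------------

# per-subject list of (times, states matrix) step functions
subject_paths <- function(dataset) {
  rec <- dataset$records
  smat <- as.matrix(rec[, dataset$nodes, drop = FALSE])
  idx <- split(seq_len(nrow(rec)), rec$subject)
  lapply(idx, function(ii) {
    starts <- cumsum(c(0, rec$t_d[ii]))[seq_along(ii)]
    list(start = starts, dur = rec$t_d[ii],
         states = smat[ii, , drop = FALSE])
  })
}

#' Joint state of every subject at one time point
#'
#' @param dataset an \code{fctbn_data}.
#' @param t time point within every subject's observation window.
#' @return integer matrix subjects x nodes.
#' @export
state_at <- function(dataset, t) {
  paths <- subject_paths(dataset)
  out <- t(vapply(paths, function(p) {
    i <- findInterval(t, p$start)
    i <- max(1L, min(i, nrow(p$states)))
    # state during [start_i, start_i + dur_i); at/after the end of the last
    # interval the final record's state still holds (censoring)
    p$states[i, ]
  }, integer(length(dataset$nodes))))
  colnames(out) <- dataset$nodes
  out
}

#' Annual binary coding of a cohort
#'
#' Codes condition x of a subject as 1 in year y exactly when the
#' condition is in state 1 at any point during the interval (y-1, y],
#' regardless of how many times it is acquired or remits within the year.
#'
#' @param dataset an \code{fctbn_data}.
#' @param n_years number of years to code (observation horizon must cover
#'   them).
#' @return integer array of dim (subjects, nodes, years).
#' @export
discretize_annual <- function(dataset, n_years) {
  paths <- subject_paths(dataset)
  nn <- length(dataset$nodes)
  out <- array(0L, dim = c(length(paths), nn, n_years),
               dimnames = list(NULL, dataset$nodes,
                               paste0("year", seq_len(n_years))))
  for (si in seq_along(paths)) {
    p <- paths[[si]]
    a <- p$start
    b <- p$start + p$dur
    b[length(b)] <- max(b[length(b)], n_years)  # final state persists
    for (y in seq_len(n_years)) {
      # interval [a, b) of state 1 intersects (y-1, y]
      hit <- (a < y) & (b > y - 1)
      if (!any(hit)) next
      on <- colSums(p$states[hit, , drop = FALSE] == 1L) > 0
      out[si, on, y] <- 1L
    }
  }
  out
}
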