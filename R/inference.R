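# Exact inference: amalgamated joint intensity matrix, distribution
# propagation by matrix exponential, risk trajectories, multi-year
# prediction and the AUC evaluation harness.

#' Amalgamate a subject's joint intensity matrix
#'
#' Builds the generator over the full joint state space for one covariate
#' vector.  The rate from joint state s to s' is nonzero only when the two
#' differ in exactly one node, and then equals that node's conditional
#' intensity given the parent states read from s; diagonals balance the
#' rows.
#'
#' @param structure an \code{fctbn_structure}.
#' @param table an \code{fctbn_coef}.
#' @param z numeric covariate vector.
#' @param cap maximum joint-state count (default 4096).
#' @return list of class \code{"fctbn_joint"} with \code{states}
#'   (configuration matrix from \code{\link{enumerate_joint_states}}) and
#'   \code{matrix} (the generator).
#' @export
amalgamate <- function(structure, table, z = numeric(0), cap = 4096) {
  nodes <- structure$nodes
  states <- enumerate_joint_states(
    setNames(rep(2L, length(nodes)), nodes), cap = cap)
  S <- nrow(states)
  Q <- matrix(0, S, S)
  # per node, the rate of flipping it depends only on its own state and
  # its parents' states; precompute per node for all joint states
  for (k in seq_along(nodes)) {
    nd <- nodes[k]
    pa <- structure$parents[[nd]]
    rates <- vapply(seq_len(S), function(i) {
      s <- states[i, ]
      dir <- if (s[k] == 0L) "01" else "10"
      if (dir == "10" && structure$progressive) return(0)
      conditional_intensity(table, nd, dir, pa[s[pa] == 1L], z)
    }, numeric(1))
    # target state: same configuration with node k flipped
    flip <- states
    flip[, k] <- 1L - flip[, k]
    tgt <- state_index(flip, states)
    Q[cbind(seq_len(S), tgt)] <- rates
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rownames(Q) <- colnames(Q) <- apply(states, 1L, paste, collapse = "")
  structure(list(states = states, matrix = Q), class = "fctbn_joint")
}

# row indices of binary configurations within the lexicographic
# enumeration (first node most significant)
state_index <- function(config, states) {
  n <- ncol(states)
  pow <- 2^((n - 1L):0)
  drop(as.matrix(config) %*% pow) + 1L
}

#' Propagate a distribution through the joint generator
#'
#' \code{p(t) = p0 expm(Q t)}; with the optional earlier time point
#' \code{k}, \code{p(t, k) = p0 expm(Q (t - k))} for \code{t >= k}.
#'
#' @param p0 probability vector over the joint states (sums to 1).
#' @param joint an \code{"fctbn_joint"} (or a plain generator matrix).
#' @param t target time.
#' @param k reference time of \code{p0} (default 0).
#' @return probability vector at time \code{t}.
#' @export
propagate <- function(p0, joint, t, k = 0) {
  Q <- if (inherits(joint, "fctbn_joint")) joint$matrix else as.matrix(joint)
  if (length(p0) != nrow(Q)) stop("p0 length does not match state count")
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  if (t < k) stop("need t >= k")
  if (t == k) return(p0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * (t - k))))
  drop(p0 %*% P)
}

# independent uniformization-based exponential (test oracle and internal
# cross-check): expm(Qt) = sum_k Pois(k; L t) P^k with P = I + Q/L
expm_uniformization <- function(Q, t, tol = 1e-14) {
  L <- max(-diag(Q))
  if (L == 0) return(diag(nrow(Q)))
  P <- diag(nrow(Q)) + Q / L
  lt <- L * t
  w <- exp(-lt)
  term <- diag(nrow(Q))
  acc <- w * term
  k <- 0
  total <- w
  while (total < 1 - tol && k < 100000L) {
    k <- k + 1
    term <- term %*% P
    w <- w * lt / k
    acc <- acc + w * term
    total <- total + w
  }
  acc
}

#' Risk trajectory of one condition
#'
#' \code{P(condition = 1 at time t | baseline joint state at 0, z)} on a
#' time grid, computed exactly by propagating the baseline point mass
#' through the subject's amalgamated generator and summing the mass of
#' joint states with the condition present.
#'
#' @param structure an \code{fctbn_structure}.
#' @param table an \code{fctbn_coef}.
#' @param z covariate vector.
#' @param baseline_state named 0/1 vector over all nodes at time 0.
#' @param condition node name queried.
#' @param time_grid ascending nonnegative times (0 allowed).
#' @return data.frame with columns \code{time} and \code{risk}.
#' @export
risk_trajectory <- function(structure, table, z, baseline_state,
                            condition, time_grid) {
  stopifnot(condition %in% structure$nodes,
            all(diff(time_grid) > 0), all(time_grid >= 0))
  joint <- amalgamate(structure, table, z)
  p0 <- numeric(nrow(joint$states))
  p0[state_index(matrix(baseline_state[structure$nodes], nrow = 1L),
                 joint$states)] <- 1
  on <- joint$states[, condition] == 1L
  risk <- vapply(time_grid, function(t)
    sum(propagate(p0, joint, t)[on]), numeric(1))
  data.frame(time = time_grid, risk = risk)
}

#' Multi-year condition predictions
#'
#' Per condition and year y, the probability that the condition is
#' present at some point during (y - 1, y], matching the annual 0/1
#' coding of \code{\link{discretize_annual}}.  Computed exactly: the
#' joint distribution is propagated to year y - 1 and the probability of
#' avoiding the condition's "present" states throughout the following
#' year is obtained from the sub-generator restricted to the
#' condition-absent states (a taboo probability).  For progressive
#' models this coincides with the marginal risk at the year end.
#'
#' @inheritParams risk_trajectory
#' @param years number of years ahead (>= 1).
#' @return matrix years x conditions of probabilities.
#' @export
predict_next_years <- function(structure, table, z, baseline_state,
                               years) {
  stopifnot(years >= 1)
  joint <- amalgamate(structure, table, z)
  S <- nrow(joint$states)
  p0 <- numeric(S)
  p0[state_index(matrix(baseline_state[structure$nodes], nrow = 1L),
                 joint$states)] <- 1
  out <- matrix(NA_real_, nrow = years, ncol = length(structure$nodes),
                dimnames = list(paste0("year", seq_len(years)),
                                structure$nodes))
  p_prev <- p0
  for (y in seq_len(years)) {
    for (nd in structure$nodes) {
      absent <- which(joint$states[, nd] == 0L)
      if (length(absent) == 0L) {
        out[y, nd] <- 1
        next
      }
      Q00 <- joint$matrix[absent, absent, drop = FALSE]
      surv <- sum(p_prev[absent] %*%
                    as.matrix(Matrix::expm(Matrix::Matrix(Q00))))
      out[y, nd] <- 1 - surv
    }
    p_prev <- propagate(p_prev, joint, 1)
  }
  out
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic:
#' the probability that a random positive outscores a random negative,
#' ties counting one half.
#'
#' @param predicted numeric scores.
#' @param observed 0/1 outcomes (at least one of each class).
#' @return AUC in [0, 1].
#' @export
auc_eval <- function(predicted, observed) {
  observed <- as.integer(observed)
  if (length(predicted) != length(observed))
    stop("scores and outcomes differ in length")
  n1 <- sum(observed == 1L)
  n0 <- sum(observed == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(predicted)
  (sum(r[observed == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-condition per-year AUC of a fitted model on a cohort
#'
#' Evaluation harness: each subject's multi-year condition probabilities
#' are predicted from their covariates and baseline joint state, and
#' scored against the cohort's annual 0/1 coding.  Condition-years where
#' the observed outcomes are single-class are reported as \code{NA}.
#'
#' @param structure an \code{fctbn_structure}.
#' @param table a fitted \code{fctbn_coef}.
#' @param dataset an \code{fctbn_data} (typically held-out subjects).
#' @param years number of years ahead.
#' @param baseline_state named 0/1 vector applied to all subjects
#'   (default: the all-zeros state).
#' @return matrix years x conditions of AUCs.
#' @export
evaluate_auc <- function(structure, table, dataset, years,
                         baseline_state = NULL) {
  nodes <- structure$nodes
  if (is.null(baseline_state))
    baseline_state <- setNames(integer(length(nodes)), nodes)
  obs <- discretize_annual(dataset, years)
  n <- nrow(dataset$covariates)
  pred <- array(NA_real_, dim = c(n, length(nodes), years))
  for (p in seq_len(n))
    pred[p, , ] <- t(predict_next_years(structure, table,
                                        dataset$covariates[p, ],
                                        baseline_state, years))
  out <- matrix(NA_real_, nrow = years, ncol = length(nodes),
                dimnames = list(paste0("year", seq_len(years)), nodes))
  for (y in seq_len(years))
    for (k in seq_along(nodes)) {
      o <- obs[, k, y]
      if (length(unique(o)) == 2L)
        out[y, k] <- auc_eval(pred[, k, y], o)
    }
  out
}
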