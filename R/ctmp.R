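# Continuous-time Markov process primitives: intensity matrices, sojourn
# laws, sufficient statistics and the closed-form rate MLE.

#' Exponential sojourn law of a Markov process state
#'
#' In a homogeneous continuous-time Markov process the time spent in a
#' state with total exit rate \code{rate} is exponential: density
#' \code{rate * exp(-rate * t)} and distribution \code{1 - exp(-rate * t)}.
#'
#' @param rate positive exit rate (per unit time).
#' @param t nonnegative sojourn time(s).
#' @return list with numeric \code{density} and \code{cdf}, vectorised
#'   over \code{t}.
#' @examples
#' sojourn_law(2, 0.5)  # density 2*exp(-1), cdf 1-exp(-1)
#' @export
sojourn_law <- function(rate, t) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0)
    stop("'rate' must be a single positive number")
  if (!is.numeric(t) || any(!is.na(t) & t < 0))
    stop("'t' must be nonnegative")
  list(density = stats::dexp(t, rate), cdf = stats::pexp(t, rate))
}

#' Construct an intensity matrix
#'
#' @param rates square numeric matrix; off-diagonal entries are
#'   nonnegative transition rates, the diagonal is set to minus the row
#'   sum of the off-diagonals (so rows sum to zero).
#' @param states character state labels (defaults to rownames or
#'   \code{s1..sk}).
#' @return a \code{"intensity_matrix"}: the rate matrix with a
#'   \code{states} attribute.
#' @export
intensity_matrix <- function(rates, states = NULL) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) stop("intensity matrix must be square")
  if (is.null(states))
    states <- if (!is.null(rownames(rates))) rownames(rates) else
      paste0("s", seq_len(nrow(rates)))
  diag(rates) <- 0
  diag(rates) <- -rowSums(rates)
  dimnames(rates) <- list(states, states)
  structure(rates, states = states, class = c("intensity_matrix", "matrix"))
}

#' Validate an intensity matrix
#'
#' Checks the two generator properties: rows sum to zero (within
#' \code{tol}) and all off-diagonal entries are nonnegative.
#'
#' @param matrix square numeric matrix.
#' @param tol numeric tolerance for the row-sum test.
#' @return list with logical \code{valid} and a character vector
#'   \code{violations} (empty on a silent pass).
#' @export
validate_intensity <- function(matrix, tol = 1e-9) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix))
    stop("intensity matrix must be square, got ", nrow(matrix), "x",
         ncol(matrix))
  violations <- character(0)
  rs <- rowSums(matrix)
  bad <- which(abs(rs) > tol)
  if (length(bad))
    violations <- c(violations,
                    sprintf("row %d sums to %.3g (should be 0)", bad, rs[bad]))
  off <- matrix
  diag(off) <- 0
  neg <- which(off < 0, arr.ind = TRUE)
  if (nrow(neg))
    violations <- c(violations,
                    sprintf("negative off-diagonal rate at (%d,%d)",
                            neg[, 1], neg[, 2]))
  list(valid = length(violations) == 0L, violations = violations)
}

# canonical string key of a parent configuration, "" when no parents
config_key <- function(parents, states) {
  if (length(parents) == 0L) return("")
  paste(paste0(parents, "=", states), collapse = ",")
}

#' Sufficient statistics of a trajectory dataset
#'
#' For every (node, state, parent configuration) cell, \code{M} counts the
#' observed transitions of the node out of that state under that
#' configuration and \code{T} accumulates the exposure time.  Censored
#' sojourns contribute exposure only.  Every record contributes exposure to
#' every node (during a sojourn all nodes sit in their current state), and
#' the parent configuration is read from the record's interval-start state.
#'
#' @param dataset an \code{fctbn_data} object.
#' @param structure an \code{fctbn_structure}; parent sets determine the
#'   configuration cells.
#' @return data.frame of class \code{"fctbn_suffstats"} with columns
#'   \code{node}, \code{state}, \code{config}, \code{M}, \code{T}.
#' @export
sufficient_stats <- function(dataset, structure) {
  stopifnot(inherits(dataset, "fctbn_data"),
            inherits(structure, "fctbn_structure"))
  if (!setequal(dataset$nodes, structure$nodes))
    stop("dataset and structure disagree on the node set")
  rec <- dataset$records
  out <- vector("list", length(structure$nodes))
  for (i in seq_along(structure$nodes)) {
    nd <- structure$nodes[i]
    pa <- structure$parents[[nd]]
    st <- rec[[nd]]
    if (length(pa)) {
      pmat <- as.matrix(rec[, pa, drop = FALSE])
      cfg <- apply(pmat, 1L, function(r) config_key(pa, r))
    } else cfg <- rep("", nrow(rec))
    key <- paste(st, cfg, sep = "\r")
    Tt <- tapply(rec$t_d, key, sum)
    ev <- (!rec$censored) & rec$event_node == nd
    ev[is.na(ev)] <- FALSE
    Mm <- tapply(as.integer(ev), key, sum)
    parts <- strsplit(names(Tt), "\r")
    out[[i]] <- data.frame(
      node = nd,
      state = as.integer(vapply(parts, `[`, "", 1L)),
      config = vapply(parts, function(p) if (length(p) > 1L) p[2L] else "",
                      ""),
      M = as.integer(Mm[names(Tt)]),
      T = as.numeric(Tt),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fctbn_suffstats", "data.frame")
  res
}

#' Closed-form maximum likelihood conditional intensities
#'
#' The event-history likelihood in terms of transition counts \code{M} and
#' exposures \code{T} is maximised in closed form by \code{qhat = M / T}.
#' Cells with zero exposure carry no information and are flagged
#' inestimable rather than raising an error.
#'
#' @param stats an \code{"fctbn_suffstats"} data.frame.
#' @return the same table with columns \code{qhat} and logical
#'   \code{estimable} appended.
#' @export
mle_intensities <- function(stats) {
  stopifnot(is.data.frame(stats), all(c("M", "T") %in% names(stats)))
  est <- stats$T > 0
  qhat <- ifelse(est, stats$M / pmax(stats$T, .Machine$double.xmin), NA_real_)
  out <- stats
  out$qhat <- qhat
  out$estimable <- est
  out
}

#' Enumerate the joint state space
#'
#' Lists every joint configuration of a set of finite-state nodes in
#' lexicographic order by node declaration order (the first node varies
#' slowest).  The joint space of n binary nodes has 2^n configurations,
#' e.g. 1,024 for ten binary conditions.
#'
#' @param n_states named integer vector: per-node state count (>= 2);
#'   names are node labels.
#' @param cap maximum number of configurations to enumerate.
#' @return integer matrix, one row per configuration, states coded
#'   \code{0 .. k-1}, columns named after the nodes.
#' @export
enumerate_joint_states <- function(n_states, cap = 2^16) {
  if (length(n_states) < 1L) stop("need at least one node")
  if (any(n_states < 2L)) stop("each node needs at least 2 states")
  if (is.null(names(n_states)))
    names(n_states) <- paste0("X", seq_along(n_states))
  total <- prod(as.numeric(n_states))
  if (total > cap)
    stop("joint state space has ", format(total, big.mark = ","),
         " configurations, exceeding the cap of ", cap)
  n <- length(n_states)
  grid <- expand.grid(rev(lapply(n_states, function(k) 0:(k - 1L))),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[, rev(seq_len(n)), drop = FALSE])
  colnames(grid) <- names(n_states)
  storage.mode(grid) <- "integer"
  rownames(grid) <- NULL
  grid
}
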