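# The functional CTBN model: network structure, coefficient tables,
# covariate-dependent conditional intensities and the event-history
# likelihood with analytic gradient.

#' Define a functional CTBN structure
#'
#' The structure names the binary condition nodes and, per node, the set of
#' candidate parents considered during learning.  Cycles across nodes are
#' permitted (a condition can be both cause and effect); self-loops are
#' not.  The number of parents per node is capped because the parameter
#' count grows with it.
#'
#' @param nodes character vector of condition names (order is the
#'   declaration order used throughout).
#' @param parents named list mapping each node to a character vector of
#'   candidate parents, or the string \code{"all"} (default) to use every
#'   other node, or \code{"none"} for independent nodes.
#' @param max_parents cap on the per-node parent-set size (default 4).
#' @param progressive logical; if \code{TRUE} the model is progressive
#'   (no remission): the 1 -> 0 rate of every node is frozen at zero and
#'   carries no coefficients.  If \code{FALSE} both transition directions
#'   get their own coefficient groups.
#' @return object of class \code{"fctbn_structure"}.
#' @export
fctbn_structure <- function(nodes, parents = "all", max_parents = 4L,
                            progressive = FALSE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (identical(parents, "all")) {
    parents <- lapply(nodes, function(nd) setdiff(nodes, nd))
    names(parents) <- nodes
  } else if (identical(parents, "none")) {
    parents <- setNames(rep(list(character(0)), length(nodes)), nodes)
  }
  if (!setequal(names(parents), nodes))
    stop("'parents' must have one entry per node")
  parents <- parents[nodes]
  for (nd in nodes) {
    pa <- as.character(parents[[nd]])
    if (nd %in% pa) stop("node ", nd, " cannot be its own parent")
    if (length(setdiff(pa, nodes)))
      stop("unknown parent(s) of ", nd, ": ",
           paste(setdiff(pa, nodes), collapse = ", "))
    if (length(pa) > max_parents)
      stop("node ", nd, " has ", length(pa),
           " candidate parents, exceeding max_parents = ", max_parents)
    parents[[nd]] <- pa
  }
  structure(list(nodes = nodes, parents = parents,
                 max_parents = as.integer(max_parents),
                 progressive = isTRUE(progressive)),
            class = "fctbn_structure")
}

#' @export
print.fctbn_structure <- function(x, ...) {
  cat("fctbn structure:", length(x$nodes), "binary nodes",
      if (x$progressive) "(progressive, no remission)" else
        "(reversible)", "\n")
  for (nd in x$nodes)
    cat("  ", nd, " <- {", paste(x$parents[[nd]], collapse = ", "), "}\n",
        sep = "")
  invisible(x)
}

# transition directions carried by the model
directions <- function(structure)
  if (structure$progressive) "01" else c("01", "10")

#' Create a coefficient table
#'
#' One coefficient group per (child node, transition direction, source),
#' where source is the baseline or one of the node's candidate parents.
#' Every group is a vector of length m + 1: intercept followed by the m
#' covariate slopes.  The log intensity of a node's transition is the sum
#' of the baseline group's linear predictor and the predictors of its
#' currently active parents, so parent effects are multiplicative on the
#' rate scale.
#'
#' @param structure an \code{fctbn_structure}.
#' @param m number of covariates.
#' @param covariate_names optional character names for the m covariates.
#' @param init numeric fill value (default 0).
#' @return object of class \code{"fctbn_coef"}: a nested list
#'   \code{x[[node]][[direction]]} of (m+1) x (1 + #parents) matrices with
#'   columns \code{".baseline"}, then the parents.
#' @export
fctbn_coef <- function(structure, m, covariate_names = NULL, init = 0) {
  stopifnot(inherits(structure, "fctbn_structure"), m >= 0)
  if (is.null(covariate_names) && m > 0)
    covariate_names <- paste0("z", seq_len(m))
  rn <- c("(Intercept)", covariate_names)
  out <- lapply(structure$nodes, function(nd) {
    cn <- c(".baseline", structure$parents[[nd]])
    mats <- lapply(directions(structure), function(d)
      matrix(init, nrow = m + 1L, ncol = length(cn),
             dimnames = list(rn, cn)))
    setNames(mats, directions(structure))
  })
  names(out) <- structure$nodes
  structure(out, m = as.integer(m), covariates = covariate_names,
            class = "fctbn_coef")
}

#' Set one coefficient group
#'
#' @param table an \code{fctbn_coef}.
#' @param node,direction,source group address; \code{source} is
#'   \code{".baseline"} or a parent name.
#' @param value numeric vector of length m + 1 (recycled if scalar).
#' @return the modified table.
#' @export
set_group <- function(table, node, direction, source, value) {
  stopifnot(inherits(table, "fctbn_coef"))
  table[[node]][[direction]][, source] <- value
  table
}

#' Covariate-dependent conditional transition intensity
#'
#' Computes \code{q = exp(zt . beta_baseline + sum_k zt . beta_k)} over
#' the active parents k, with \code{zt = c(1, z)}.  This is the Poisson
#' regression form of the conditional intensity; the multiplicative parent
#' assumption makes each active parent contribute a rate factor
#' \code{exp(zt . beta_k)}.
#'
#' @param table an \code{fctbn_coef}.
#' @param node child node name.
#' @param direction \code{"01"} (acquisition) or \code{"10"} (remission).
#' @param active_parents character vector of parents currently in state 1
#'   (subset of the node's candidate parents).
#' @param z numeric covariate vector of length m.
#' @return positive scalar rate.
#' @export
conditional_intensity <- function(table, node, direction, active_parents,
                                  z = numeric(0)) {
  stopifnot(inherits(table, "fctbn_coef"))
  if (!node %in% names(table)) stop("unknown node: ", node)
  B <- table[[node]][[direction]]
  if (is.null(B)) {
    if (direction == "10") return(0)  # progressive model: no remission
    stop("unknown direction: ", direction)
  }
  if (length(setdiff(active_parents, colnames(B))))
    stop("unknown parent(s) of ", node, ": ",
         paste(setdiff(active_parents, colnames(B)), collapse = ", "))
  if (length(z) != nrow(B) - 1L)
    stop("covariate vector has length ", length(z), ", expected ",
         nrow(B) - 1L)
  zt <- c(1, z)
  eta <- sum(zt * B[, ".baseline"])
  for (p in active_parents) eta <- eta + sum(zt * B[, p])
  exp(eta)
}

#' Per-subject conditional intensity matrices
#'
#' Instantiates, for one covariate vector, the full set of 2 x 2
#' conditional intensity matrices of every node: one matrix per parent
#' configuration, rows summing to zero.
#'
#' @inheritParams conditional_intensity
#' @param structure an \code{fctbn_structure}.
#' @return named list: per node, a list of entries with elements
#'   \code{parent_config} (named 0/1 vector) and \code{matrix}
#'   (an \code{intensity_matrix} over states 0/1).
#' @export
build_subject_cims <- function(structure, table, z = numeric(0)) {
  out <- lapply(structure$nodes, function(nd) {
    pa <- structure$parents[[nd]]
    cfgs <- if (length(pa))
      enumerate_joint_states(setNames(rep(2L, length(pa)), pa))
    else matrix(integer(0), nrow = 1L, ncol = 0L)
    lapply(seq_len(nrow(cfgs)), function(i) {
      cfg <- cfgs[i, , drop = TRUE]
      act <- pa[cfg == 1L]
      q01 <- conditional_intensity(table, nd, "01", act, z)
      q10 <- if (structure$progressive) 0
             else conditional_intensity(table, nd, "10", act, z)
      list(parent_config = setNames(as.integer(cfg), pa),
           matrix = intensity_matrix(matrix(c(0, q10, q01, 0), 2L, 2L,
                                            dimnames = list(c("0", "1"),
                                                            c("0", "1")))))
    })
  })
  names(out) <- structure$nodes
  out
}

# --- likelihood machinery ---------------------------------------------------

# Per (node, direction), records where the node occupies the direction's
# source state contribute exposure t_d at rate exp(X theta); the record
# whose event is this (node, direction) additionally contributes log q.
# X has one column block of width m+1 per source (baseline first, then each
# parent, zeroed when that parent is off), so X %*% as.vector(B) is the
# log intensity.  Shared by the likelihood, gradient and FISTA solver.
build_design <- function(structure, dataset) {
  rec <- dataset$records
  m <- ncol(dataset$covariates)
  Zt <- cbind(1, dataset$covariates)[rec$subject, , drop = FALSE]
  des <- lapply(structure$nodes, function(nd) {
    pa <- structure$parents[[nd]]
    st <- rec[[nd]]
    out <- list()
    for (d in directions(structure)) {
      src <- if (d == "01") 0L else 1L
      rows <- which(st == src)
      if (length(pa)) {
        U <- as.matrix(rec[rows, pa, drop = FALSE])
        X <- do.call(cbind, c(list(Zt[rows, , drop = FALSE]),
                              lapply(seq_along(pa), function(k)
                                Zt[rows, , drop = FALSE] * U[, k])))
      } else {
        X <- Zt[rows, , drop = FALSE]
      }
      y <- as.numeric(!rec$censored[rows] & !is.na(rec$event_node[rows]) &
                        rec$event_node[rows] == nd)
      out[[d]] <- list(X = X, y = y, t = rec$t_d[rows], rows = rows)
    }
    out
  })
  names(des) <- structure$nodes
  attr(des, "m") <- m
  des
}

nll_block <- function(theta, blk) {
  eta <- drop(blk$X %*% theta)
  sum(blk$t * exp(eta)) - sum(blk$y * eta)
}

grad_block <- function(theta, blk) {
  eta <- drop(blk$X %*% theta)
  drop(crossprod(blk$X, blk$t * exp(eta) - blk$y))
}

#' Negative log-likelihood of a trajectory dataset
#'
#' The event-history likelihood decomposes over records: during every
#' sojourn each node accumulates exposure \code{q * t_d} at its currently
#' active exit rate, and the transitioning node of a non-censored record
#' contributes \code{log q}.  Censored records contribute exposure only.
#'
#' @param table an \code{fctbn_coef}.
#' @param structure an \code{fctbn_structure}.
#' @param dataset an \code{fctbn_data}.
#' @return scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(table, structure, dataset) {
  des <- build_design(structure, dataset)
  tot <- 0
  for (nd in structure$nodes)
    for (d in directions(structure))
      tot <- tot + nll_block(as.vector(table[[nd]][[d]]), des[[nd]][[d]])
  tot
}

#' Analytic gradient of the negative log-likelihood
#'
#' @inheritParams neg_log_likelihood
#' @return an \code{fctbn_coef}-shaped object holding the partial
#'   derivatives with respect to every coefficient.
#' @export
nll_gradient <- function(table, structure, dataset) {
  des <- build_design(structure, dataset)
  out <- fctbn_coef(structure, attr(des, "m"),
                    covariate_names = attr(table, "covariates"))
  for (nd in structure$nodes)
    for (d in directions(structure)) {
      g <- grad_block(as.vector(table[[nd]][[d]]), des[[nd]][[d]])
      out[[nd]][[d]][] <- g
    }
  out
}

#' Parameter count of the model
#'
#' Under the full parent-configuration parameterisation every node carries
#' one coefficient vector per direction per configuration of its parents;
#' the multiplicative assumption replaces the 2^p configurations by 1 + p
#' additive sources, shrinking the count from
#' \code{n (m+1) 2 * 2^p} to \code{n (m+1) 2 (p+1)} with p the parent cap.
#'
#' @param structure an \code{fctbn_structure}.
#' @param m covariate count.
#' @param mode \code{"multiplicative"} (default) or \code{"full"}.
#' @return integer.
#' @export
parameter_count <- function(structure, m,
                            mode = c("multiplicative", "full")) {
  mode <- match.arg(mode)
  n <- length(structure$nodes)
  p <- structure$max_parents
  if (mode == "full") as.integer(n * (m + 1) * 2 * 2^p)
  else as.integer(n * (m + 1) * 2 * (p + 1))
}

# --- serialization ----------------------------------------------------------

#' Write / read a model as a structured text document
#'
#' Serialises a structure plus coefficient table to JSON with
#' full-precision numbers, so that write then read round-trips exactly.
#'
#' @param structure an \code{fctbn_structure}.
#' @param table an \code{fctbn_coef} (or \code{NULL} for structure only).
#' @param path file path.
#' @return \code{read_fctbn} returns \code{list(structure, table)}.
#' @export
write_fctbn <- function(structure, table, path) {
  doc <- list(
    format = "fctbn-model/1",
    nodes = structure$nodes,
    parents = structure$parents,
    max_parents = structure$max_parents,
    progressive = structure$progressive,
    m = if (!is.null(table)) attr(table, "m") else NULL,
    covariates = if (!is.null(table)) attr(table, "covariates") else NULL,
    coefficients = if (!is.null(table))
      lapply(structure$nodes, function(nd)
        lapply(table[[nd]], function(B) as.data.frame(B)))
    else NULL)
  if (!is.null(doc$coefficients)) names(doc$coefficients) <- structure$nodes
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fctbn
#' @export
read_fctbn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  parents <- lapply(doc$parents, function(p)
    if (length(p)) as.character(unlist(p)) else character(0))
  names(parents) <- names(doc$parents)
  str <- fctbn_structure(doc$nodes, parents,
                         max_parents = doc$max_parents,
                         progressive = doc$progressive)
  tab <- NULL
  if (!is.null(doc$coefficients)) {
    tab <- fctbn_coef(str, doc$m, covariate_names = doc$covariates)
    for (nd in str$nodes)
      for (d in names(tab[[nd]])) {
        B <- as.matrix(doc$coefficients[[nd]][[d]])
        tab[[nd]][[d]][] <- B
      }
  }
  list(structure = str, table = tab)
}
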