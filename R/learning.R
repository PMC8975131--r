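# Joint structure and parameter learning: unpenalized Poisson-regression
# fits, adaptive group weights, group soft-thresholding, monotone FISTA
# with backtracking, regularization path and cross-validated lambda.

# --- covariate standardization ---------------------------------------------

# standardize subject covariates (zero mean / unit sd over subjects);
# constant columns are centred only
standardize_data <- function(dataset) {
  Z <- dataset$covariates
  if (ncol(Z) == 0L)
    return(list(data = dataset, center = numeric(0), scale = numeric(0)))
  mu <- colMeans(Z)
  sdv <- apply(Z, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Zs <- sweep(sweep(Z, 2L, mu), 2L, sdv, "/")
  d2 <- dataset
  d2$covariates <- Zs
  list(data = d2, center = mu, scale = sdv)
}

# map a coefficient table fitted on standardized covariates back to the
# original covariate scale: slopes divide by sd, intercept absorbs means.
# exact zeros stay exactly zero, so active groups are scale-invariant.
unstandardize_coef <- function(table, center, scale) {
  if (length(center) == 0L) return(table)
  out <- table
  for (nd in names(table))
    for (d in names(table[[nd]])) {
      B <- table[[nd]][[d]]
      slopes <- B[-1L, , drop = FALSE] / scale
      B[1L, ] <- B[1L, ] - colSums(B[-1L, , drop = FALSE] * center / scale)
      B[-1L, ] <- slopes
      out[[nd]][[d]] <- B
    }
  out
}

# --- penalized group bookkeeping -------------------------------------------

# per node: list of penalized groups; each group is a set of indices into
# the node's stacked parameter vector c(vec(B_01), vec(B_10)).
# grouping "edge" couples both directions of a (child, parent) pair so an
# edge dies as a unit; "direction" penalizes each direction separately.
node_groups <- function(structure, m, node, grouping = "edge") {
  pa <- structure$parents[[node]]
  dirs <- directions(structure)
  w <- m + 1L                         # block width per source
  nsrc <- 1L + length(pa)
  blk <- function(di, si) ((di - 1L) * nsrc + (si - 1L)) * w + seq_len(w)
  baseline <- unlist(lapply(seq_along(dirs), function(di) blk(di, 1L)))
  groups <- list()
  if (length(pa)) {
    if (grouping == "edge") {
      for (k in seq_along(pa)) {
        idx <- unlist(lapply(seq_along(dirs), function(di) blk(di, k + 1L)))
        groups[[paste0(pa[k], "->", node)]] <- idx
      }
    } else {
      for (di in seq_along(dirs))
        for (k in seq_along(pa))
          groups[[paste0(pa[k], "->", node, ":", dirs[di])]] <-
            blk(di, k + 1L)
    }
  }
  list(baseline = baseline, groups = groups, width = length(dirs) * nsrc * w)
}

theta_get <- function(table, node, dirs)
  unlist(lapply(dirs, function(d) as.vector(table[[node]][[d]])),
         use.names = FALSE)

theta_set <- function(table, node, dirs, theta) {
  off <- 0L
  for (d in dirs) {
    B <- table[[node]][[d]]
    n <- length(B)
    table[[node]][[d]][] <- theta[off + seq_len(n)]
    off <- off + n
  }
  table
}

#' Adaptive group-lasso weights
#'
#' Each penalized group j receives the multiplier
#' \code{1 / max(||beta_tilde_j||, floor)}, so groups the unpenalized fit
#' estimates as large are shrunk little and near-zero groups are pushed
#' hard toward exact zero.  The floor guards against infinite penalties.
#'
#' @param beta_tilde an \code{fctbn_coef} of unpenalized estimates.
#' @param structure the matching \code{fctbn_structure}.
#' @param floor small positive lower bound on the group norm.
#' @param grouping \code{"edge"} (both directions of a parent-child pair
#'   in one group, the default) or \code{"direction"}.
#' @return named numeric vector of weights, one per penalized group.
#' @export
adaptive_weights <- function(beta_tilde, structure, floor = 1e-4,
                             grouping = c("edge", "direction")) {
  grouping <- match.arg(grouping)
  m <- attr(beta_tilde, "m")
  dirs <- directions(structure)
  out <- numeric(0)
  for (nd in structure$nodes) {
    gi <- node_groups(structure, m, nd, grouping)
    th <- theta_get(beta_tilde, nd, dirs)
    for (g in names(gi$groups)) {
      nrm <- sqrt(sum(th[gi$groups[[g]]]^2))
      out[[g]] <- 1 / max(nrm, floor)
    }
  }
  out
}

#' Group soft-thresholding operator
#'
#' The proximal map of \code{threshold * ||v||_2}: scales \code{v} by
#' \code{max(0, 1 - threshold / ||v||_2)}, returning an exact zero vector
#' when the norm is at or below the threshold.
#'
#' @param v numeric vector.
#' @param threshold nonnegative scalar.
#' @return shrunk vector.
#' @export
group_prox <- function(v, threshold) {
  if (threshold < 0) stop("threshold must be nonnegative")
  if (threshold == 0) return(v)
  nrm <- sqrt(sum(v^2))
  if (nrm <= threshold) return(rep(0, length(v)))
  v * (1 - threshold / nrm)
}

# --- unpenalized fit --------------------------------------------------------

#' Unpenalized maximum-likelihood fit
#'
#' Each (node, direction) block of the likelihood is an ordinary Poisson
#' regression with log-exposure offset, fitted by iteratively reweighted
#' least squares (\code{glm.fit}).  Covariates are standardized internally;
#' coefficients are reported on the original scale, with the
#' standardized-scale table in attribute \code{"std"} (used to form the
#' adaptive weights).
#'
#' @param structure an \code{fctbn_structure}.
#' @param dataset an \code{fctbn_data}.
#' @param standardize standardize covariates internally (default TRUE).
#' @return an \code{fctbn_coef} on the original covariate scale.
#' @export
fit_unpenalized <- function(structure, dataset, standardize = TRUE) {
  sd_info <- if (standardize) standardize_data(dataset)
  else list(data = dataset, center = numeric(0), scale = numeric(0))
  des <- build_design(structure, sd_info$data)
  m <- attr(des, "m")
  tab <- fctbn_coef(structure, m,
                    covariate_names = colnames(dataset$covariates))
  for (nd in structure$nodes)
    for (d in directions(structure)) {
      blk <- des[[nd]][[d]]
      if (length(blk$y) == 0L || sum(blk$y) == 0L)
        stop("no observed ", d, " transitions for node ", nd,
             "; unpenalized fit is unbounded")
      fit <- stats::glm.fit(blk$X, blk$y, family = stats::poisson(),
                            offset = log(blk$t),
                            control = list(epsilon = 1e-12, maxit = 200L))
      if (!fit$converged)
        stop("IRLS did not converge for node ", nd, " direction ", d)
      tab[[nd]][[d]][] <- fit$coefficients
    }
  out <- unstandardize_coef(tab, sd_info$center, sd_info$scale)
  attr(out, "std") <- list(table = tab, center = sd_info$center,
                           scale = sd_info$scale)
  out
}

# --- FISTA ------------------------------------------------------------------

#' Solver options for \code{fista_fit}
#'
#' @param max_iter iteration cap.
#' @param tol relative objective-change tolerance.
#' @param patience number of consecutive iterations the tolerance must
#'   hold before declaring convergence.
#' @param L0 initial Lipschitz estimate for backtracking.
#' @param backtrack_factor multiplier applied to L when the majorization
#'   test fails.
#' @param group_size \code{"sqrt"} (default) scales each group's penalty
#'   by the square root of its coefficient count, the usual group-lasso
#'   size correction; \code{"linear"} uses the count itself.
#' @param grouping \code{"edge"} or \code{"direction"} (see
#'   \code{\link{adaptive_weights}}).
#' @return list of options.
#' @export
fista_opts <- function(max_iter = 50000L, tol = 1e-7, patience = 10L,
                       L0 = 1, backtrack_factor = 2,
                       group_size = c("sqrt", "linear"),
                       grouping = c("edge", "direction")) {
  list(max_iter = as.integer(max_iter), tol = tol,
       patience = as.integer(patience), L0 = L0,
       backtrack_factor = backtrack_factor,
       group_size = match.arg(group_size),
       grouping = match.arg(grouping))
}

# monotone FISTA with backtracking on one node's stacked parameter vector
fista_node <- function(blocks, gi, lambda_thresholds, theta0, opts) {
  f_val <- function(th) {
    v <- 0
    off <- 0L
    for (b in blocks) {
      nc <- ncol(b$X)
      v <- v + nll_block(th[off + seq_len(nc)], b)
      off <- off + nc
    }
    v
  }
  f_grad <- function(th) {
    g <- numeric(length(th))
    off <- 0L
    for (b in blocks) {
      nc <- ncol(b$X)
      g[off + seq_len(nc)] <- grad_block(th[off + seq_len(nc)], b)
      off <- off + nc
    }
    g
  }
  pen_val <- function(th) {
    v <- 0
    for (g in names(gi$groups))
      v <- v + lambda_thresholds[[g]] *
        sqrt(sum(th[gi$groups[[g]]]^2))
    v
  }
  prox <- function(th, step) {
    for (g in names(gi$groups))
      th[gi$groups[[g]]] <-
        group_prox(th[gi$groups[[g]]], step * lambda_thresholds[[g]])
    th
  }
  x <- theta0
  y <- x
  tk <- 1
  L <- opts$L0
  Fx <- f_val(x) + pen_val(x)
  trace <- numeric(0)
  ok_run <- 0L
  converged <- FALSE
  for (it in seq_len(opts$max_iter)) {
    fy <- f_val(y)
    gy <- f_grad(y)
    if (!is.finite(fy) || any(!is.finite(gy))) {
      # extrapolation overshot; restart momentum from the last iterate
      y <- x
      tk <- 1
      fy <- f_val(y)
      gy <- f_grad(y)
      if (!is.finite(fy) || any(!is.finite(gy)))
        stop("FISTA diverged: objective not finite (L = ", L, ")")
    }
    repeat {
      z <- prox(y - gy / L, 1 / L)
      dz <- z - y
      fz <- f_val(z)
      if (is.finite(fz) &&
          fz <= fy + sum(gy * dz) + L / 2 * sum(dz^2) + 1e-12)
        break
      L <- L * opts$backtrack_factor
      if (L > 1e18) stop("FISTA step-size search failed (L exceeded 1e18)")
    }
    Fz <- fz + pen_val(z)
    # monotone variant: never accept an objective increase
    x_new <- if (Fz <= Fx) z else x
    F_new <- min(Fz, Fx)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + (tk / t_new) * (z - x_new) +
      ((tk - 1) / t_new) * (x_new - x)
    rel <- abs(Fx - F_new) / (1 + abs(F_new))
    x <- x_new
    Fx <- F_new
    tk <- t_new
    trace <- c(trace, Fx)
    ok_run <- if (rel < opts$tol) ok_run + 1L else 0L
    if (ok_run >= opts$patience) {
      converged <- TRUE
      break
    }
    L <- max(L / 1.5, 1e-10)  # allow the step to grow again
  }
  list(theta = x, objective = Fx, trace = trace, converged = converged,
       iterations = length(trace), L = L)
}

#' Penalized fit by monotone FISTA
#'
#' Minimises the negative log-likelihood plus the adaptive group penalty
#' \code{sum_j size_j * lambda * w_j * ||beta_j||_2} over the penalized
#' parent groups; baseline groups are never penalized.  Uses proximal
#' gradient steps with backtracking line search and Nesterov momentum in
#' the monotone (objective never increases) variant.  Covariates are
#' standardized internally and the penalty applies on that scale;
#' reported coefficients are back-transformed.
#'
#' @param structure an \code{fctbn_structure}.
#' @param dataset an \code{fctbn_data}.
#' @param lambda nonnegative penalty level.
#' @param weights named per-group adaptive multipliers; computed from an
#'   internal unpenalized fit when \code{NULL} and \code{lambda > 0}.
#' @param opts solver options from \code{\link{fista_opts}}.
#' @param init optional \code{fctbn_coef} (original scale) to initialise
#'   from (warm start).
#' @param standardize standardize covariates internally (default TRUE).
#' @return object of class \code{"fctbn_fit"}: coefficients (original
#'   scale), standardized-scale coefficients, objective trace, lambda,
#'   convergence flag, active penalized groups, and the per-group weights
#'   used.
#' @export
fista_fit <- function(structure, dataset, lambda, weights = NULL,
                      opts = fista_opts(), init = NULL,
                      standardize = TRUE) {
  stopifnot(lambda >= 0)
  sd_info <- if (standardize) standardize_data(dataset)
  else list(data = dataset, center = numeric(0), scale = numeric(0))
  des <- build_design(structure, sd_info$data)
  m <- attr(des, "m")
  dirs <- directions(structure)
  if (is.null(weights) && lambda > 0) {
    bt <- fit_unpenalized(structure, dataset, standardize = standardize)
    weights <- adaptive_weights(attr(bt, "std")$table, structure,
                                grouping = opts$grouping)
  }
  tab_std <- fctbn_coef(structure, m,
                        covariate_names = colnames(dataset$covariates))
  if (!is.null(init)) {
    init_std <- restandardize_coef(init, sd_info$center, sd_info$scale)
    for (nd in structure$nodes)
      for (d in dirs) tab_std[[nd]][[d]][] <- init_std[[nd]][[d]]
  }
  objective <- 0
  trace_all <- list()
  converged <- TRUE
  iterations <- 0L
  for (nd in structure$nodes) {
    gi <- node_groups(structure, m, nd, opts$grouping)
    thr <- vapply(names(gi$groups), function(g) {
      sz <- length(gi$groups[[g]])
      sf <- if (opts$group_size == "sqrt") sqrt(sz) else sz
      lambda * sf * (if (!is.null(weights)) weights[[g]] else 1)
    }, numeric(1))
    names(thr) <- names(gi$groups)
    blocks <- lapply(dirs, function(d) des[[nd]][[d]])
    res <- fista_node(blocks, gi, thr, theta_get(tab_std, nd, dirs), opts)
    tab_std <- theta_set(tab_std, nd, dirs, res$theta)
    objective <- objective + res$objective
    trace_all[[nd]] <- res$trace
    converged <- converged && res$converged
    iterations <- max(iterations, res$iterations)
  }
  coef_orig <- unstandardize_coef(tab_std, sd_info$center, sd_info$scale)
  active <- active_groups(tab_std, structure, opts$grouping)
  structure(list(coefficients = coef_orig,
                 coefficients_std = tab_std,
                 standardization = list(center = sd_info$center,
                                        scale = sd_info$scale),
                 objective = objective,
                 objective_trace = trace_all,
                 lambda = lambda, weights = weights,
                 converged = converged, iterations = iterations,
                 active_groups = active, opts = opts),
            class = "fctbn_fit")
}

# map an original-scale table onto standardized covariates (inverse of
# unstandardize_coef); used for warm starts
restandardize_coef <- function(table, center, scale) {
  if (length(center) == 0L) return(table)
  out <- table
  for (nd in names(table))
    for (d in names(table[[nd]])) {
      B <- table[[nd]][[d]]
      B[1L, ] <- B[1L, ] + colSums(B[-1L, , drop = FALSE] * center)
      B[-1L, ] <- B[-1L, , drop = FALSE] * scale
      out[[nd]][[d]] <- B
    }
  out
}

#' Active penalized groups of a coefficient table
#'
#' @param table an \code{fctbn_coef}.
#' @param structure the matching structure.
#' @param grouping \code{"edge"} or \code{"direction"}.
#' @return character vector of group labels with nonzero norm.
#' @export
active_groups <- function(table, structure, grouping = "edge") {
  m <- attr(table, "m")
  dirs <- directions(structure)
  out <- character(0)
  for (nd in structure$nodes) {
    gi <- node_groups(structure, m, nd, grouping)
    th <- theta_get(table, nd, dirs)
    for (g in names(gi$groups))
      if (any(th[gi$groups[[g]]] != 0)) out <- c(out, g)
  }
  out
}

#' @export
print.fctbn_fit <- function(x, ...) {
  cat("fctbn penalized fit (lambda =", format(x$lambda), ")\n")
  cat("  objective:    ", format(x$objective), "\n")
  cat("  converged:    ", x$converged, "after", x$iterations,
      "iterations (max over nodes)\n")
  cat("  active groups:", length(x$active_groups), "\n")
  invisible(x)
}

# fraction of penalized coefficients that are exactly zero
sparsity_ratio <- function(fit, structure) {
  m <- attr(fit$coefficients_std, "m")
  dirs <- directions(structure)
  zeroed <- 0L
  total <- 0L
  for (nd in structure$nodes) {
    gi <- node_groups(structure, m, nd, fit$opts$grouping)
    th <- theta_get(fit$coefficients_std, nd, dirs)
    for (g in names(gi$groups)) {
      total <- total + length(gi$groups[[g]])
      zeroed <- zeroed + sum(th[gi$groups[[g]]] == 0)
    }
  }
  if (total == 0L) return(0)
  zeroed / total
}

#' Regularization path
#'
#' Fits the model over an ascending lambda grid with warm starts
#' (small to large), reporting the sparsity ratio (fraction of penalized
#' coefficients exactly zero) along the path.  The path is how the level
#' of sparsity of the learned graph is controlled.
#'
#' @param structure an \code{fctbn_structure}.
#' @param dataset an \code{fctbn_data}.
#' @param lambda_grid nonnegative values, sorted ascending.
#' @param opts solver options.
#' @param weights optional adaptive weights (computed once internally
#'   when NULL).
#' @return object of class \code{"fctbn_path"}: a summary data.frame
#'   (lambda, objective, sparsity, n_active_groups, converged) plus the
#'   list of fits.
#' @export
regularization_path <- function(structure, dataset, lambda_grid,
                                opts = fista_opts(), weights = NULL) {
  if (is.unsorted(lambda_grid))
    stop("lambda_grid must be sorted ascending")
  if (is.null(weights) && any(lambda_grid > 0)) {
    bt <- fit_unpenalized(structure, dataset)
    weights <- adaptive_weights(attr(bt, "std")$table, structure,
                                grouping = opts$grouping)
  }
  fits <- vector("list", length(lambda_grid))
  init <- NULL
  for (i in seq_along(lambda_grid)) {
    fits[[i]] <- fista_fit(structure, dataset, lambda_grid[i],
                           weights = weights, opts = opts, init = init)
    init <- fits[[i]]$coefficients
  }
  summary <- data.frame(
    lambda = lambda_grid,
    objective = vapply(fits, `[[`, 0, "objective"),
    sparsity = vapply(fits, sparsity_ratio, 0, structure = structure),
    n_active_groups = vapply(fits, function(f) length(f$active_groups), 0L),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  structure(list(summary = summary, fits = fits, weights = weights),
            class = "fctbn_path")
}

#' @export
print.fctbn_path <- function(x, ...) {
  cat("fctbn regularization path\n")
  print(x$summary)
  invisible(x)
}

#' Cross-validated lambda selection
#'
#' Subjects (never individual records) are partitioned into folds; for
#' every lambda on the grid the model is fitted on the training folds and
#' scored by the mean held-out negative log-likelihood per record.  Ties
#' are broken toward the larger lambda (the sparser model).  The default
#' grid is \code{0, 1, 10, ..., 1e6}.
#'
#' @param structure an \code{fctbn_structure}.
#' @param dataset an \code{fctbn_data}.
#' @param lambda_grid candidate penalty levels.
#' @param k_folds number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @param opts solver options.
#' @return list with \code{best_lambda}, \code{cv_table} (lambda,
#'   cv_error), \code{fold_id}, and \code{fit} — the final model refitted
#'   on the full data at the selected lambda.
#' @export
cross_validate <- function(structure, dataset,
                           lambda_grid = c(0, 10^(0:6)), k_folds = 5L,
                           seed = 1L, opts = fista_opts()) {
  stopifnot(k_folds >= 2L)
  n <- nrow(dataset$covariates)
  if (n < k_folds) stop("fewer subjects than folds")
  lambda_grid <- sort(lambda_grid)
  fold_id <- withr::with_seed(seed,
    sample(rep_len(seq_len(k_folds), n)))
  err <- matrix(NA_real_, nrow = length(lambda_grid), ncol = k_folds)
  for (f in seq_len(k_folds)) {
    tr <- subset_subjects(dataset, which(fold_id != f))
    te <- subset_subjects(dataset, which(fold_id == f))
    if (nrow(te$records) == 0L) stop("empty fold ", f)
    bt <- fit_unpenalized(structure, tr)
    w <- adaptive_weights(attr(bt, "std")$table, structure,
                          grouping = opts$grouping)
    init <- NULL
    for (i in seq_along(lambda_grid)) {
      fit <- fista_fit(structure, tr, lambda_grid[i], weights = w,
                       opts = opts, init = init)
      init <- fit$coefficients
      err[i, f] <- neg_log_likelihood(fit$coefficients, structure, te) /
        nrow(te$records)
    }
  }
  cv_error <- rowMeans(err)
  # argmin with ties toward larger lambda
  best_i <- max(which(cv_error <= min(cv_error) + 1e-12))
  best_lambda <- lambda_grid[best_i]
  final <- fista_fit(structure, dataset, best_lambda, opts = opts)
  list(best_lambda = best_lambda,
       cv_table = data.frame(lambda = lambda_grid, cv_error = cv_error),
       fold_errors = err, fold_id = fold_id, fit = final)
}
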