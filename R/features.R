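# Risk-factor preprocessing: one-hot encoding and linear PCA used to
# compress many exogenous covariates into a few scores before fitting.

#' Numerically encode a covariate table
#'
#' Numeric columns pass through; factor/character columns are one-hot
#' encoded dropping the first level (treatment coding).
#'
#' @param df data.frame of covariates.
#' @return numeric matrix with informative column names.
#' @export
encode_covariates <- function(df) {
  stopifnot(is.data.frame(df))
  if (ncol(df) == 0L)
    return(matrix(numeric(0), nrow = nrow(df), ncol = 0L,
                  dimnames = list(rownames(df), NULL)))
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      lv <- levels(f)
      if (length(lv) < 2L) {
        # constant column carries no information but keep it for shape
        cols[[nm]] <- matrix(0, nrow = length(f), ncol = 1L,
                             dimnames = list(NULL, paste0(nm, ".", lv[1L])))
      } else {
        mm <- vapply(lv[-1L], function(l) as.numeric(f == l),
                     numeric(length(f)))
        colnames(mm) <- paste0(nm, ".", lv[-1L])
        cols[[nm]] <- mm
      }
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(df)
  out
}

#' Fit a PCA and project covariates
#'
#' Thin wrapper over \code{\link[stats]{prcomp}} with a deterministic sign
#' convention (the largest-magnitude entry of every loading vector is made
#' positive) so repeated fits and serialisation round-trips agree.
#'
#' @param Z numeric matrix (subjects x m); categorical covariates must be
#'   one-hot encoded first (see \code{\link{encode_covariates}}).
#' @param n_components number of components to keep.
#' @param scale. standardise columns to unit variance before rotation
#'   (default TRUE; constant columns are left unscaled).
#' @return list with \code{model} (class \code{"fctbn_pca"}: loadings,
#'   explained-variance ratios, centers, scales) and \code{scores}
#'   (subjects x n_components).
#' @export
pca_fit_transform <- function(Z, n_components = 1L, scale. = TRUE) {
  Z <- as.matrix(Z)
  m <- ncol(Z)
  if (n_components > min(nrow(Z) - 1L, m))
    stop("n_components must be <= min(subjects - 1, m)")
  sds <- apply(Z, 2L, stats::sd)
  do_scale <- if (scale.) ifelse(sds > 0, sds, 1) else rep(1, m)
  pc <- stats::prcomp(Z, center = TRUE, scale. = do_scale)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  keep <- n_components
  if (rank < n_components) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; returning ", rank)
    keep <- rank
  }
  rot <- pc$rotation[, seq_len(keep), drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  model <- structure(
    list(loadings = rot, explained_ratios = ratios[seq_len(keep)],
         all_ratios = ratios, center = pc$center, scale = do_scale),
    class = "fctbn_pca")
  scores <- sweep(Z, 2L, pc$center) %*% diag(1 / do_scale, m) %*% rot
  colnames(scores) <- colnames(rot)
  list(model = model, scores = scores)
}

#' Project new covariates with a fitted PCA
#'
#' @param model an \code{"fctbn_pca"}.
#' @param Z numeric matrix with the training columns.
#' @return score matrix.
#' @export
pca_transform <- function(model, Z) {
  Z <- as.matrix(Z)
  sweep(Z, 2L, model$center) %*%
    diag(1 / model$scale, ncol(Z)) %*% model$loadings
}

#' Cumulative explained-variance table
#'
#' @param model an \code{"fctbn_pca"}.
#' @return data.frame with per-component and cumulative variance ratios
#'   over the full spectrum, used to decide how many components to keep.
#' @export
explained_variance_report <- function(model) {
  stopifnot(inherits(model, "fctbn_pca"))
  data.frame(component = seq_along(model$all_ratios),
             ratio = model$all_ratios,
             cumulative = cumsum(model$all_ratios))
}
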