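#' Trajectory dataset container
#'
#' Holds a cohort of event-history trajectories: one covariate vector per
#' subject plus one row per observed sojourn.  Every row records the full
#' joint state of all condition nodes at the start of the interval, the
#' sojourn duration \code{t_d}, and either the node that transitioned at the
#' end of the interval (with its new state) or a censoring flag for the
#' final, right-censored sojourn of a subject.
#'
#' @param nodes character vector of condition node names.
#' @param covariates numeric matrix (subjects x m) of risk factors; row
#'   names are subject ids.  May have zero columns.
#' @param records data.frame with columns \code{subject} (integer row index
#'   into \code{covariates}), one 0/1 column per node (state at interval
#'   start), \code{t_d} (> 0), \code{event_node} (\code{NA} when censored),
#'   \code{event_state}, \code{censored} (logical).
#' @param time_unit character scalar naming the time unit (e.g. "years").
#'   Purely declarative; no rescaling is ever applied.
#' @param validate logical; run the schema checks.
#' @return An object of class \code{"fctbn_data"}.
#' @export
fctbn_data <- function(nodes, covariates, records, time_unit = "years",
                       validate = TRUE) {
  if (!is.matrix(covariates)) covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  obj <- structure(
    list(nodes = as.character(nodes), covariates = covariates,
         records = records, time_unit = time_unit),
    class = "fctbn_data")
  if (validate) validate_fctbn_data(obj)
  obj
}

#' Validate a trajectory dataset
#'
#' Checks the schema invariants: all node columns present and binary,
#' durations strictly positive, event columns empty exactly on censored
#' rows, subject indices in range, records time-ordered within subject with
#' consecutive joint states differing in exactly the transitioning node,
#' and at most the last record per subject censored.
#'
#' @param x an \code{fctbn_data} object.
#' @return \code{x}, invisibly; stops with an informative error otherwise.
#' @export
validate_fctbn_data <- function(x) {
  stopifnot(inherits(x, "fctbn_data"))
  rec <- x$records
  need <- c("subject", x$nodes, "t_d", "event_node", "event_state", "censored")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("records missing columns: ", paste(miss, collapse = ", "))
  if (nrow(rec) == 0L) return(invisible(x))
  smat <- as.matrix(rec[, x$nodes, drop = FALSE])
  if (!all(smat %in% c(0, 1)))
    stop("node state columns must be 0/1")
  bad <- which(!(rec$t_d > 0))
  if (length(bad))
    stop("non-positive sojourn duration t_d at record row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(rec$subject < 1L | rec$subject > nrow(x$covariates)))
    stop("record subject index out of range")
  cen <- as.logical(rec$censored)
  bad <- which(!cen & (is.na(rec$event_node) | is.na(rec$event_state)))
  if (length(bad))
    stop("non-censored rows must name an event_node and event_state; row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(cen & !is.na(rec$event_node))
  if (length(bad))
    stop("censored rows must leave event columns empty; row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  unk <- setdiff(unique(rec$event_node[!cen]), x$nodes)
  if (length(unk))
    stop("event_node names unknown node(s): ", paste(unk, collapse = ", "))
  # per-subject ordering / consistency
  idx <- split(seq_len(nrow(rec)), rec$subject)
  for (ii in idx) {
    if (length(ii) > 1L && any(diff(ii) < 0))
      stop("records of a subject must be contiguous and time-ordered")
    ci <- which(cen[ii])
    if (length(ci) > 1L || (length(ci) == 1L && ci != length(ii)))
      stop("only the final record of a subject may be censored")
    if (length(ii) > 1L) {
      for (k in seq_len(length(ii) - 1L)) {
        r1 <- ii[k]; r2 <- ii[k + 1L]
        dif <- which(smat[r1, ] != smat[r2, ])
        ev <- match(rec$event_node[r1], x$nodes)
        if (length(dif) != 1L || dif != ev ||
            smat[r2, ev] != rec$event_state[r1])
          stop("consecutive states of subject ", rec$subject[r1],
               " must differ in exactly the transitioning node (record ",
               r1, " -> ", r2, ")")
      }
    }
  }
  invisible(x)
}

#' @export
print.fctbn_data <- function(x, ...) {
  cat("fctbn trajectory dataset\n")
  cat("  subjects:  ", nrow(x$covariates), "\n")
  cat("  nodes:     ", paste(x$nodes, collapse = ", "), "\n")
  cat("  covariates:", ncol(x$covariates),
      if (ncol(x$covariates)) paste0("(", paste(colnames(x$covariates),
                                                collapse = ", "), ")"), "\n")
  cat("  records:   ", nrow(x$records),
      sprintf("(%d censored)", sum(x$records$censored)), "\n")
  cat("  time unit: ", x$time_unit, "\n")
  invisible(x)
}

#' Concatenate trajectory datasets
#'
#' Stacks subjects of two compatible cohorts (same nodes, covariates and
#' time unit).  Sufficient statistics are additive over this operation.
#'
#' @param a,b \code{fctbn_data} objects.
#' @return combined \code{fctbn_data}.
#' @export
bind_data <- function(a, b) {
  stopifnot(identical(a$nodes, b$nodes),
            identical(colnames(a$covariates), colnames(b$covariates)),
            identical(a$time_unit, b$time_unit))
  off <- nrow(a$covariates)
  rb <- b$records
  rb$subject <- rb$subject + off
  cov <- rbind(a$covariates, b$covariates)
  rownames(cov) <- make.unique(c(rownames(a$covariates),
                                 rownames(b$covariates)))
  fctbn_data(a$nodes, cov, rbind(a$records, rb), a$time_unit,
             validate = FALSE)
}

#' Subset a cohort by subject
#'
#' @param x an \code{fctbn_data} object.
#' @param subjects integer vector of subject indices to keep.
#' @return \code{fctbn_data} with re-indexed subjects.
#' @export
subset_subjects <- function(x, subjects) {
  subjects <- sort(unique(as.integer(subjects)))
  keep <- x$records$subject %in% subjects
  rec <- x$records[keep, , drop = FALSE]
  rec$subject <- match(rec$subject, subjects)
  rownames(rec) <- NULL
  fctbn_data(x$nodes, x$covariates[subjects, , drop = FALSE], rec,
             x$time_unit, validate = FALSE)
}
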