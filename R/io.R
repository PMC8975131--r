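# Dataset file format: one CSV row per observed sojourn plus a JSON
# sidecar declaring nodes, covariates and the time unit.  Numbers are
# written with 17 significant digits so write -> read -> write is
# byte-stable.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

meta_path <- function(path) paste0(path, ".meta.json")

#' Write a trajectory dataset
#'
#' Writes the record table as CSV (one row per sojourn: subject id,
#' covariates, interval-start state of every node, duration, event node
#' and state, censoring flag) plus a \code{<path>.meta.json} sidecar
#' naming the nodes, covariates and time unit.
#'
#' @param dataset an \code{fctbn_data}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  rec <- dataset$records
  ids <- rownames(dataset$covariates)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(dataset$covariates)))
  covn <- colnames(dataset$covariates)
  header <- c("subject_id", covn, dataset$nodes, "t_d", "event_node",
              "event_state", "censored")
  cols <- list(ids[rec$subject])
  for (j in seq_along(covn))
    cols[[length(cols) + 1L]] <- fmt_num(dataset$covariates[rec$subject, j])
  for (nd in dataset$nodes)
    cols[[length(cols) + 1L]] <- sprintf("%d", rec[[nd]])
  cols[[length(cols) + 1L]] <- fmt_num(rec$t_d)
  ev <- rec$event_node
  ev[is.na(ev)] <- ""
  cols[[length(cols) + 1L]] <- ev
  es <- sprintf("%d", rec$event_state)
  es[is.na(rec$event_state)] <- ""
  cols[[length(cols) + 1L]] <- es
  cols[[length(cols) + 1L]] <- sprintf("%d", as.integer(rec$censored))
  lines <- c(paste(header, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  jsonlite::write_json(
    list(format = "fctbn-dataset/1", nodes = dataset$nodes,
         covariates = as.list(covn), time_unit = dataset$time_unit),
    meta_path(path), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory dataset
#'
#' Inverse of \code{\link{write_dataset}}.  Malformed rows (non-positive
#' durations, event fields filled on censored rows or missing on
#' non-censored ones) are reported with their row numbers; unknown or
#' missing columns raise a schema error.
#'
#' @param path CSV file path (sidecar \code{<path>.meta.json} must
#'   exist).
#' @return an \code{fctbn_data}.
#' @export
read_dataset <- function(path) {
  if (!file.exists(meta_path(path)))
    stop("missing metadata sidecar: ", meta_path(path))
  meta <- jsonlite::read_json(meta_path(path), simplifyVector = TRUE)
  covn <- as.character(unlist(meta$covariates))
  nodes <- as.character(meta$nodes)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("subject_id", covn, nodes, "t_d", "event_node", "event_state",
            "censored")
  if (!identical(names(df), need))
    stop("schema error: expected columns [",
         paste(need, collapse = ", "), "], found [",
         paste(names(df), collapse = ", "), "]")
  n <- nrow(df)
  t_d <- as.numeric(df$t_d)
  bad <- which(!is.finite(t_d) | t_d <= 0)
  if (length(bad))
    stop("parse error: non-positive or unreadable t_d at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  censored <- as.integer(df$censored) == 1L
  ev <- df$event_node
  ev[ev == ""] <- NA_character_
  es <- suppressWarnings(as.integer(df$event_state))
  bad <- which(censored & !is.na(ev))
  if (length(bad))
    stop("parse error: censored rows carry an event at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(!censored & (is.na(ev) | is.na(es)))
  if (length(bad))
    stop("parse error: non-censored rows missing the event at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  ids <- unique(df$subject_id)
  subject <- match(df$subject_id, ids)
  cov <- matrix(0, nrow = length(ids), ncol = length(covn),
                dimnames = list(ids, covn))
  first <- match(ids, df$subject_id)
  for (j in seq_along(covn)) cov[, j] <- as.numeric(df[[covn[j]]][first])
  rec <- data.frame(subject = subject)
  for (nd in nodes) rec[[nd]] <- as.integer(df[[nd]])
  rec$t_d <- t_d
  rec$event_node <- ev
  rec$event_state <- es
  rec$censored <- censored
  fctbn_data(nodes, cov, rec, time_unit = meta$time_unit)
}
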