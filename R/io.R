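#' Write and read a feature matrix
#'
#' The matrix is stored as CSV with full `%.17g` precision (so values
#' round-trip bit-exactly) next to a JSON sidecar (`<path>.json`) holding
#' the column metadata, condition tag and analysis window.
#'
#' @param X a `feature_matrix` from [build_feature_matrix()].
#' @param path CSV file path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the reconstructed `feature_matrix`.
#' @export
write_feature_matrix <- function(X, path) {
  stopifnot(inherits(X, "feature_matrix"))
  txt <- apply(X, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  header <- paste(c("subject", colnames(X)), collapse = ",")
  lines <- paste(rownames(X), txt, sep = ",")
  writeLines(c(header, lines), path)
  meta <- list(meta = attr(X, "meta"), condition = attr(X, "condition"),
               window = attr(X, "window"))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  subjects <- vapply(body, `[[`, character(1), 1L)
  X <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1])))
  dimnames(X) <- list(subjects, header[-1])
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(X, "meta") <- as.data.frame(side$meta, stringsAsFactors = FALSE)
  attr(X, "condition") <- side$condition
  attr(X, "window") <- as.numeric(side$window)
  class(X) <- c("feature_matrix", class(X))
  X
}

#' Read a cohort configuration from a key/value text file
#'
#' Accepts a YAML (or JSON) file whose top-level keys are
#' [cohort_config()] arguments; `rt` may be a nested mapping and
#' `spatial_weights` a named mapping. Unknown keys are an error, so
#' typos do not silently fall back to defaults.
#'
#' @param path file path.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$spatial_weights))
    vals$spatial_weights <- unlist(vals$spatial_weights)
  if (!is.null(vals$channels)) vals$channels <- unlist(vals$channels)
  do.call(cohort_config, vals)
}

#' Write and read response-locked epochs
#'
#' Epochs are written as a directory of plain-text files: `data.csv`
#' (rows = flattened channel x time, columns = trials, `%.17g`
#' precision), `trials.csv` (the trial table) and `meta.json` (channel
#' labels, time axis, sampling step).
#'
#' @param epochs an `epoch_set`.
#' @param dir directory to create/populate.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()`
#'   returns the `epoch_set`.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, nrow = d[1] * d[2], ncol = d[3])
  txt <- apply(flat, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, file.path(dir, "data.csv"))
  write.csv(epochs$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  jsonlite::write_json(list(channels = epochs$channels,
                            times = epochs$times),
                       file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  trials <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  lines <- readLines(file.path(dir, "data.csv"))
  flat <- do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE),
                                as.numeric))
  nch <- length(meta$channels)
  nt <- length(meta$times)
  data <- array(flat, dim = c(nch, nt, nrow(trials)))
  epoch_set(data, as.numeric(meta$times), meta$channels, trials)
}
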