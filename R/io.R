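# Delimited-text I/O. All files are CSV or TSV (auto-detected on read);
# frame indices are 0-based in files and 1-based in memory, stated in every
# output header comment.

.detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a subject's region-by-time matrix
#'
#' Reads a delimited (comma or tab) table whose first column holds region ids
#' and whose remaining columns are time frames. Errors on ragged rows, NA
#' cells or duplicate region ids.
#'
#' @param path file path.
#' @return V x T numeric matrix with region ids as rownames.
#' @export
readSubjectMatrix <- function(path) {
  sep <- .detectSep(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) stop("parse error in ", path, ": no time columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("parse error in ", path, ": duplicate region ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m)))
    stop("parse error in ", path, ": NA cells present")
  rownames(m) <- ids
  m
}

#' Write a subject's region-by-time matrix
#'
#' Inverse of [readSubjectMatrix()]; round-trips within 1e-12.
#'
#' @param x V x T numeric matrix (rownames used as region ids).
#' @param path output path; ".tsv" extension selects tabs, otherwise commas.
#' @export
writeSubjectMatrix <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("r%03d", seq_len(nrow(x)))
  df <- data.frame(region = ids, x, check.names = FALSE)
  colnames(df) <- c("region", sprintf("f%d", seq_len(ncol(x)) - 1L))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a task design table
#'
#' Reads a delimited table with columns `frame` (0-based in the file), `task`,
#' `block`, `position` (0-based within block) and `run`. Validates that every
#' frame 0..T-1 appears exactly once and that within-block positions are
#' contiguous from 0. The returned data.frame has `frame` converted to
#' 1-based indices for direct use against coordinate rows.
#'
#' @param path file path.
#' @return validated design data.frame.
#' @export
readDesign <- function(path) {
  sep <- .detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "task", "block", "position", "run")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  fr <- sort(df$frame)
  expect <- seq_len(nrow(df)) - 1L
  if (!identical(as.integer(fr), expect)) {
    gaps <- setdiff(expect, df$frame)
    stop("parse error in ", path, ": frames not labeled exactly once",
         if (length(gaps)) paste0("; missing frames: ",
                                  paste(utils::head(gaps, 10), collapse = ", ")))
  }
  df <- df[order(df$frame), , drop = FALSE]
  # within-block positions contiguous from 0
  rep_id <- cumsum(df$position == 0)
  bad <- tapply(df$position, rep_id, function(p)
    !identical(as.integer(p), seq_along(p) - 1L))
  if (any(unlist(bad)))
    stop("parse error in ", path,
         ": within-block positions not contiguous from 0")
  df$frame <- df$frame + 1L
  rownames(df) <- NULL
  df
}

#' Write a task design table
#'
#' Inverse of [readDesign()]: the in-memory 1-based `frame` column is written
#' 0-based.
#'
#' @param design design data.frame (1-based frames).
#' @param path output path.
#' @export
writeDesign <- function(design, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  design$frame <- design$frame - 1L
  utils::write.table(design, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Assemble per-subject matrix files into a group tensor
#'
#' Reads one matrix file per subject and stacks them into a
#' [GroupTensor-class], checking that all subjects share the same regions and
#' frame count; mismatches name the offending file.
#'
#' @param paths character vector of matrix files, one per subject.
#' @param subjectIds labels (default: file base names).
#' @param synchronized synchronization flag stored on the tensor.
#' @return a [GroupTensor-class].
#' @export
assembleTensor <- function(paths, subjectIds = NULL, synchronized = TRUE) {
  if (is.null(subjectIds))
    subjectIds <- sub("\\.[^.]*$", "", basename(paths))
  mats <- lapply(paths, readSubjectMatrix)
  V <- nrow(mats[[1L]]); Tn <- ncol(mats[[1L]])
  ids <- rownames(mats[[1L]])
  for (i in seq_along(mats)) {
    if (nrow(mats[[i]]) != V || !identical(rownames(mats[[i]]), ids))
      stop("region mismatch in ", paths[i])
    if (ncol(mats[[i]]) != Tn)
      stop("frame-count mismatch in ", paths[i], ": ", ncol(mats[[i]]),
           " frames, expected ", Tn)
  }
  arr <- array(0, dim = c(length(mats), V, Tn))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  GroupTensor(arr, subjectIds = subjectIds, regionIds = ids,
              synchronized = synchronized)
}

#' Write embedding coordinates as a delimited table
#'
#' Emits a T x d coordinate table with a 0-based `frame` index as the first
#' column (stated in the header comment), for a [TwoStepEmbedding-class],
#' [ExtendedCoordinates-class], [DiffusionEmbedding-class] or plain matrix.
#'
#' @param x object carrying coordinates.
#' @param path output path.
#' @export
writeCoordinates <- function(x, path) {
  co <- if (is.matrix(x)) x else embCoordinates(x)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(frame = seq_len(nrow(co)) - 1L, co)
  colnames(df) <- c("frame", sprintf("dim%d", seq_len(ncol(co))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frame indices are 0-based", con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a run configuration file
#'
#' Reads a YAML run configuration and merges it over the package defaults:
#' `d1` (7), `d2` (3), `diffusion_time` (1), `kernel_scale` ("median"),
#' `knn` (15), `mtd_window` (14), `k_range` (2..10), `kmeans_seed` (1),
#' `kmeans_restarts` (50), `louvain_seed` (1), `louvain_resolution` (1).
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(d1 = 7L, d2 = 3L, diffusion_time = 1L,
                   kernel_scale = "median", knn = 15L,
                   mtd_window = 14L, k_range = 2:10,
                   kmeans_seed = 1L, kmeans_restarts = 50L,
                   louvain_seed = 1L, louvain_resolution = 1)
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}
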