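# Delimited-text readers and writers with defensive error reporting.

detect_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a samples-by-features matrix from delimited text
#'
#' First row = feature names, first column = sample ids. Separator is
#' inferred from the extension (.csv = comma, otherwise tab).
#'
#' @param path file path.
#' @param sep field separator override.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, sep = detect_sep(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("matrix file needs a header and at least one row")
  parts <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(parts)
  header <- parts[[1]]
  n_fields <- length(header)
  bad <- which(widths[-1] != n_fields) + 1L
  if (length(bad))
    stop("ragged rows in ", path, ": line(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " have a different number of fields than the header")
  feature_names <- header[-1]
  ids <- vapply(parts[-1], `[[`, character(1), 1)
  vals <- matrix(NA_real_, length(ids), length(feature_names))
  for (r in seq_along(ids)) {
    x <- suppressWarnings(as.numeric(parts[[r + 1L]][-1]))
    if (anyNA(x))
      stop("non-numeric cell in ", path, " at data row ", r,
           " (line ", r + 1L, "), sample '", ids[r], "'")
    vals[r, ] <- x
  }
  rownames(vals) <- ids
  colnames(vals) <- feature_names
  vals
}

#' Write a matrix as delimited text (inverse of \code{read_matrix})
#' @param X matrix with dimnames.
#' @param path destination path.
#' @param sep field separator (default from extension).
#' @export
write_matrix <- function(X, path, sep = detect_sep(path)) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  header <- paste(c("id", colnames(X)), collapse = sep)
  body <- vapply(seq_len(nrow(X)), function(i)
    paste(c(rownames(X)[i],
            format(X[i, ], digits = 17, trim = TRUE, scientific = NA)),
          collapse = sep), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read per-sample labels
#'
#' Accepts one column (labels in matrix row order) or two columns
#' (sample id, label; joined against \code{sample_ids}).
#'
#' @param path file path (no header for one column; two-column files may
#'   have any header).
#' @param sample_ids ids to align against (required for two-column files).
#' @param sep separator.
#' @return character vector of labels, one per sample.
#' @export
read_labels <- function(path, sample_ids = NULL, sep = detect_sep(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1) return(as.character(tab[[1]]))
  if (ncol(tab) >= 2) {
    ids <- as.character(tab[[1]])
    labs <- as.character(tab[[2]])
    if (ids[1] %in% c("id", "sample", "sample_id")) {
      ids <- ids[-1]; labs <- labs[-1]
    }
    if (is.null(sample_ids)) return(stats::setNames(labs, ids))
    missing <- setdiff(sample_ids, ids)
    if (length(missing))
      stop("labels file is missing sample id(s): ",
           paste(utils::head(missing, 10), collapse = ", "))
    return(labs[match(sample_ids, ids)])
  }
  stop("labels file must have one or two columns")
}

#' Write a report (list) as JSON
#' @param x a list or data frame.
#' @param path destination .json path.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
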