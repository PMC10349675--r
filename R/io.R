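# On-disk formats.  Canonical dialects:
#   ratings      comma-separated UTF-8, optional header auto-detected,
#                columns user_id,item_id,rating[,timestamp]
#   transactions one whitespace-separated itemset per line; blank line =
#                empty itemset
#   actigraphy   per-subject CSV with columns timestamp,date,activity plus a
#                scores.csv metadata table

#' Read a ratings CSV into a [ratings_matrix()]
#'
#' The header is auto-detected: a first line whose third field is not numeric
#' is treated as a header.  Malformed rows (wrong field count or non-numeric
#' rating) abort with the offending line number; an empty file yields an
#' empty matrix with a warning.
#'
#' @param path file path.
#' @param scale,relevance passed to [ratings_matrix()].
#' @return A `ratings_matrix`.
#' @export
read_ratings <- function(path, scale = c(1, 5), relevance = 4) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty ratings file; returning empty matrix", call. = FALSE)
    return(ratings_matrix(
      data.frame(user_id = character(), item_id = character(),
                 rating = numeric(), stringsAsFactors = FALSE),
      scale = scale, relevance = relevance))
  }
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(
    as.numeric(trimws(first[3]))))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  rows <- strsplit(body, ",", fixed = TRUE)
  parsed <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    f <- trimws(rows[[k]])
    if (!(length(f) %in% c(3L, 4L))) {
      stop(sprintf("malformed ratings row at line %d: expected 3-4 fields, got %d",
                   k + offset, length(f)), call. = FALSE)
    }
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) {
      stop(sprintf("malformed ratings row at line %d: non-numeric rating %s",
                   k + offset, dQuote(f[3])), call. = FALSE)
    }
    ts <- if (length(f) == 4L) suppressWarnings(as.integer(f[4])) else NA_integer_
    parsed[[k]] <- list(f[1], f[2], r, ts)
  }
  df <- data.frame(
    user_id = vapply(parsed, `[[`, character(1), 1),
    item_id = vapply(parsed, `[[`, character(1), 2),
    rating = vapply(parsed, `[[`, numeric(1), 3),
    timestamp = vapply(parsed, `[[`, integer(1), 4),
    stringsAsFactors = FALSE
  )
  ratings_matrix(df, scale = scale, relevance = relevance)
}

#' Write a [ratings_matrix()] as canonical CSV
#'
#' @param rm a `ratings_matrix`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(rm, path) {
  stopifnot(inherits(rm, "ratings_matrix"))
  df <- rm$ratings
  if (is.null(df$timestamp)) df$timestamp <- NA_integer_
  utils::write.table(
    df[, c("user_id", "item_id", "rating", "timestamp")],
    path, sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE,
    fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a transactions file
#'
#' One whitespace-separated itemset per line; duplicates within a line are
#' collapsed and a blank line is retained as an empty itemset.
#'
#' @param path file path.
#' @return A [transaction_db()].
#' @export
read_transactions <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  lines <- readLines(path, encoding = "UTF-8")
  transaction_db(lapply(lines, function(l) {
    strsplit(trimws(l), "\\s+")[[1]]
  }))
}

#' Write a [transaction_db()] to its canonical one-line-per-itemset format
#'
#' @param db a `transaction_db`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  writeLines(vapply(db$transactions, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read an actigraphy bundle from a directory
#'
#' Expects one CSV per subject (columns `timestamp`, `date`, `activity`) and
#' a `scores.csv` metadata table whose `number` column matches the CSV file
#' stems.  Subjects whose file stem starts with `condition` are assigned to
#' the condition group, others to control.
#'
#' @param dir directory holding the per-subject CSVs and `scores.csv`.
#' @return An `actigraphy_bundle` (see [gen_actigraphy()]).
#' @export
read_actigraphy <- function(dir) {
  if (!dir.exists(dir)) stop_field("dir", paste("no such directory:", dir))
  score_path <- file.path(dir, "scores.csv")
  if (!file.exists(score_path)) stop_field("scores.csv", "missing from dir")
  scores <- utils::read.csv(score_path, stringsAsFactors = FALSE)
  if (!"number" %in% names(scores)) {
    stop_field("number", "column missing from scores.csv")
  }
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), "scores.csv")
  ids <- sub("\\.csv$", "", files)
  records <- stats::setNames(vector("list", length(files)), ids)
  for (k in seq_along(files)) {
    d <- utils::read.csv(file.path(dir, files[k]), stringsAsFactors = FALSE)
    miss <- setdiff(c("timestamp", "date", "activity"), names(d))
    if (length(miss)) {
      stop_field(miss[1], sprintf("column missing from %s", files[k]))
    }
    records[[k]] <- d[, c("timestamp", "date", "activity")]
  }
  groups <- stats::setNames(
    ifelse(startsWith(ids, "condition"), "condition", "control"), ids)
  structure(list(records = records, scores = scores, groups = groups),
            class = "actigraphy_bundle")
}

#' Write an actigraphy bundle to a directory of CSVs
#'
#' @param bundle an `actigraphy_bundle`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_actigraphy <- function(bundle, dir) {
  stopifnot(inherits(bundle, "actigraphy_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(bundle$records)) {
    utils::write.csv(bundle$records[[id]], file.path(dir, paste0(id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(bundle$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a weighted directed graph from edge-list TSV
#'
#' Columns `src`, `dst`, `distance` (tab-separated, with header).  Used for
#' river-formation-dynamics environments.
#'
#' @param path file path.
#' @return An `rfd_environment` (see [rfd_environment()]) without a goal set;
#'   pass the result to [rfd_environment()] helpers or set `goal` downstream.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop_field("path", paste("no such file:", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("src", "dst", "distance"), names(d))
  if (length(miss)) stop_field(miss[1], "column missing from edge list")
  d
}

#' Write a graph edge list as TSV
#'
#' @param edges data frame with columns `src`, `dst`, `distance`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(edges, path) {
  utils::write.table(edges[, c("src", "dst", "distance")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
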