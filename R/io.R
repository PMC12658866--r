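#' Read a per-sample long point table
#'
#' Reads the canonical long format — one row per detected peak with columns
#' `t_r1_s`, `t_r2_s`, `mz`, `intensity` (an optional `sample_id` column is
#' kept) — from CSV or, when the arrow package is available, Parquet.
#' Rows are returned in lexicographic `(t_r1_s, t_r2_s)` order; malformed
#' cells are reported with their row and column.
#'
#' @param path File path (`.csv` or `.parquet`).
#' @param sample_id Optional sample code to attach (defaults to an existing
#'   `sample_id` column, else the file stem).
#' @return A tibble.
#' @export
read_sample_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("Reading Parquet requires the arrow package.", call. = FALSE)
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("t_r1_s", "t_r2_s", "mz", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("Missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("Empty point table: ", path, call. = FALSE)
  for (col in required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (anyNA(df[[col]]) || length(bad) > 0) {
      row <- c(which(is.na(df[[col]])), bad)[1]
      stop(sprintf("Non-numeric value in column '%s', row %d.", col, row),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  neg <- which(df$intensity < 0)
  if (length(neg) > 0) {
    stop(sprintf("Negative intensity in row %d.", neg[1]), call. = FALSE)
  }
  if (any(df$mz <= 0)) {
    stop(sprintf("Non-positive m/z in row %d.", which(df$mz <= 0)[1]),
         call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(df)) NULL else
      tools::file_path_sans_ext(basename(path))
  }
  tb <- tibble::as_tibble(df)
  if (!is.null(sample_id)) tb$sample_id <- sample_id
  dplyr::arrange(tb, .data$t_r1_s, .data$t_r2_s, .data$mz)
}

#' Write a long point table
#'
#' Counterpart of [read_sample_table()]; CSV or Parquet by extension.
#' Round-trips exactly with the reader.
#'
#' @param tbl Data frame with the canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tbl, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("Writing Parquet requires the arrow package.", call. = FALSE)
    }
    arrow::write_parquet(tbl, path)
  } else {
    utils::write.csv(tbl, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path CSV with columns `sample_id`, `country`, `winery`,
#'   `category`, `vintage`.
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "country", "winery", "category", "vintage")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("Missing metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}
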