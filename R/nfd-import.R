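#' Read an unaligned nontargeted peak list
#'
#' Imports per-file peak lists produced by a nontargeted feature detection
#' tool, in one of the declared dialects, and normalizes them to a common
#' tibble (retention times in seconds). Rows with non-positive area are
#' dropped and the count is reported via a message.
#'
#' Dialects and their required columns:
#' \describe{
#'   \item{`generic_csv`}{`file, mz, rt, rt_min, rt_max, area` (optional
#'     `height`); rt in seconds.}
#'   \item{`xcms_peaks`}{`mz, rt, rtmin, rtmax, into, maxo, sample`; rt in
#'     seconds (the native unit of XCMS peak tables). `sample` indices are
#'     translated through `sample_names` when given.}
#'   \item{`mzmine_peaks`}{`file, mz, rt, rt_min, rt_max, area` (optional
#'     `height`); rt in minutes, converted to seconds.}
#' }
#'
#' @param path Delimited text file.
#' @param dialect One of `"generic_csv"`, `"xcms_peaks"`, `"mzmine_peaks"`.
#' @param sep Field separator.
#' @param sample_names Optional character vector mapping xcms sample indices
#'   to file ids.
#' @return A tibble of class `nfd_peaks` with columns `file`, `mz`, `rt`,
#'   `rt_min`, `rt_max`, `area`, `height`, `source_row`.
#' @export
read_unaligned <- function(path, dialect = c("generic_csv", "xcms_peaks",
                                             "mzmine_peaks"),
                           sep = ",", sample_names = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- switch(dialect,
    generic_csv = c("file", "mz", "rt", "rt_min", "rt_max", "area"),
    xcms_peaks = c("mz", "rt", "rtmin", "rtmax", "into", "maxo", "sample"),
    mzmine_peaks = c("file", "mz", "rt", "rt_min", "rt_max", "area"))
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    rlang::abort(sprintf("Dialect '%s' requires missing column(s): %s",
                         dialect, paste(miss, collapse = ", ")),
                 class = "irbench_io_error")
  }
  df$source_row <- seq_len(nrow(df))
  out <- switch(dialect,
    generic_csv = tibble::tibble(
      file = as.character(df$file), mz = df$mz, rt = df$rt,
      rt_min = df$rt_min, rt_max = df$rt_max, area = df$area,
      height = if ("height" %in% names(df)) df$height else NA_real_,
      source_row = df$source_row),
    xcms_peaks = tibble::tibble(
      file = if (!is.null(sample_names)) sample_names[df$sample]
             else as.character(df$sample),
      mz = df$mz, rt = df$rt, rt_min = df$rtmin, rt_max = df$rtmax,
      area = df$into, height = df$maxo, source_row = df$source_row),
    mzmine_peaks = tibble::tibble(
      file = as.character(df$file), mz = df$mz, rt = df$rt * 60,
      rt_min = df$rt_min * 60, rt_max = df$rt_max * 60, area = df$area,
      height = if ("height" %in% names(df)) df$height else NA_real_,
      source_row = df$source_row))
  bad <- is.na(out$area) | out$area <= 0
  if (any(bad)) {
    message(sprintf("Dropped %d row(s) with non-positive area.", sum(bad)))
    out <- out[!bad, ]
  }
  out$rt <- pmin(pmax(out$rt, out$rt_min), out$rt_max)
  structure(out, class = c("nfd_peaks", class(out)))
}

#' Read an aligned nontargeted feature table
#'
#' Imports a wide feature x sample abundance matrix and returns it in long
#' form, one row per feature x file. Abundance columns are declared through
#' `sample_cols` (a named character vector, `c(column_name = file_id)`);
#' optional per-sample gap-filled flag columns and peak label columns are
#' declared analogously. Features with no non-missing abundance are rejected
#' (count reported via a message).
#'
#' @param path Delimited text file with columns `feature_id`, `mz`, `rt`
#'   plus the declared sample columns.
#' @param dialect `"generic_csv"` (rt in seconds) or `"mzmine_aligned"`
#'   (rt in minutes, converted).
#' @param sample_cols Named character vector mapping abundance column names
#'   to file ids. `NULL` uses every column not otherwise claimed, with the
#'   column name as file id.
#' @param gap_cols,label_cols Optional named character vectors mapping flag /
#'   label column names to file ids.
#' @param sep Field separator.
#' @return A tibble of class `nfd_features` with columns `feature_id`, `mz`,
#'   `rt`, `file`, `abundance`, `gap_filled`, `label`.
#' @export
read_aligned <- function(path, dialect = c("generic_csv", "mzmine_aligned"),
                         sample_cols = NULL, gap_cols = NULL,
                         label_cols = NULL, sep = ",") {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("feature_id", "mz", "rt")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    rlang::abort(sprintf("Aligned table is missing column(s): %s",
                         paste(miss, collapse = ", ")),
                 class = "irbench_io_error")
  }
  if (anyDuplicated(df$feature_id)) {
    rlang::abort("Duplicated feature_id in aligned table.",
                 class = "irbench_io_error")
  }
  if (is.null(sample_cols)) {
    rest <- setdiff(names(df), c(req, names(gap_cols), names(label_cols)))
    sample_cols <- stats::setNames(rest, rest)
  }
  miss <- setdiff(names(sample_cols), names(df))
  if (length(miss)) {
    rlang::abort(sprintf("Declared sample column(s) not in table: %s",
                         paste(miss, collapse = ", ")),
                 class = "irbench_io_error")
  }
  rt_scale <- if (dialect == "mzmine_aligned") 60 else 1
  rows <- purrr::imap(sample_cols, function(file_id, col) {
    gcol <- names(gap_cols)[match(file_id, gap_cols)]
    lcol <- names(label_cols)[match(file_id, label_cols)]
    tibble::tibble(
      feature_id = as.character(df$feature_id),
      mz = df$mz, rt = df$rt * rt_scale,
      file = file_id,
      abundance = as.numeric(df[[col]]),
      gap_filled = if (!is.na(gcol) && !is.null(gcol)) as.logical(df[[gcol]])
                   else FALSE,
      label = if (!is.na(lcol) && !is.null(lcol)) as.character(df[[lcol]])
              else NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  empty <- out |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(all_na = all(is.na(.data$abundance))) |>
    dplyr::filter(.data$all_na)
  if (nrow(empty) > 0L) {
    message(sprintf("Rejected %d feature(s) with no non-missing abundance.",
                    nrow(empty)))
    out <- out[!out$feature_id %in% empty$feature_id, ]
  }
  structure(out, class = c("nfd_features", class(out)))
}
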