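#' Read a samples-by-features table from CSV/TSV
#'
#' Loads a delimited feature table (comma-separated by default; tab-separated
#' for `.tsv`/`.txt` extensions), validates that every feature column is
#' numeric, and applies the missing-value policy: `"error"` (default) rejects
#' the file naming the first offending cell, `"half_min"` imputes each missing
#' value with half the per-feature minimum observed value (a common
#' below-detection-limit convention in LC-MS tables).
#'
#' @param path File path.
#' @param label Name of the label column that must be present. Default
#'   `"label"`.
#' @param missing `"error"` or `"half_min"`.
#' @return A tibble with `sample_id` (created if absent), the label column as
#'   a factor with lexicographically ordered levels, and numeric feature
#'   columns.
#' @export
read_feature_table <- function(path, label = "label",
                               missing = c("error", "half_min")) {
  missing <- match.arg(missing)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  # base parser: correctly rounded doubles, so write -> read is bit-exact
  data <- tibble::as_tibble(utils::read.table(
    path, header = TRUE, sep = delim, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\"", comment.char = ""
  ))
  if (!label %in% names(data)) {
    stop(sprintf("label column '%s' not found in %s.", label, path), call. = FALSE)
  }
  feat_cols <- setdiff(names(data), c(label, "sample_id"))
  not_num <- feat_cols[!vapply(data[feat_cols], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric feature columns: ",
         paste(utils::head(not_num, 5), collapse = ", "), call. = FALSE)
  }
  if (missing == "half_min") {
    data <- dplyr::mutate(data, dplyr::across(
      dplyr::all_of(feat_cols),
      ~ tidyr::replace_na(.x, min(.x, na.rm = TRUE) / 2)
    ))
  } else {
    for (cl in feat_cols) {
      if (anyNA(data[[cl]])) {
        stop(sprintf("missing value at row %d, column '%s' (policy = \"error\").",
                     which(is.na(data[[cl]]))[1], cl), call. = FALSE)
      }
    }
  }
  const <- feat_cols[vapply(data[feat_cols], function(x) stats::var(x) == 0, logical(1))]
  if (length(const) > 0) {
    warning("all-constant feature columns: ",
            paste(utils::head(const, 5), collapse = ", "), call. = FALSE)
  }
  data[[label]] <- factor(as.character(data[[label]]),
                          levels = sort(unique(as.character(data[[label]]))))
  if (!"sample_id" %in% names(data)) {
    data <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("sample_", seq_len(nrow(data)))), data
    )
  }
  tibble::as_tibble(data)
}

#' Write a feature table to CSV/TSV
#'
#' Full-precision delimited output (comma by default, tab for `.tsv`/`.txt`),
#' so that a write/read round trip reproduces the numeric values exactly.
#'
#' @param data Data frame to write.
#' @param path Output path; extension selects the delimiter.
#' @return `data`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- dplyr::mutate(tibble::as_tibble(data), dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)  # bitwise round trip
  ))
  readr::write_delim(out, path, delim = delim)
  invisible(data)
}
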