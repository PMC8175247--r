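# CSV/JSON input-output with a fixed, documented dialect.
# Multi-lab per-animal tables: lab_id, genotype, arm, x, u, y.
# Study-result tables: lab_id, genotype, mean_effect, se, n1, n2, x, s2.

multilab_cols <- c("lab_id", "genotype", "arm", "x", "u", "y")
study_cols <- c("lab_id", "genotype", "mean_effect", "se", "n1", "n2", "x", "s2")

#' Read and write the package's tabular formats
#'
#' Tidy CSV with a header, UTF-8, dot decimal; column order is fixed so that
#' identical data produce byte-identical files. `read_*` functions validate
#' the header and column types, so parsing the package's own output is
#' lossless.
#'
#' @param data The tibble to write.
#' @param path File path.
#' @return The tibble (invisibly for writers).
#' @name table-io
NULL

#' @rdname table-io
#' @export
write_multilab_csv <- function(data, path) {
  miss <- setdiff(multilab_cols, names(data))
  if (length(miss)) {
    abort_structural(sprintf("Multi-lab data is missing column(s) %s.",
                             paste(miss, collapse = ", ")))
  }
  readr::write_csv(data[multilab_cols], path)
  invisible(data)
}

#' @rdname table-io
#' @export
read_multilab_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    lab_id = readr::col_integer(), genotype = readr::col_character(),
    arm = readr::col_character(), x = readr::col_double(),
    u = readr::col_double(), y = readr::col_double()
  ))
}

#' @rdname table-io
#' @export
write_study_csv <- function(data, path) {
  miss <- setdiff(study_cols, names(data))
  if (length(miss)) {
    abort_structural(sprintf("Study table is missing column(s) %s.",
                             paste(miss, collapse = ", ")))
  }
  readr::write_csv(data[study_cols], path)
  invisible(data)
}

#' @rdname table-io
#' @export
read_study_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    lab_id = readr::col_integer(), genotype = readr::col_character(),
    mean_effect = readr::col_double(), se = readr::col_double(),
    n1 = readr::col_integer(), n2 = readr::col_integer(),
    x = readr::col_double(), s2 = readr::col_double()
  ))
}

#' Write replication assessments as JSON records
#'
#' @param assessments A tibble from one of the `assess_*()` functions.
#' @param path Output path.
#' @export
write_assessments_json <- function(assessments, path) {
  jsonlite::write_json(assessments, path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(assessments)
}
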