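#' Read and write delimited trial and cohort tables
#'
#' Plain-text interchange for the package's tabular formats: trial records
#' (one row per trial, empty fields for absent `rt_ms`/`ssd_ms`) and cohort
#' tables (one row per participant). Files are comma-delimited with a
#' mandatory header.
#'
#' @param trials,cohort A tibble to write.
#' @param path File path.
#' @return Readers return a tibble; writers return the input invisibly.
#' @name sst_io
NULL

#' @rdname sst_io
#' @export
write_sst_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(trials)
}

#' @rdname sst_io
#' @export
read_sst_trials <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE, na = "",
    col_types = readr::cols(
      participant_id = "c", block = "i", trial = "i", is_stop = "l",
      ssd_ms = "d", responded = "l", correct = "l", rt_ms = "d"
    )
  )
}

#' @rdname sst_io
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}

#' @rdname sst_io
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, na = "")
  if ("sex" %in% names(out)) {
    out$sex <- factor(out$sex, levels = c("female", "male"))
  }
  out
}
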