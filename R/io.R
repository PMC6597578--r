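#' Read and write SEG-style segment tables
#'
#' SEG files are tab-delimited with columns sample, chrom, start, end,
#' n_markers, value, using 1-based inclusive coordinates. In memory the
#' package uses 0-based half-open coordinates; these helpers convert.
#'
#' @param segments Segment tibble (0-based half-open).
#' @param path File path.
#' @return `read_seg()` returns the segment tibble (0-based half-open);
#'   `write_seg()` returns `path` invisibly.
#' @export
write_seg <- function(segments, path) {
  segments |>
    mutate(start = .data$start + 1) |>
    select("sample", "chrom", "start", "end", "n_markers", "value") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = readr::col_character())) |>
    mutate(start = .data$start - 1)
}

#' Read and write expression matrices
#'
#' Tab-delimited, probes (or genes) in rows, samples in columns, first
#' column `probe`; values on the log2 scale.
#'
#' @param expr Probes x samples numeric matrix.
#' @param path File path.
#' @return `read_expression()` returns the matrix; `write_expression()`
#'   returns `path` invisibly.
#' @export
write_expression <- function(expr, path) {
  as_tibble(expr, rownames = "probe") |> readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  m
}

#' Read a clinical table
#'
#' Expects tab-delimited columns sample, time_months, event, grade,
#' size_cm, nodes_positive, cohort (extra columns pass through).
#'
#' @param path File path.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample", "time_months", "event")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    abort(paste0("clinical table missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  d
}

#' Write one simulated cohort to a directory
#'
#' Emits `segments.seg`, `expression.tsv`, `probe_map.tsv`,
#' `clinical.tsv` and `truth.json` (planted gene sets, directions and
#' per-sample latent risk) under `dir`.
#'
#' @param cohort_data A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_seg(cohort_data$segments, file.path(dir, "segments.seg"))
  write_expression(cohort_data$expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort_data$probe_map, file.path(dir, "probe_map.tsv"))
  readr::write_tsv(cohort_data$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort_data$truth
  jsonlite::write_json(
    list(
      cn_driven_genes = truth$cn_driven_genes,
      prognostic_genes = truth$prognostic,
      latent_risk = cohort_data$risk
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}
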