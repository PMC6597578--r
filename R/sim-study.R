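#' Simulate one cohort end to end
#'
#' @param config A [sim_config()].
#' @param cohort Cohort index.
#' @param truth Optional [plant_truth()] object (so all cohorts of one
#'   study share one ground truth); planted afresh when NULL.
#' @return List: `segments`, `expr`, `probe_map`, `risk`, `clinical`,
#'   `dialect`, `truth`.
#' @export
simulate_cohort <- function(config, cohort, truth = NULL) {
  truth <- truth %||% plant_truth(config)
  segments <- simulate_segments(config, cohort)
  ex <- simulate_expression(segments, truth, config, cohort)
  clinical <- simulate_survival(ex$risk, config, cohort)
  list(segments = segments, expr = ex$expr, probe_map = ex$probe_map,
       risk = ex$risk, clinical = clinical,
       dialect = config$dialects[cohort], truth = truth)
}

#' Simulate a full multi-cohort study
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `config`, `truth`, and `cohorts` (one
#'   [simulate_cohort()] result per cohort).
#' @export
#' @examples
#' cfg <- sim_config(n_cohorts = 2, cohort_sizes = c(20, 30),
#'                   dialects = c("absolute", "logratio"), n_genes = 100,
#'                   n_cn_driven = 5, n_prognostic = 5, seed = 7)
#' study <- simulate_study(cfg)
#' names(study$cohorts[[1]])
simulate_study <- function(config) {
  truth <- plant_truth(config)
  cohorts <- purrr::map(seq_len(config$n_cohorts),
                        function(k) simulate_cohort(config, k, truth))
  structure(list(config = config, truth = truth, cohorts = cohorts),
            class = "sim_study")
}
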