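# Follow-up horizon T_max for uniform censoring on [0, T_max] achieving
# the target expected censor rate given per-sample exponential hazards:
# P(censored | lambda) = (1 - exp(-lambda T)) / (lambda T).
solve_censor_horizon <- function(lambda, censor_rate) {
  f <- function(Tmax) {
    mean((1 - exp(-lambda * Tmax)) / (lambda * Tmax)) - censor_rate
  }
  # f(T) decreases from 1 (T -> 0) to 0 (T -> Inf)
  upper <- 10 / min(lambda)
  while (f(upper) > 0) upper <- upper * 10
  uniroot(f, lower = 1e-6, upper = upper, tol = 1e-8)$root
}

#' Simulate clinical and survival outcomes for one cohort
#'
#' Event times are exponential with hazard
#' `baseline_hazard x hazard_ratio^risk` (risk is the realized latent
#' risk, SD 1, so `hazard_ratio` is the hazard ratio per risk SD).
#' Censoring is uniform on `[0, T_max]` with `T_max` solved numerically
#' so the expected censored fraction equals `censor_rate`; with
#' `censor_rate = 0` no censoring is applied. Grade and nodal stage are
#' drawn with a mild positive association with risk; tumor size is
#' log-normal. Units: months.
#'
#' @param risk Tibble `sample`, `risk` (from [simulate_expression()]).
#' @param config A [sim_config()].
#' @param cohort Cohort index.
#' @return Clinical tibble: `sample`, `cohort`, `time_months`,
#'   `event` (1 = death from disease), `grade` (1-3), `size_cm`,
#'   `nodes_positive` (nodal stage 1-3).
#' @export
simulate_survival <- function(risk, config, cohort) {
  assert_that_(config$hazard_ratio > 0, "`hazard_ratio` must be > 0")
  n <- nrow(risk)
  with_seed_(stage_seed(config$seed, cohort, 3L), {
    lambda <- config$baseline_hazard * config$hazard_ratio^risk$risk
    t_event <- rexp(n, rate = lambda)
    if (config$censor_rate > 0) {
      t_max <- solve_censor_horizon(lambda, config$censor_rate)
      t_cens <- runif(n, 0, t_max)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    grade <- findInterval(risk$risk + rnorm(n, sd = 1.2), c(-0.8, 0.9)) + 1L
    nodes <- findInterval(risk$risk + rnorm(n, sd = 1.5), c(0.7, 1.8)) + 1L
    size <- round(pmin(pmax(exp(rnorm(n, log(2.2), 0.35)), 0.5), 8), 1)
    tibble(
      sample = risk$sample,
      cohort = paste0("cohort", cohort),
      time_months = time,
      event = event,
      grade = grade,
      size_cm = size,
      nodes_positive = nodes
    )
  })
}
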