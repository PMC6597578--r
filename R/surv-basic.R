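#' Kaplan-Meier estimates per group
#'
#' Product-limit survival curves and median survival per group.
#'
#' @param data Data frame with survival columns.
#' @param time,event,group Column names (strings) for follow-up time,
#'   event indicator (0/1) and group label; `group = NULL` fits a single
#'   curve.
#' @return List: `curves` (tibble `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`) and `medians` (tibble `group`, `n`, `events`,
#'   `median`; the median is NA where the curve never falls to 0.5,
#'   e.g. a group with no events).
#' @export
km_estimate <- function(data, time = "time_months", event = "event",
                        group = NULL) {
  assert_that_(all(data[[time]] >= 0), "negative survival times")
  g <- if (is.null(group)) rep("all", nrow(data)) else as.character(data[[group]])
  assert_that_(all(table(g) > 0), "every group must be non-empty")
  sf <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ g)
  strata <- if (is.null(sf$strata)) {
    rep("all", length(sf$time))
  } else {
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  curves <- tibble(
    group = strata, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, n_censor = sf$n.censor, surv = sf$surv
  )
  st <- summary(sf)$table
  if (is.null(dim(st))) st <- matrix(st, nrow = 1, dimnames = list("all", names(st)))
  medians <- tibble(
    group = sub("^g=", "", rownames(st)),
    n = as.integer(st[, "records"]),
    events = as.integer(st[, "events"]),
    median = as.numeric(st[, "median"])
  )
  structure(list(curves = curves, medians = medians), class = "km_fit")
}

#' Log-rank test between survival curves
#'
#' Standard (unweighted) log-rank test over the pooled risk set;
#' supports k > 2 groups (df = k - 1), as needed for tertile splits.
#'
#' @inheritParams km_estimate
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `events`.
#' @export
logrank_test <- function(data, time = "time_months", event = "event",
                         group = "group") {
  g <- factor(data[[group]])
  assert_that_(nlevels(droplevels(g)) >= 2,
               "log-rank needs at least two non-empty groups")
  assert_that_(sum(data[[event]]) >= 1, "log-rank needs at least one event")
  sd <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ g, rho = 0)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
         n = sum(sd$n), events = sum(sd$obs))
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit with Efron tie handling. Warns when
#' events are fewer than covariates; errors if the fit fails to
#' converge.
#'
#' @param data Data frame.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @inheritParams km_estimate
#' @return A `cox_fit` object wrapping the fit; see [tidy.cox_fit()]
#'   and [glance.cox_fit()].
#' @export
cox_fit <- function(data, covariates, time = "time_months",
                    event = "event", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  assert_that_(length(covariates) >= 1, "no covariates given")
  for (v in covariates) {
    vals <- data[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2) {
      abort(paste0("covariate `", v, "` is constant"))
    }
  }
  if (sum(data[[event]]) < length(covariates)) {
    warn("fewer events than covariates; estimates may be unstable")
  }
  f <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = data, ties = ties,
                         control = survival::coxph.control(
                           eps = 1e-9, iter.max = 100))
  if (any(is.na(stats::coef(fit)))) {
    abort("Cox fit produced undefined coefficients (collinear covariates?)")
  }
  structure(list(fit = fit, covariates = covariates), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>\n")
  print(tidy(x))
  invisible(x)
}
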