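#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_col geom_hline
#'   labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot Kaplan-Meier curves
#'
#' @param object A [km_estimate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- object$curves |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L,
             n_censor = 0L, surv = 1),
      .x)) |>
    ungroup()
  ggplot(d, aes(x = .data$time, y = .data$surv,
                colour = .data$group)) +
    geom_step() +
    labs(x = "Time (months)", y = "Survival probability",
         colour = NULL) +
    theme_minimal()
}

#' Genome-wide alteration-frequency plot
#'
#' Stacked per-gene frequencies of gains/amplifications (up) and
#' losses/homozygous deletions (down) along the genome.
#'
#' @param freq An [alteration_frequency()] table.
#' @return A ggplot.
#' @export
plot_alteration_frequency <- function(freq) {
  d <- freq |>
    tidyr::pivot_longer(c("amp", "gain", "loss", "homd"),
                        names_to = "state", values_to = "frequency") |>
    mutate(frequency = ifelse(.data$state %in% c("loss", "homd"),
                              -.data$frequency, .data$frequency),
           state = factor(.data$state,
                          levels = c("amp", "gain", "loss", "homd")))
  ggplot(d, aes(x = .data$start, y = 100 * .data$frequency,
                fill = .data$state)) +
    geom_col(position = "identity", width = 3e5) +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    facet_wrap(~ .data$chrom, nrow = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(
      amp = "#b2182b", gain = "#f4a582",
      loss = "#92c5de", homd = "#2166ac")) +
    labs(x = "Genomic position", y = "Altered samples (%)",
         fill = NULL) +
    theme_minimal()
}

#' Plot a boosting cross-validation curve
#'
#' @param object A [coxboost_select()] result (fitted with CV).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boost_fit <- function(object, ...) {
  assert_that_(!is.null(object$cv_curve),
               "fit has no CV curve (n_steps was fixed)")
  d <- tibble(step = seq_along(object$cv_curve) - 1,
              cv = object$cv_curve)
  ggplot(d, aes(x = .data$step, y = .data$cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$n_steps,
                        linetype = "dashed") +
    labs(x = "Boosting steps",
         y = "CV validation partial log-likelihood") +
    theme_minimal()
}

#' Score distribution by risk class
#'
#' @param scores Tibble with `score` and `class` columns (e.g. from
#'   [derive_signature()]'s `scores`).
#' @return A ggplot.
#' @export
plot_score_classes <- function(scores) {
  ggplot(scores, aes(x = .data$class, y = .data$score,
                     colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    labs(x = NULL, y = "Metagene score", colour = NULL) +
    theme_minimal()
}
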