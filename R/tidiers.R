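#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Cox fit
#'
#' @param x A [cox_fit()] object.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log hazard ratio),
#'   `hazard_ratio`, `std_error`, `statistic`, `p_value`.
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "coef"],
         hazard_ratio = s[, "exp(coef)"],
         std_error = s[, "se(coef)"], statistic = s[, "z"],
         p_value = s[, "Pr(>|z|)"])
}

#' @rdname tidy.cox_fit
#' @return `glance()`: one-row tibble with `n`, `events`, `logLik`
#'   (maximized partial log-likelihood), `concordance`.
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  f <- x$fit
  tibble(n = f$n, events = f$nevent,
         logLik = as.numeric(tail(f$loglik, 1)),
         concordance = unname(f$concordance["concordance"]))
}

#' Tidy a boosting fit
#'
#' @param x A [coxboost_select()] result.
#' @param ... Unused.
#' @return Tibble of nonzero coefficients with first-selection step.
#' @method tidy boost_fit
#' @export
tidy.boost_fit <- function(x, ...) {
  first <- x$selection_order |>
    group_by(.data$gene) |>
    summarise(first_step = min(.data$step), .groups = "drop")
  boost_selected(x) |> left_join(first, by = "gene") |>
    arrange(.data$first_step)
}

#' @rdname tidy.boost_fit
#' @method glance boost_fit
#' @export
glance.boost_fit <- function(x, ...) {
  tibble(n_steps = x$n_steps,
         n_selected = sum(x$coefficients != 0),
         penalty = x$penalty,
         train_logLik = as.numeric(tail(x$train_pl, 1)),
         cv_max = if (is.null(x$cv_curve)) NA_real_ else max(x$cv_curve))
}

#' Tidy a signature model
#'
#' @param x A [signature_model()].
#' @param ... Unused.
#' @return Tibble: `gene`, `coefficient`.
#' @method tidy signature_model
#' @export
tidy.signature_model <- function(x, ...) {
  tibble(gene = x$genes, coefficient = x$coefficients)
}

#' @rdname tidy.signature_model
#' @method glance signature_model
#' @export
glance.signature_model <- function(x, ...) {
  tibble(n_genes = length(x$genes),
         n_positive = sum(x$coefficients == 1),
         n_negative = sum(x$coefficients == -1),
         cutoff = x$cutoff)
}

#' @rdname evaluate_strata
#' @param x A `strata_report`.
#' @param ... Unused.
#' @method glance strata_report
#' @export
glance.strata_report <- function(x, ...) {
  hr <- tidy(x$cox) |> slice(1)
  tibble(logrank_p = x$logrank$p_value, auc = x$auc,
         cox_hr = hr$hazard_ratio, cox_p = hr$p_value)
}
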