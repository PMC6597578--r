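#' Evaluate a risk stratification against survival and outcome
#'
#' Per-class sample and event counts, KM curves and medians, overall
#' log-rank p, a Cox model of class adjusted for the requested clinical
#' covariates, and the ROC AUC of the continuous score against the
#' deceased label.
#'
#' @param data Tibble with one row per sample: survival columns, a
#'   `class` column (e.g. High/Low), a `score` column, and any
#'   covariates.
#' @param covariates Character vector of adjustment covariates present
#'   in `data` (constant covariates are dropped with a message).
#' @param horizon Optional horizon for the deceased AUC label.
#' @param time,event,class,score Column names.
#' @return A `strata_report`: list with `classes` (per-class tibble),
#'   `logrank`, `km`, `cox` (a [cox_fit()] or NULL when no events
#'   permit), `auc`.
#' @export
evaluate_strata <- function(data, covariates = character(),
                            horizon = NULL, time = "time_months",
                            event = "event", class = "class",
                            score = "score") {
  cls <- data[[class]]
  assert_that_(length(unique(cls)) >= 2,
               "need at least two classes to evaluate a stratification")
  missing_cov <- setdiff(covariates, names(data))
  assert_that_(length(missing_cov) == 0,
               paste0("covariates absent from data: ",
                      paste(missing_cov, collapse = ", ")))
  keep <- vapply(covariates, function(v) {
    length(unique(data[[v]])) > 1
  }, logical(1))
  if (any(!keep)) {
    inform(paste0("dropping constant covariate(s): ",
                  paste(covariates[!keep], collapse = ", ")))
  }
  covariates <- covariates[keep]

  km <- km_estimate(data, time = time, event = event, group = class)
  lr <- logrank_test(data, time = time, event = event, group = class)
  d <- data
  d$.class <- factor(cls)
  # report the adverse class against "Low" (or the first level) as
  # reference, so the leading Cox term reads High-vs-Low
  if ("Low" %in% levels(d$.class)) {
    d$.class <- stats::relevel(d$.class, ref = "Low")
  }
  cox <- cox_fit(d, c(".class", covariates), time = time, event = event)

  lab <- deceased_label(data, horizon, time = time, event = event)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = data[[score]],
    direction = "<", levels = c(0, 1), quiet = TRUE)))

  classes <- tibble(class = as.character(cls),
                    event = data[[event]]) |>
    group_by(.data$class) |>
    summarise(n = dplyr::n(), events = sum(.data$event),
              .groups = "drop") |>
    left_join(km$medians |> select("group", "median"),
              by = c("class" = "group"))

  structure(list(classes = classes, logrank = lr, km = km, cox = cox,
                 auc = auc),
            class = "strata_report")
}

#' @export
print.strata_report <- function(x, ...) {
  cat("<strata_report>\n")
  print(x$classes)
  cat(sprintf("log-rank p = %.3g; AUC = %.3f\n",
              x$logrank$p_value, x$auc))
  invisible(x)
}

#' Chi-square enrichment of an annotation across strata
#'
#' Pearson chi-square (no continuity correction) on the classes x
#' annotation contingency table, with expected counts reported and a
#' warning when any expected count is below 5.
#'
#' @param classes Character/factor vector of strata labels.
#' @param annotation Character/factor vector of the same length (e.g.
#'   molecular subtype, mutation status).
#' @return List: `table` (observed counts), `expected`, `test` (tibble
#'   `statistic`, `df`, `p_value`).
#' @export
chi_square_enrichment <- function(classes, annotation) {
  assert_that_(length(classes) == length(annotation), "length mismatch")
  tab <- table(classes, annotation)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2) {
    abort("degenerate contingency table (a zero margin or single level)")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    warn("some expected counts are below 5; chi-square approximation is weak")
  }
  list(table = tab, expected = ct$expected,
       test = tibble(statistic = unname(ct$statistic),
                     df = unname(ct$parameter),
                     p_value = ct$p.value))
}

#' Nottingham Prognostic Index
#'
#' `NPI = 0.2 x size_cm + grade + node_stage`, banded good < 3.4,
#' moderate 3.4-5.4, poor > 5.4 (band edges configurable; the good band
#' is `< bands[1]`, poor is `> bands[2]`).
#'
#' @param size_cm Tumor size in cm (> 0).
#' @param grade Histological grade 1-3.
#' @param node_stage Nodal stage 1-3.
#' @param bands Length-2 numeric band edges.
#' @return Tibble: `npi`, `band` (good/moderate/poor).
#' @export
#' @examples
#' npi(2.0, 2, 1)  # 3.4, moderate
npi <- function(size_cm, grade, node_stage, bands = c(3.4, 5.4)) {
  assert_that_(all(size_cm > 0), "size_cm must be > 0")
  assert_that_(all(grade %in% 1:3), "grade must be 1, 2 or 3")
  assert_that_(all(node_stage %in% 1:3), "node_stage must be 1, 2 or 3")
  v <- 0.2 * size_cm + grade + node_stage
  tibble(npi = v,
         band = dplyr::case_when(v < bands[1] ~ "good",
                                 v > bands[2] ~ "poor",
                                 TRUE ~ "moderate"))
}

#' Hierarchical clustering of expression with rank-based distances
#'
#' Genes are standardized by median-centering and dividing by the
#' median absolute deviation (zero-MAD genes are dropped with a
#' message); samples are clustered on 1 - Spearman correlation and
#' genes on 1 - Pearson correlation, with agglomerative (average
#' linkage by default) clustering and a k-cluster tree cut for
#' samples.
#'
#' @param expr Genes x samples matrix.
#' @param genes Optional gene subset.
#' @param k Clusters for the sample tree cut.
#' @param linkage hclust method (default `"average"`).
#' @return List: `sample_hclust`, `gene_hclust`, `sample_clusters`
#'   (named integer vector), `standardized` matrix.
#' @export
cluster_expression <- function(expr, genes = NULL, k = 2,
                               linkage = "average") {
  if (!is.null(genes)) expr <- expr[intersect(genes, rownames(expr)), , drop = FALSE]
  assert_that_(nrow(expr) >= 3 && ncol(expr) >= 3,
               "need at least 3 genes and 3 samples")
  med <- apply(expr, 1, median)
  madv <- apply(expr, 1, mad)
  drop <- madv == 0
  if (any(drop)) {
    inform(paste0("dropping ", sum(drop), " zero-MAD gene(s)"))
    expr <- expr[!drop, , drop = FALSE]
    med <- med[!drop]; madv <- madv[!drop]
  }
  assert_that_(nrow(expr) >= 3, "fewer than 3 genes left after MAD filter")
  std <- sweep(sweep(expr, 1, med), 1, madv, "/")
  d_samp <- as.dist(1 - cor(std, method = "spearman"))
  d_gene <- as.dist(1 - cor(t(std), method = "pearson"))
  hs <- hclust(d_samp, method = linkage)
  hg <- hclust(d_gene, method = linkage)
  list(sample_hclust = hs, gene_hclust = hg,
       sample_clusters = cutree(hs, k = k), standardized = std)
}
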