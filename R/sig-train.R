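#' ROC-optimal cutoff by exhaustive midpoint scan
#'
#' Scans the midpoints of consecutive sorted unique scores (plus one
#' candidate below the minimum and one above the maximum) and returns
#' the cutoff maximizing sensitivity + specificity for predicting
#' `label == 1` by `score > cutoff`. Ties are broken toward the
#' smallest cutoff (favoring sensitivity).
#'
#' @param score Numeric scores.
#' @param label 0/1 outcome (1 = deceased).
#' @return List: `cutoff`, `sensitivity`, `specificity`.
#' @export
roc_cutoff <- function(score, label) {
  assert_that_(length(score) == length(label), "length mismatch")
  assert_that_(all(label %in% c(0, 1)), "label must be 0/1")
  assert_that_(any(label == 1) && any(label == 0),
               "need both outcome classes to place a cutoff; use stratified folds")
  u <- sort(unique(score))
  cands <- c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  stat <- vapply(cands, function(cc) {
    sens <- sum(score > cc & label == 1) / n1
    spec <- sum(score <= cc & label == 0) / n0
    sens + spec
  }, numeric(1))
  best <- which.max(stat)                     # first max = smallest cutoff
  cc <- cands[best]
  list(cutoff = cc,
       sensitivity = sum(score > cc & label == 1) / n1,
       specificity = sum(score <= cc & label == 0) / n0)
}

#' Deceased label for cutoff training
#'
#' The training outcome is the event flag, optionally restricted to
#' events within a follow-up horizon (samples censored before the
#' horizon keep label 0).
#'
#' @param clinical Clinical tibble.
#' @param horizon Optional horizon in months (e.g. 120 for 10-year).
#' @param time,event Column names.
#' @return Integer 0/1 vector along the rows of `clinical`.
#' @export
deceased_label <- function(clinical, horizon = NULL,
                           time = "time_months", event = "event") {
  lab <- as.integer(clinical[[event]] == 1)
  if (!is.null(horizon)) {
    lab <- as.integer(lab == 1 & clinical[[time]] <= horizon)
  }
  lab
}

#' Cross-validated High/Low classification of metagene scores
#'
#' Five-fold (by default) cross-validation: for each fold the
#' ROC-optimal cutoff (maximum sensitivity + specificity for the
#' deceased label) is chosen on the other folds and applied to the
#' held-out fold, so every sample is classified exactly once. Folds are
#' stratified by outcome. The deployable cutoff is the median of the
#' fold cutoffs.
#'
#' @param scores Tibble with `sample`, `score` and the outcome column.
#' @param outcome Name of the 0/1 outcome column (default
#'   `"deceased"`).
#' @param k Number of folds.
#' @param seed Seed for fold assignment.
#' @return List: `results` (tibble `sample`, `score`, `fold`,
#'   `cutoff`, `class` in {High, Low}), `fold_cutoffs`, `cutoff`
#'   (median of fold cutoffs), `seed`.
#' @export
cv_train_classify <- function(scores, outcome = "deceased", k = 5,
                              seed = 1) {
  y <- scores[[outcome]]
  assert_that_(all(y %in% c(0, 1)), "outcome must be 0/1")
  folds <- with_seed_(seed, caret::createFolds(factor(y), k = k))
  res <- purrr::imap_dfr(folds, function(idx, nm) {
    tr <- setdiff(seq_len(nrow(scores)), idx)
    if (length(unique(y[tr])) < 2) {
      abort("a training split contains a single outcome class; use stratified folds or fewer folds")
    }
    cut <- roc_cutoff(scores$score[tr], y[tr])
    tibble(
      sample = scores$sample[idx],
      score = scores$score[idx],
      fold = as.integer(sub("^Fold0*", "", nm)),
      cutoff = cut$cutoff,
      class = ifelse(scores$score[idx] > cut$cutoff, "High", "Low")
    )
  })
  fold_cutoffs <- res |> distinct(.data$fold, .data$cutoff) |>
    arrange(.data$fold) |> pull("cutoff")
  list(results = res, fold_cutoffs = fold_cutoffs,
       cutoff = median(fold_cutoffs), seed = seed)
}

#' Derive a prognostic signature from candidate genes
#'
#' The full signature-construction pass: candidates are filtered for
#' univariate prognostic value ([filter_prognostic()]) and, in
#' parallel, subjected to component-wise likelihood-based boosting
#' ([coxboost_select()]); the two gene lists are combined (union by
#' default; intersection available for sensitivity analysis). Each
#' signature gene gets a +/-1 coefficient: the filter's direction where
#' available, otherwise the sign of its boosting coefficient. Scores
#' are then computed on the training cohort and the High/Low cutoff
#' trained by [cv_train_classify()].
#'
#' @param clinical Training clinical tibble.
#' @param expr Probes (or genes) x samples expression matrix.
#' @param candidates Character vector of candidate genes.
#' @param probe_map Optional probe/gene map.
#' @param split,p_thresh Filter settings, see [filter_prognostic()].
#' @param combine `"union"` (default) or `"intersection"` of the
#'   filter-passed and boosting-selected gene lists.
#' @param penalty,max_steps,cv_folds Boosting settings.
#' @param folds Folds for cutoff training.
#' @param horizon Optional deceased-label horizon (months).
#' @param seed Seed (folds for boosting and cutoff training).
#' @param time,event Clinical column names.
#' @return List: `model` ([signature_model()] with trained cutoff),
#'   `filter_records`, `boost_fit`, `scores` (training scores with CV
#'   classes), `cv` (the [cv_train_classify()] result).
#' @export
derive_signature <- function(clinical, expr, candidates,
                             probe_map = NULL,
                             split = "tertile", p_thresh = 0.01,
                             combine = c("union", "intersection"),
                             penalty = NULL, max_steps = 100,
                             cv_folds = 10, folds = 5, horizon = NULL,
                             seed = 1, time = "time_months",
                             event = "event") {
  combine <- match.arg(combine)
  gexpr <- if (is.null(probe_map)) expr else collapse_probes(expr, probe_map)
  candidates <- intersect(candidates, rownames(gexpr))
  assert_that_(length(candidates) > 0, "no candidate genes in expression")

  records <- filter_prognostic(clinical, expr, candidates, probe_map,
                               split = split, p_thresh = p_thresh,
                               time = time, event = event)
  uni_genes <- records$gene[records$passed]

  samples <- intersect(colnames(gexpr), clinical$sample)
  bfit <- coxboost_select(
    clinical[match(samples, clinical$sample), ],
    gexpr[candidates, samples, drop = FALSE],
    time = time, event = event, penalty = penalty,
    max_steps = max_steps, cv_folds = cv_folds, seed = seed)
  boost_genes <- boost_selected(bfit)

  genes <- switch(combine,
    union = union(uni_genes, boost_genes$gene),
    intersection = intersect(uni_genes, boost_genes$gene))
  assert_that_(length(genes) > 0,
               "no genes survived filtering and boosting")
  dir <- stats::setNames(records$direction, records$gene)[genes]
  bsign <- stats::setNames(sign(boost_genes$coefficient), boost_genes$gene)
  dir[is.na(dir)] <- bsign[genes[is.na(dir)]]
  model <- signature_model(
    genes, as.integer(dir),
    provenance = list(split = split, p_thresh = p_thresh,
                      combine = combine, penalty = bfit$penalty,
                      boost_steps = bfit$n_steps, seed = seed))

  sc <- compute_score(expr, model, probe_map) |>
    inner_join(clinical, by = "sample")
  sc$deceased <- deceased_label(sc, horizon, time = time, event = event)
  cv <- cv_train_classify(sc, outcome = "deceased", k = folds,
                          seed = seed)
  model$cutoff <- cv$cutoff
  scores <- sc |>
    select("sample", "score", "deceased") |>
    left_join(cv$results |> select("sample", "fold", "class"),
              by = "sample")
  list(model = model, filter_records = records, boost_fit = bfit,
       scores = scores, cv = cv)
}
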