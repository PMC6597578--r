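# Restricted mean survival time: area under the KM step function up to
# `horizon`. `times`/`surv` are one group's KM curve (event/censor
# times ascending), with S(0) = 1.
rmst_km <- function(times, surv, horizon) {
  tt <- c(0, times[times <= horizon], horizon)
  ss <- c(1, surv[times <= horizon])
  sum(ss * diff(tt))
}

# Expression bins (1 = lowest) by tertile or quartile.
expression_bins <- function(x, split = c("tertile", "quartile")) {
  split <- match.arg(split)
  k <- if (split == "tertile") 3L else 4L
  dplyr::ntile(x, k)
}

#' Filter candidate genes for univariate prognostic value
#'
#' Applies the three-part survival filter to each candidate gene: split
#' samples into expression tertiles (default) or quartiles, and demand
#' (i) a monotone spread of the per-bin survival curves, computed as a
#' strictly monotone ordering of per-bin restricted mean survival up to
#' the longest follow-up; (ii) when a gene has several probes, that all
#' probes pass with the same direction; and (iii) a significant k-group
#' log-rank separation (`p < p_thresh`). The direction is +1 when
#' higher expression means worse survival.
#'
#' @param clinical Clinical tibble (`sample`, time/event columns).
#' @param expr Probes (or genes) x samples expression matrix.
#' @param candidates Character vector of gene ids to test.
#' @param probe_map Optional `probe`/`gene` map; when NULL the matrix
#'   rows are taken as genes.
#' @param split `"tertile"` (default) or `"quartile"`.
#' @param p_thresh Log-rank significance threshold (default 0.01).
#' @param time,event Clinical column names.
#' @return Tibble (one row per candidate found in the matrix): `gene`,
#'   `n_probes`, `min_p`, `monotonic`, `probes_consistent`,
#'   `direction` (+1/-1, NA when failed), `passed`.
#' @export
filter_prognostic <- function(clinical, expr, candidates,
                              probe_map = NULL,
                              split = c("tertile", "quartile"),
                              p_thresh = 0.01,
                              time = "time_months", event = "event") {
  split <- match.arg(split)
  assert_that_(length(candidates) > 0, "no candidate genes given")
  if (is.null(probe_map)) {
    probe_map <- tibble(probe = rownames(expr), gene = rownames(expr))
  }
  probe_map <- probe_map |> filter(.data$probe %in% rownames(expr))
  found <- intersect(candidates, probe_map$gene)
  skipped <- setdiff(candidates, found)
  if (length(skipped) > 0) {
    inform(paste0(length(skipped),
                  " candidate gene(s) absent from expression; skipped"))
  }
  samples <- intersect(colnames(expr), clinical$sample)
  assert_that_(length(samples) >= 12,
               "too few shared samples for a binned survival split")
  cl <- clinical[match(samples, clinical$sample), ]
  horizon <- max(cl[[time]])

  probe_test <- function(p) {
    x <- expr[p, samples]
    bin <- expression_bins(x, split)
    d <- tibble(t = cl[[time]], e = cl[[event]], bin = bin)
    lr <- logrank_test(d, time = "t", event = "e", group = "bin")
    km <- km_estimate(d, time = "t", event = "e", group = "bin")
    rm <- vapply(sort(unique(bin)), function(b) {
      cv <- km$curves |> filter(.data$group == as.character(b))
      rmst_km(cv$time, cv$surv, horizon)
    }, numeric(1))
    mono <- all(diff(rm) > 0) || all(diff(rm) < 0)
    # +1: highest-expression bin has the worse (smaller) restricted mean
    dir <- if (rm[length(rm)] < rm[1]) 1L else -1L
    tibble(p_value = lr$p_value, monotonic = mono, direction = dir)
  }

  purrr::map_dfr(found, function(g) {
    probes <- probe_map$probe[probe_map$gene == g]
    res <- purrr::map_dfr(probes, probe_test)
    probe_pass <- res$p_value < p_thresh & res$monotonic
    consistent <- all(probe_pass) && length(unique(res$direction)) == 1
    passed <- consistent && all(probe_pass)
    tibble(
      gene = g, n_probes = length(probes), min_p = min(res$p_value),
      monotonic = all(res$monotonic), probes_consistent = consistent,
      direction = if (passed) res$direction[1] else NA_integer_,
      passed = passed
    )
  })
}
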