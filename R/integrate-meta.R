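#' DerSimonian-Laird random-effects meta-analysis of correlations
#'
#' Per gene: Fisher z-transform each cohort's Spearman rho, weight by
#' the inverse within-study variance 1/(n-3), estimate the
#' between-study variance tau^2 by the DerSimonian-Laird moment
#' estimator (truncated at 0), pool with weights 1/(1/(n-3) + tau^2),
#' and back-transform the pooled z to the correlation scale. Cohorts
#' with n <= 3 or missing rho are excluded; a gene needs at least
#' `min_cohorts` contributing cohorts.
#'
#' @param stats Tibble with columns `gene`, `cohort`, `n`, `rho`.
#' @param min_cohorts Minimum contributing cohorts per gene (default 2;
#'   with a single cohort the pooled correlation is that cohort's rho).
#' @return Tibble: `gene`, `combined_effect` (pooled correlation),
#'   `tau2`, `combined_p` (two-sided normal test of the pooled z),
#'   `n_cohorts_used`.
#' @export
#' @examples
#' toy <- tibble::tibble(gene = "g1", cohort = c("a", "b", "c"),
#'                       n = c(30, 60, 80), rho = c(0.8, 0.8, 0.8))
#' dl_meta_correlation(toy)$combined_effect  # 0.8, tau2 = 0
dl_meta_correlation <- function(stats, min_cohorts = 2) {
  stats |>
    filter(!is.na(.data$rho), .data$n > 3) |>
    mutate(
      z = atanh(pmin(pmax(.data$rho, -1 + 1e-12), 1 - 1e-12)),
      v = 1 / (.data$n - 3)
    ) |>
    group_by(.data$gene) |>
    summarise(
      n_cohorts_used = dplyr::n(),
      {
        w <- 1 / .data$v
        zf <- sum(w * .data$z) / sum(w)
        q <- sum(w * (.data$z - zf)^2)
        cc <- sum(w) - sum(w^2) / sum(w)
        tau2 <- if (dplyr::n() > 1) max(0, (q - (dplyr::n() - 1)) / cc) else 0
        ws <- 1 / (.data$v + tau2)
        pooled <- sum(ws * .data$z) / sum(ws)
        se <- sqrt(1 / sum(ws))
        tibble(combined_effect = tanh(pooled), tau2 = tau2,
               combined_p = 2 * pnorm(abs(pooled / se), lower.tail = FALSE))
      },
      .groups = "drop"
    ) |>
    filter(.data$n_cohorts_used >= min_cohorts) |>
    select("gene", "combined_effect", "tau2", "combined_p",
           "n_cohorts_used")
}

#' Stouffer Z combination of per-cohort p-values, weighted by sample size
#'
#' Converts each cohort p to a one-sided z = qnorm(1 - p) and combines
#' with sample-size weights: Z = sum(n_i z_i) / sqrt(sum(n_i^2));
#' combined p = 1 - Phi(Z). By default the Benjamini-Hochberg adjusted
#' per-cohort p-values are combined (`use_adjusted = FALSE` switches to
#' raw p). Zero p-values are clipped to the smallest positive double
#' (with a message); p-values of 1 are clipped just below 1 so the z
#' stays finite.
#'
#' @param stats Tibble with columns `gene`, `cohort`, `n`, and
#'   `anova_p` / `anova_p_adj`.
#' @param use_adjusted Combine BH-adjusted p-values (default TRUE).
#' @param min_cohorts Minimum contributing cohorts per gene.
#' @return Tibble: `gene`, `combined_z`, `combined_p`,
#'   `n_cohorts_used`.
#' @export
stouffer_meta <- function(stats, use_adjusted = TRUE, min_cohorts = 2) {
  pcol <- if (use_adjusted) "anova_p_adj" else "anova_p"
  assert_that_(pcol %in% names(stats),
               paste0("stats must carry a `", pcol, "` column"))
  d <- stats |>
    mutate(p = .data[[pcol]]) |>
    filter(!is.na(.data$p))
  if (any(d$p == 0)) {
    inform("p-values of 0 clipped to the smallest positive double")
    d$p[d$p == 0] <- .Machine$double.xmin
  }
  d |>
    mutate(z = qnorm(pmin(.data$p, 1 - 1e-16), lower.tail = FALSE)) |>
    group_by(.data$gene) |>
    summarise(
      n_cohorts_used = dplyr::n(),
      combined_z = sum(.data$n * .data$z) / sqrt(sum(.data$n^2)),
      .groups = "drop"
    ) |>
    filter(.data$n_cohorts_used >= min_cohorts) |>
    mutate(combined_p = pnorm(.data$combined_z, lower.tail = FALSE)) |>
    select("gene", "combined_z", "combined_p", "n_cohorts_used")
}

#' Select copy-number-driven candidate genes from the meta-analyses
#'
#' Retains genes whose pooled correlation exceeds `rho_cut` (strictly)
#' or whose Stouffer-combined p is below `p_cut` (strictly), and labels
#' each selected gene by which arm(s) selected it.
#'
#' @param meta_rho [dl_meta_correlation()] output.
#' @param meta_p [stouffer_meta()] output.
#' @param rho_cut Pooled-correlation retention threshold (default 0.6).
#' @param p_cut Combined-p retention threshold (default 1e-5).
#' @return Tibble: `gene`, `combined_effect`, `tau2`, `combined_p`,
#'   `by_spearman`, `by_anova`, `selected_by` (one of `"spearman"`,
#'   `"anova"`, `"both"`, `"none"`).
#' @export
select_candidates <- function(meta_rho, meta_p, rho_cut = 0.6,
                              p_cut = 1e-5) {
  dplyr::full_join(
    meta_rho |> select("gene", "combined_effect", "tau2"),
    meta_p |> select("gene", "combined_z", "combined_p"),
    by = "gene"
  ) |>
    mutate(
      by_spearman = !is.na(.data$combined_effect) &
        .data$combined_effect > rho_cut,
      by_anova = !is.na(.data$combined_p) & .data$combined_p < p_cut,
      selected_by = dplyr::case_when(
        .data$by_spearman & .data$by_anova ~ "both",
        .data$by_spearman ~ "spearman",
        .data$by_anova ~ "anova",
        TRUE ~ "none"
      )
    )
}

#' Integrate copy number and expression across the cohorts of a study
#'
#' Full integration pass over a list of cohorts: per-cohort gene-level
#' copy-number assignment, Spearman + ANOVA statistics, both
#' meta-analyses, and candidate selection.
#'
#' @param cohorts List of cohorts, each a list with `segments`, `expr`,
#'   `probe_map`, `dialect` (as produced by [simulate_cohort()], or
#'   assembled from files).
#' @param genes Gene annotation tibble.
#' @param rho_cut,p_cut Selection thresholds, see [select_candidates()].
#' @param use_adjusted Combine BH-adjusted ANOVA p-values.
#' @param thresholds [cn_thresholds()] for state calling.
#' @return List: `stats` (per-cohort tibble), `meta` (selection tibble
#'   from [select_candidates()]), `candidates` (character vector of
#'   selected genes).
#' @export
integrate_cohorts <- function(cohorts, genes, rho_cut = 0.6,
                              p_cut = 1e-5, use_adjusted = TRUE,
                              thresholds = cn_thresholds()) {
  stats <- purrr::imap_dfr(cohorts, function(co, i) {
    called <- call_states(co$segments, co$dialect, thresholds)
    gcn <- assign_gene_cn(called, genes)
    cohort_stats(co$expr, gcn, co$probe_map, cohort = paste0("cohort", i))
  })
  meta_rho <- dl_meta_correlation(
    stats |> select("gene", "cohort", n = "n_rho", "rho"))
  meta_p <- stouffer_meta(
    stats |> select("gene", "cohort", n = "n_anova", "anova_p",
                    "anova_p_adj"),
    use_adjusted = use_adjusted)
  meta <- select_candidates(meta_rho, meta_p, rho_cut, p_cut)
  list(stats = stats,
       meta = meta,
       candidates = meta$gene[meta$selected_by != "none"])
}
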