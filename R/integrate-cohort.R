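#' Per-cohort Spearman correlation of expression with copy-number dosage
#'
#' For every gene, the rank correlation between (log-scale) expression
#' and the gene-level copy-number log-ratio over samples where both are
#' available. Genes with fewer than 4 paired samples or a constant
#' vector get a missing rho.
#'
#' @param expr Probes (or genes) x samples log2 expression matrix.
#' @param gene_cn A [assign_gene_cn()] result carrying log-ratios.
#' @param probe_map Optional tibble `probe`, `gene`; when given, probes
#'   are averaged to gene level first.
#' @param cohort Cohort id recorded in the output.
#' @return Tibble: `gene`, `cohort`, `n`, `rho`.
#' @export
spearman_per_cohort <- function(expr, gene_cn, probe_map = NULL,
                                cohort = "cohort") {
  gexpr <- if (is.null(probe_map)) expr else collapse_probes(expr, probe_map)
  samples <- intersect(colnames(gexpr), colnames(gene_cn$logratio))
  assert_that_(length(samples) >= 4,
               "need at least 4 shared samples between expression and CN")
  genes <- intersect(rownames(gexpr), rownames(gene_cn$logratio))
  E <- gexpr[genes, samples, drop = FALSE]
  L <- gene_cn$logratio[genes, samples, drop = FALSE]
  res <- vapply(seq_along(genes), function(i) {
    x <- E[i, ]; y <- L[i, ]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(c(n, NA_real_))
    }
    c(n, cor(x[ok], y[ok], method = "spearman"))
  }, numeric(2))
  tibble(gene = genes, cohort = cohort,
         n = as.integer(res[1, ]), rho = res[2, ])
}

# Closed-form one-way equal-variance ANOVA; returns c(F, df1, df2, p).
oneway_f <- function(y, g) {
  tab <- table(g)
  tab <- tab[tab >= 2]
  if (length(tab) < 2) return(c(NA, NA, NA, NA))
  keep <- g %in% names(tab)
  y <- y[keep]; g <- factor(g[keep])
  n <- length(y); k <- nlevels(g)
  gm <- tapply(y, g, mean)
  ybar <- mean(y)
  ssb <- sum(tabulate(g) * (gm - ybar)^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  c(f, df1, df2, pf(f, df1, df2, lower.tail = FALSE))
}

#' Per-cohort ANOVA of expression across discrete copy-number states
#'
#' One-way (equal-variance) ANOVA of a gene's expression across its
#' discrete copy-number states, per cohort, with Benjamini-Hochberg
#' adjustment across the genes tested in that cohort. A gene needs at
#' least two states each carrying >= 2 samples; otherwise its p is
#' missing (not 1).
#'
#' @inheritParams spearman_per_cohort
#' @return Tibble: `gene`, `cohort`, `n`, `anova_f`, `anova_p`,
#'   `anova_p_adj`.
#' @export
anova_per_cohort <- function(expr, gene_cn, probe_map = NULL,
                             cohort = "cohort") {
  gexpr <- if (is.null(probe_map)) expr else collapse_probes(expr, probe_map)
  samples <- intersect(colnames(gexpr), colnames(gene_cn$states))
  assert_that_(length(samples) >= 4,
               "need at least 4 shared samples between expression and CN")
  genes <- intersect(rownames(gexpr), rownames(gene_cn$states))
  E <- gexpr[genes, samples, drop = FALSE]
  C <- gene_cn$states[genes, samples, drop = FALSE]
  res <- vapply(seq_along(genes), function(i) {
    ok <- !is.na(C[i, ]) & !is.na(E[i, ])
    out <- oneway_f(E[i, ok], C[i, ok])
    c(sum(ok), out[1], out[4])
  }, numeric(3))
  out <- tibble(gene = genes, cohort = cohort,
                n = as.integer(res[1, ]),
                anova_f = res[2, ], anova_p = res[3, ])
  out$anova_p_adj <- NA_real_
  tested <- !is.na(out$anova_p)
  out$anova_p_adj[tested] <- p.adjust(out$anova_p[tested], method = "BH")
  out
}

#' All per-cohort integration statistics for one cohort
#'
#' Convenience join of [spearman_per_cohort()] and [anova_per_cohort()].
#'
#' @inheritParams spearman_per_cohort
#' @return Tibble: `gene`, `cohort`, `n_rho`, `rho`, `n_anova`,
#'   `anova_f`, `anova_p`, `anova_p_adj` (the two n's can differ when
#'   log-ratios are missing for part of the samples).
#' @export
cohort_stats <- function(expr, gene_cn, probe_map = NULL,
                         cohort = "cohort") {
  sp <- spearman_per_cohort(expr, gene_cn, probe_map, cohort) |>
    rename(n_rho = "n")
  an <- anova_per_cohort(expr, gene_cn, probe_map, cohort) |>
    rename(n_anova = "n")
  dplyr::full_join(sp, an, by = c("gene", "cohort"))
}
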