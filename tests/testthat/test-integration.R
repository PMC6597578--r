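# Assemble a gene_cn object directly from matrices.
mk_gcn <- function(L = NULL, C = NULL) {
  m <- if (is.null(L)) C else L
  genes <- tibble::tibble(gene = rownames(m), chrom = "1",
                          start = seq_len(nrow(m)) * 100,
                          end = seq_len(nrow(m)) * 100 + 50, strand = "+")
  if (is.null(C)) {
    C <- m; C[] <- NA_character_
  }
  if (is.null(L)) {
    L <- matrix(NA_real_, nrow(C), ncol(C), dimnames = dimnames(C))
  }
  structure(list(states = C, logratio = L, genes = genes),
            class = "gene_cn")
}

test_that("Spearman recovers a monotone identity and a hand-ranked fixture", {
  L <- rbind(gA = c(3.2, 1.1, 5.5, 2.2, 6.6, 4.4))
  colnames(L) <- paste0("s", 1:6)
  # identity: expression equal to L
  gcn <- mk_gcn(L = L)
  sp <- spearman_per_cohort(L, gcn)
  expect_equal(sp$rho, 1)
  # hand computation: ranks x = (3,1,5,2,6,4), y = (2,1,4,3,6,5)
  # d = (1,0,1,-1,0,-1), sum d^2 = 4, rho = 1 - 24/210 = 31/35
  E <- rbind(gA = c(2, 1, 4, 3, 6, 5))
  colnames(E) <- paste0("s", 1:6)
  sp2 <- spearman_per_cohort(E, gcn)
  expect_equal(sp2$rho, 31 / 35, tolerance = 1e-12)
  expect_equal(sp2$n, 6L)
})

test_that("Spearman null distribution stays near zero at n = 100", {
  withr::with_seed(31, {
    n_genes <- 400
    L <- matrix(rnorm(n_genes * 100), n_genes, 100,
                dimnames = list(sprintf("g%03d", 1:n_genes),
                                sprintf("s%03d", 1:100)))
    E <- matrix(rnorm(n_genes * 100), n_genes, 100,
                dimnames = dimnames(L))
    sp <- spearman_per_cohort(E, mk_gcn(L = L))
    expect_gte(mean(abs(sp$rho) < 0.3), 0.99)
  })
})

test_that("too few pairs or constant vectors give missing rho", {
  L <- rbind(gA = c(1, 2, 3, NA, NA, NA),
             gB = rep(1, 6))
  colnames(L) <- paste0("s", 1:6)
  E <- rbind(gA = rnorm(6), gB = rnorm(6))
  dimnames(E) <- dimnames(L)
  sp <- spearman_per_cohort(E, mk_gcn(L = L))
  expect_true(all(is.na(sp$rho)))
})

test_that("one-way ANOVA matches the closed form on a hand-solved 3x3 table", {
  # groups NEUT (1,2,3), GAIN (2,3,4), AMP (4,5,6):
  # SSB = 14, SSW = 6, F = (14/2)/(6/6) = 7
  E <- rbind(gA = c(1, 2, 3, 2, 3, 4, 4, 5, 6))
  colnames(E) <- paste0("s", 1:9)
  C <- rbind(gA = rep(c("NEUT", "GAIN", "AMP"), each = 3))
  dimnames(C) <- dimnames(E)
  an <- anova_per_cohort(E, mk_gcn(C = C))
  expect_equal(an$anova_f, 7, tolerance = 1e-12)
  expect_equal(an$anova_p, pf(7, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against stats::aov on the same data
  fit <- summary(stats::aov(y ~ g, data.frame(y = E[1, ],
                                              g = factor(C[1, ]))))[[1]]
  expect_equal(an$anova_f, fit[["F value"]][1], tolerance = 1e-10)
  expect_equal(an$anova_p, fit[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(5, {
    y <- rnorm(20)
    g <- rep(c("NEUT", "GAIN"), each = 10)
    E <- rbind(gA = y); colnames(E) <- paste0("s", 1:20)
    C <- rbind(gA = g); dimnames(C) <- dimnames(E)
    an <- anova_per_cohort(E, mk_gcn(C = C))
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(an$anova_f, unname(tt$statistic)^2, tolerance = 1e-10)
  })
})

test_that("identical group means give F = 0 and degenerate groups go missing", {
  E <- rbind(flat = c(1, 3, 2, 2, 1, 3),
             single = rnorm(6),
             thin = rnorm(6))
  colnames(E) <- paste0("s", 1:6)
  C <- rbind(flat = rep(c("NEUT", "GAIN"), each = 3),
             single = rep("NEUT", 6),
             thin = c(rep("NEUT", 5), "GAIN"))
  dimnames(C) <- dimnames(E)
  an <- anova_per_cohort(E, mk_gcn(C = C))
  expect_equal(an$anova_f[an$gene == "flat"], 0)
  expect_equal(an$anova_p[an$gene == "flat"], 1)
  expect_true(is.na(an$anova_p[an$gene == "single"]))
  expect_true(is.na(an$anova_p[an$gene == "thin"]))
})

test_that("BH adjustment is per cohort and never below the raw p", {
  withr::with_seed(8, {
    E <- matrix(rnorm(50 * 12), 50, 12,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:12)))
    C <- matrix(sample(c("NEUT", "GAIN"), 50 * 12, TRUE), 50, 12,
                dimnames = dimnames(E))
    an <- anova_per_cohort(E, mk_gcn(C = C))
    tested <- !is.na(an$anova_p)
    expect_true(all(an$anova_p_adj[tested] >= an$anova_p[tested]))
    expect_equal(an$anova_p_adj[tested],
                 p.adjust(an$anova_p[tested], "BH"))
  })
})

test_that("DerSimonian-Laird pooling is exact at zero heterogeneity", {
  toy <- tibble::tibble(gene = "g1", cohort = c("a", "b", "c"),
                        n = c(30, 60, 80), rho = 0.8)
  dl <- dl_meta_correlation(toy)
  expect_equal(dl$combined_effect, 0.8, tolerance = 1e-12)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$n_cohorts_used, 3L)
})

test_that("DL matches metafor and the plain moment formulas on a 3-study toy", {
  skip_if_not_installed("metafor")
  rho <- c(0.5, 0.7, 0.9); n <- c(20, 50, 30)
  toy <- tibble::tibble(gene = "g1", cohort = c("a", "b", "c"),
                        n = n, rho = rho)
  dl <- dl_meta_correlation(toy)
  ref <- metafor::rma(yi = atanh(rho), vi = 1 / (n - 3), method = "DL")
  expect_equal(dl$combined_effect, tanh(as.numeric(ref$b)),
               tolerance = 1e-8)
  expect_equal(dl$tau2, ref$tau2, tolerance = 1e-8)
  ora <- oracle_dl(rho, n)
  expect_equal(dl$combined_effect, ora$effect, tolerance = 1e-12)
  expect_equal(dl$tau2, ora$tau2, tolerance = 1e-12)
})

test_that("DL drops tiny cohorts and reduces to the single remaining rho", {
  toy <- tibble::tibble(gene = "g1", cohort = c("a", "b"),
                        n = c(3, 40), rho = c(0.9, 0.55))
  dl <- dl_meta_correlation(toy, min_cohorts = 1)
  expect_equal(dl$n_cohorts_used, 1L)
  expect_equal(dl$combined_effect, 0.55, tolerance = 1e-12)
  # default minimum of 2 cohorts drops the gene entirely
  expect_equal(nrow(dl_meta_correlation(toy)), 0)
})

test_that("DL pooled z stays within the per-cohort Fisher-z range", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      toy <- tibble::tibble(gene = "g", cohort = paste0("c", 1:k),
                            n = sample(10:200, k),
                            rho = runif(k, -0.9, 0.9))
      dl <- dl_meta_correlation(toy)
      zs <- atanh(toy$rho)
      expect_gte(atanh(dl$combined_effect), min(zs) - 1e-12)
      expect_lte(atanh(dl$combined_effect), max(zs) + 1e-12)
    }
  })
})

test_that("Stouffer combination obeys its algebraic identities", {
  # k equal-size, equal-p studies: Z = sqrt(k) * z_single
  for (k in 2:5) {
    toy <- tibble::tibble(gene = "g", cohort = paste0("c", 1:k),
                          n = 50, anova_p = 0.01,
                          anova_p_adj = 0.01)
    st <- stouffer_meta(toy)
    expect_equal(st$combined_z, sqrt(k) * qnorm(0.99),
                 tolerance = 1e-10)
  }
  # a p = 0.5 study contributes a zero z
  base <- tibble::tibble(gene = "g", cohort = c("a", "b"),
                         n = c(50, 50), anova_p_adj = c(0.01, 0.5))
  st2 <- stouffer_meta(base)
  expect_equal(st2$combined_z,
               50 * qnorm(0.99) / sqrt(50^2 + 50^2), tolerance = 1e-12)
  # hand-computed 3-study weighted Z
  p <- c(1e-4, 0.01, 0.2); n <- c(30, 60, 80)
  toy3 <- tibble::tibble(gene = "g", cohort = c("a", "b", "c"),
                         n = n, anova_p_adj = p)
  z_hand <- sum(n * qnorm(1 - p)) / sqrt(sum(n^2))
  st3 <- stouffer_meta(toy3)
  expect_equal(st3$combined_z, z_hand, tolerance = 1e-10)
  expect_equal(st3$combined_p, 1 - pnorm(z_hand), tolerance = 1e-10)
})

test_that("Stouffer Z is invariant to uniform cohort-size scaling", {
  p <- c(1e-3, 0.05, 0.4); n <- c(25, 50, 100)
  t1 <- tibble::tibble(gene = "g", cohort = c("a", "b", "c"),
                       n = n, anova_p_adj = p)
  t2 <- dplyr::mutate(t1, n = n * 10)
  expect_equal(stouffer_meta(t1)$combined_z,
               stouffer_meta(t2)$combined_z, tolerance = 1e-12)
})

test_that("zero p-values are clipped with a message and raw-p mode works", {
  toy <- tibble::tibble(gene = "g", cohort = c("a", "b"), n = 50,
                        anova_p = c(0, 0.01), anova_p_adj = c(0, 0.02))
  expect_message(st <- stouffer_meta(toy), "clipped")
  expect_true(is.finite(st$combined_z))
  raw <- suppressMessages(stouffer_meta(toy, use_adjusted = FALSE))
  adj <- suppressMessages(stouffer_meta(toy, use_adjusted = TRUE))
  expect_gt(raw$combined_z, adj$combined_z)
})

test_that("candidate selection is strict and partitions genes", {
  meta_rho <- tibble::tibble(gene = c("a", "b", "c", "d"),
                             combined_effect = c(0.6, 0.61, 0.9, 0.2),
                             tau2 = 0)
  meta_p <- tibble::tibble(gene = c("a", "b", "c", "d"),
                           combined_z = 4,
                           combined_p = c(1e-5, 2e-6, 1e-7, 0.5))
  sel <- select_candidates(meta_rho, meta_p)
  expect_equal(sel$selected_by[sel$gene == "a"], "none")   # both at the line
  expect_equal(sel$selected_by[sel$gene == "b"], "both")
  expect_equal(sel$selected_by[sel$gene == "c"], "both")
  expect_equal(sel$selected_by[sel$gene == "d"], "none")
  # brute-force filter oracle on a random meta table
  withr::with_seed(3, {
    mr <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                         combined_effect = runif(200, -1, 1), tau2 = 0)
    mp <- tibble::tibble(gene = mr$gene, combined_z = 0,
                         combined_p = 10^runif(200, -8, 0))
    sel2 <- select_candidates(mr, mp)
    manual <- (mr$combined_effect > 0.6) | (mp$combined_p < 1e-5)
    expect_setequal(sel2$gene[sel2$selected_by != "none"],
                    mr$gene[manual])
    expect_length(intersect(sel2$gene[sel2$selected_by == "spearman"],
                            sel2$gene[sel2$selected_by == "anova"]), 0)
  })
})

test_that("multi-cohort integration recovers planted dosage genes", {
  cfg <- sim_config(n_cohorts = 3, cohort_sizes = c(30, 60, 80),
                    dialects = c("absolute", "discrete", "logratio"),
                    n_genes = 300, n_cn_driven = 15, n_prognostic = 0,
                    seed = 77)
  st <- simulate_study(cfg)
  it <- integrate_cohorts(st$cohorts, st$truth$annotation)
  planted <- st$truth$cn_driven_genes
  expect_gte(mean(planted %in% it$candidates), 0.9)
  expect_gte(mean(it$candidates %in% planted), 0.9)
  # discrete cohort contributes no Spearman rho but does contribute ANOVA
  s2 <- dplyr::filter(it$stats, cohort == "cohort2")
  expect_true(all(is.na(s2$rho)))
  expect_gt(sum(!is.na(s2$anova_p)), 0)
})
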