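# Genes x samples cellular dosage implied by generator segments (which
# carry continuous `copies_true`), picking the overlapping segment of
# maximal |copies - 2| severity.
gene_copies_from_segments <- function(segments, annotation) {
  hits <- annotation |>
    select("gene", "chrom", gstart = "start", gend = "end") |>
    inner_join(segments, by = "chrom", relationship = "many-to-many") |>
    filter(.data$start < .data$gend, .data$end > .data$gstart) |>
    mutate(sev = abs(.data$copies - 2L)) |>
    group_by(.data$gene, .data$sample) |>
    arrange(dplyr::desc(.data$sev), .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  samples <- unique(segments$sample)
  m <- matrix(2, nrow = nrow(annotation), ncol = length(samples),
              dimnames = list(annotation$gene, samples))
  m[cbind(hits$gene, hits$sample)] <- hits$copies_true
  m
}

#' Simulate probe-level expression for one cohort
#'
#' Expression is Gaussian noise around a per-gene baseline; the planted
#' dosage-driven genes add `cn_expr_slope x (copies - 2)` and the planted
#' prognostic genes add `risk_effect x direction x latent risk` (latent
#' risk drawn N(0,1) per sample). With `probes_per_gene = 2` each probe
#' carries the same signal with independent noise. The realized latent
#' risk recorded in the output is the standardized, sign-corrected mean
#' expression of the prognostic genes — exactly the quantity a signed
#' metagene estimates — and is what drives simulated survival.
#'
#' @param segments Generator segment tibble from [simulate_segments()]
#'   (must carry the generator `copies` and `copies_true` columns).
#' @param truth A [plant_truth()] object.
#' @param config A [sim_config()].
#' @param cohort Cohort index.
#' @return List: `expr` (probes x samples matrix), `probe_map` (tibble
#'   `probe`, `gene`), `risk` (tibble `sample`, `risk`).
#' @export
simulate_expression <- function(segments, truth, config, cohort) {
  assert_that_(all(c("copies", "copies_true") %in% names(segments)),
               "segments must carry generator copy columns")
  ann <- truth$annotation
  samples <- unique(segments$sample)
  n <- length(samples)

  with_seed_(stage_seed(config$seed, cohort, 2L), {
    risk0 <- rnorm(n)
    copies <- gene_copies_from_segments(
      segments, ann |> filter(.data$gene %in% truth$cn_driven_genes))

    npb <- config$probes_per_gene
    probe_map <- tibble(
      gene = rep(ann$gene, each = npb),
      probe = paste0(rep(ann$gene, each = npb), "_p",
                     rep(seq_len(npb), times = nrow(ann)))
    ) |> select("probe", "gene")

    signal <- matrix(rep(truth$gene_baseline[ann$gene], each = n),
                     nrow = nrow(ann), ncol = n, byrow = TRUE,
                     dimnames = list(ann$gene, samples))
    signal[rownames(copies), ] <- signal[rownames(copies), ] +
      config$cn_expr_slope * (copies - 2)
    prog <- truth$prognostic
    signal[prog$gene, ] <- signal[prog$gene, ] +
      config$risk_effect * outer(prog$direction, risk0)

    expr <- signal[probe_map$gene, , drop = FALSE] +
      matrix(rnorm(nrow(probe_map) * n, sd = config$noise_sd),
             nrow = nrow(probe_map))
    rownames(expr) <- probe_map$probe

    # realized latent risk: standardized sign-corrected prognostic mean
    # (identically 0 when no prognostic program is planted)
    if (nrow(prog) > 0) {
      gexpr <- collapse_probes(expr, probe_map)
      realized <- as.numeric(crossprod(
        gexpr[prog$gene, , drop = FALSE], prog$direction)) / nrow(prog)
      realized <- as.numeric(scale(realized))
    } else {
      realized <- rep(0, n)
    }

    list(expr = expr, probe_map = probe_map,
         risk = tibble(sample = samples, risk = realized))
  })
}

#' Collapse a probe-level matrix to gene level by averaging probes
#'
#' @param expr Probes x samples matrix.
#' @param probe_map Tibble with `probe`, `gene`.
#' @return Genes x samples matrix.
#' @export
collapse_probes <- function(expr, probe_map) {
  map <- probe_map |> filter(.data$probe %in% rownames(expr))
  g <- factor(map$gene, levels = unique(map$gene))
  out <- rowsum(expr[map$probe, , drop = FALSE], g) /
    as.vector(table(g)[levels(g)])
  rownames(out) <- levels(g)
  out
}
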