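#' Recurrent copy-number alteration layout for the toy genome
#'
#' The default layout plants the kinds of events recurrent in invasive
#' lobular breast carcinoma: whole-arm gains and losses plus rare focal
#' amplifications and a focal homozygous deletion. Coordinates live on a
#' toy genome of 3 chromosomes x 100 Mb with the centromere at 50 Mb.
#'
#' @param chrom_length Chromosome length in bp (all chromosomes equal).
#' @return A tibble with columns `chrom`, `arm`, `type` (one of `gain`,
#'   `loss`, `amp`, `homd`), `fraction` (carrier fraction of samples),
#'   and `focal_start`/`focal_end` (NA for whole-arm events).
#' @export
default_arm_events <- function(chrom_length = 1e8) {
  cen <- chrom_length / 2
  tibble(
    chrom       = c("1",   "2",    "2",    "2",    "3",    "3",   "1"),
    arm         = c("q",   "p",    "p",    "q",    "p",    "q",   "p"),
    type        = c("gain", "loss", "amp",  "amp",  "gain", "loss", "homd"),
    fraction    = c(0.40,  0.30,   0.10,   0.12,   0.35,   0.45,  0.05),
    focal_start = c(NA,    NA,     0.20,   0.60,   NA,     NA,    0.30) * chrom_length,
    focal_end   = c(NA,    NA,     0.25,   0.64,   NA,     NA,    0.33) * chrom_length
  )
}

#' Configuration for the synthetic multi-cohort study generator
#'
#' Bundles and validates every knob of the generator. The defaults mirror
#' a three-cohort integrative breast-cancer study: cohorts of 30, 125 and
#' 146 tumors whose copy-number substrates arrive in three dialects
#' (absolute integer copies, pre-called discrete states, CBS-style
#' log-ratios), 2,000 genes on a 3 x 100 Mb toy genome, 40 planted
#' dosage-driven genes, and a 30-gene prognostic program with a high/low
#' hazard ratio of 2.5 on breast-cancer-specific survival.
#'
#' @param n_cohorts Number of cohorts.
#' @param cohort_sizes Integer vector of per-cohort sample counts (each
#'   >= 10).
#' @param n_genes Number of genes on the toy genome.
#' @param n_cn_driven Number of planted genes whose expression is linearly
#'   driven by copy number.
#' @param cn_expr_slope Expression units (log2 scale) per copy above/below
#'   the diploid 2.
#' @param n_prognostic Number of planted prognostic-program genes.
#' @param hazard_ratio Hazard ratio per standard deviation of the latent
#'   risk (must be > 0).
#' @param censor_rate Target fraction of censored samples in `[0, 1)`.
#' @param baseline_hazard Baseline exponential hazard per month.
#' @param dialects Character vector (length `n_cohorts`) of copy-number
#'   encodings, each one of `"absolute"`, `"discrete"`, `"logratio"`.
#' @param seed Study seed; every simulation routine derives its RNG stream
#'   from it (R's default Mersenne-Twister), so a fixed seed reproduces
#'   outputs bit-identically.
#' @param noise_sd Residual Gaussian SD of probe-level expression.
#' @param dosage_wobble_sd SD of the per-sample tumor purity factor
#'   scaling every aberration's deviation from diploid (neutral
#'   segments stay diploid); shared by measured log-ratios and
#'   dosage-driven expression.
#' @param segment_noise_sd SD of segment-level log-ratio measurement
#'   noise (log-ratio dialect only).
#' @param risk_effect Expression shift per SD of latent risk for
#'   prognostic genes.
#' @param probes_per_gene 1 or 2 probes per gene; 2 exercises the
#'   multi-probe consistency filter.
#' @param arm_events Alteration layout, see [default_arm_events()].
#' @param n_chrom,chrom_length Toy genome shape.
#' @param allow_overlap Allow the planted dosage-driven and prognostic
#'   gene sets to overlap (default: disjoint).
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(cohort_sizes = c(20, 20), n_cohorts = 2,
#'                   dialects = c("absolute", "logratio"), n_genes = 200,
#'                   n_cn_driven = 10, n_prognostic = 5, seed = 1)
sim_config <- function(n_cohorts = 3,
                       cohort_sizes = c(30, 125, 146),
                       n_genes = 2000,
                       n_cn_driven = 40,
                       cn_expr_slope = 1,
                       n_prognostic = 30,
                       hazard_ratio = 2.5,
                       censor_rate = 0.6,
                       baseline_hazard = 0.01,
                       dialects = c("absolute", "discrete", "logratio"),
                       seed = 1,
                       noise_sd = 0.2,
                       dosage_wobble_sd = 0.3,
                       segment_noise_sd = 0.05,
                       risk_effect = 1,
                       probes_per_gene = 1,
                       arm_events = default_arm_events(chrom_length),
                       n_chrom = 3,
                       chrom_length = 1e8,
                       allow_overlap = FALSE) {
  assert_that_(length(cohort_sizes) == n_cohorts,
               "`cohort_sizes` must have one entry per cohort")
  assert_that_(all(cohort_sizes >= 10), "all cohort sizes must be >= 10")
  assert_that_(length(dialects) == n_cohorts,
               "`dialects` must have one entry per cohort")
  bad <- setdiff(dialects, c("absolute", "discrete", "logratio"))
  if (length(bad) > 0) {
    abort(paste0("unknown copy-number dialect: ", paste(bad, collapse = ", ")))
  }
  assert_that_(n_cn_driven + n_prognostic <= n_genes || allow_overlap,
               "n_cn_driven + n_prognostic must not exceed n_genes")
  assert_that_(hazard_ratio > 0, "`hazard_ratio` must be > 0")
  assert_that_(censor_rate >= 0 && censor_rate < 1,
               "`censor_rate` must be in [0, 1)")
  assert_that_(baseline_hazard > 0, "`baseline_hazard` must be > 0")
  assert_that_(probes_per_gene %in% c(1L, 2L), "`probes_per_gene` must be 1 or 2")

  structure(
    list(
      n_cohorts = as.integer(n_cohorts),
      cohort_sizes = as.integer(cohort_sizes),
      n_genes = as.integer(n_genes),
      n_cn_driven = as.integer(n_cn_driven),
      cn_expr_slope = cn_expr_slope,
      n_prognostic = as.integer(n_prognostic),
      hazard_ratio = hazard_ratio,
      censor_rate = censor_rate,
      baseline_hazard = baseline_hazard,
      dialects = dialects,
      seed = as.integer(seed),
      noise_sd = noise_sd,
      dosage_wobble_sd = dosage_wobble_sd,
      segment_noise_sd = segment_noise_sd,
      risk_effect = risk_effect,
      probes_per_gene = as.integer(probes_per_gene),
      arm_events = arm_events,
      n_chrom = as.integer(n_chrom),
      chrom_length = chrom_length,
      allow_overlap = allow_overlap
    ),
    class = "sim_config"
  )
}

#' Gene annotation for the toy genome
#'
#' Places `n_genes` 10-kb genes evenly across the toy chromosomes.
#'
#' @param config A [sim_config()].
#' @return BED-style tibble: `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
gene_annotation <- function(config) {
  per_chrom <- rep(config$n_genes %/% config$n_chrom, config$n_chrom)
  rem <- config$n_genes %% config$n_chrom
  if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L
  width <- 1e4
  purrr::map2_dfr(as.character(seq_len(config$n_chrom)), per_chrom, function(ch, k) {
    starts <- floor(seq(1e6, config$chrom_length - 1e6 - width, length.out = k))
    tibble(chrom = ch, start = starts, end = starts + width,
           strand = rep_len(c("+", "-"), k))
  }) |>
    mutate(gene = sprintf("g%04d", dplyr::row_number())) |>
    select("gene", "chrom", "start", "end", "strand")
}

# Event regions as (chrom, start, end) intervals on the toy genome.
event_regions <- function(config) {
  cen <- config$chrom_length / 2
  config$arm_events |>
    mutate(
      start = dplyr::if_else(is.na(.data$focal_start),
                             dplyr::if_else(.data$arm == "p", 0, cen),
                             .data$focal_start),
      end = dplyr::if_else(is.na(.data$focal_end),
                           dplyr::if_else(.data$arm == "p", cen, config$chrom_length),
                           .data$focal_end),
      event = dplyr::row_number()
    ) |>
    select("event", "chrom", "arm", "type", "fraction", "start", "end")
}

#' Plant the ground truth of a synthetic study
#'
#' Chooses the dosage-driven genes (inside recurrently altered regions, so
#' their copy number actually varies), the prognostic program genes with
#' per-gene direction (+1 = high expression is adverse), and per-gene
#' baseline expression. Shared by all cohorts of one study.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `annotation`, `cn_driven_genes`,
#'   `prognostic` (tibble `gene`, `direction`), `gene_baseline` (named
#'   vector), `regions` (event regions used).
#' @export
plant_truth <- function(config) {
  ann <- gene_annotation(config)
  regions <- event_regions(config)
  with_seed_(stage_seed(config$seed, 0L, 0L), {
    in_region <- ann |>
      inner_join(regions, by = "chrom", suffix = c("", ".r"),
                 relationship = "many-to-many") |>
      filter(.data$start >= .data$start.r, .data$end <= .data$end.r) |>
      distinct(.data$gene) |>
      pull("gene")
    assert_that_(length(in_region) >= config$n_cn_driven,
                 "toy genome has too few genes in altered regions for n_cn_driven")
    cn_driven <- sort(sample(in_region, config$n_cn_driven))
    pool <- if (config$allow_overlap) ann$gene else setdiff(ann$gene, in_region)
    assert_that_(length(pool) >= config$n_prognostic,
                 "too few genes outside altered regions for n_prognostic")
    prognostic <- sort(sample(pool, config$n_prognostic))
    direction <- sample(c(1L, -1L), config$n_prognostic, replace = TRUE)
    baseline <- stats::setNames(rnorm(nrow(ann), mean = 8, sd = 1), ann$gene)
    structure(
      list(
        annotation = ann,
        cn_driven_genes = cn_driven,
        prognostic = tibble(gene = prognostic, direction = direction),
        gene_baseline = baseline,
        regions = regions
      ),
      class = "sim_truth"
    )
  })
}
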