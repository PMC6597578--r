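#' Lift segment-level copy number to gene level by maximal severity
#'
#' A gene takes the state (and that segment's log-ratio) of the
#' overlapping segment whose state has maximal absolute severity
#' (NEUT 0, GAIN/HETD +/-1, AMP/HOMD +/-2). A gene fully inside one
#' segment therefore simply inherits it; a gene split by several
#' segments gets the most severe one. Severity ties are broken by the
#' larger overlap length, then in favor of the positive (AMP) state.
#' Genes covered by no segment of a sample are missing; a gene whose
#' chromosome is absent from the segment data is missing everywhere
#' (reported once per chromosome).
#'
#' @param segments Segment tibble carrying `state` and `logratio`
#'   columns (see [call_states()]).
#' @param genes Gene annotation tibble: `gene`, `chrom`, `start`, `end`
#'   (0-based half-open; strand is ignored, copy number is
#'   strand-agnostic).
#' @return A `gene_cn` object: list with `states` and `logratio`
#'   (genes x samples matrices) and the `genes` annotation.
#' @export
assign_gene_cn <- function(segments, genes) {
  assert_that_(all(c("state", "logratio") %in% names(segments)),
               "segments must carry `state` and `logratio`; run call_states() first")
  absent <- setdiff(unique(genes$chrom), unique(segments$chrom))
  if (length(absent) > 0) {
    inform(paste0("no segments on chromosome(s) ",
                  paste(absent, collapse = ", "),
                  "; their genes are missing"))
  }
  samples <- unique(segments$sample)
  hits <- genes |>
    select("gene", "chrom", gstart = "start", gend = "end") |>
    inner_join(segments, by = "chrom", relationship = "many-to-many") |>
    filter(.data$start < .data$gend, .data$end > .data$gstart) |>
    mutate(
      sev = cn_severity(.data$state),
      ovl = pmin(.data$end, .data$gend) - pmax(.data$start, .data$gstart)
    ) |>
    arrange(dplyr::desc(abs(.data$sev)), dplyr::desc(.data$ovl),
            dplyr::desc(.data$sev)) |>
    distinct(.data$gene, .data$sample, .keep_all = TRUE)

  states <- matrix(NA_character_, nrow(genes), length(samples),
                   dimnames = list(genes$gene, samples))
  lr <- matrix(NA_real_, nrow(genes), length(samples),
               dimnames = list(genes$gene, samples))
  idx <- cbind(hits$gene, hits$sample)
  states[idx] <- hits$state
  lr[idx] <- hits$logratio
  structure(list(states = states, logratio = lr, genes = genes),
            class = "gene_cn")
}

#' @export
print.gene_cn <- function(x, ...) {
  cat(sprintf("<gene_cn> %d genes x %d samples; %.1f%% called\n",
              nrow(x$states), ncol(x$states),
              100 * mean(!is.na(x$states))))
  invisible(x)
}

#' Genome-wide alteration frequencies
#'
#' Per-gene fraction of (non-missing) samples in each non-neutral state;
#' together with the neutral fraction these sum to 1.
#'
#' @param gene_cn A [assign_gene_cn()] result.
#' @return Tibble: `gene`, `chrom`, `start`, `n` (informative samples),
#'   `amp`, `gain`, `loss`, `homd` fractions.
#' @export
alteration_frequency <- function(gene_cn) {
  st <- gene_cn$states
  assert_that_(length(st) > 0, "empty copy-number matrix")
  n <- unname(rowSums(!is.na(st)))
  frac <- function(lbl) {
    unname(rowSums(st == lbl, na.rm = TRUE)) / pmax(n, 1L)
  }
  gene_cn$genes |>
    select("gene", "chrom", "start") |>
    mutate(n = as.integer(n),
           amp = frac("AMP"), gain = frac("GAIN"),
           loss = frac("HETD"), homd = frac("HOMD"))
}

#' Co-amplification between two genomic regions
#'
#' A sample carries an amplification of a region if any gene of the
#' region is AMP. Returns carrier counts for each region, their
#' intersection, conditional fractions, and the per-gene-pair
#' co-amplification table for heatmap display.
#'
#' @param gene_cn A [assign_gene_cn()] result.
#' @param region_a,region_b Character vectors of gene ids.
#' @param names Length-2 labels for the regions.
#' @return List: `counts` (tibble with `n_a`, `n_b`, `n_ab`,
#'   `frac_ab_given_a`, `frac_ab_given_b`) and `pairwise` (tibble
#'   `gene_a`, `gene_b`, `n_co`, `frac_co`).
#' @export
coamplification <- function(gene_cn, region_a, region_b,
                            names = c("A", "B")) {
  st <- gene_cn$states
  ga <- intersect(region_a, rownames(st))
  gb <- intersect(region_b, rownames(st))
  if (length(ga) == 0) abort(paste0("region ", names[1], " has no genes in the matrix"))
  if (length(gb) == 0) abort(paste0("region ", names[2], " has no genes in the matrix"))
  amp <- !is.na(st) & st == "AMP"
  carrier_a <- colSums(amp[ga, , drop = FALSE]) > 0
  carrier_b <- colSums(amp[gb, , drop = FALSE]) > 0
  n_a <- sum(carrier_a); n_b <- sum(carrier_b)
  n_ab <- sum(carrier_a & carrier_b)
  pairwise <- tidyr::expand_grid(gene_a = ga, gene_b = gb) |>
    mutate(
      n_co = purrr::map2_int(.data$gene_a, .data$gene_b,
                             function(a, b) sum(amp[a, ] & amp[b, ])),
      frac_co = .data$n_co / ncol(st)
    )
  list(
    counts = tibble(
      region_a = names[1], region_b = names[2],
      n_a = n_a, n_b = n_b, n_ab = n_ab,
      frac_ab_given_a = if (n_a > 0) n_ab / n_a else NA_real_,
      frac_ab_given_b = if (n_b > 0) n_ab / n_b else NA_real_
    ),
    pairwise = pairwise
  )
}
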