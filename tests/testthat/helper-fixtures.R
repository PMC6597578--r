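# Small configurations used across tests.

tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_cohorts = 2, cohort_sizes = c(25, 30),
    dialects = c("absolute", "logratio"),
    n_genes = 120, n_cn_driven = 8, n_prognostic = 6, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# A single-event layout: one whole-arm gain on 1q carried by 40% of
# samples; convenient when a test needs one homogeneous planted class.
gain_only_events <- function(chrom_length = 1e8) {
  tibble::tibble(chrom = "1", arm = "q", type = "gain", fraction = 0.4,
                 focal_start = NA_real_, focal_end = NA_real_)
}

# Hand-checkable 6-subject survival fixture with one censored subject.
six_subjects <- function() {
  tibble::tibble(
    sample = paste0("s", 1:6),
    time_months = c(1, 2, 3, 4, 5, 6),
    event = c(1L, 0L, 1L, 1L, 1L, 1L)
  )
}

# Exponential survival for two labelled arms with a given hazard ratio.
two_arm_surv <- function(n_per_arm, hr, base = 0.02, censor = NULL) {
  lam <- rep(c(base, base * hr), each = n_per_arm)
  t_ev <- stats::rexp(2 * n_per_arm, rate = lam)
  d <- tibble::tibble(
    sample = sprintf("s%04d", seq_len(2 * n_per_arm)),
    arm = rep(c("low", "high"), each = n_per_arm),
    time_months = t_ev, event = 1L
  )
  if (!is.null(censor)) {
    t_c <- stats::runif(2 * n_per_arm, 0, censor)
    d$event <- as.integer(d$time_months <= t_c)
    d$time_months <- pmin(d$time_months, t_c)
  }
  d
}

# A random segment table (states already called) plus gene annotation,
# for oracle comparisons of the gene-level assignment.
random_segmentation <- function(n_genes = 50, n_samples = 4,
                                chrom_length = 1e6) {
  genes <- tibble::tibble(
    gene = sprintf("g%03d", seq_len(n_genes)),
    chrom = "1",
    start = sort(sample.int(chrom_length - 2000, n_genes)),
    end = 0, strand = "+"
  )
  genes$end <- genes$start + sample(200:2000, n_genes, replace = TRUE)
  segs <- purrr::map_dfr(seq_len(n_samples), function(s) {
    k <- sample(3:8, 1)
    cuts <- sort(c(0, sample.int(chrom_length, k - 1), chrom_length))
    tibble::tibble(
      sample = sprintf("s%02d", s), chrom = "1",
      start = cuts[-length(cuts)], end = cuts[-1],
      n_markers = 10L,
      state = sample(c("HOMD", "HETD", "NEUT", "GAIN", "AMP"), k,
                     replace = TRUE),
      logratio = round(stats::rnorm(k), 3)
    )
  })
  # drop a random ~10% of segments so some genes are uncovered
  segs <- segs[stats::runif(nrow(segs)) > 0.1, ]
  list(genes = genes, segments = segs)
}
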