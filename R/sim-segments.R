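# Integer copies implied by an event type; amplification draws 6-8 copies.
event_copies <- function(type, n) {
  switch(type,
    gain = sample(3:5, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    loss = rep(1L, n),
    homd = rep(0L, n),
    amp  = sample(6:8, n, replace = TRUE),
    abort(paste0("unknown event type: ", type))
  )
}

# Partition one chromosome of one sample into constant-copy segments.
# `ev` has columns start, end, copies, focal (logical); focal events
# override whole-arm events where they overlap.
partition_chrom <- function(ev, chrom_length) {
  if (nrow(ev) == 0) {
    return(tibble(start = 0, end = chrom_length, copies = 2L))
  }
  cuts <- sort(unique(c(0, chrom_length, ev$start, ev$end)))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  mids <- (starts + ends) / 2
  copies <- rep(2L, length(mids))
  for (pass in c(FALSE, TRUE)) {        # arm-level first, focal override
    sub <- ev[ev$focal == pass, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      hit <- mids >= sub$start[i] & mids < sub$end[i]
      copies[hit] <- sub$copies[i]
    }
  }
  # merge adjacent runs of equal copy number
  run <- cumsum(c(TRUE, copies[-1] != copies[-length(copies)]))
  tibble(start = starts, end = ends, copies = copies, run = run) |>
    group_by(.data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              copies = .data$copies[1], .groups = "drop") |>
    select("start", "end", "copies")
}

copies_to_state <- function(copies) {
  dplyr::case_when(
    copies == 0 ~ "HOMD",
    copies == 1 ~ "HETD",
    copies == 2 ~ "NEUT",
    copies <= 5 ~ "GAIN",
    TRUE ~ "AMP"
  )
}

#' Simulate per-sample copy-number segments for one cohort
#'
#' Tiles the toy genome with non-overlapping constant-copy segments.
#' Each recurrent event in `config$arm_events` is carried by a Bernoulli
#' fraction of samples; carried whole-arm events set the arm's copy
#' number and focal events override the arm within their window. The
#' `value` column encodes copy number in the cohort's dialect: absolute
#' integer copies, CBS-style log2 ratios (with segment-level jitter,
#' SD 0.05), or discrete state labels. The true integer copies are kept
#' in the `copies` column (dropped by [write_seg()]).
#'
#' Coordinates are 0-based half-open internally; [write_seg()] and
#' [read_seg()] convert to/from the 1-based inclusive SEG convention.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort index in `1:n_cohorts`.
#' @return Segment tibble: `sample`, `chrom`, `start`, `end`,
#'   `n_markers`, `value`, `copies`.
#' @export
simulate_segments <- function(config, cohort) {
  assert_that_(cohort >= 1 && cohort <= config$n_cohorts,
               "`cohort` out of range")
  dialect <- config$dialects[cohort]
  n <- config$cohort_sizes[cohort]
  samples <- sprintf("c%d_s%03d", cohort, seq_len(n))
  regions <- event_regions(config) |>
    mutate(focal = !is.na(config$arm_events$focal_start))

  with_seed_(stage_seed(config$seed, cohort, 1L), {
    carried <- purrr::map_dfr(seq_len(nrow(regions)), function(e) {
      carriers <- which(runif(n) < regions$fraction[e])
      if (length(carriers) == 0) return(NULL)
      tibble(
        sample = samples[carriers],
        chrom = regions$chrom[e],
        start = regions$start[e],
        end = regions$end[e],
        focal = regions$focal[e],
        copies = event_copies(regions$type[e], length(carriers))
      )
    })

    segs <- purrr::map_dfr(samples, function(s) {
      purrr::map_dfr(as.character(seq_len(config$n_chrom)), function(ch) {
        ev <- if (nrow(carried) > 0) {
          carried |> filter(.data$sample == s, .data$chrom == ch)
        } else {
          carried
        }
        partition_chrom(ev, config$chrom_length) |>
          mutate(sample = s, chrom = ch)
      })
    })

    segs <- segs |>
      mutate(n_markers = pmax(1L, as.integer((.data$end - .data$start) %/% 5e4)))

    # continuous cellular dosage: the deviation from diploid scales with
    # a per-sample purity/subclonality factor, so neutral segments stay
    # exactly diploid while aberrations attenuate or amplify per sample;
    # shared by the measured log-ratio and by dosage-driven expression
    purity <- stats::setNames(
      pmax(rnorm(n, mean = 1, sd = config$dosage_wobble_sd), 0.1), samples)
    segs$copies_true <- pmax(
      2 + (segs$copies - 2) * purity[segs$sample], 0.05)

    segs$value <- switch(dialect,
      absolute = as.numeric(segs$copies),
      logratio = log2(segs$copies_true / 2) +
        (if (config$segment_noise_sd > 0)
           rnorm(nrow(segs), sd = config$segment_noise_sd) else 0),
      discrete = copies_to_state(segs$copies)
    )
    segs |>
      select("sample", "chrom", "start", "end", "n_markers", "value",
             "copies", "copies_true")
  })
}
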