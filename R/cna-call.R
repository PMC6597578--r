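#' Thresholds for discrete copy-number state calling
#'
#' Absolute-copy calling is fixed (0 HOMD, 1 HETD, 2 NEUT, 3-5 GAIN,
#' >= 6 AMP). Log-ratio calling uses +/-0.3 for gain/loss; the
#' amplification and homozygous-deletion log-ratio cutoffs are
#' cohort-business normally delegated to sample-specific segmentation
#' output, so they are configurable and default to +/-1.0.
#'
#' @param gain_logratio,loss_logratio Gain/loss log2-ratio cutoffs.
#' @param amp_logratio,homd_logratio Amplification / homozygous-deletion
#'   log2-ratio cutoffs.
#' @return A `cn_thresholds` list.
#' @export
cn_thresholds <- function(gain_logratio = 0.3, loss_logratio = -0.3,
                          amp_logratio = 1.0, homd_logratio = -1.0) {
  assert_that_(amp_logratio > gain_logratio && gain_logratio > 0,
               "require amp_logratio > gain_logratio > 0")
  assert_that_(homd_logratio < loss_logratio && loss_logratio < 0,
               "require homd_logratio < loss_logratio < 0")
  structure(list(gain_logratio = gain_logratio,
                 loss_logratio = loss_logratio,
                 amp_logratio = amp_logratio,
                 homd_logratio = homd_logratio),
            class = "cn_thresholds")
}

# Accepted aliases for pre-called discrete states.
normalize_state_label <- function(x) {
  up <- toupper(trimws(x))
  map <- c(
    HOMD = "HOMD", HD = "HOMD", HOMDEL = "HOMD", "-2" = "HOMD",
    HETD = "HETD", LOSS = "HETD", DEL = "HETD", DELETION = "HETD", "-1" = "HETD",
    NEUT = "NEUT", NEUTRAL = "NEUT", DIPLOID = "NEUT", "0" = "NEUT",
    GAIN = "GAIN", "1" = "GAIN",
    AMP = "AMP", AMPLIFICATION = "AMP", "2" = "AMP"
  )
  unname(map[up])
}

#' Call discrete copy-number states on segments
#'
#' Labels every segment with one of HOMD, HETD, NEUT, GAIN, AMP
#' according to the cohort's encoding dialect, and attaches a `logratio`
#' column so downstream gene-level integration always has a continuous
#' dosage value where one is derivable: the segment value itself for the
#' log-ratio dialect, `log2(copies/2)` for absolute copies (0 copies
#' mapped to log2(0.1/2)), and NA for pre-called discrete states.
#'
#' @param segments Segment tibble with a `value` column.
#' @param dialect One of `"absolute"`, `"logratio"`, `"discrete"`.
#' @param thresholds A [cn_thresholds()] object.
#' @return The segment tibble with `state` and `logratio` columns.
#' @export
#' @examples
#' segs <- tibble::tibble(sample = "s1", chrom = "1", start = 0,
#'                        end = 1e6, n_markers = 10, value = 4)
#' call_states(segs, "absolute")$state  # "GAIN"
call_states <- function(segments, dialect, thresholds = cn_thresholds()) {
  if (!dialect %in% c("absolute", "logratio", "discrete")) {
    abort(paste0("unknown copy-number dialect: ", dialect))
  }
  th <- thresholds
  if (dialect == "absolute") {
    copies <- round(as.numeric(segments$value))
    if (anyNA(copies) || any(copies < 0)) {
      abort("absolute dialect requires non-negative numeric copy values")
    }
    segments$state <- copies_to_state(copies)
    segments$logratio <- log2(pmax(copies, 0.1) / 2)
  } else if (dialect == "logratio") {
    lr <- as.numeric(segments$value)
    segments$state <- dplyr::case_when(
      lr > th$amp_logratio ~ "AMP",
      lr > th$gain_logratio ~ "GAIN",
      lr < th$homd_logratio ~ "HOMD",
      lr < th$loss_logratio ~ "HETD",
      TRUE ~ "NEUT"
    )
    segments$logratio <- lr
  } else {
    st <- normalize_state_label(as.character(segments$value))
    if (anyNA(st)) {
      i <- which(is.na(st))[1]
      abort(sprintf(
        "unmappable copy-number state label '%s' (sample %s, %s:%s-%s)",
        segments$value[i], segments$sample[i], segments$chrom[i],
        format(segments$start[i], scientific = FALSE),
        format(segments$end[i], scientific = FALSE)))
    }
    segments$state <- st
    segments$logratio <- NA_real_
  }
  segments
}
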