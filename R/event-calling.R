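# Five-bin copy-number classification, per-tumor CNA event counts and
# cohort marker-level frequency tracks.

CNA_CLASSES <- c("homodeleted", "deleted", "unchanged", "gained", "amplified")

#' Copy-number bin thresholds
#'
#' The five-bin classification of segment copy number: amplified (> 3.8
#' copies), gained (2.3 to 3.8), unchanged (1.7 to 2.3), deleted (0.5 to
#' 1.7), homozygously deleted (< 0.5).
#'
#' @param homodel_max,loss_max,neutral_max,gain_max Bin boundaries in copies;
#'   must be strictly increasing and positive.
#' @return Named numeric vector of class `cna_bins`.
#' @export
cna_bins <- function(homodel_max = 0.5, loss_max = 1.7, neutral_max = 2.3,
                     gain_max = 3.8) {
  b <- c(
    homodel_max = homodel_max, loss_max = loss_max,
    neutral_max = neutral_max, gain_max = gain_max
  )
  if (any(b <= 0) || any(diff(b) <= 0)) {
    abort("bin thresholds must be positive and strictly increasing")
  }
  class(b) <- "cna_bins"
  b
}

#' Classify copy-number values into the five bins
#'
#' Boundary values go to the more conservative (no-call-ward) bin: exactly
#' 1.7 and 2.3 are unchanged, exactly 3.8 is gained, exactly 0.5 is deleted.
#'
#' @param cn Numeric copy numbers (>= 0).
#' @param bins Thresholds from [cna_bins()].
#' @return Ordered factor with levels homodeleted < deleted < unchanged <
#'   gained < amplified.
#' @export
classify_cn <- function(cn, bins = cna_bins()) {
  if (any(cn < 0, na.rm = TRUE)) abort("copy number must be >= 0")
  out <- rep(NA_character_, length(cn))
  out[cn > bins["gain_max"]] <- "amplified"
  out[cn > bins["neutral_max"] & cn <= bins["gain_max"]] <- "gained"
  out[cn >= bins["loss_max"] & cn <= bins["neutral_max"]] <- "unchanged"
  out[cn >= bins["homodel_max"] & cn < bins["loss_max"]] <- "deleted"
  out[cn < bins["homodel_max"]] <- "homodeleted"
  factor(out, levels = CNA_CLASSES, ordered = TRUE)
}

#' Attach CNA classes to a segment table
#'
#' @param segments Segment tibble with `mean_cn`.
#' @param bins Thresholds from [cna_bins()].
#' @return The segments with a `cna_class` column and a `direction` column
#'   (+1 gained/amplified, -1 deleted/homodeleted, 0 unchanged).
#' @export
classify_segments <- function(segments, bins = cna_bins()) {
  check_columns(segments, c("sample_id", "chrom", "start", "end", "mean_cn"))
  segments %>%
    mutate(
      cna_class = classify_cn(.data$mean_cn, bins),
      direction = case_when(
        .data$cna_class %in% c("gained", "amplified") ~ 1,
        .data$cna_class %in% c("deleted", "homodeleted") ~ -1,
        TRUE ~ 0
      )
    )
}

#' Count CNA events per tumor
#'
#' An event is a maximal run of adjacent same-direction non-neutral segments
#' on one chromosome: adjacent gained and amplified segments merge into one
#' gain event, and likewise for deletions. Sex chromosomes are excluded by
#' default.
#'
#' @param segments Classified segment tibble (see [classify_segments()]);
#'   unclassified input is classified with default bins.
#' @param include_sex Count events on X/Y as well.
#' @return Tibble `sample_id`, `n_events`.
#' @export
count_events <- function(segments, include_sex = FALSE) {
  if (!"direction" %in% names(segments)) segments <- classify_segments(segments)
  all_samples <- unique(segments$sample_id)
  counted <- segments %>%
    filter(include_sex | !is_sex_chrom(.data$chrom)) %>%
    arrange(.data$sample_id, chrom_factor(.data$chrom), .data$start) %>%
    group_by(.data$sample_id) %>%
    summarize(
      n_events = sum(.data$direction != 0 &
        (row_number() == 1 |
          .data$direction != lag(.data$direction, default = 0) |
          .data$chrom != lag(.data$chrom, default = ""))),
      .groups = "drop"
    )
  tibble(sample_id = all_samples) %>%
    left_join(counted, by = "sample_id") %>%
    mutate(n_events = as.integer(coalesce(.data$n_events, 0L)))
}

#' Build a marker grid
#'
#' @param genome Genome table.
#' @param width Marker spacing in bp (e.g. 1e5 for the fixed cross-cohort
#'   grid); defaults to the genome's probe spacing.
#' @return Tibble `chrom`, `pos`.
#' @export
marker_grid <- function(genome, width = NULL) {
  width <- width %||% attr(genome, "spacing") %||% 1e5
  g <- genome
  attr(g, "spacing") <- width
  probe_map(g) %>% select("chrom", "pos")
}

#' Cohort gain/loss frequency track
#'
#' At each marker, the gain fraction is the share of samples whose covering
#' segment is gained or amplified; the loss fraction likewise for deleted or
#' homozygously deleted. A sample with no covering segment at a marker is
#' treated as unchanged there.
#'
#' @param segments Classified segment tibble for the cohort.
#' @param markers Marker tibble with `chrom`, `pos` (typically the probe map
#'   or [marker_grid()]).
#' @return A `cna_freq_track` tibble: `chrom`, `pos`, `gain_freq`,
#'   `loss_freq`, `n_samples`.
#' @export
frequency_track <- function(segments, markers) {
  if (!"direction" %in% names(segments)) segments <- classify_segments(segments)
  check_columns(markers, c("chrom", "pos"), "markers")
  samples <- unique(segments$sample_id)
  n <- length(samples)
  if (n < 1) abort("frequency_track needs at least one sample")
  markers <- markers %>% arrange(chrom_factor(.data$chrom), .data$pos)
  gain <- loss <- numeric(nrow(markers))
  uncovered <- 0L
  for (ch in unique(markers$chrom)) {
    mrows <- which(markers$chrom == ch)
    pos <- markers$pos[mrows]
    seg_ch <- segments[segments$chrom == ch, ]
    seg_ch <- seg_ch[order(seg_ch$start), ]
    for (s in samples) {
      seg <- seg_ch[seg_ch$sample_id == s, ]
      if (nrow(seg) == 0) {
        uncovered <- uncovered + length(pos)
        next
      }
      idx <- findInterval(pos, seg$start)
      dir <- rep(0, length(pos))
      inside <- idx >= 1 & pos < seg$end[pmax(idx, 1)]
      dir[inside] <- seg$direction[idx[inside]]
      uncovered <- uncovered + sum(!inside)
      gain[mrows] <- gain[mrows] + (dir > 0)
      loss[mrows] <- loss[mrows] + (dir < 0)
    }
  }
  if (uncovered > 0) {
    inform(paste0(
      uncovered, " marker-sample pairs had no covering segment; treated as unchanged"
    ))
  }
  new_tidycna_tbl(
    markers %>% mutate(
      gain_freq = gain / n, loss_freq = loss / n, n_samples = n
    ),
    "cna_freq_track"
  )
}

#' Read a frequency track at a genomic position
#'
#' Convenience accessor: the track row whose marker is nearest `pos` on
#' `chrom`.
#'
#' @param track A [frequency_track()] result.
#' @param chrom Chromosome label.
#' @param pos Position (0-based internal coordinates).
#' @return One-row tibble.
#' @export
track_at <- function(track, chrom, pos) {
  rows <- track[track$chrom == normalize_chrom(chrom), ]
  if (nrow(rows) == 0) abort(paste0("no markers on chromosome ", chrom))
  rows[which.min(abs(rows$pos - pos)), ]
}
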