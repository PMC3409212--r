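# Minimal common regions (MCRs) of recurrent gain/loss and the STAC-style
# permutation significance test.

# Directed aberration indicator matrix (samples x markers) for one
# chromosome: 1 where the sample's covering segment matches `direction`.
marker_indicator <- function(segments, markers_chrom, chrom, direction) {
  samples <- unique(segments$sample_id)
  pos <- markers_chrom$pos
  out <- matrix(0L, length(samples), length(pos),
    dimnames = list(samples, NULL)
  )
  seg_ch <- segments[segments$chrom == chrom, ]
  seg_ch <- seg_ch[order(seg_ch$start), ]
  for (i in seq_along(samples)) {
    seg <- seg_ch[seg_ch$sample_id == samples[i], ]
    if (nrow(seg) == 0) next
    idx <- findInterval(pos, seg$start)
    inside <- idx >= 1 & pos < seg$end[pmax(idx, 1)]
    hit <- inside & sign(seg$direction[pmax(idx, 1)]) == sign(direction)
    out[i, hit] <- 1L
  }
  out
}

#' STAC-style permutation test for recurrent aberration
#'
#' Given a binary aberration matrix for one chromosome and direction (rows =
#' samples, columns = ordered markers), the observed statistic at a marker is
#' its carrier count. The null preserves each sample's aberration structure:
#' every permutation re-places each of the sample's aberration intervals
#' (lengths preserved, no wrapping) uniformly along the chromosome. The
#' reported p-value is max-corrected: the fraction of permutations whose
#' maximum marker count anywhere on the chromosome reaches the observed
#' count.
#'
#' @param aber Binary matrix, samples x markers.
#' @param n_perm Number of permutations (a warning is raised below 100).
#' @param seed Integer seed.
#' @return Tibble `marker` (column index), `count`, `freq`, `p`.
#' @export
stac_test <- function(aber, n_perm = 1000, seed = 1L) {
  if (!is.matrix(aber) || nrow(aber) == 0 || ncol(aber) == 0) {
    abort("aber must be a non-empty samples x markers matrix")
  }
  if (n_perm < 100) warn("fewer than 100 permutations: p-values are coarse")
  m <- ncol(aber)
  runs <- lapply(seq_len(nrow(aber)), function(i) {
    r <- rle(aber[i, ] != 0)
    as.integer(r$lengths[r$values])
  })
  null_max <- with_seed(
    derive_seed(seed, "stac"),
    .stac_null_max(m, runs, as.integer(n_perm))
  )
  counts <- colSums(aber != 0)
  p <- map_dbl(counts, ~ mean(null_max >= .x))
  tibble(
    marker = seq_len(m), count = as.integer(counts),
    freq = counts / nrow(aber), p = p
  )
}

#' Find minimal common regions of recurrent gain/loss
#'
#' For each direction, maximal marker runs with cohort frequency at or above
#' `min_freq` are located on the frequency track; within each run the MCR is
#' the contiguous plateau attaining the run's maximum frequency — the
#' minimal region shared by the largest set of overlapping events. Each MCR
#' gets a STAC permutation p-value (max-corrected over its chromosome) and
#' its carrier set at the plateau.
#'
#' @param track A [frequency_track()] for the cohort.
#' @param segments The classified segments the track was built from.
#' @param min_freq Frequency threshold in (0, 1] for candidate runs.
#' @param n_perm STAC permutations.
#' @param p_cutoff Significance cutoff for the `significant` flag.
#' @param seed Integer seed.
#' @return A `cna_mcr` tibble: `chrom`, `start`, `end`, `direction`,
#'   `peak_frequency`, `n_carriers`, `stac_p`, `significant`, `carriers`
#'   (list-column of sample ids).
#' @export
find_mcrs <- function(track, segments, min_freq = 0.10, n_perm = 1000,
                      p_cutoff = 0.01, seed = 1L) {
  if (!is.numeric(min_freq) || min_freq <= 0 || min_freq > 1) {
    abort("min_freq must be in (0, 1]")
  }
  if (!"direction" %in% names(segments)) segments <- classify_segments(segments)
  out <- list()
  for (dir in c("gain", "loss")) {
    sgn <- if (dir == "gain") 1 else -1
    fcol <- if (dir == "gain") "gain_freq" else "loss_freq"
    for (ch in unique(track$chrom)) {
      tr <- track[track$chrom == ch, ]
      freq <- tr[[fcol]]
      hi <- freq >= min_freq
      if (!any(hi)) next
      aber <- NULL
      stac_null <- NULL
      r <- rle(hi)
      stops <- cumsum(r$lengths)
      starts_run <- stops - r$lengths + 1
      spacing <- if (nrow(tr) > 1) median(diff(tr$pos)) else 1
      for (k in which(r$values)) {
        run <- starts_run[k]:stops[k]
        fmax <- max(freq[run])
        at_max <- freq[run] == fmax
        # first maximal contiguous block at the run maximum
        rr <- rle(at_max)
        rstop <- cumsum(rr$lengths)
        b <- which(rr$values)[1]
        plateau <- run[(rstop[b] - rr$lengths[b] + 1):rstop[b]]
        if (is.null(aber)) {
          aber <- marker_indicator(segments, tr, ch, sgn)
          stac_res <- stac_test(aber, n_perm = n_perm, seed = seed)
        }
        mid_marker <- plateau[ceiling(length(plateau) / 2)]
        carriers <- rownames(aber)[aber[, mid_marker] == 1]
        out[[length(out) + 1]] <- tibble(
          chrom = ch,
          start = tr$pos[plateau[1]],
          end = tr$pos[plateau[length(plateau)]] + spacing,
          direction = dir,
          peak_frequency = fmax,
          n_carriers = length(carriers),
          stac_p = stac_res$p[mid_marker],
          carriers = list(carriers)
        )
      }
    }
  }
  res <- if (length(out) == 0) {
    tibble(
      chrom = character(), start = numeric(), end = numeric(),
      direction = character(), peak_frequency = numeric(),
      n_carriers = integer(), stac_p = numeric(), carriers = list()
    )
  } else {
    list_rbind(out)
  }
  new_tidycna_tbl(
    res %>%
      mutate(significant = .data$stac_p < p_cutoff) %>%
      arrange(chrom_factor(.data$chrom), .data$start),
    "cna_mcr"
  )
}
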