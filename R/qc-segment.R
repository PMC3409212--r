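# Sample QC (MAPD), profile centering and circular binary segmentation.

#' Median absolute pairwise difference (MAPD) per sample
#'
#' MAPD is the median over consecutive-probe absolute differences
#' `|v[i+1] - v[i]|`; differences never span a chromosome boundary. Noisy
#' FFPE-derived samples are conventionally removed at MAPD > 0.6.
#'
#' @param profiles Wide probe tibble (`probe_id`, `chrom`, `pos`, samples).
#' @param threshold Pass/fail cutoff; `pass` is `mapd <= threshold`.
#' @return Tibble `sample_id`, `mapd`, `pass`.
#' @export
qc_mapd <- function(profiles, threshold = 0.6) {
  check_columns(profiles, c("probe_id", "chrom", "pos"), "profiles")
  samples <- sample_cols(profiles)
  keep <- profiles$chrom[-1] == profiles$chrom[-nrow(profiles)]
  if (!any(keep)) {
    abort("MAPD needs at least 2 probes on at least one chromosome")
  }
  mapd <- map_dbl(samples, function(s) {
    v <- profiles[[s]]
    median(abs(diff(v))[keep])
  })
  tibble(sample_id = samples, mapd = mapd, pass = mapd <= threshold)
}

#' Center copy-number profiles at diploid
#'
#' Shifts each sample so the mode of its per-probe copy-number density sits
#' at 2.0 copies (the diploid cluster dominates typical tumor profiles). If a
#' baseline cohort of normal profiles is supplied, each probe is first
#' divided by the normal-cohort median at that probe and rescaled to copies,
#' which removes probe-specific response before the mode anchoring.
#'
#' @param profiles Wide probe tibble.
#' @param baseline Optional wide probe tibble of normal samples on the same
#'   probe grid.
#' @return Centered profiles (same shape).
#' @export
center_profiles <- function(profiles, baseline = NULL) {
  samples <- sample_cols(profiles)
  out <- profiles
  if (!is.null(baseline)) {
    norm_cols <- sample_cols(baseline)
    if (length(norm_cols) == 0) abort("baseline cohort has no sample columns")
    if (nrow(baseline) != nrow(profiles)) {
      abort("baseline must share the probe grid of `profiles`")
    }
    med <- apply(as.matrix(baseline[norm_cols]), 1, median)
    if (any(med <= 0)) abort("baseline median is non-positive at some probes")
    for (s in samples) out[[s]] <- out[[s]] / med * 2
  }
  for (s in samples) {
    d <- density(out[[s]])
    mode <- d$x[which.max(d$y)]
    out[[s]] <- out[[s]] + (2 - mode)
  }
  out
}

#' Circular binary segmentation of probe profiles
#'
#' Recursive change-point detection per chromosome: the best circular arc is
#' the pair `(i, j)` maximizing a two-sample statistic comparing probes
#' inside the arc against the rest. An optional rank transform
#' (`use_ranks`) adds robustness to outliers, but the rank statistic is
#' bounded above by `1.73 / sqrt(1/k + 1/(n-k))` for a k-probe arc, so at
#' very stringent `alpha` it cannot accept short change-points regardless
#' of amplitude; the classical value-based statistic is therefore the
#' default. A split is accepted when it is significant at
#' `alpha`; because a pure permutation p cannot resolve very small `alpha`
#' with a bounded number of permutations, significance uses a hybrid rule:
#' accept when the conservative all-arcs normal-tail bound is already
#' `<= alpha`, otherwise fall back to a label-permutation p-value
#' (`n_perm` permutations, early stopping in both directions). Adjacent
#' segments with means closer than `merge_tol` copies are merged, and
#' segments shorter than `min_probes` are absorbed into the neighbor with
#' the closer mean. Segment means are always computed from the original
#' copy-number values.
#'
#' @param profiles Wide probe tibble (centered).
#' @param alpha Split significance threshold in (0, 1).
#' @param n_perm Permutations for the fallback permutation test.
#' @param min_probes Minimum probes per segment.
#' @param merge_tol Merge adjacent segments whose means differ by less than
#'   this many copies.
#' @param use_ranks Rank-transform probe values before the split statistic.
#' @param seed Integer seed for the permutation stream.
#' @return Segment tibble: `sample_id`, `chrom`, `start`, `end` (0-based
#'   half-open, tiling each chromosome's probed span), `n_probes`, `mean_cn`.
#' @export
cbs_segment <- function(profiles, alpha = 1e-6, n_perm = 10000,
                        min_probes = 3, merge_tol = 0.3, use_ranks = FALSE,
                        seed = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)")
  }
  check_columns(profiles, c("probe_id", "chrom", "pos"), "profiles")
  samples <- sample_cols(profiles)
  chroms <- unique(profiles$chrom)
  acc <- list()
  with_seed(derive_seed(seed, "cbs"), {
    for (ch in chroms) {
      rows <- profiles$chrom == ch
      pos <- profiles$pos[rows]
      np <- length(pos)
      spacing <- if (np > 1) median(diff(pos)) else 1
      bounds_end <- c(pos[-1], pos[np] + spacing)
      mat <- as.matrix(profiles[rows, samples, drop = FALSE])
      all_breaks <- if (np < 2 * min_probes) {
        rep(list(integer(0)), length(samples))
      } else {
        .cbs_breakpoints_matrix(mat, alpha, n_perm, min_probes, use_ranks)
      }
      for (si in seq_along(samples)) {
        seg <- build_segments(mat[, si], all_breaks[[si]], min_probes, merge_tol)
        k <- length(seg$first)
        acc[[length(acc) + 1]] <- list(
          sample_id = rep(samples[si], k),
          chrom = rep(ch, k),
          start = pos[seg$first],
          end = bounds_end[seg$last],
          n_probes = seg$last - seg$first + 1L,
          mean_cn = seg$mean
        )
      }
    }
  })
  tibble(
    sample_id = unlist(map(acc, "sample_id")),
    chrom = unlist(map(acc, "chrom")),
    start = unlist(map(acc, "start")),
    end = unlist(map(acc, "end")),
    n_probes = unlist(map(acc, "n_probes")),
    mean_cn = unlist(map(acc, "mean_cn"))
  ) %>%
    arrange(.data$sample_id, chrom_factor(.data$chrom), .data$start)
}

# Turn breakpoints (0-based starts of interior segments) into segments with
# mean/merge post-processing. Returns a list of parallel vectors first/last
# (1-based probe indices) and mean.
build_segments <- function(v, breaks, min_probes, merge_tol) {
  n <- length(v)
  starts <- c(1L, as.integer(breaks) + 1L)
  ends <- c(as.integer(breaks), n)
  cs <- c(0, cumsum(v))
  sums <- cs[ends + 1] - cs[starts]
  cnt <- ends - starts + 1L
  # absorb under-length segments into the closer-mean neighbor
  repeat {
    small <- which(cnt < min_probes)
    if (length(small) == 0 || length(cnt) == 1) break
    i <- small[1]
    mean_i <- sums[i] / cnt[i]
    left <- if (i > 1) abs(sums[i - 1] / cnt[i - 1] - mean_i) else Inf
    right <- if (i < length(cnt)) abs(sums[i + 1] / cnt[i + 1] - mean_i) else Inf
    j <- if (left <= right) i - 1 else i + 1
    sums[j] <- sums[j] + sums[i]
    cnt[j] <- cnt[j] + cnt[i]
    starts[j] <- min(starts[j], starts[i])
    ends[j] <- max(ends[j], ends[i])
    sums <- sums[-i]; cnt <- cnt[-i]; starts <- starts[-i]; ends <- ends[-i]
  }
  # merge adjacent segments with close means, closest pair first
  repeat {
    if (length(cnt) == 1) break
    d <- abs(diff(sums / cnt))
    i <- which.min(d)
    if (d[i] >= merge_tol) break
    sums[i] <- sums[i] + sums[i + 1]
    cnt[i] <- cnt[i] + cnt[i + 1]
    ends[i] <- ends[i + 1]
    sums <- sums[-(i + 1)]; cnt <- cnt[-(i + 1)]
    starts <- starts[-(i + 1)]; ends <- ends[-(i + 1)]
  }
  # copy number is physically non-negative; noise around a homozygous
  # deletion can average fractionally below zero after centering
  list(first = starts, last = ends, mean = pmax(sums / cnt, 0))
}

#' Best single circular split of one probe series
#'
#' Exposes the maximal arc statistic used inside [cbs_segment()]: the arc
#' `[i, j)` (0-based) with the largest two-sample statistic, plus the
#' conservative all-arcs significance bound.
#'
#' @param v Numeric probe values for one chromosome.
#' @param min_probes Minimum probes on each side of the split.
#' @param use_ranks Rank-transform before the statistic.
#' @return List with `t`, `i`, `j`, `p_bound`.
#' @export
max_arc_stat <- function(v, min_probes = 3, use_ranks = FALSE) {
  .max_arc_stat(v, min_probes, use_ranks)
}
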