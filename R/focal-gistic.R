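# GISTIC-style focal analysis: arm-median decomposition, per-marker G-score
# with a circular-shift permutation null, Benjamini-Hochberg q-values and
# iterative peel-off peak calling.

# Marker-level copy-number matrix (markers x samples) from tiled segments;
# markers with no covering segment are diploid (2.0).
marker_cn_matrix <- function(segments, markers) {
  samples <- unique(segments$sample_id)
  out <- matrix(2, nrow(markers), length(samples),
    dimnames = list(NULL, samples)
  )
  for (ch in unique(markers$chrom)) {
    mrows <- which(markers$chrom == ch)
    pos <- markers$pos[mrows]
    seg_ch <- segments[segments$chrom == ch, ]
    seg_ch <- seg_ch[order(seg_ch$start), ]
    for (i in seq_along(samples)) {
      seg <- seg_ch[seg_ch$sample_id == samples[i], ]
      if (nrow(seg) == 0) next
      idx <- findInterval(pos, seg$start)
      inside <- idx >= 1 & pos < seg$end[pmax(idx, 1)]
      out[mrows[inside], i] <- seg$mean_cn[idx[inside]]
    }
  }
  out
}

#' Per-marker focal amplitude decomposition
#'
#' Separates focal from broad signal: within each sample and chromosome arm,
#' the arm's median marker copy number is subtracted; the positive remainder
#' is focal amplification amplitude and the negative remainder (sign
#' flipped) focal deletion amplitude, both in copies. A whole-arm gain
#' therefore contributes no focal amplitude, while a focal amplicon on a
#' broadly gained arm scores only its excess above the arm level.
#'
#' @param segments Segment tibble for the cohort.
#' @param markers Marker tibble (`chrom`, `pos`), typically the probe map.
#' @param arms Chromosome-arm table from [chrom_arms()]; required.
#' @return A `cna_focal` list: `markers` (with `arm`), `amp` and `del`
#'   amplitude matrices (markers x samples).
#' @export
focal_component <- function(segments, markers, arms) {
  if (missing(arms) || is.null(arms)) {
    abort("an arm boundaries table is required (see chrom_arms())")
  }
  markers <- markers %>% arrange(chrom_factor(.data$chrom), .data$pos)
  cn <- marker_cn_matrix(segments, markers)
  arm_id <- character(nrow(markers))
  for (r in seq_len(nrow(arms))) {
    hit <- markers$chrom == arms$chrom[r] &
      markers$pos >= arms$start[r] & markers$pos < arms$end[r]
    arm_id[hit] <- paste0(arms$chrom[r], arms$arm[r])
  }
  if (any(arm_id == "")) {
    abort("some markers fall outside the arm boundaries table")
  }
  dev <- cn
  for (a in unique(arm_id)) {
    rows <- arm_id == a
    med <- apply(cn[rows, , drop = FALSE], 2, median)
    dev[rows, ] <- sweep(cn[rows, , drop = FALSE], 2, med)
  }
  structure(
    list(
      markers = markers %>% mutate(arm = arm_id),
      amp = pmax(dev, 0), del = pmax(-dev, 0)
    ),
    class = "cna_focal"
  )
}

# p-values of observed scores against a pooled permutation sample
# (fraction of pooled null scores >= observed).
pooled_p <- function(g, null_sorted) {
  n <- length(null_sorted)
  n_less <- findInterval(g, null_sorted, left.open = TRUE)
  (n - n_less) / n
}

#' G-scores and q-values for focal aberrations
#'
#' The G-score at a marker is the sum over samples of its focal amplitude in
#' the given direction. The null permutes each sample's amplitude vector by
#' an independent circular shift within each chromosome (preserving the
#' sample's amplitude spectrum and within-chromosome autocorrelation while
#' decoupling marker positions across samples); the empirical p at a marker
#' is the fraction of pooled permuted scores (any marker, any permutation)
#' reaching its G, and q is the Benjamini-Hochberg adjustment over markers.
#'
#' @param focal A [focal_component()] result.
#' @param n_perm Permutations (a warning is raised below 100).
#' @param seed Integer seed.
#' @return A `cna_gscore` tibble: `chrom`, `pos`, `direction`, `gscore`,
#'   `p`, `q`, with the amplitude matrices and null score pools attached as
#'   attributes for [call_peaks()].
#' @export
gscore_and_q <- function(focal, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(focal, "cna_focal"))
  if (n_perm < 100) warn("fewer than 100 permutations: p-values are coarse")
  mk <- focal$markers
  chrom_rle <- rle(mk$chrom)
  chrom_len <- chrom_rle$lengths
  chrom_start <- cumsum(c(0L, head(chrom_len, -1)))
  nulls <- list()
  rows <- list()
  for (dir in c("amp", "del")) {
    a <- focal[[dir]]
    pooled <- with_seed(
      derive_seed(seed, "gistic"),
      .gistic_null_scores(
        a, as.integer(chrom_start), as.integer(chrom_len), as.integer(n_perm)
      )
    )
    pooled <- sort(pooled)
    g <- rowSums(a)
    p <- pooled_p(g, pooled)
    rows[[dir]] <- mk %>%
      select("chrom", "pos") %>%
      mutate(
        direction = if (dir == "amp") "amplification" else "deletion",
        gscore = g, p = p, q = p.adjust(p, "BH")
      )
    nulls[[dir]] <- pooled
  }
  out <- new_tidycna_tbl(list_rbind(rows), "cna_gscore")
  attr(out, "focal") <- focal
  attr(out, "nulls") <- nulls
  out
}

#' Call focal peaks by iterative peel-off
#'
#' Repeatedly takes the genome-wide maximum G-score among markers with
#' `q < q_cutoff`; the peak interval is the maximal surrounding run of
#' significant markers, trimmed by leave-one-out (the single sample
#' contributing most at the peak marker is removed and the still-significant
#' run re-extended). The called peak's carrier amplitudes are then subtracted
#' over the significant run and scores are recomputed against the original
#' permutation null until no marker passes. Genes overlapping each peak
#' interval are annotated.
#'
#' @param gscore A [gscore_and_q()] result.
#' @param q_cutoff Q-value cutoff for significance (default 0.25).
#' @param genes Optional gene model tibble; peaks get overlapping gene ids
#'   (a warning is raised when absent).
#' @return A `cna_peaks` tibble: `chrom`, `start`, `end`, `direction`,
#'   `peak_gscore`, `qvalue`, `n_carriers`, `genes` (list-column).
#' @export
call_peaks <- function(gscore, q_cutoff = 0.25, genes = NULL) {
  stopifnot(inherits(gscore, "cna_gscore"))
  focal <- attr(gscore, "focal")
  nulls <- attr(gscore, "nulls")
  if (is.null(genes)) {
    warn("no gene model supplied: peaks will have empty gene lists")
  }
  mk <- focal$markers
  spacing_by_chrom <- mk %>%
    group_by(.data$chrom) %>%
    summarize(spacing = if (n() > 1) median(diff(.data$pos)) else 1)
  out <- list()
  for (dir in c("amp", "del")) {
    a <- focal[[dir]]
    pooled <- nulls[[dir]]
    for (iter in seq_len(100)) {
      g <- rowSums(a)
      if (all(g <= 0)) break
      q <- p.adjust(pooled_p(g, pooled), "BH")
      sig <- q < q_cutoff
      if (!any(sig)) break
      peak <- which(sig)[which.max(g[sig])]
      run <- significant_run(sig, mk$chrom, peak)
      # leave-one-out: drop the top contributor at the peak and re-extend
      top <- which.max(a[peak, ])
      g2 <- g - a[, top]
      q2 <- p.adjust(pooled_p(g2, pooled), "BH")
      sig2 <- q2 < q_cutoff
      trimmed <- if (sig2[peak]) significant_run(sig2, mk$chrom, peak) else run
      sp <- spacing_by_chrom$spacing[spacing_by_chrom$chrom == mk$chrom[peak]]
      start <- mk$pos[trimmed[1]]
      end <- mk$pos[trimmed[length(trimmed)]] + sp
      carriers <- colnames(a)[a[peak, ] > 0]
      peak_genes <- if (!is.null(genes)) {
        genes$gene_id[genes$chrom == mk$chrom[peak] &
          genes$start < end & genes$end > start]
      } else {
        character(0)
      }
      out[[length(out) + 1]] <- tibble(
        chrom = mk$chrom[peak], start = start, end = end,
        direction = if (dir == "amp") "amplification" else "deletion",
        peak_gscore = g[peak], qvalue = q[peak],
        n_carriers = length(carriers), genes = list(peak_genes)
      )
      # peel off: remove the carriers' amplitude over the significant run
      a[run, carriers] <- 0
    }
  }
  res <- if (length(out) == 0) {
    tibble(
      chrom = character(), start = numeric(), end = numeric(),
      direction = character(), peak_gscore = numeric(), qvalue = numeric(),
      n_carriers = integer(), genes = list()
    )
  } else {
    list_rbind(out)
  }
  new_tidycna_tbl(res, "cna_peaks")
}

# Maximal run of TRUE around `center`, confined to one chromosome.
significant_run <- function(sig, chrom, center) {
  lo <- center
  while (lo > 1 && sig[lo - 1] && chrom[lo - 1] == chrom[center]) lo <- lo - 1
  hi <- center
  while (hi < length(sig) && sig[hi + 1] && chrom[hi + 1] == chrom[center]) hi <- hi + 1
  lo:hi
}
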