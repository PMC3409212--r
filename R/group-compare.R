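# Group frequency comparisons (Fisher exact + percentage-point rule),
# CNA-burden tests, hierarchical clustering and cluster-label enrichment.

# Memoized two-sided Fisher exact p for 2x2 tables.
fisher_p_2x2 <- local({
  cache <- new.env(parent = emptyenv())
  function(a, b, c, d) {
    key <- paste(a, b, c, d, sep = "_")
    p <- cache[[key]]
    if (is.null(p)) {
      p <- fisher.test(matrix(c(a, b, c, d), 2))$p.value
      cache[[key]] <- p
    }
    p
  }
})

#' Compare directed CNA frequencies between two sample groups
#'
#' Per marker, carriers of the directed aberration in each group form a 2x2
#' table tested with a two-sided Fisher exact test. A marker is flagged
#' significant when both rules hold: the absolute frequency difference
#' exceeds `diff_threshold` percentage points AND the Fisher p is below
#' `p_threshold` (the two rules can be toggled independently by setting one
#' of them to 0 resp. 1). Adjacent flagged markers merge into regions. A
#' Benjamini-Hochberg column is emitted alongside the unadjusted p for
#' transparency; the flag uses the unadjusted p.
#'
#' @param segments Classified segment tibble for both groups combined.
#' @param markers Marker tibble (`chrom`, `pos`).
#' @param groups Tibble `sample_id`, `group` with exactly two group levels.
#' @param direction "gain" or "loss".
#' @param diff_threshold Percentage-point difference rule (default 15).
#' @param p_threshold Fisher p rule (default 0.01).
#' @return A `cna_group_compare` tibble per marker: `chrom`, `pos`,
#'   `freq_a`, `freq_b`, `diff` (points, a minus b), `fisher_p`, `fisher_q`,
#'   `significant`; merged flagged regions in `attr(, "regions")` and the
#'   group levels in `attr(, "groups")`.
#' @export
compare_frequencies <- function(segments, markers, groups,
                                direction = c("gain", "loss"),
                                diff_threshold = 15, p_threshold = 0.01) {
  direction <- match.arg(direction)
  check_columns(groups, c("sample_id", "group"), "groups")
  lv <- sort(unique(as.character(groups$group)))
  if (length(lv) != 2) abort("groups must have exactly two levels")
  if (!"direction" %in% names(segments)) segments <- classify_segments(segments)
  ids_a <- groups$sample_id[groups$group == lv[1]]
  ids_b <- groups$sample_id[groups$group == lv[2]]
  if (length(ids_a) == 0 || length(ids_b) == 0) abort("empty group")
  sgn <- if (direction == "gain") 1 else -1
  markers <- markers %>% arrange(chrom_factor(.data$chrom), .data$pos)
  res <- markers %>% mutate(carriers_a = 0L, carriers_b = 0L)
  for (ch in unique(markers$chrom)) {
    mrows <- which(markers$chrom == ch)
    ind <- marker_indicator(segments, markers[mrows, ], ch, sgn)
    res$carriers_a[mrows] <- colSums(ind[rownames(ind) %in% ids_a, , drop = FALSE])
    res$carriers_b[mrows] <- colSums(ind[rownames(ind) %in% ids_b, , drop = FALSE])
  }
  na <- length(ids_a)
  nb <- length(ids_b)
  res <- res %>%
    mutate(
      n_a = na, n_b = nb,
      freq_a = .data$carriers_a / na,
      freq_b = .data$carriers_b / nb,
      diff = 100 * (.data$freq_a - .data$freq_b),
      fisher_p = map2_dbl(
        .data$carriers_a, .data$carriers_b,
        ~ fisher_p_2x2(.x, na - .x, .y, nb - .y)
      ),
      fisher_q = p.adjust(.data$fisher_p, "BH"),
      significant = abs(.data$diff) > diff_threshold & .data$fisher_p < p_threshold
    )
  regions <- if (!any(res$significant)) {
    tibble(
      chrom = character(), start = numeric(), end = numeric(),
      peak_diff = numeric(), min_p = numeric()
    )
  } else {
    res %>%
      group_by(.data$chrom) %>%
      mutate(run = cumsum(.data$significant & !coalesce(lag(.data$significant), FALSE))) %>%
      ungroup() %>%
      filter(.data$significant) %>%
      group_by(.data$chrom, .data$run) %>%
      summarize(
        start = min(.data$pos), end = max(.data$pos),
        peak_diff = .data$diff[which.max(abs(.data$diff))],
        min_p = min(.data$fisher_p), .groups = "drop"
      ) %>%
      select(-"run")
  }
  out <- new_tidycna_tbl(res, "cna_group_compare")
  attr(out, "regions") <- regions
  attr(out, "groups") <- lv
  attr(out, "direction") <- direction
  out
}

#' @importFrom purrr map2_dbl
NULL

#' Welch t-test on per-tumor CNA burden between two groups
#'
#' @param counts Tibble with one row per sample, e.g. from [count_events()]
#'   joined to clinical labels.
#' @param count_col,group_col Column names (strings) of the event count and
#'   the two-level group label.
#' @return A `cna_burden_test` one-row tibble: group means/sds/sizes, the
#'   Welch `t`, `df` and `p_value`.
#' @export
burden_ttest <- function(counts, count_col = "n_events", group_col = "group") {
  check_columns(counts, c(count_col, group_col), "counts")
  lv <- sort(unique(as.character(counts[[group_col]])))
  if (length(lv) != 2) abort("burden_ttest needs exactly two groups")
  x <- counts[[count_col]][counts[[group_col]] == lv[1]]
  y <- counts[[count_col]][counts[[group_col]] == lv[2]]
  if (length(x) < 2 || length(y) < 2) abort("each group needs >= 2 samples")
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate: both groups constant; t is 0 when the means agree
    same <- isTRUE(all.equal(mean(x), mean(y)))
    ht <- list(
      statistic = c(t = if (same) 0 else Inf * sign(mean(x) - mean(y))),
      parameter = c(df = NA_real_), p.value = if (same) 1 else 0
    )
  } else {
    ht <- t.test(x, y, var.equal = FALSE)
  }
  new_tidycna_tbl(
    tibble(
      group_a = lv[1], group_b = lv[2],
      n_a = length(x), n_b = length(y),
      mean_a = mean(x), sd_a = sd(x),
      mean_b = mean(y), sd_b = sd(y),
      t = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value
    ),
    "cna_burden_test"
  )
}

#' Hierarchical clustering of samples on gene-level copy number
#'
#' Agglomerative clustering with complete linkage on sample-sample distances
#' (Euclidean by default, or 1 - Pearson correlation), cut into `k`
#' clusters. Sex chromosomes are ignored by convention: supplying
#' sex-chromosome genes is an error so the exclusion is always explicit
#' upstream.
#'
#' @param gene_cn Wide gene-level copy-number tibble (`gene_id`, `chrom`,
#'   ... annotation, then sample columns), e.g. from [gene_level_cn()].
#' @param k Number of clusters.
#' @param metric "euclidean" or "pearson" (1 - correlation distance).
#' @return Tibble `sample_id`, `cluster` (integer), invariant to input
#'   sample order.
#' @export
cluster_cohort <- function(gene_cn, k = 3, metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  if ("chrom" %in% names(gene_cn) && any(is_sex_chrom(gene_cn$chrom))) {
    abort("gene_cn contains sex-chromosome genes; exclude them before clustering")
  }
  samples <- sort(sample_cols(gene_cn))
  if (k > length(samples)) abort("k exceeds the number of samples")
  m <- t(as.matrix(gene_cn[samples]))
  if (anyNA(m)) abort("gene_cn contains missing values; impute or drop upstream")
  d <- if (metric == "euclidean") dist(m) else as.dist(1 - cor(t(m)))
  cl <- cutree(hclust(d, method = "complete"), k = k)
  tibble(sample_id = samples, cluster = unname(cl))
}

#' Cluster-label enrichment by Fisher exact test
#'
#' For every cluster and every level of every label column, tests the 2x2
#' table label-level-in-cluster vs rest (two-sided). Samples with a missing
#' label are excluded pairwise; label columns with fewer than two observed
#' levels are skipped with a warning.
#'
#' @param assignment Tibble `sample_id`, `cluster` from [cluster_cohort()].
#' @param labels Tibble `sample_id` plus one or more label columns.
#' @return Tibble `label`, `level`, `cluster`, `n_in_cluster`, `n_cluster`,
#'   `n_level`, `n_total`, `p_value`.
#' @export
label_enrichment <- function(assignment, labels) {
  check_columns(assignment, c("sample_id", "cluster"))
  check_columns(labels, "sample_id")
  label_cols <- setdiff(names(labels), "sample_id")
  if (length(label_cols) == 0) {
    warn("no label columns supplied")
    return(tibble(
      label = character(), level = character(), cluster = integer(),
      n_in_cluster = integer(), n_cluster = integer(), n_level = integer(),
      n_total = integer(), p_value = numeric()
    ))
  }
  joined <- assignment %>% inner_join(labels, by = "sample_id")
  out <- list()
  for (lab in label_cols) {
    v <- joined[[lab]]
    ok <- !is.na(v)
    lv <- unique(as.character(v[ok]))
    if (length(lv) < 2) {
      warn(paste0("label '", lab, "' has fewer than two observed levels; skipped"))
      next
    }
    for (level in lv) {
      for (cl in sort(unique(joined$cluster))) {
        in_cl <- joined$cluster[ok] == cl
        is_lv <- as.character(v[ok]) == level
        a <- sum(in_cl & is_lv)
        out[[length(out) + 1]] <- tibble(
          label = lab, level = level, cluster = cl,
          n_in_cluster = a, n_cluster = sum(in_cl),
          n_level = sum(is_lv), n_total = sum(ok),
          p_value = fisher_p_2x2(
            a, sum(in_cl) - a, sum(is_lv) - a,
            sum(!in_cl & !is_lv)
          )
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(
      label = character(), level = character(), cluster = integer(),
      n_in_cluster = integer(), n_cluster = integer(), n_level = integer(),
      n_total = integer(), p_value = numeric()
    ))
  }
  list_rbind(out)
}
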