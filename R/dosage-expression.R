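# Gene-level copy-number summarization, cis copy-number/expression
# concordance and pathway over-representation with a permutation FDR.

#' Gene-level copy number from segments
#'
#' Per gene and sample, the unweighted mean of the mean copy numbers of all
#' segments overlapping the gene interval (the convention for gene-level
#' summaries of segmented data); missing where no segment overlaps. A
#' length-weighted mean is available behind `weighted`.
#'
#' @param segments Segment tibble for the cohort.
#' @param genes Gene model tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param weighted Use overlap-length weights instead of the plain mean.
#' @return Wide tibble: `gene_id`, `symbol` (if present), `chrom`, `start`,
#'   `end`, then one copy-number column per sample.
#' @export
gene_level_cn <- function(segments, genes, weighted = FALSE) {
  check_columns(segments, c("sample_id", "chrom", "start", "end", "mean_cn"))
  check_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  missing_chrom <- setdiff(unique(genes$chrom), unique(segments$chrom))
  if (length(missing_chrom) > 0) {
    warn(paste0(
      "no segments on chromosome(s) ", paste(missing_chrom, collapse = ", "),
      "; their genes are missing"
    ))
  }
  samples <- unique(segments$sample_id)
  hits <- genes %>%
    select("gene_id", "chrom", g_start = "start", g_end = "end") %>%
    inner_join(segments, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$start < .data$g_end, .data$end > .data$g_start)
  summarized <- if (weighted) {
    hits %>%
      mutate(w = pmin(.data$end, .data$g_end) - pmax(.data$start, .data$g_start)) %>%
      group_by(.data$gene_id, .data$sample_id) %>%
      summarize(cn = sum(.data$mean_cn * .data$w) / sum(.data$w), .groups = "drop")
  } else {
    hits %>%
      group_by(.data$gene_id, .data$sample_id) %>%
      summarize(cn = mean(.data$mean_cn), .groups = "drop")
  }
  wide <- summarized %>%
    pivot_wider(names_from = "sample_id", values_from = "cn")
  for (s in setdiff(samples, names(wide))) wide[[s]] <- NA_real_
  ann_cols <- intersect(c("gene_id", "symbol", "chrom", "start", "end"), names(genes))
  genes %>%
    select(all_of(ann_cols)) %>%
    left_join(wide, by = "gene_id") %>%
    arrange(chrom_factor(.data$chrom), .data$start)
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a numeric response across ordered groups.
#' The statistic is the sum over ordered group pairs of Mann-Whitney counts
#' (ties count one half); the p-value uses the large-sample normal
#' approximation (two-sided).
#'
#' @param x Numeric response.
#' @param g Ordered factor (or coercible) of group membership.
#' @return List with `statistic`, `z`, `p_value`, `n`.
#' @export
jonckheere_test <- function(x, g) {
  g <- as.ordered(g)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- droplevels(g[keep])
  lv <- levels(g)
  if (length(lv) < 2) abort("jonckheere_test needs >= 2 observed groups")
  j <- 0
  for (a in seq_len(length(lv) - 1)) {
    xa <- x[g == lv[a]]
    for (b in (a + 1):length(lv)) {
      xb <- x[g == lv[b]]
      cmp <- outer(xa, xb, "<")
      tie <- outer(xa, xb, "==")
      j <- j + sum(cmp) + 0.5 * sum(tie)
    }
  }
  n <- length(x)
  ni <- tabulate(g)
  mu <- (n^2 - sum(ni^2)) / 4
  sigma2 <- (n^2 * (2 * n + 3) - sum(ni^2 * (2 * ni + 3))) / 72
  z <- (j - mu) / sqrt(sigma2)
  list(statistic = j, z = z, p_value = 2 * pnorm(-abs(z)), n = n)
}

#' Cis concordance of copy number and expression
#'
#' For each gene present in both matrices, samples are categorized by their
#' copy-number class (homozygous deletion, deletion, no-change, gain,
#' amplification); expression is centered per gene; the monotone trend of
#' expression across the ordered classes is assessed with the
#' Jonckheere-Terpstra test, alongside the Spearman correlation between
#' numeric copy number and expression. Genes with fewer than two classes
#' holding at least `min_per_class` samples are flagged untestable.
#'
#' @param gene_cn Wide gene-level copy-number tibble (from
#'   [gene_level_cn()]).
#' @param expression Wide expression tibble (`gene_id` + sample columns).
#' @param bins Thresholds from [cna_bins()].
#' @param min_per_class Minimum samples per class for testability (default
#'   2).
#' @return A `cna_concordance` tibble per gene: `gene_id`, `n`,
#'   `n_classes`, `testable`, `jt_p`, `spearman_rho`, `spearman_p`,
#'   `class_summary` (list-column of per-class n/mean/median of centered
#'   expression).
#' @export
cis_concordance <- function(gene_cn, expression, bins = cna_bins(),
                            min_per_class = 2) {
  check_columns(expression, "gene_id", "expression")
  shared_genes <- intersect(gene_cn$gene_id, expression$gene_id)
  shared_samples <- intersect(sample_cols(gene_cn), sample_cols(expression))
  if (length(shared_samples) < 3) abort("need >= 3 shared samples")
  cn_m <- as.matrix(gene_cn[match(shared_genes, gene_cn$gene_id), shared_samples])
  ex_m <- as.matrix(expression[match(shared_genes, expression$gene_id), shared_samples])
  rows <- map(seq_along(shared_genes), function(i) {
    cn <- cn_m[i, ]
    ex <- ex_m[i, ]
    ok <- !is.na(cn) & !is.na(ex)
    cn <- cn[ok]
    ex <- ex[ok] - mean(ex[ok])
    cls <- classify_cn(cn, bins)
    tab <- table(cls)
    n_classes <- sum(tab > 0)
    testable <- sum(tab >= min_per_class) >= 2
    summ <- tibble(
      cna_class = factor(CNA_CLASSES, levels = CNA_CLASSES, ordered = TRUE),
      n = as.integer(tab[CNA_CLASSES]),
      mean_expr = map_dbl(CNA_CLASSES, ~ if (tab[.x] > 0) mean(ex[cls == .x]) else NA_real_),
      median_expr = map_dbl(CNA_CLASSES, ~ if (tab[.x] > 0) median(ex[cls == .x]) else NA_real_)
    )
    jt_p <- NA_real_
    rho <- rho_p <- NA_real_
    if (testable) {
      jt_p <- jonckheere_test(ex, cls)$p_value
      ct <- suppressWarnings(cor.test(cn, ex, method = "spearman"))
      rho <- unname(ct$estimate)
      rho_p <- ct$p.value
    } else if (length(unique(cn)) > 1) {
      ct <- suppressWarnings(cor.test(cn, ex, method = "spearman"))
      rho <- unname(ct$estimate)
      rho_p <- ct$p.value
    }
    tibble(
      gene_id = shared_genes[i], n = sum(ok), n_classes = n_classes,
      testable = testable, jt_p = jt_p,
      spearman_rho = rho, spearman_p = rho_p, class_summary = list(summ)
    )
  })
  new_tidycna_tbl(list_rbind(rows), "cna_concordance")
}

#' Pathway over-representation with a permutation FDR
#'
#' Fisher exact over-representation of `hits` in each gene set (one-sided:
#' the question is whether hits are over-represented, so depletion is never
#' flagged and a disjoint set scores p = 1), after
#' intersecting sets with the `universe` and excluding sets outside
#' `size_bounds` (by convention fewer than 10 or more than 500 members).
#' Fold enrichment is `(k / n_hits) / (set_size / n_universe)`. The FDR is a
#' plug-in permutation estimate: for each of `n_perm` permutations a random
#' gene set of the same size is drawn from the universe for every tested
#' set; FDR(set) is the mean count of random-set p-values at or below the
#' set's p, divided by the observed count of sets at or below it (capped at
#' 1).
#'
#' @param hits Character vector of hit genes; must be contained in
#'   `universe`.
#' @param gene_sets Gene-set tibble from [read_gmt()] (or with `set`,
#'   `genes` columns).
#' @param universe Character vector of all candidate genes.
#' @param n_perm Number of permutations (default 100).
#' @param size_bounds Length-2 inclusive bounds on post-intersection set
#'   size.
#' @param seed Integer seed.
#' @return Tibble `set`, `size`, `overlap`, `fold_enrichment`, `fisher_p`,
#'   `perm_fdr`, ordered by `fisher_p`.
#' @export
pathway_enrichment <- function(hits, gene_sets, universe, n_perm = 100,
                               size_bounds = c(10, 500), seed = 1L) {
  hits <- unique(hits)
  universe <- unique(universe)
  stray <- setdiff(hits, universe)
  if (length(stray) > 0) {
    abort(paste0(
      "hit genes absent from the universe: ",
      paste(head(stray, 5), collapse = ", "),
      if (length(stray) > 5) ", ..." else ""
    ))
  }
  check_columns(gene_sets, c("set", "genes"), "gene_sets")
  sets <- gene_sets %>%
    mutate(
      genes = map(.data$genes, intersect, universe),
      size = lengths(.data$genes)
    ) %>%
    filter(.data$size >= size_bounds[1], .data$size <= size_bounds[2])
  if (nrow(sets) == 0) {
    return(tibble(
      set = character(), size = integer(), overlap = integer(),
      fold_enrichment = numeric(), fisher_p = numeric(), perm_fdr = numeric()
    ))
  }
  n_u <- length(universe)
  n_h <- length(hits)
  set_p <- function(members) {
    k <- length(intersect(hits, members))
    m <- length(members)
    # one-sided over-representation: P(overlap >= k) under the
    # hypergeometric null
    p <- stats::phyper(k - 1, m, n_u - m, n_h, lower.tail = FALSE)
    list(k = k, p = p)
  }
  obs <- map(sets$genes, set_p)
  res <- sets %>%
    mutate(
      overlap = map_int(obs, ~ as.integer(.x$k)),
      fisher_p = map_dbl(obs, "p"),
      fold_enrichment = (.data$overlap / n_h) / (.data$size / n_u)
    )
  perm_p <- with_seed(derive_seed(seed, "fdr"), {
    vapply(seq_len(n_perm), function(b) {
      vapply(
        res$size,
        function(m) set_p(sample(universe, m))$p,
        numeric(1)
      )
    }, numeric(nrow(res)))
  })
  perm_p <- matrix(perm_p, nrow = nrow(res))
  res$perm_fdr <- map_dbl(res$fisher_p, function(p) {
    n_obs <- sum(res$fisher_p <= p)
    min(1, mean(colSums(perm_p <= p)) / n_obs)
  })
  res %>%
    select("set", "size", "overlap", "fold_enrichment", "fisher_p", "perm_fdr") %>%
    arrange(.data$fisher_p)
}
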