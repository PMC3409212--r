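# Genome-wide gene-gene copy-number correlation, significant-edge graphs,
# degree distributions and the per-chromosome randomization null.

#' Pairwise gene-gene copy-number correlations
#'
#' Pearson correlation between all gene pairs across samples, pairwise
#' complete; pairs with fewer than 3 complete observations, and constant
#' genes, are undefined (NA). Pairs on the same chromosome are flagged
#' `linked` — correlation between unlinked (different-chromosome) loci is
#' the co-selection signal of interest.
#'
#' @param gene_cn Wide gene-level copy-number tibble (`gene_id`, `chrom`,
#'   annotation, sample columns).
#' @return A `cna_corr` object (correlation matrix plus gene annotation);
#'   use [tidy()] for the edge-list form.
#' @export
pairwise_correlations <- function(gene_cn) {
  check_columns(gene_cn, c("gene_id", "chrom"), "gene_cn")
  samples <- sample_cols(gene_cn)
  if (length(samples) < 3) abort("need >= 3 samples")
  m <- t(as.matrix(gene_cn[samples]))
  colnames(m) <- gene_cn$gene_id
  if (anyNA(m)) {
    n_pair <- crossprod(!is.na(m))
    r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
    r[n_pair < 3] <- NA
  } else {
    r <- suppressWarnings(cor(m))
  }
  diag(r) <- 1
  structure(
    list(r = r, genes = gene_cn %>% select("gene_id", "chrom")),
    class = "cna_corr"
  )
}

#' @export
print.cna_corr <- function(x, ...) {
  cat("<cna_corr> ", nrow(x$r), " genes\n", sep = "")
  invisible(x)
}

#' @rdname pairwise_correlations
#' @param x A `cna_corr` object.
#' @param ... Unused.
#' @return `tidy()`: tibble `gene_a`, `gene_b`, `pearson_r`, `linked`
#'   (same chromosome), one row per unordered pair.
#' @export
tidy.cna_corr <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    gene_a = rownames(x$r)[idx[, 1]],
    gene_b = colnames(x$r)[idx[, 2]],
    pearson_r = x$r[idx],
    linked = x$genes$chrom[idx[, 1]] == x$genes$chrom[idx[, 2]]
  )
}

#' Significant-correlation gene graph
#'
#' Nodes are genes; edges connect pairs with `|r| >= r_threshold`
#' (conventionally 0.3), optionally restricted to unlinked
#' (inter-chromosome) pairs.
#'
#' @param corr A [pairwise_correlations()] result.
#' @param r_threshold Absolute-correlation edge threshold.
#' @param unlinked_only Keep only inter-chromosome edges.
#' @return An igraph graph with vertex attributes `name` and `chrom` and
#'   edge attribute `r`.
#' @export
edge_graph <- function(corr, r_threshold = 0.3, unlinked_only = FALSE) {
  stopifnot(inherits(corr, "cna_corr"))
  edges <- tidy(corr) %>%
    filter(!is.na(.data$pearson_r), abs(.data$pearson_r) >= r_threshold)
  if (unlinked_only) edges <- edges %>% filter(!.data$linked)
  g <- igraph::graph_from_data_frame(
    edges %>% select("gene_a", "gene_b", r = "pearson_r"),
    directed = FALSE,
    vertices = corr$genes %>% select(name = "gene_id", "chrom")
  )
  g
}

#' Degree distribution of a significant-edge graph
#'
#' Per-gene significant-edge degrees, binned counts over nonzero degrees,
#' and the ordinary-least-squares slope of log10(count) on log10(degree) —
#' the summary under which hub-dominated (scale-free-like) graphs show a
#' steep negative slope.
#'
#' @param graph An [edge_graph()] result.
#' @return A `cna_degree` object: `degrees` (tibble `gene_id`, `degree`),
#'   `bins` (tibble `degree`, `count`), `slope` (NA when fewer than 2
#'   nonzero bins).
#' @export
degree_distribution <- function(graph) {
  deg <- igraph::degree(graph)
  degrees <- tibble(gene_id = names(deg), degree = as.integer(unname(deg)))
  bins <- degrees %>%
    filter(.data$degree >= 1) %>%
    count(.data$degree, name = "count")
  slope <- NA_real_
  if (nrow(bins) >= 2) {
    slope <- unname(coef(lm(log10(count) ~ log10(degree), data = bins))[2])
  }
  structure(
    list(degrees = degrees, bins = bins, slope = slope),
    class = "cna_degree"
  )
}

#' @export
print.cna_degree <- function(x, ...) {
  cat(
    "<cna_degree> ", sum(x$degrees$degree > 0), "/", nrow(x$degrees),
    " connected genes; log-log slope ", round(x$slope, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.cna_degree <- function(x, ...) {
  tibble(
    n_genes = nrow(x$degrees),
    n_connected = sum(x$degrees$degree > 0),
    max_degree = max(c(0L, x$degrees$degree)),
    loglog_slope = x$slope
  )
}

#' Per-chromosome randomization null for the correlation network
#'
#' Each permutation independently shuffles the sample labels of every
#' chromosome's genes (one permutation per chromosome), which preserves all
#' within-chromosome correlations exactly while destroying cross-chromosome
#' structure. The inter-chromosome edge graph and degree distribution are
#' recomputed per permutation and the observed degrees are compared to the
#' pooled null degrees with a two-sample Kolmogorov-Smirnov test.
#'
#' @param gene_cn Wide gene-level copy-number tibble.
#' @param n_perm Number of permutations (a warning is raised below 10).
#' @param r_threshold Edge threshold passed to [edge_graph()].
#' @param seed Integer seed.
#' @return A `cna_network_null` object: `observed` degrees, `null_degrees`
#'   (pooled), `ks_stat`, `ks_p`, `n_perm`; `NULL` fields and a warning when
#'   only one chromosome is present (no inter-chromosome pairs).
#' @export
randomization_null <- function(gene_cn, n_perm = 20, r_threshold = 0.3,
                               seed = 1L) {
  if (n_perm < 10) warn("fewer than 10 permutations: the null is coarse")
  chroms <- unique(gene_cn$chrom)
  if (length(chroms) < 2) {
    warn("single-chromosome input: no inter-chromosome pairs to test")
    return(structure(
      list(
        observed = NULL, null_degrees = NULL, ks_stat = NA_real_,
        ks_p = NA_real_, n_perm = 0L
      ),
      class = "cna_network_null"
    ))
  }
  samples <- sample_cols(gene_cn)
  obs_deg <- degree_distribution(
    edge_graph(pairwise_correlations(gene_cn), r_threshold, unlinked_only = TRUE)
  )$degrees
  null_deg <- with_seed(derive_seed(seed, "network"), {
    map(seq_len(n_perm), function(b) {
      perm <- gene_cn
      for (ch in chroms) {
        rows <- perm$chrom == ch
        shuffled <- sample(samples)
        perm[rows, samples] <- perm[rows, shuffled]
      }
      degree_distribution(
        edge_graph(pairwise_correlations(perm), r_threshold, unlinked_only = TRUE)
      )$degrees$degree
    })
  })
  pooled <- unlist(null_deg)
  ks <- suppressWarnings(ks.test(obs_deg$degree, pooled))
  structure(
    list(
      observed = obs_deg, null_degrees = pooled,
      ks_stat = unname(ks$statistic), ks_p = ks$p.value, n_perm = n_perm
    ),
    class = "cna_network_null"
  )
}

#' @export
print.cna_network_null <- function(x, ...) {
  cat(
    "<cna_network_null> ", x$n_perm, " permutations; KS = ",
    round(x$ks_stat, 3), ", p = ", signif(x$ks_p, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.cna_network_null <- function(x, ...) {
  tibble(ks_stat = x$ks_stat, ks_p = x$ks_p, n_perm = x$n_perm)
}
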