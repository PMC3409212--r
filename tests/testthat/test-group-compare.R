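test_that("identical groups produce no significant frequency differences", {
  segs <- classify_segments(dplyr::bind_rows(lapply(1:20, function(i) {
    cn <- if (i %% 2 == 0) 3.0 else 2.0
    make_segments(paste0("S", i), "1", 0, 2e6, cn)
  })))
  groups <- tibble::tibble(
    sample_id = paste0("S", 1:20),
    group = rep(c("A", "B"), each = 10)
  )
  markers <- tibble::tibble(chrom = "1", pos = c(0, 1e6))
  cmp <- compare_frequencies(segs, markers, groups, direction = "gain")
  expect_false(any(cmp$significant))
  expect_error(
    compare_frequencies(segs, markers, groups %>% dplyr::mutate(group = "A")),
    "two levels"
  )
})

test_that("Fisher p matches the hypergeometric oracle on the reported contrast", {
  # 8/33 MSI carriers vs 19/269 MSS carriers
  p_pkg <- tidycna:::fisher_p_2x2(8, 33 - 8, 19, 269 - 19)
  p_oracle <- fisher_oracle(8, 33 - 8, 19, 269 - 19)
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  diff <- 100 * (8 / 33 - 19 / 269)
  expect_gt(abs(diff), 15)
  expect_lt(p_pkg, 0.01)
})

test_that("both comparison rules are required and toggleable", {
  # construct a marker where diff > 15 points but p is large (tiny n)
  segs <- classify_segments(dplyr::bind_rows(
    make_segments("A1", "1", 0, 1e6, 1.0),
    make_segments("A2", "1", 0, 1e6, 2.0),
    lapply(1:6, function(i) make_segments(paste0("B", i), "1", 0, 1e6, 2.0))
  ))
  groups <- tibble::tibble(
    sample_id = c("A1", "A2", paste0("B", 1:6)),
    group = c("A", "A", rep("B", 6))
  )
  markers <- tibble::tibble(chrom = "1", pos = 0)
  cmp <- compare_frequencies(segs, markers, groups, direction = "loss")
  expect_gt(abs(cmp$diff), 15)
  expect_false(cmp$significant)
  # disable the p rule: the point rule alone now flags it
  cmp2 <- compare_frequencies(segs, markers, groups,
    direction = "loss", p_threshold = 1.01
  )
  expect_true(cmp2$significant)
  # disable the point rule instead: p alone decides
  cmp3 <- compare_frequencies(segs, markers, groups,
    direction = "loss", diff_threshold = 0
  )
  expect_equal(cmp3$significant, cmp3$fisher_p < 0.01)
})

test_that("burden Welch test recovers the planted group separation", {
  set.seed(10)
  counts <- tibble::tibble(
    n_events = c(
      pmax(round(rnorm(269, 33.2, 17.6)), 0),
      pmax(round(rnorm(33, 10.2, 6.5)), 0)
    ),
    group = rep(c("MSS", "MSI"), c(269, 33))
  )
  bt <- burden_ttest(counts)
  expect_lt(bt$p_value, 0.01)
  expect_equal(bt$group_a, "MSI")
  expect_lt(bt$mean_a, bt$mean_b)

  # identical constant groups: t = 0 by convention
  const <- tibble::tibble(n_events = rep(5, 10), group = rep(c("A", "B"), 5))
  expect_equal(burden_ttest(const)$t, 0)
  expect_error(
    burden_ttest(tibble::tibble(n_events = 1:3, group = c("A", "B", "B"))),
    ">= 2 samples"
  )
})

test_that("burden test p-values are uniform under the null", {
  set.seed(11)
  ps <- vapply(1:300, function(i) {
    counts <- tibble::tibble(
      n_events = rnorm(60, 20, 5),
      group = rep(c("A", "B"), 30)
    )
    burden_ttest(counts)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

mk_gene_cn <- function(m, chrom = NULL) {
  # m: genes x samples matrix
  g <- tibble::tibble(
    gene_id = paste0("g", seq_len(nrow(m))),
    chrom = chrom %||% rep("1", nrow(m)),
    start = seq_len(nrow(m)) * 1e5, end = seq_len(nrow(m)) * 1e5 + 5e4
  )
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  dplyr::bind_cols(g, tibble::as_tibble(m))
}

test_that("clustering recovers well-separated planted profiles", {
  set.seed(12)
  base <- matrix(2, 30, 30)
  base[1:10, 1:10] <- 5 # chr20-amplified-like pattern
  base[11:20, 11:20] <- 0.8 # deletion pattern
  m <- base + matrix(rnorm(900, 0, 0.05), 30)
  cl <- cluster_cohort(mk_gene_cn(m), k = 3)
  # samples are returned in sorted-id order; rebuild truth accordingly
  truth <- (as.integer(sub("S", "", cl$sample_id)) - 1) %/% 10 + 1
  expect_equal(adjusted_rand(cl$cluster, truth), 1.0)

  # sample-order invariance
  perm <- sample(30)
  gcn <- mk_gene_cn(m)
  gcn2 <- gcn[, c(names(gcn)[1:4], paste0("S", perm))]
  cl2 <- cluster_cohort(gcn2, k = 3)
  expect_equal(cl$cluster, cl2$cluster)

  # sex-chromosome genes must be excluded upstream
  expect_error(
    cluster_cohort(mk_gene_cn(m, chrom = c(rep("1", 29), "X")), k = 3),
    "sex-chromosome"
  )

  # n = k: every sample its own cluster
  cl3 <- cluster_cohort(mk_gene_cn(m[, 1:4]), k = 4)
  expect_equal(sort(unique(cl3$cluster)), 1:4)
  expect_error(cluster_cohort(mk_gene_cn(m[, 1:2]), k = 3), "exceeds")
})

test_that("label enrichment matches the exact oracle and handles degenerate labels", {
  assignment <- tibble::tibble(
    sample_id = paste0("S", 1:20),
    cluster = rep(1:2, each = 10)
  )
  labels <- tibble::tibble(
    sample_id = paste0("S", 1:20),
    marker = rep(c("pos", "neg"), each = 10)
  )
  enr <- label_enrichment(assignment, labels)
  row <- enr[enr$cluster == 1 & enr$level == "pos", ]
  expect_equal(row$p_value, fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)

  expect_warning(
    out <- label_enrichment(
      assignment,
      tibble::tibble(sample_id = paste0("S", 1:20), flat = "same")
    ),
    "fewer than two"
  )
  expect_equal(nrow(out), 0)

  expect_warning(
    out2 <- label_enrichment(assignment, tibble::tibble(sample_id = paste0("S", 1:20))),
    "no label columns"
  )
  expect_equal(nrow(out2), 0)
})
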