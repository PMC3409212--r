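test_that("gene-level copy number averages overlapping segments as specified", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), symbol = gene_id,
    chrom = c("1", "1", "2"),
    start = c(1e5, 9e5, 1e5), end = c(3e5, 1.3e6, 3e5)
  )
  segs <- dplyr::bind_rows(
    make_segments("S1", "1", 0, 1e6, 3.1),
    make_segments("S1", "1", 1e6, 2e6, 2.0)
  )
  expect_warning(gcn <- gene_level_cn(segs, genes), "chromosome")
  expect_equal(gcn$S1[gcn$gene_id == "gA"], 3.1)
  # gB spans segments at 3.1 and 2.0: the unweighted mean is forced
  expect_equal(gcn$S1[gcn$gene_id == "gB"], mean(c(3.1, 2.0)))
  expect_true(is.na(gcn$S1[gcn$gene_id == "gC"]))

  # length-weighted option differs when overlaps are asymmetric
  gcn_w <- suppressWarnings(gene_level_cn(segs, genes, weighted = TRUE))
  w <- c(1e5, 3e5) / 4e5
  expect_equal(gcn_w$S1[gcn_w$gene_id == "gB"], sum(c(3.1, 2.0) * w))

  # refinement invariance: splitting a segment at one value changes nothing
  segs_split <- dplyr::bind_rows(
    make_segments("S1", "1", 0, 5e5, 3.1),
    make_segments("S1", "1", 5e5, 1e6, 3.1),
    make_segments("S1", "1", 1e6, 2e6, 2.0)
  )
  gcn2 <- suppressWarnings(gene_level_cn(segs_split, genes))
  expect_equal(gcn2$S1[gcn2$gene_id == "gA"], 3.1)
})

test_that("cis concordance finds planted dosage and flags untestable genes", {
  set.seed(20)
  n <- 100
  cn_amp <- c(rep(6, 20), rep(2, 80))
  cn_flat <- rep(2, n)
  gcn <- tibble::tibble(
    gene_id = c("dosage", "flat", "inverse"), symbol = gene_id,
    chrom = "1", start = c(1e5, 2e5, 3e5), end = c(1.5e5, 2.5e5, 3.5e5)
  )
  expr <- gcn[, "gene_id"]
  m <- rbind(
    1 + 0.5 * cn_amp + rnorm(n, 0, 0.3),
    rnorm(n),
    cn_amp # exact monotone identity for rho
  )
  for (i in seq_len(n)) {
    gcn[[paste0("S", i)]] <- c(cn_amp[i], cn_flat[i], cn_amp[i])
    expr[[paste0("S", i)]] <- m[, i]
  }
  cc <- cis_concordance(gcn, expr)
  dosage <- cc[cc$gene_id == "dosage", ]
  expect_true(dosage$testable)
  expect_lt(dosage$jt_p, 0.01)
  summ <- dosage$class_summary[[1]]
  expect_gt(
    summ$mean_expr[summ$cna_class == "amplified"],
    summ$mean_expr[summ$cna_class == "unchanged"]
  )
  expect_false(cc$testable[cc$gene_id == "flat"])
  expect_equal(cc$spearman_rho[cc$gene_id == "inverse"], 1.0)
})

test_that("expression independent of copy number shows no spurious correlation", {
  set.seed(21)
  n <- 213
  rhos <- vapply(1:40, function(i) {
    cn <- sample(c(2, 3), n, replace = TRUE)
    expr <- rnorm(n)
    suppressWarnings(cor.test(cn, expr, method = "spearman"))$estimate
  }, numeric(1))
  expect_gt(mean(abs(rhos) < 0.2), 0.95)
})

test_that("the Jonckheere-Terpstra test detects trends and calibrates under the null", {
  set.seed(22)
  x <- c(rnorm(20, 0), rnorm(20, 1), rnorm(20, 2))
  g <- factor(rep(c("a", "b", "c"), each = 20), ordered = TRUE)
  expect_lt(jonckheere_test(x, g)$p_value, 1e-6)

  ps <- vapply(1:200, function(i) {
    jonckheere_test(rnorm(45), factor(rep(1:3, each = 15), ordered = TRUE))$p_value
  }, numeric(1))
  # the JT statistic is discrete, so tied p-values are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(jonckheere_test(1:5, rep("a", 5)), ">= 2")
})

test_that("pathway enrichment reproduces the worked fold-enrichment example", {
  universe <- paste0("g", 1:1000)
  hits <- paste0("g", 1:50)
  sets <- tibble::tibble(
    set = c("target", "disjoint", "tiny"),
    description = "",
    genes = list(
      paste0("g", c(1:20, 101:180)), # 100 members, overlap 20
      paste0("g", 900:999), # 100 members, overlap 0
      paste0("g", 1:9) # excluded by the size filter
    )
  )
  enr <- pathway_enrichment(hits, sets, universe, n_perm = 50, seed = 1)
  expect_false("tiny" %in% enr$set)
  target <- enr[enr$set == "target", ]
  expect_equal(target$fold_enrichment, 4.0)
  # one-sided over-representation oracle by direct hypergeometric enumeration
  p_one_sided <- sum(stats::dhyper(20:50, 100, 900, 50))
  expect_equal(target$fisher_p, p_one_sided, tolerance = 1e-12)
  disj <- enr[enr$set == "disjoint", ]
  expect_equal(disj$overlap, 0L)
  expect_equal(disj$fold_enrichment, 0)
  expect_equal(disj$fisher_p, 1, tolerance = 1e-9)
  expect_true(all(enr$perm_fdr >= 0 & enr$perm_fdr <= 1))
  expect_lt(target$perm_fdr, 0.2)

  expect_error(
    pathway_enrichment(c(hits, "absent"), sets, universe),
    "absent"
  )
})
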