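test_that("perfectly linked genes correlate at 1 and constants are undefined", {
  set.seed(30)
  shared <- 2 + rnorm(50, 0, 0.5)
  m <- rbind(shared, shared, rep(2, 50), 2 + rnorm(50, 0, 0.5))
  corr <- pairwise_correlations(mk_cn(m, c("1", "1", "1", "2")))
  ed <- tidy(corr)
  expect_equal(ed$pearson_r[ed$gene_a == "g1" & ed$gene_b == "g2"], 1.0)
  expect_true(is.na(ed$pearson_r[ed$gene_a == "g1" & ed$gene_b == "g3"]))
  expect_true(ed$linked[ed$gene_a == "g1" & ed$gene_b == "g2"])
  expect_false(ed$linked[ed$gene_a == "g1" & ed$gene_b == "g4"])
  expect_error(pairwise_correlations(mk_cn(m[, 1:2], rep("1", 4))), ">= 3 samples")
})

test_that("independent genes at n=269 stay below the edge threshold", {
  set.seed(31)
  m <- matrix(2 + rnorm(60 * 269, 0, 0.4), 60)
  corr <- pairwise_correlations(mk_cn(m, rep(c("1", "2", "3"), each = 20)))
  r <- tidy(corr)$pearson_r
  expect_lt(quantile(abs(r), 0.95), 0.15)
})

test_that("edge graphs and degree distributions follow their definitions", {
  set.seed(32)
  n <- 500
  hub <- rnorm(n)
  # satellites correlate ~0.5 with the hub but only ~0.25 with each other,
  # so the hub alone exceeds the 0.3 edge threshold against all of them
  m <- rbind(
    2 + hub,
    2 + hub + rnorm(n, 0, sqrt(3)),
    2 + hub + rnorm(n, 0, sqrt(3)),
    2 + hub + rnorm(n, 0, sqrt(3)),
    2 + hub + rnorm(n, 0, sqrt(3)),
    2 + matrix(rnorm(n * 3, 0, 1), 3)
  )
  gcn <- mk_cn(m, as.character(1:8))
  corr <- pairwise_correlations(gcn)
  g <- edge_graph(corr, r_threshold = 0.3, unlinked_only = TRUE)
  dd <- degree_distribution(g)
  expect_equal(
    dd$degrees$gene_id[which.max(dd$degrees$degree)], "g1"
  )
  # a block of 10 fully correlated genes: degree 9 each
  blk <- matrix(rep(rnorm(40), 10), 10, byrow = TRUE) + 2
  corr_blk <- pairwise_correlations(mk_cn(blk, as.character(1:10)))
  g_blk <- edge_graph(corr_blk, r_threshold = 0.3)
  expect_true(all(igraph::degree(g_blk) == 9))
  # an impossible threshold yields no edges
  expect_equal(igraph::ecount(edge_graph(corr_blk, r_threshold = 1.01)), 0)
})

test_that("per-chromosome shuffling preserves within-chromosome correlation exactly", {
  set.seed(33)
  m <- matrix(2 + rnorm(20 * 40, 0, 0.5), 20)
  m[1:10, ] <- m[1:10, ] + rep(rnorm(40, 0, 0.6), each = 10)
  gcn <- mk_cn(m, rep(c("1", "2"), each = 10))
  samples <- paste0("S", 1:40)
  shuffled <- gcn
  rows <- shuffled$chrom == "1"
  shuffled[rows, samples] <- shuffled[rows, sample(samples)]
  r0 <- pairwise_correlations(gcn)$r
  r1 <- pairwise_correlations(shuffled)$r
  expect_equal(r1[1:10, 1:10], r0[1:10, 1:10], tolerance = 1e-12)
  expect_equal(r1[11:20, 11:20], r0[11:20, 11:20], tolerance = 1e-12)
})

test_that("the randomization null separates co-selected from independent genomes", {
  set.seed(34)
  n <- 120
  # co-selected: one latent factor drives blocks on two chromosomes
  latent <- rbinom(n, 1, 0.5)
  co_m <- rbind(
    matrix(rep(2 + latent, each = 8), 8, byrow = FALSE),
    matrix(rep(2 + latent, each = 8), 8, byrow = FALSE)
  ) + matrix(rnorm(16 * n, 0, 0.2), 16)
  co_null <- randomization_null(
    mk_cn(co_m, rep(c("1", "2"), each = 8)),
    n_perm = 20, seed = 1
  )
  expect_lt(co_null$ks_p, 0.01)

  # independent chromosomes: observed inside the null envelope
  ind_m <- matrix(2 + rnorm(16 * n, 0, 0.4), 16)
  ind_null <- randomization_null(
    mk_cn(ind_m, rep(c("1", "2"), each = 8)),
    n_perm = 20, seed = 1
  )
  expect_gt(ind_null$ks_p, 0.05)

  expect_warning(
    vac <- randomization_null(mk_cn(ind_m, rep("1", 16)), n_perm = 15),
    "single-chromosome"
  )
  expect_true(is.na(vac$ks_p))
})

test_that("planted co-selection shows up as cross-chromosome structure in a cohort", {
  spec <- cohort_spec(
    n_mss = 120, n_msi = 2,
    mss_burden = c(3, 1.5), msi_burden = c(3, 1.5),
    planted_events = tibble::tibble(
      name = c("gain_20q", "gain_8q"),
      chrom = c("20", "8"), start = c(1.4e6, 2.3e6), end = c(3.1e6, 7.3e6),
      kind = "gain", target_cn = 3, frequency = c(0.725, 0.331),
      restrict_var = NA_character_, restrict_level = NA_character_
    ),
    noise_sd = 0.2
  )
  rho <- matrix(c(1, 0.8, 0.8, 1), 2)
  co <- simulate_correlated_events(spec, rho, seed = 44)
  seg <- classify_segments(cbs_segment(center_profiles(co$profiles), seed = 44))
  gcn <- gene_level_cn(seg, spec$genes) %>%
    dplyr::filter(!chrom %in% c("X", "Y"))
  corr <- pairwise_correlations(gcn)
  ed <- tidy(corr) %>% dplyr::filter(!linked)
  g20 <- spec$genes$gene_id[spec$genes$chrom == "20" & spec$genes$start > 1.5e6]
  g8 <- spec$genes$gene_id[spec$genes$chrom == "8" & spec$genes$start > 2.4e6]
  cross <- ed %>% dplyr::filter(
    (gene_a %in% g20 & gene_b %in% g8) | (gene_a %in% g8 & gene_b %in% g20)
  )
  expect_gt(mean(cross$pearson_r), 0.2)
  expect_true(any(abs(cross$pearson_r) >= 0.3))
})
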