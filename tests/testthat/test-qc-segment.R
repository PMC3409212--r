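test_that("MAPD matches hand-enumerated differences and respects chromosome bounds", {
  p <- make_profiles(list("1" = c(2, 2, 2, 2)))
  expect_equal(qc_mapd(p)$mapd, 0)

  p <- make_profiles(list("1" = c(2.0, 2.4, 2.0, 2.4, 2.0)))
  expect_equal(qc_mapd(p)$mapd, 0.4)

  # a huge cross-chromosome jump must not enter the median
  p2 <- make_profiles(list("1" = c(2, 2, 2), "2" = c(8, 8, 8)))
  expect_equal(qc_mapd(p2)$mapd, 0)

  # noise calibrated to MAPD ~ 0.7 fails the 0.6 cutoff
  set.seed(1)
  v <- 2 + rnorm(4000, 0, 0.7 / (sqrt(2) * qnorm(0.75)))
  qc <- qc_mapd(make_profiles(list("1" = v)), threshold = 0.6)
  expect_gt(qc$mapd, 0.6)
  expect_false(qc$pass)
})

test_that("centering anchors the diploid mode", {
  set.seed(2)
  v <- 2.3 + rnorm(2000, 0, 0.1) # uniform +0.3 offset
  cent <- center_profiles(make_profiles(list("1" = v)))
  d <- density(cent$S1)
  expect_lt(abs(d$x[which.max(d$y)] - 2), 0.03)

  # 60% diploid / 40% at 3.0: the mode anchor picks the diploid cluster
  v <- c(2 + rnorm(1200, 0, 0.15), 3 + rnorm(800, 0, 0.15)) + 0.4
  cent <- center_profiles(make_profiles(list("1" = v)))
  expect_lt(abs(median(cent$S1[1:1200]) - 2), 0.05)

  # constant-2 baseline is neutral
  prof <- make_profiles(list("1" = 2 + rnorm(500, 0, 0.1)))
  base <- make_profiles(list("1" = rep(2, 500)), sample_ids = c("N1"))
  expect_equal(
    center_profiles(prof, baseline = base)$S1,
    center_profiles(prof)$S1,
    tolerance = 1e-10
  )
  expect_error(
    center_profiles(prof, baseline = prof[, 1:3]),
    "no sample columns"
  )
})

test_that("CBS leaves pure noise unsplit and localizes planted steps", {
  set.seed(3)
  v <- 2 + rnorm(200, 0, 0.2)
  seg <- cbs_segment(make_profiles(list("1" = v)), alpha = 1e-6, seed = 1)
  expect_equal(nrow(seg), 1)

  # step of +1 copy at probe 50 of 100: breakpoint within +/- 2 probes
  hits <- vapply(1:20, function(i) {
    set.seed(100 + i)
    v <- c(rep(2, 50), rep(3, 50)) + rnorm(100, 0, 0.1)
    seg <- cbs_segment(make_profiles(list("1" = v)), alpha = 1e-6, seed = i)
    nrow(seg) == 2 && abs(seg$start[2] / 5e4 - 50) <= 2
  }, logical(1))
  expect_true(all(hits))

  # 10-probe focal amplicon to copy number 5
  set.seed(4)
  v <- rep(2, 100)
  v[46:55] <- 5
  v <- v + rnorm(100, 0, 0.1)
  seg <- cbs_segment(make_profiles(list("1" = v)), alpha = 1e-6, seed = 2)
  expect_equal(nrow(seg), 3)
  expect_lt(abs(seg$mean_cn[2] - 5), 0.2)

  expect_error(cbs_segment(make_profiles(list("1" = v)), alpha = 0), "alpha")

  # short chromosomes return a single segment
  seg <- cbs_segment(make_profiles(list("1" = c(2, 5, 2, 5))), min_probes = 3)
  expect_equal(nrow(seg), 1)
})

test_that("the compiled arc scan agrees with the brute-force oracle", {
  for (i in 1:10) {
    set.seed(200 + i)
    v <- 2 + rnorm(sample(30:80, 1), 0, 0.3)
    if (i %% 2 == 0) v[10:20] <- v[10:20] + 1
    got <- max_arc_stat(v, min_probes = 3, use_ranks = FALSE)
    want <- max_arc_oracle(v, min_seg = 3)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(c(got$i, got$j), c(want$i, want$j))
  }
})

test_that("segment means reconstruct the probe mean exactly", {
  co <- shared_cohort()
  seg <- co$segments
  prof <- center_profiles(co$cohort$profiles)
  for (s in head(sample_cols(prof), 3)) {
    for (ch in c("1", "13", "20")) {
      v <- prof[[s]][prof$chrom == ch]
      sub <- seg[seg$sample_id == s & seg$chrom == ch, ]
      # clamping at zero is the only allowed deviation; these profiles stay
      # positive so the identity is exact
      expect_equal(
        sum(sub$mean_cn * sub$n_probes) / sum(sub$n_probes),
        mean(v),
        tolerance = 1e-9
      )
    }
  }
})

test_that("lowering alpha never increases the number of segments", {
  set.seed(5)
  v <- c(rep(2, 60), rep(2.6, 30), rep(2, 60), rep(1.2, 20), rep(2, 40)) +
    rnorm(210, 0, 0.25)
  p <- make_profiles(list("1" = v))
  n_loose <- nrow(cbs_segment(p, alpha = 1e-2, n_perm = 500, seed = 3))
  n_mid <- nrow(cbs_segment(p, alpha = 1e-4, n_perm = 500, seed = 3))
  n_tight <- nrow(cbs_segment(p, alpha = 1e-8, n_perm = 500, seed = 3))
  expect_true(n_tight <= n_mid && n_mid <= n_loose)
})

test_that("the rank transform is available and robust to a gross outlier", {
  set.seed(6)
  v <- c(rep(2, 50), rep(3, 50)) + rnorm(100, 0, 0.1)
  v[10] <- 30 # corrupt probe
  seg <- cbs_segment(make_profiles(list("1" = v)),
    alpha = 1e-4, n_perm = 2000, use_ranks = TRUE, seed = 4
  )
  expect_gte(nrow(seg), 2)
  expect_lt(abs(seg$start[nrow(seg)] / 5e4 - 50), 3)
})
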