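test_that("arm-median subtraction removes broad signal and keeps focal excess", {
  # whole-arm gain to 3.0: no focal amplitude anywhere on the arm
  segs <- classify_segments(dplyr::bind_rows(
    make_segments("S1", "1", 0, 2.5e6, 3.0),
    make_segments("S1", "1", 2.5e6, 5e6, 2.0)
  ))
  f <- focal_component(segs, mk2(), arms1())
  expect_true(all(f$amp == 0))
  expect_true(all(f$del == 0))

  # focal CN 5 amplicon on a diploid arm: amplitude 3 inside, 0 outside
  segs <- classify_segments(dplyr::bind_rows(
    make_segments("S1", "1", 0, 1e6, 2.0),
    make_segments("S1", "1", 1e6, 1.5e6, 5.0),
    make_segments("S1", "1", 1.5e6, 5e6, 2.0)
  ))
  f <- focal_component(segs, mk2(), arms1())
  inside <- f$markers$pos >= 1e6 & f$markers$pos < 1.5e6
  expect_true(all(abs(f$amp[inside, 1] - 3) < 1e-9))
  expect_true(all(f$amp[!inside, 1] == 0))

  # focal CN 5 on an arm broadly at 3.0: amplitude 2
  segs <- classify_segments(dplyr::bind_rows(
    make_segments("S1", "1", 0, 1e6, 3.0),
    make_segments("S1", "1", 1e6, 1.5e6, 5.0),
    make_segments("S1", "1", 1.5e6, 2.5e6, 3.0),
    make_segments("S1", "1", 2.5e6, 5e6, 2.0)
  ))
  f <- focal_component(segs, mk2(), arms1())
  expect_true(all(abs(f$amp[inside, 1] - 2) < 1e-9))

  expect_error(focal_component(segs, mk2(), NULL), "arm boundaries")
})

test_that("G-scores follow their definition and a diploid cohort stays null", {
  segs <- classify_segments(dplyr::bind_rows(lapply(1:5, function(i) {
    make_segments(paste0("S", i), "1", 0, 5e6, 2.0)
  })))
  f <- focal_component(segs, mk2(), arms1())
  g <- suppressWarnings(gscore_and_q(f, n_perm = 200, seed = 1))
  expect_true(all(g$gscore == 0))
  expect_false(any(g$q < 0.25))

  # a single focal contribution of 2.8 copies at one marker region
  segs <- classify_segments(dplyr::bind_rows(
    make_segments("S1", "1", 0, 1e6, 2.0),
    make_segments("S1", "1", 1e6, 1.2e6, 4.8),
    make_segments("S1", "1", 1.2e6, 5e6, 2.0),
    make_segments("S2", "1", 0, 5e6, 2.0)
  ))
  f <- focal_component(segs, mk2(), arms1())
  g <- suppressWarnings(gscore_and_q(f, n_perm = 200, seed = 1))
  amp <- g[g$direction == "amplification", ]
  at <- amp$gscore[amp$pos == 1e6]
  expect_equal(at, 2.8, tolerance = 1e-9)

  # G-score additivity: duplicating every sample doubles G
  segs2 <- dplyr::bind_rows(
    segs,
    segs %>% dplyr::mutate(sample_id = paste0(sample_id, "_dup"))
  )
  f2 <- focal_component(segs2, mk2(), arms1())
  expect_equal(rowSums(f2$amp), 2 * rowSums(f$amp))
})

test_that("planted amplicons reach significance and peel-off separates two peaks", {
  segs <- planted_cohort_segs()
  f <- focal_component(segs, mk2(), arms1())
  g <- gscore_and_q(f, n_perm = 1000, seed = 7)
  amp <- g[g$direction == "amplification", ]
  inside <- amp$pos >= 2e6 & amp$pos < 2.5e6
  expect_true(all(amp$q[inside] < 0.25))

  peaks <- call_peaks(g, genes = NULL) %>% suppressWarnings()
  peaks <- peaks[peaks$direction == "amplification", ]
  expect_equal(nrow(peaks), 1)
  expect_true(peaks$start <= 2.05e6 && peaks$end >= 2.45e6)

  # two disjoint amplicons on one chromosome
  segs2 <- planted_cohort_segs(second = c(3.6e6, 4.0e6))
  f2 <- focal_component(segs2, mk2(), arms1())
  g2 <- gscore_and_q(f2, n_perm = 1000, seed = 7)
  peaks2 <- suppressWarnings(call_peaks(g2, genes = NULL))
  peaks2 <- peaks2[peaks2$direction == "amplification", ]
  expect_equal(nrow(peaks2), 2)
  expect_setequal(
    vapply(seq_len(2), function(i) {
      any(peaks2$start[i] < c(2.2e6, 3.8e6) & peaks2$end[i] > c(2.2e6, 3.8e6))
    }, logical(1)),
    c(TRUE, TRUE)
  )

  # null cohort: no peaks
  segs0 <- classify_segments(dplyr::bind_rows(lapply(1:20, function(i) {
    make_segments(paste0("S", i), "1", 0, 5e6, 2.0)
  })))
  g0 <- suppressWarnings(
    gscore_and_q(focal_component(segs0, mk2(), arms1()), n_perm = 200, seed = 1)
  )
  expect_equal(nrow(suppressWarnings(call_peaks(g0, genes = NULL))), 0)
})

test_that("peaks annotate overlapping genes", {
  segs <- planted_cohort_segs()
  g <- gscore_and_q(focal_component(segs, mk2(), arms1()), n_perm = 500, seed = 2)
  genes <- tibble::tibble(
    gene_id = c("IN", "OUT"), symbol = gene_id,
    chrom = "1", start = c(2.1e6, 4.5e6), end = c(2.2e6, 4.6e6)
  )
  peaks <- call_peaks(g, genes = genes)
  expect_equal(peaks$genes[[1]], "IN")
})
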