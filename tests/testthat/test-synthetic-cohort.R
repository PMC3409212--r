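quiet_spec <- function(...) {
  # essentially event-free background so constructed checks stay exact
  cohort_spec(
    n_mss = 6, n_msi = 2,
    mss_burden = c(1e-4, 5e-5), msi_burden = c(1e-4, 5e-5),
    planted_events = NULL, noise_sd = 0,
    ...
  )
}

test_that("an event-free noiseless cohort is uniformly diploid", {
  co <- simulate_cohort(quiet_spec(), seed = 1)
  m <- as.matrix(co$profiles[sample_cols(co$profiles)])
  expect_true(all(m == 2))
  expect_equal(nrow(co$truth$sample_events), 0)
})

test_that("simulation is deterministic under a fixed seed", {
  spec <- cohort_spec(n_mss = 15, n_msi = 5)
  a <- simulate_cohort(spec, seed = 9)
  b <- simulate_cohort(spec, seed = 9)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$sample_events, b$truth$sample_events)
  c <- simulate_cohort(spec, seed = 10)
  expect_false(identical(a$profiles, c$profiles))
})

test_that("planted carrier fractions land within 3 binomial SE of their frequency", {
  co <- shared_cohort()$cohort
  ev <- co$truth$events
  n_elig <- vapply(seq_len(nrow(ev)), function(i) {
    if (is.na(ev$restrict_var[i])) return(nrow(co$clinical))
    sum(co$clinical[[ev$restrict_var[i]]] == ev$restrict_level[i])
  }, numeric(1))
  se <- sqrt(ev$frequency * (1 - ev$frequency) / n_elig)
  expect_true(all(
    abs(ev$carrier_fraction_realized - ev$frequency) <= 3 * se + 1e-9
  ))
})

test_that("specs with impossible parameters are rejected", {
  expect_error(cohort_spec(mss_burden = c(0.5, 1)), "infeasible burden")
  expect_error(cohort_spec(mss_burden = c(33.2, 0)), "sd must be")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  bad_ev <- default_planted_events() %>%
    dplyr::mutate(target_cn = ifelse(name == "gain_20q", 4.5, target_cn))
  expect_error(
    cohort_spec(planted_events = bad_ev),
    "inconsistent with its kind"
  )
})

two_event_spec <- function(n = 400, f1 = 0.5, f2 = 0.5) {
  g <- default_genome()
  ev <- tibble::tibble(
    name = c("evA", "evB"), chrom = c("4", "9"),
    start = 0, end = 2e6, kind = "gain", target_cn = 3,
    frequency = c(f1, f2), restrict_var = NA_character_,
    restrict_level = NA_character_
  )
  cohort_spec(
    n_mss = n, n_msi = 1, mss_burden = c(2, 1), msi_burden = c(2, 1),
    planted_events = ev, noise_sd = 0
  )
}

test_that("copula carriers reduce to independence at rho 0 and comonotone at rho 1", {
  spec <- two_event_spec()
  co0 <- simulate_correlated_events(spec, diag(2), seed = 5)
  carr <- co0$truth$carriers
  expect_lt(abs(cor(carr[, 1], carr[, 2])), 0.15)

  rho1 <- matrix(c(1, 1, 1, 1), 2)
  co1 <- simulate_correlated_events(spec, rho1, seed = 5)
  carr1 <- co1$truth$carriers
  expect_identical(carr1[, 1], carr1[, 2]) # same frequency, same latent draw
})

test_that("copula phi coefficient matches the orthant-probability oracle", {
  rho <- matrix(c(1, 0.5, 0.5, 1), 2)
  spec <- two_event_spec(n = 1000)
  co <- simulate_correlated_events(spec, rho, seed = 21)
  carr <- co$truth$carriers
  phi_hat <- cor(carr[, 1], carr[, 2])
  p11 <- bvn_orthant(qnorm(0.5), qnorm(0.5), 0.5)
  phi_true <- (p11 - 0.25) / 0.25
  expect_lt(abs(phi_hat - phi_true), 0.05)
  # marginals preserved within 3 binomial SE
  expect_true(all(abs(colMeans(carr[co$clinical$msi == "MSS", ]) - 0.5) <=
    3 * sqrt(0.25 / 1000)))
})

test_that("non-positive-semidefinite correlation targets are rejected", {
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  spec <- two_event_spec()
  spec$planted_events <- spec$planted_events[c(1, 2, 2), ] %>%
    dplyr::mutate(name = c("evA", "evB", "evC"), chrom = c("4", "9", "11"))
  expect_error(
    simulate_correlated_events(spec, bad, seed = 1),
    "positive semi-definite"
  )
  expect_error(
    simulate_correlated_events(spec, diag(2), seed = 1),
    "one row per planted event"
  )
})

test_that("the expression dosage slope is recoverable by regression at low noise", {
  ev <- tibble::tibble(
    name = "evA", chrom = "4", start = 0, end = 3e6, kind = "gain",
    target_cn = 3, frequency = 0.5, restrict_var = NA_character_,
    restrict_level = NA_character_
  )
  spec <- cohort_spec(
    n_mss = 200, n_msi = 1, mss_burden = c(1, 0.5), msi_burden = c(1, 0.5),
    planted_events = ev, noise_sd = 0, expr_noise_sd = 0.05
  )
  co <- simulate_cohort(spec, seed = 8)
  genes <- spec$genes
  expr <- as.matrix(co$expression[sample_cols(co$expression)])
  idx <- which(genes$chrom == "4" & genes$end <= 3e6)
  carr <- co$truth$carriers[, "evA"]
  # background events may also cover a gene; use the recorded truth events
  sev <- co$truth$sample_events
  slopes <- vapply(idx, function(i) {
    mid <- (genes$start[i] + genes$end[i]) / 2
    hit <- sev[sev$chrom == "4" & sev$start <= mid & sev$end > mid, ]
    cn <- rep(2, ncol(expr))
    for (r in seq_len(nrow(hit))) {
      s <- match(hit$sample_id[r], colnames(expr))
      cn[s] <- cn[s] + hit$delta[r]
    }
    coef(lm(expr[i, ] ~ cn))[2]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - spec$expr_slope) / spec$expr_slope, 0.10)
})

test_that("per-group drawn event counts match the burden moments", {
  co <- shared_cohort()$cohort
  counts <- dplyr::inner_join(
    co$truth$counts, co$clinical[, c("sample_id", "msi")],
    by = "sample_id"
  )
  mss <- counts$n_drawn[counts$msi == "MSS"]
  # one cohort of 60: allow 3 SE around the spec mean
  expect_lt(abs(mean(mss) - 33.2), 3 * 17.6 / sqrt(length(mss)))
  expect_lt(abs(sd(mss) - 17.6) / 17.6, 0.5)
})
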