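# Independent oracles and small fixture builders shared across tests.

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum of probabilities of all tables (same margins) no more likely than the
# observed one.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b # row 1 total
  n <- c + d # row 2 total
  k <- a + c # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent log-rank score test: standard observed-minus-expected with
# hypergeometric variance at each distinct event time.
logrank_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# P(Z1 <= a, Z2 <= b) for standard bivariate normal with correlation rho,
# by 1-d numerical integration (conditioning on Z1).
bvn_orthant <- function(a, b, rho) {
  stats::integrate(
    function(z) stats::dnorm(z) * stats::pnorm((b - rho * z) / sqrt(1 - rho^2)),
    -Inf, a,
    rel.tol = 1e-10
  )$value
}

# Brute-force single best arc: maximize the two-sample statistic over all
# contiguous arcs [i, j) by direct double loop (reference for the compiled
# scan).
max_arc_oracle <- function(v, min_seg = 3) {
  n <- length(v)
  s <- sqrt(var(v))
  best <- list(t = 0, i = -1, j = -1)
  for (i in 0:(n - min_seg)) {
    for (j in (i + min_seg):n) {
      k <- j - i
      if (n - k < min_seg) next
      m_in <- mean(v[(i + 1):j])
      m_out <- mean(v[-((i + 1):j)])
      t <- abs(m_in - m_out) / (s * sqrt(1 / k + 1 / (n - k)))
      if (t > best$t) best <- list(t = t, i = i, j = j)
    }
  }
  best
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Tiny genome: a couple of equal chromosomes with a centromere in the
# middle; handy for constructed segment fixtures.
tiny_genome <- function(chroms = c("1", "2"), len = 5e6, spacing = 5e4) {
  g <- tibble::tibble(
    chrom = chroms, length = len, centromere = len / 2,
    is_sex = chroms %in% c("X", "Y")
  )
  attr(g, "spacing") <- spacing
  g
}

# Wide profile tibble from a named list of per-chromosome value matrices
# (probes x samples).
make_profiles <- function(values_by_chrom, spacing = 5e4,
                          sample_ids = NULL) {
  stopifnot(length(values_by_chrom) > 0)
  parts <- lapply(names(values_by_chrom), function(ch) {
    m <- values_by_chrom[[ch]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    ids <- sample_ids %||% paste0("S", seq_len(ncol(m)))
    out <- tibble::tibble(
      probe_id = paste0("p", ch, "_", seq_len(nrow(m))),
      chrom = ch,
      pos = (seq_len(nrow(m)) - 1) * spacing
    )
    for (i in seq_along(ids)) out[[ids[i]]] <- m[, i]
    out
  })
  dplyr::bind_rows(parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal helper used pervasively in fixtures
sample_cols <- function(x) tidycna:::sample_cols(x)

# Segment tibble builder: each row chrom/start/end/cn for one sample.
make_segments <- function(sample_id, chrom, start, end, cn, n_probes = NULL) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, start = start, end = end,
    n_probes = n_probes %||% pmax(1L, as.integer((end - start) / 5e4)),
    mean_cn = cn
  )
}

# One small shared cohort, simulated once per test run.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_mss = 60, n_msi = 12)
      co <- simulate_cohort(spec, seed = 42)
      seg <- classify_segments(cbs_segment(center_profiles(co$profiles), seed = 42))
      cache <<- list(cohort = co, segments = seg)
    }
    cache
  }
})
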