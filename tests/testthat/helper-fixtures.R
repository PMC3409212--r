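# Fixture builders shared by the module suites and the acceptance suite.

# Marker grid on one 100-probe chromosome.
mk2 <- function(m = 100, spacing = 5e4) {
  tibble::tibble(chrom = "1", pos = (seq_len(m) - 1) * spacing)
}

# Two-arm table for that chromosome.
arms1 <- function(len = 5e6) {
  tibble::tibble(
    chrom = "1", arm = c("p", "q"),
    start = c(0, len / 2), end = c(len / 2, len)
  )
}

# Wide gene-level CN tibble from a genes x samples matrix.
mk_cn <- function(m, chrom) {
  ids <- paste0("g", seq_len(nrow(m)))
  g <- tibble::tibble(
    gene_id = ids, symbol = ids, chrom = chrom,
    start = seq_len(nrow(m)) * 1e5, end = seq_len(nrow(m)) * 1e5 + 5e4
  )
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  dplyr::bind_cols(g, tibble::as_tibble(m))
}

# Cohort of tiled single-chromosome segment sets with focal amplicons
# planted in the first `carriers` samples (and optionally a second amplicon
# in the last `carriers`).
planted_cohort_segs <- function(n = 100, carriers = 20, where = c(2e6, 2.5e6),
                                second = NULL) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    base <- make_segments(paste0("S", i), "1", 0, 5e6, 2.0)
    rows <- list()
    if (i <= carriers) {
      rows <- c(rows, list(
        make_segments(paste0("S", i), "1", where[1], where[2], 4.0)
      ))
    }
    if (!is.null(second) && i > n - carriers) {
      rows <- c(rows, list(
        make_segments(paste0("S", i), "1", second[1], second[2], 4.0)
      ))
    }
    if (length(rows) == 0) {
      return(base)
    }
    occ <- dplyr::bind_rows(rows)
    free <- list()
    bounds <- sort(unique(c(0, occ$start, occ$end, 5e6)))
    for (k in seq_len(length(bounds) - 1)) {
      if (!any(occ$start <= bounds[k] & occ$end >= bounds[k + 1])) {
        free <- c(free, list(make_segments(
          paste0("S", i), "1", bounds[k], bounds[k + 1], 2.0
        )))
      }
    }
    dplyr::bind_rows(c(rows, free))
  })) %>% classify_segments()
}

# Two-group exponential survival with uniform censoring.
sim_surv <- function(n, hr = 1, p_carrier = 0.5, rate = log(2) / 60,
                     fu = c(60, 120)) {
  carrier <- runif(n) < p_carrier
  t_event <- rexp(n, rate * ifelse(carrier, hr, 1))
  t_cens <- runif(n, fu[1], fu[2])
  tibble::tibble(
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    carrier = carrier
  )
}
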