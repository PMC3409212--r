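# Synthetic cohort generator. Emulates the statistical structure of a large
# MSS/MSI stage-II/III colorectal cancer copy-number cohort: group-specific
# CNA burdens, recurrent arm-level gains/losses at fixed cohort frequencies,
# group-restricted focal deletions, high-amplitude focal amplicons, a cis
# dosage effect of DNA copy number on expression, and survival coupled to
# 20q-gain carriership. Ground truth (realized events and carriers) is
# recorded so every downstream stage can be tested against it.

#' Scale a real-genome locus onto a (miniature) genome
#'
#' Maps NCBI36 bp coordinates onto the scaled genome and enforces a minimum
#' event width so planted focal events stay detectable at the default probe
#' spacing.
#'
#' @param genome Genome table from [default_genome()].
#' @param chrom Chromosome label.
#' @param real_start,real_end NCBI36 coordinates (bp).
#' @param min_len Minimum width on the scaled genome (bp).
#' @return One-row tibble `chrom`, `start`, `end`.
#' @export
scaled_locus <- function(genome, chrom, real_start, real_end, min_len = 5e5) {
  chrom <- normalize_chrom(chrom)
  len <- genome$length[genome$chrom == chrom]
  if (length(len) == 0) abort(paste0("chromosome ", chrom, " not in genome"))
  ref <- HUMAN_CHROM_BP$length[HUMAN_CHROM_BP$chrom == chrom]
  scale <- len / ref
  mid <- (real_start + real_end) / 2 * scale
  half <- max(min_len, (real_end - real_start) * scale) / 2
  start <- max(0, min(mid - half, len - 2 * half))
  tibble(chrom = chrom, start = floor(start), end = floor(start + 2 * half))
}

#' Default planted-event catalog
#'
#' Recurrent events of a stage-II/III colorectal cohort: MSS arm-level gains
#' on 20q (72.5%), 13q (51.0%), chromosome 7 (41.8%) and 8q (33.1%), loss of
#' chromosome 18 (58.6%); focal deletions enriched in MSI tumors at
#' 16q23.1-like (24.2% MSI vs 7.1% MSS) and 20q11.1-like (24.4% vs 8.9%)
#' loci; a 3p14.2-like focal deletion enriched in stage III (24.3% vs 3.3%);
#' and two high-amplitude focal amplicons (12p13.33-like and 20q13.33-like).
#'
#' @param genome Genome table from [default_genome()].
#' @return Planted-event tibble with columns `name`, `chrom`, `start`, `end`,
#'   `kind`, `target_cn`, `frequency`, `restrict_var`, `restrict_level`.
#' @export
default_planted_events <- function(genome = default_genome()) {
  arm_ev <- function(name, region, kind, cn, freq, rv = "msi", rl = "MSS") {
    region %>% mutate(
      name = name, kind = kind, target_cn = cn, frequency = freq,
      restrict_var = rv, restrict_level = rl
    )
  }
  bind_rows(
    arm_ev("gain_20q", arm_interval(genome, "20q"), "gain", 3.0, 0.725),
    arm_ev("gain_13q", arm_interval(genome, "13q"), "gain", 3.0, 0.510),
    arm_ev("gain_7", arm_interval(genome, "7"), "gain", 3.0, 0.418),
    arm_ev("gain_8q", arm_interval(genome, "8q"), "gain", 3.0, 0.331),
    arm_ev("loss_18", arm_interval(genome, "18"), "loss", 1.0, 0.586),
    arm_ev(
      "del_16q23_msi", scaled_locus(genome, "16", 77231391, 77261567),
      "loss", 1.0, 0.242, "msi", "MSI"
    ),
    arm_ev(
      "del_16q23_mss", scaled_locus(genome, "16", 77231391, 77261567),
      "loss", 1.0, 0.071, "msi", "MSS"
    ),
    arm_ev(
      "del_20q11_msi", scaled_locus(genome, "20", 28118678, 28244164),
      "loss", 1.0, 0.244, "msi", "MSI"
    ),
    arm_ev(
      "del_20q11_mss", scaled_locus(genome, "20", 28118678, 28244164),
      "loss", 1.0, 0.089, "msi", "MSS"
    ),
    arm_ev(
      "del_3p14_iii", scaled_locus(genome, "3", 59700000, 61200000),
      "loss", 1.0, 0.243, "stage", "III"
    ),
    arm_ev(
      "del_3p14_ii", scaled_locus(genome, "3", 59700000, 61200000),
      "loss", 1.0, 0.033, "stage", "II"
    ),
    arm_ev(
      "amp_12p13", scaled_locus(genome, "12", 700000, 1300000),
      "amplification", 6.0, 0.10
    ),
    arm_ev(
      "amp_20q13", scaled_locus(genome, "20", 61440621, 61778204),
      "amplification", 6.0, 0.08
    )
  ) %>%
    select(
      "name", "chrom", "start", "end", "kind", "target_cn",
      "frequency", "restrict_var", "restrict_level"
    )
}

#' Place a regular synthetic gene model on a genome
#'
#' @param genome Genome table.
#' @param spacing Distance between gene starts (bp).
#' @param gene_length Gene length (bp).
#' @param include_sex Keep sex-chromosome genes (they are needed to exercise
#'   the "sex chromosomes ignored" rules downstream).
#' @return Gene tibble `gene_id`, `symbol`, `chrom`, `start`, `end`.
#' @export
simulate_gene_model <- function(genome, spacing = 6e5, gene_length = 2e5,
                                include_sex = TRUE) {
  genome %>%
    filter(include_sex | !.data$is_sex) %>%
    mutate(start = map(.data$length, ~ seq(1e5, .x - gene_length, by = spacing))) %>%
    select("chrom", "start") %>%
    unnest("start") %>%
    group_by(.data$chrom) %>%
    mutate(gene_id = paste0("g", .data$chrom, "_", row_number())) %>%
    ungroup() %>%
    transmute(
      gene_id = .data$gene_id, symbol = .data$gene_id,
      chrom = .data$chrom, start = .data$start, end = .data$start + gene_length
    )
}

#' Specify a synthetic cohort
#'
#' The defaults are the study conditions the package emulates: 269 MSS and 33
#' MSI tumors; per-tumor background CNA counts negative-binomially distributed
#' with moments 33.2 +/- 17.6 (MSS) and 10.2 +/- 6.5 (MSI); the planted-event
#' catalog of [default_planted_events()]; per-probe Gaussian noise of 0.25
#' copies (MAPD about 0.24, a typical passing FFPE sample); a cis expression model
#' `expr = intercept + slope * copy_number + noise`; and exponential survival
#' with a hazard ratio of 0.5 on overall survival for 20q-gain carriers,
#' censored uniformly over a 60-120 month follow-up window.
#'
#' @param n_mss,n_msi Group sample counts.
#' @param mss_burden,msi_burden Length-2 numeric `c(mean, sd)` of the
#'   per-tumor background event count.
#' @param stage_ii_frac Named fractions of stage-II samples per group
#'   (defaults reproduce 30/269 MSS stage II and a comparable MSI split).
#' @param planted_events Planted-event tibble (see
#'   [default_planted_events()]); may be `NULL` for a background-only cohort.
#' @param genome Genome table.
#' @param genes Gene model tibble for the expression/gene-level layers.
#' @param noise_sd Per-probe copy-number noise (copies).
#' @param bg_min_len,bg_gap Background-event minimum length and guard gap
#'   between events (bp); lengths are log-uniform between `bg_min_len` and
#'   the containing arm's length.
#' @param expr_intercept,expr_slope,expr_noise_sd Expression model (per-gene
#'   linear dosage response on absolute copy number).
#' @param os_rate,rfs_rate Baseline exponential hazards (per month).
#' @param survival_effects Tibble `event`, `endpoint` ("os"/"rfs"), `hr`:
#'   multiplicative hazards for carriers of planted events.
#' @param followup Length-2 numeric, censoring window in months.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mss = 269, n_msi = 33,
                        mss_burden = c(33.2, 17.6),
                        msi_burden = c(10.2, 6.5),
                        stage_ii_frac = c(MSS = 30 / 269, MSI = 4 / 33),
                        planted_events = default_planted_events(genome),
                        genome = default_genome(),
                        genes = simulate_gene_model(genome),
                        noise_sd = 0.25,
                        bg_min_len = 5e5, bg_gap = 2.5e5,
                        expr_intercept = 1.0, expr_slope = 0.5,
                        expr_noise_sd = 0.5,
                        os_rate = log(2) / 60, rfs_rate = log(2) / 48,
                        survival_effects = tibble(
                          event = "gain_20q", endpoint = "os", hr = 0.5
                        ),
                        followup = c(60, 120)) {
  spec <- list(
    n_mss = n_mss, n_msi = n_msi,
    mss_burden = mss_burden, msi_burden = msi_burden,
    stage_ii_frac = stage_ii_frac,
    planted_events = planted_events, genome = genome, genes = genes,
    noise_sd = noise_sd, bg_min_len = bg_min_len, bg_gap = bg_gap,
    expr_intercept = expr_intercept, expr_slope = expr_slope,
    expr_noise_sd = expr_noise_sd,
    os_rate = os_rate, rfs_rate = rfs_rate,
    survival_effects = survival_effects, followup = followup
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_mss <= 0 || spec$n_msi < 0) abort("sample counts must be positive")
  for (b in list(spec$mss_burden, spec$msi_burden)) {
    if (b[1] <= 0) abort("burden mean must be > 0")
    if (b[2] <= 0) abort("burden sd must be > 0")
  }
  if (spec$noise_sd < 0) abort("noise_sd must be >= 0")
  ev <- spec$planted_events
  if (!is.null(ev) && nrow(ev) > 0) {
    if (any(ev$frequency < 0 | ev$frequency > 1)) {
      abort("planted frequencies must be in [0, 1]")
    }
    bins <- cna_bins()
    kind_class <- c(
      gain = "gained", amplification = "amplified",
      loss = "deleted", homozygous_deletion = "homodeleted"
    )
    got <- as.character(classify_cn(ev$target_cn, bins))
    want <- kind_class[ev$kind]
    if (any(got != want)) {
      bad <- ev$name[got != want][1]
      abort(paste0(
        "planted event '", bad,
        "' has a target copy number inconsistent with its kind under the bin thresholds"
      ))
    }
    # feasibility: the burden mean must exceed the expected planted count
    for (grp in c("MSS", "MSI")) {
      expected <- sum(ev$frequency[is.na(ev$restrict_var) |
        ev$restrict_var != "msi" |
        ev$restrict_level == grp])
      mean_b <- if (grp == "MSS") spec$mss_burden[1] else spec$msi_burden[1]
      if (mean_b < expected) {
        abort(paste0(
          "infeasible burden for ", grp, ": mean ", mean_b,
          " < expected planted events ", round(expected, 2)
        ))
      }
    }
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(
    "<cohort_spec> ", x$n_mss, " MSS + ", x$n_msi, " MSI samples, ",
    nrow(x$planted_events %||% tibble()), " planted events, noise_sd ",
    x$noise_sd, "\n",
    sep = ""
  )
  invisible(x)
}

# Negative-binomial count matched to (mean, sd), truncated at 0; Poisson
# fallback when the requested variance is sub-Poisson.
rcount_moments <- function(n, mean, sd) {
  v <- sd^2
  if (v > mean) {
    size <- mean^2 / (v - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

simulate_clinical <- function(spec) {
  n <- spec$n_mss + spec$n_msi
  sample_id <- sprintf("S%03d", seq_len(n))
  msi <- c(rep("MSS", spec$n_mss), rep("MSI", spec$n_msi))
  n2_mss <- round(spec$n_mss * spec$stage_ii_frac[["MSS"]])
  n2_msi <- round(spec$n_msi * spec$stage_ii_frac[["MSI"]])
  stage <- c(
    rep(c("II", "III"), c(n2_mss, spec$n_mss - n2_mss)),
    rep(c("II", "III"), c(n2_msi, spec$n_msi - n2_msi))
  )
  braf <- ifelse(runif(n) < ifelse(msi == "MSI", 0.40, 0.08), "mut", "wt")
  kras <- ifelse(runif(n) < 0.40, "mut", "wt")
  brafm_like <- ifelse(braf == "mut" | runif(n) < 0.10, "BRAFm-like", "non-BRAFm-like")
  tibble(
    sample_id = sample_id, msi = msi, stage = stage,
    braf = braf, kras = kras, brafm_like = brafm_like
  )
}

# Draw planted-event carrier indicators: independent Bernoulli per event,
# restricted to the eligible group.
draw_carriers <- function(ev, clinical) {
  n <- nrow(clinical)
  carriers <- matrix(FALSE, n, nrow(ev), dimnames = list(clinical$sample_id, ev$name))
  for (j in seq_len(nrow(ev))) {
    eligible <- rep(TRUE, n)
    if (!is.na(ev$restrict_var[j])) {
      eligible <- clinical[[ev$restrict_var[j]]] == ev$restrict_level[j]
    }
    carriers[, j] <- eligible & runif(n) < ev$frequency[j]
  }
  carriers
}

# Gaussian-copula carriers with target pairwise correlations among the
# planted events' latent indicators; marginal frequencies preserved.
draw_carriers_copula <- function(ev, clinical, rho) {
  k <- nrow(ev)
  if (!isTRUE(all.equal(rho, t(rho)))) abort("rho_matrix must be symmetric")
  eig <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(eig) < -1e-8) abort("rho_matrix is not positive semi-definite")
  n <- nrow(clinical)
  z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = rho)
  if (k == 1) z <- matrix(z, ncol = 1)
  carriers <- matrix(FALSE, n, k, dimnames = list(clinical$sample_id, ev$name))
  for (j in seq_len(k)) {
    eligible <- rep(TRUE, n)
    if (!is.na(ev$restrict_var[j])) {
      eligible <- clinical[[ev$restrict_var[j]]] == ev$restrict_level[j]
    }
    carriers[, j] <- eligible & z[, j] <= qnorm(ev$frequency[j])
  }
  carriers
}

# Place n_bg background events on the autosomes of one sample, avoiding the
# planted intervals and each other (guard gap), by rejection sampling with
# bounded retries (compiled core). Returns a base data frame of placed
# events.
place_background <- function(n_bg, arms, blocked, bg_min_len, bg_gap,
                             max_tries = 60L) {
  if (n_bg == 0) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(), delta = numeric()
    ))
  }
  chrom_idx <- match(arms$chrom, CHROM_LEVELS)
  m <- .place_background(
    as.integer(n_bg), arms$start, arms$end, chrom_idx,
    blocked$start, blocked$end, match(blocked$chrom, CHROM_LEVELS),
    bg_min_len, bg_gap, as.integer(max_tries)
  )
  data.frame(
    chrom = arms$chrom[m[, 1]], start = m[, 2], end = m[, 3],
    delta = sample(c(-1, 1), nrow(m), replace = TRUE)
  )
}

#' Simulate a cohort with recorded ground truth
#'
#' Generates probe-level copy-number profiles, a clinical table, an
#' expression matrix and a ground-truth record from a [cohort_spec()].
#' Planted events are carried independently at their cohort frequencies
#' (within their group restriction); background events are drawn so the
#' per-tumor event count matches the group's burden moments, with lengths
#' log-uniform between `bg_min_len` and the containing arm, placed away from
#' planted loci and from each other so the drawn count is the realized count.
#' Overlapping events add in copy number, floored at zero. Expression follows
#' the linear dosage model; survival is exponential with per-event hazard
#' ratios and uniform censoring over the follow-up window.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; all randomness is derived from it.
#' @param carriers Optional pre-drawn carrier matrix (used by
#'   [simulate_correlated_events()]).
#' @return A `cna_cohort` list: `profiles` (wide probe tibble), `clinical`,
#'   `expression` (wide gene tibble), `truth` (list: `events`,
#'   `sample_events`, `counts`), plus the `spec`.
#' @export
simulate_cohort <- function(spec, seed = 1L, carriers = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  with_seed(derive_seed(seed, "cohort"), {
    genome <- spec$genome
    probes <- probe_map(genome)
    clinical <- simulate_clinical(spec)
    n <- nrow(clinical)
    ev <- spec$planted_events %||%
      tibble(
        name = character(), chrom = character(), start = numeric(),
        end = numeric(), kind = character(), target_cn = numeric(),
        frequency = numeric(), restrict_var = character(),
        restrict_level = character()
      )
    if (is.null(carriers)) {
      carriers <- draw_carriers(ev, clinical)
    }

    arms <- chrom_arms(genome) %>% filter(!is_sex_chrom(.data$chrom))
    blocked <- ev %>% select("chrom", "start", "end")
    burden_mean <- ifelse(clinical$msi == "MSS", spec$mss_burden[1], spec$msi_burden[1])
    burden_sd <- ifelse(clinical$msi == "MSS", spec$mss_burden[2], spec$msi_burden[2])
    n_planted <- if (nrow(ev) > 0) rowSums(carriers) else rep(0L, n)
    total_target <- numeric(n)
    for (g in unique(clinical$msi)) {
      idx <- clinical$msi == g
      total_target[idx] <- rcount_moments(sum(idx), burden_mean[idx][1], burden_sd[idx][1])
    }
    n_bg <- pmax(total_target - n_planted, 0)

    # per-sample realized event list (planted + background), assembled as
    # plain vectors for speed
    ev_delta <- if (nrow(ev) > 0) ev$target_cn - 2 else numeric(0)
    acc <- vector("list", n)
    for (i in seq_len(n)) {
      pl <- if (nrow(ev) > 0) which(carriers[i, ]) else integer(0)
      bg_i <- place_background(
        n_bg[i], arms, blocked, spec$bg_min_len, spec$bg_gap
      )
      n_i <- length(pl) + nrow(bg_i)
      if (n_i == 0) next
      acc[[i]] <- data.frame(
        sample_id = rep(clinical$sample_id[i], n_i),
        name = c(
          ev$name[pl],
          if (nrow(bg_i) > 0) paste0("bg_", i, "_", seq_len(nrow(bg_i))) else character(0)
        ),
        chrom = c(ev$chrom[pl], bg_i$chrom),
        start = c(ev$start[pl], bg_i$start),
        end = c(ev$end[pl], bg_i$end),
        delta = c(ev_delta[pl], bg_i$delta)
      )
    }
    sample_events <- as_tibble(do.call(rbind, acc[!vapply(acc, is.null, logical(1))]))
    if (nrow(sample_events) == 0) {
      sample_events <- tibble(
        sample_id = character(), name = character(), chrom = character(),
        start = numeric(), end = numeric(), delta = numeric()
      )
    }

    # probe-level profiles: diploid + event deltas + noise, floored at 0.
    # The probe grid is regular, so event rows are index arithmetic.
    cn <- matrix(2, nrow(probes), n, dimnames = list(probes$probe_id, clinical$sample_id))
    sidx <- match(sample_events$sample_id, clinical$sample_id)
    spacing <- attr(genome, "spacing") %||% 5e4
    n_per_chrom <- table(factor(probes$chrom, levels = unique(probes$chrom)))
    chrom_offset <- setNames(
      cumsum(c(0, head(as.numeric(n_per_chrom), -1))),
      names(n_per_chrom)
    )
    for (r in seq_len(nrow(sample_events))) {
      off <- chrom_offset[[sample_events$chrom[r]]]
      k1 <- ceiling(sample_events$start[r] / spacing) + 1
      k2 <- min(
        ceiling(sample_events$end[r] / spacing),
        n_per_chrom[[sample_events$chrom[r]]]
      )
      if (k1 > k2) next
      rows <- (off + k1):(off + k2)
      cn[rows, sidx[r]] <- cn[rows, sidx[r]] + sample_events$delta[r]
    }
    if (spec$noise_sd > 0) {
      cn <- cn + matrix(rnorm(length(cn), 0, spec$noise_sd), nrow(cn))
    }
    cn[cn < 0] <- 0
    profiles <- bind_cols(probes, as_tibble(cn))

    # true gene-level copy number (noiseless) -> expression dosage model
    genes <- spec$genes
    gene_cn_true <- matrix(
      2, nrow(genes), n,
      dimnames = list(genes$gene_id, clinical$sample_id)
    )
    gmid <- (genes$start + genes$end) / 2
    gene_rows <- split(seq_len(nrow(genes)), genes$chrom)
    for (r in seq_len(nrow(sample_events))) {
      cand <- gene_rows[[sample_events$chrom[r]]]
      rows <- cand[gmid[cand] >= sample_events$start[r] &
        gmid[cand] < sample_events$end[r]]
      gene_cn_true[rows, sidx[r]] <- gene_cn_true[rows, sidx[r]] + sample_events$delta[r]
    }
    gene_cn_true[gene_cn_true < 0] <- 0
    expr <- spec$expr_intercept + spec$expr_slope * gene_cn_true +
      matrix(rnorm(length(gene_cn_true), 0, spec$expr_noise_sd), nrow(gene_cn_true))
    expression <- bind_cols(genes["gene_id"], as_tibble(expr))

    # survival: exponential hazards with per-event HRs, uniform censoring
    hr_tbl <- spec$survival_effects %||% tibble(event = character(), endpoint = character(), hr = numeric())
    surv <- map(c(os = "os", rfs = "rfs"), function(ep) {
      rate <- rep(if (ep == "os") spec$os_rate else spec$rfs_rate, n)
      eff <- hr_tbl %>% filter(.data$endpoint == ep, .data$event %in% colnames(carriers))
      for (r in seq_len(nrow(eff))) {
        rate <- rate * ifelse(carriers[, eff$event[r]], eff$hr[r], 1)
      }
      t_event <- rexp(n, rate)
      t_cens <- runif(n, spec$followup[1], spec$followup[2])
      tibble(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
    })
    clinical <- clinical %>% mutate(
      os_time = surv$os$time, os_event = surv$os$event,
      rfs_time = surv$rfs$time, rfs_event = surv$rfs$event
    )

    # ground truth
    realized <- if (nrow(ev) > 0) {
      ev %>% mutate(
        n_carriers = colSums(carriers),
        carrier_fraction_planted = .data$frequency,
        carrier_fraction_realized = map_dbl(.data$name, function(nm) {
          j <- which(colnames(carriers) == nm)
          eligible <- rep(TRUE, n)
          if (!is.na(ev$restrict_var[match(nm, ev$name)])) {
            eligible <- clinical[[ev$restrict_var[match(nm, ev$name)]]] ==
              ev$restrict_level[match(nm, ev$name)]
          }
          mean(carriers[eligible, j])
        }),
        carrier_ids = map(.data$name, ~ clinical$sample_id[carriers[, .x]])
      )
    } else {
      ev
    }
    counts <- sample_events %>%
      count(.data$sample_id, name = "n_events") %>%
      right_join(clinical["sample_id"], by = "sample_id") %>%
      mutate(n_events = coalesce(.data$n_events, 0L)) %>%
      mutate(
        n_drawn = total_target[match(.data$sample_id, clinical$sample_id)],
        n_planted = n_planted[match(.data$sample_id, clinical$sample_id)]
      )

    structure(
      list(
        profiles = profiles, clinical = clinical, expression = expression,
        truth = list(
          events = realized, sample_events = sample_events,
          counts = counts, carriers = carriers
        ),
        spec = spec
      ),
      class = "cna_cohort"
    )
  })
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat(
    "<cna_cohort> ", ncol(x$profiles) - 3, " samples x ", nrow(x$profiles),
    " probes; ", nrow(x$truth$sample_events), " realized events\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a cohort with correlated planted-event carriers
#'
#' Identical to [simulate_cohort()] except that planted-event carrier
#' indicators are drawn from a Gaussian copula with the requested pairwise
#' latent correlations, preserving each event's marginal frequency. Used to
#' emulate co-selection of aberrations at unlinked loci (e.g. 20q gain with
#' 8q gain).
#'
#' @param spec A [cohort_spec()].
#' @param rho_matrix Symmetric positive semi-definite latent correlation
#'   matrix, one row/column per planted event (in `spec$planted_events`
#'   order).
#' @param seed Integer seed.
#' @return A `cna_cohort`, as [simulate_cohort()].
#' @export
simulate_correlated_events <- function(spec, rho_matrix, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  ev <- spec$planted_events
  if (is.null(ev) || nrow(ev) == 0) abort("spec has no planted events")
  if (!is.matrix(rho_matrix) || nrow(rho_matrix) != nrow(ev) ||
    ncol(rho_matrix) != nrow(ev)) {
    abort("rho_matrix must be square with one row per planted event")
  }
  carriers <- with_seed(derive_seed(seed, "carriers"), {
    draw_carriers_copula(ev, with_seed(
      derive_seed(seed, "cohort"),
      simulate_clinical(spec)
    ), rho_matrix)
  })
  simulate_cohort(spec, seed = seed, carriers = carriers)
}
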