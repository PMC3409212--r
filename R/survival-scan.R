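# Kaplan-Meier / log-rank association of recurrent regions with outcome.

#' Two-group Kaplan-Meier / log-rank comparison
#'
#' Standard two-group log-rank test (chi-square on 1 df) with per-group
#' Kaplan-Meier estimates. The direction is read from the sign of
#' observed-minus-expected events in carriers: fewer events than expected
#' means carriers fare better.
#'
#' @param data Data frame with time, event and group columns.
#' @param time_col,event_col Column names (strings) of the follow-up time
#'   and the 0/1 event indicator.
#' @param group_col Column name of the logical/two-level carrier indicator.
#' @return A `cna_logrank` object; `glance()` gives the test summary,
#'   `tidy()` the KM curve coordinates.
#' @export
km_logrank <- function(data, time_col = "time", event_col = "event",
                       group_col = "carrier") {
  check_columns(data, c(time_col, event_col, group_col))
  d <- tibble(
    time = data[[time_col]],
    event = as.integer(data[[event_col]]),
    group = data[[group_col]]
  ) %>% filter(!is.na(.data$time), !is.na(.data$event), !is.na(.data$group))
  lv <- sort(unique(as.character(d$group)))
  if (length(lv) != 2) abort("km_logrank needs exactly two non-empty groups")
  if (sum(d$event) < 1) abort("no events observed")
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = d
  )
  p <- stats::pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  # carriers are the TRUE / second-sorted level
  carrier_level <- if (all(lv %in% c("FALSE", "TRUE"))) "TRUE" else lv[2]
  ci <- which(sub("^group=", "", names(sd_fit$n)) == carrier_level)
  direction <- if (sd_fit$obs[ci] < sd_fit$exp[ci]) "carrier_better" else "carrier_worse"
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  curves <- tibble(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, surv = sf$surv, n_risk = sf$n.risk, n_event = sf$n.event
  )
  structure(
    list(
      p_value = p, chisq = unname(sd_fit$chisq), direction = direction,
      n = as.integer(sd_fit$n), obs = sd_fit$obs, exp = sd_fit$exp,
      carrier_level = carrier_level, curves = curves
    ),
    class = "cna_logrank"
  )
}

#' @export
print.cna_logrank <- function(x, ...) {
  cat(
    "<cna_logrank> chisq = ", round(x$chisq, 2), ", p = ",
    signif(x$p_value, 3), " (", x$direction, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `cna_logrank` object.
#' @param ... Unused.
#' @export
tidy.cna_logrank <- function(x, ...) x$curves

#' @rdname km_logrank
#' @export
glance.cna_logrank <- function(x, ...) {
  tibble(
    chisq = x$chisq, p_value = x$p_value, direction = x$direction,
    n_carrier = x$n[which(x$carrier_level == sort(unique(x$curves$group)))],
    n_total = sum(x$n)
  )
}

# Carrier indicator of a directed region: the sample's covering segment at
# the region midpoint matches the region direction.
region_carriers <- function(segments, chrom, start, end, direction) {
  if (!"direction" %in% names(segments)) segments <- classify_segments(segments)
  sgn <- if (direction %in% c("gain", "amplification")) 1 else -1
  mid <- (start + end) / 2
  seg_ch <- segments[segments$chrom == chrom, ]
  hit <- seg_ch[seg_ch$start <= mid & seg_ch$end > mid & sign(seg_ch$direction) == sgn, ]
  unique(hit$sample_id)
}

#' Survival scan over recurrent regions
#'
#' For every region (MCRs and/or focal peaks), endpoint and stage stratum,
#' carriers (samples whose copy-number class at the region matches its
#' direction) are compared to non-carriers with [km_logrank()]. The
#' unadjusted log-rank p is reported with the conventional `p < p_cutoff`
#' flag, together with a Benjamini-Hochberg column (adjusted within each
#' endpoint-stratum scan) since the scan is heavily multiple.
#'
#' @param regions Tibble with `chrom`, `start`, `end`, `direction` (MCR or
#'   peak tables work directly).
#' @param segments Classified cohort segments.
#' @param clinical Clinical tibble with `sample_id`, `stage` and
#'   `<endpoint>_time` / `<endpoint>_event` columns.
#' @param endpoints Endpoints to scan (default OS and RFS).
#' @param strata Stage strata; "combined" pools all samples.
#' @param p_cutoff Significance cutoff on the unadjusted p (default 0.01).
#' @return A `cna_survival_scan` tibble: `region`, `chrom`, `start`, `end`,
#'   `direction`, `endpoint`, `stratum`, `carrier_n`, `noncarrier_n`,
#'   `logrank_p`, `effect` (carrier_better/worse), `significant`, `bh_q`.
#' @export
scan_regions <- function(regions, segments, clinical,
                         endpoints = c("os", "rfs"),
                         strata = c("II", "III", "combined"),
                         p_cutoff = 0.01) {
  check_columns(regions, c("chrom", "start", "end", "direction"), "regions")
  check_columns(clinical, c("sample_id", "stage"), "clinical")
  if (!"direction" %in% names(segments)) segments <- classify_segments(segments)
  out <- list()
  for (r in seq_len(nrow(regions))) {
    carriers <- region_carriers(
      segments, regions$chrom[r], regions$start[r], regions$end[r],
      regions$direction[r]
    )
    for (ep in endpoints) {
      tcol <- paste0(ep, "_time")
      ecol <- paste0(ep, "_event")
      if (!all(c(tcol, ecol) %in% names(clinical))) next
      for (st in strata) {
        cl <- if (st == "combined") clinical else clinical[clinical$stage == st, ]
        cl <- cl %>% mutate(carrier = .data$sample_id %in% carriers)
        n_car <- sum(cl$carrier)
        if (n_car == 0 || n_car == nrow(cl)) {
          warn(paste0(
            "region ", regions$chrom[r], ":", regions$start[r], "-",
            regions$end[r], " (", regions$direction[r], "), ", ep, "/", st,
            ": degenerate carrier split; skipped"
          ))
          next
        }
        if (sum(cl[[ecol]], na.rm = TRUE) < 1) {
          warn(paste0("stratum ", st, " has no ", ep, " events; skipped"))
          next
        }
        fit <- km_logrank(cl, tcol, ecol, "carrier")
        out[[length(out) + 1]] <- tibble(
          region = paste0(
            regions$chrom[r], ":", regions$start[r], "-", regions$end[r]
          ),
          chrom = regions$chrom[r], start = regions$start[r],
          end = regions$end[r], direction = regions$direction[r],
          endpoint = ep, stratum = st,
          carrier_n = n_car, noncarrier_n = nrow(cl) - n_car,
          logrank_p = fit$p_value, effect = fit$direction
        )
      }
    }
  }
  res <- if (length(out) == 0) {
    tibble(
      region = character(), chrom = character(), start = numeric(),
      end = numeric(), direction = character(), endpoint = character(),
      stratum = character(), carrier_n = integer(), noncarrier_n = integer(),
      logrank_p = numeric(), effect = character()
    )
  } else {
    list_rbind(out)
  }
  new_tidycna_tbl(
    res %>%
      group_by(.data$endpoint, .data$stratum) %>%
      mutate(bh_q = p.adjust(.data$logrank_p, "BH")) %>%
      ungroup() %>%
      mutate(significant = .data$logrank_p < p_cutoff),
    "cna_survival_scan"
  )
}
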