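# ggplot2 presentation layer: one autoplot method per main result type.

#' Plot a genome-wide gain/loss frequency track
#'
#' Gain frequency above the axis, loss frequency (negated) below, faceted by
#' chromosome — the conventional cohort frequency plot.
#'
#' @param object A [frequency_track()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cna_freq_track <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(chrom = chrom_factor(.data$chrom))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$gain_freq), fill = "#2166ac") +
    ggplot2::geom_area(ggplot2::aes(y = -.data$loss_freq), fill = "#b2182b") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::scale_y_continuous(limits = c(-1, 1), name = "loss  |  gain fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.spacing.x = ggplot2::unit(0.5, "pt"),
      panel.grid = ggplot2::element_blank()
    ) +
    ggplot2::labs(x = "chromosome")
}

#' Plot G-score significance along the genome
#'
#' @param object A [gscore_and_q()] result.
#' @param q_cutoff Reference line for the significance cutoff.
#' @param ... Unused.
#' @return A ggplot of -log10(q) per marker, faceted by chromosome.
#' @export
autoplot.cna_gscore <- function(object, q_cutoff = 0.25, ...) {
  df <- as_tibble(object) %>%
    mutate(
      chrom = chrom_factor(.data$chrom),
      neglog_q = -log10(pmax(.data$q, 1e-12))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$pos, y = .data$neglog_q, color = .data$direction
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(q_cutoff), linetype = 2) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::scale_color_manual(values = c(
      amplification = "#b2182b", deletion = "#2166ac"
    )) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.spacing.x = ggplot2::unit(0.5, "pt"),
      panel.grid = ggplot2::element_blank()
    ) +
    ggplot2::labs(x = "chromosome", y = "-log10 q")
}

#' Plot Kaplan-Meier curves of a two-group comparison
#'
#' @param object A [km_logrank()] result.
#' @param ... Unused.
#' @return A ggplot of the step survival curves.
#' @export
autoplot.cna_logrank <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(
    x = .data$time, y = .data$surv, color = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "time", y = "survival probability",
      subtitle = paste0(
        "log-rank p = ", signif(object$p_value, 3), " (", object$direction, ")"
      )
    )
}

#' Log-log degree-distribution plot
#'
#' @param object A [degree_distribution()] result.
#' @param ... Unused.
#' @return A ggplot of log10(count) vs log10(degree) with the OLS fit.
#' @export
autoplot.cna_degree <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(
    x = log10(.data$degree), y = log10(.data$count)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "log10 degree", y = "log10 gene count",
      subtitle = paste0("slope ", round(object$slope, 2))
    )
}

#' Plot one sample's copy-number profile with its segments
#'
#' @param profiles Wide probe tibble.
#' @param segments Segment tibble (optional overlay).
#' @param sample_id Sample column to plot.
#' @return A ggplot of probe copy number along the genome.
#' @export
plot_profile <- function(profiles, segments = NULL, sample_id) {
  df <- profiles %>%
    select("chrom", "pos", cn = all_of(sample_id)) %>%
    mutate(chrom = chrom_factor(.data$chrom))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$cn)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.4) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.spacing.x = ggplot2::unit(0.5, "pt"),
      panel.grid = ggplot2::element_blank()
    ) +
    ggplot2::labs(x = "chromosome", y = "copy number", title = sample_id)
  if (!is.null(segments)) {
    seg <- segments %>%
      filter(.data$sample_id == !!sample_id) %>%
      mutate(chrom = chrom_factor(.data$chrom))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$mean_cn, yend = .data$mean_cn
      ),
      color = "#b2182b", linewidth = 0.8
    )
  }
  p
}
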