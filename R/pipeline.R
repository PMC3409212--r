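# End-to-end orchestration: qc -> center -> segment -> classify ->
# {recurrence, focal, comparisons, clustering, gene-level, concordance,
# enrichment, network, survival} with one config and stage-scoped seeds.

#' Pipeline configuration with conventional defaults
#'
#' Collects every stage threshold in one place. Defaults follow the
#' conventional analysis settings for MIP copy-number cohorts: MAPD cutoff
#' 0.6; CBS p cutoff 1e-6; bins 0.5 / 1.7 / 2.3 / 3.8 copies; MCR frequency
#' threshold 10% with STAC p < 0.01; GISTIC-style q < 0.25; group
#' comparisons at > 15 percentage points and Fisher p < 0.01; three
#' clusters; correlation-edge threshold |r| >= 0.3; pathway set sizes
#' 10-500 with a 100-permutation FDR; survival p < 0.01.
#'
#' @param ... Overrides of the defaults listed in the source.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mapd_cutoff = 0.6,
    cbs_alpha = 1e-6, cbs_n_perm = 10000, min_probes = 3, merge_tol = 0.3,
    use_ranks = FALSE,
    bins = cna_bins(),
    mcr_min_freq = 0.10, stac_n_perm = 1000, stac_p = 0.01,
    gistic_n_perm = 1000, gistic_q = 0.25,
    compare_diff = 15, compare_p = 0.01,
    cluster_k = 3,
    r_threshold = 0.3, network_n_perm = 20,
    perm_fdr_n = 100, set_size = c(10, 500),
    survival_p = 0.01,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full CNA pipeline
#'
#' Executes every stage on a cohort (either a simulated `cna_cohort` or
#' profiles/clinical read from files), writes one tab-delimited result table
#' per stage into `out_dir` (with `#` metadata headers) and returns the
#' results invisibly. Deterministic given the config seed.
#'
#' @param profiles Wide probe tibble, or a `cna_cohort` (whose profiles,
#'   clinical, expression and gene model are then used).
#' @param clinical Clinical tibble (ignored when `profiles` is a cohort).
#' @param genes Optional gene model tibble.
#' @param expression Optional wide expression tibble.
#' @param gene_sets Optional gene-set tibble from [read_gmt()].
#' @param genome Genome table supplying arm boundaries (defaults to
#'   [default_genome()]).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return (Invisibly) a named list of per-stage results plus a `manifest`
#'   tibble of stage row counts and seeds.
#' @export
run_pipeline <- function(profiles, clinical = NULL, genes = NULL,
                         expression = NULL, gene_sets = NULL,
                         genome = default_genome(),
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(profiles, "cna_cohort")) {
    cohort <- profiles
    profiles <- cohort$profiles
    clinical <- clinical %||% cohort$clinical
    expression <- expression %||% cohort$expression
    genes <- genes %||% cohort$spec$genes
    genome <- cohort$spec$genome
  }
  res <- list()

  res$qc <- run_stage("qc", qc_mapd(profiles, config$mapd_cutoff))
  kept <- res$qc$sample_id[res$qc$pass]
  if (length(kept) == 0) {
    abort(paste0(
      "pipeline stage 'qc' failed: all samples exceed MAPD cutoff ",
      config$mapd_cutoff
    ))
  }
  profiles <- profiles[c("probe_id", "chrom", "pos", kept)]
  if (!is.null(clinical)) clinical <- clinical[clinical$sample_id %in% kept, ]

  profiles <- run_stage("center", center_profiles(profiles))
  segments <- run_stage("segment", cbs_segment(
    profiles,
    alpha = config$cbs_alpha, n_perm = config$cbs_n_perm,
    min_probes = config$min_probes, merge_tol = config$merge_tol,
    use_ranks = config$use_ranks, seed = config$seed
  ))
  segments <- run_stage("classify", classify_segments(segments, config$bins))
  res$segments <- segments

  res$event_counts <- run_stage("count", count_events(segments))
  if (!is.null(clinical) && "msi" %in% names(clinical) &&
    all(table(clinical$msi) >= 2) && n_distinct(clinical$msi) == 2) {
    res$burden_test <- run_stage("burden", burden_ttest(
      res$event_counts %>% inner_join(clinical, by = "sample_id"),
      group_col = "msi"
    ))
  }

  markers <- profiles %>% select("chrom", "pos")
  res$track <- run_stage("track", frequency_track(segments, markers))
  res$mcrs <- run_stage("mcr", find_mcrs(
    res$track, segments,
    min_freq = config$mcr_min_freq, n_perm = config$stac_n_perm,
    p_cutoff = config$stac_p, seed = config$seed
  ))

  res$gscore <- run_stage("gistic", {
    focal <- focal_component(segments, markers, chrom_arms(genome))
    gscore_and_q(focal, n_perm = config$gistic_n_perm, seed = config$seed)
  })
  res$peaks <- run_stage("peaks", call_peaks(
    res$gscore,
    q_cutoff = config$gistic_q, genes = genes
  ))

  if (!is.null(clinical)) {
    for (grp in c("msi", "stage")) {
      if (!grp %in% names(clinical) || n_distinct(clinical[[grp]]) != 2) next
      groups <- clinical %>% select("sample_id", group = all_of(grp))
      for (dir in c("gain", "loss")) {
        res[[paste0("compare_", grp, "_", dir)]] <- run_stage(
          paste0("compare_", grp),
          compare_frequencies(
            segments, markers, groups,
            direction = dir,
            diff_threshold = config$compare_diff,
            p_threshold = config$compare_p
          )
        )
      }
    }
  }

  if (!is.null(genes)) {
    res$gene_cn <- run_stage("gene_cn", gene_level_cn(segments, genes))
    auto_cn <- res$gene_cn %>% filter(!is_sex_chrom(.data$chrom))
    complete <- stats::complete.cases(auto_cn[sample_cols(auto_cn)])
    auto_cn <- auto_cn[complete, ]
    if (nrow(auto_cn) >= 2 &&
      config$cluster_k <= length(sample_cols(auto_cn))) {
      res$clusters <- run_stage(
        "cluster",
        cluster_cohort(auto_cn, k = config$cluster_k)
      )
      if (!is.null(clinical)) {
        lab_cols <- intersect(
          c("msi", "stage", "braf", "kras", "brafm_like"), names(clinical)
        )
        res$cluster_enrichment <- run_stage("enrich_labels", label_enrichment(
          res$clusters, clinical %>% select("sample_id", all_of(lab_cols))
        ))
      }
    }
    if (!is.null(expression)) {
      res$concordance <- run_stage(
        "concordance",
        cis_concordance(res$gene_cn, expression, bins = config$bins)
      )
    }
    if (!is.null(gene_sets) && nrow(res$peaks) > 0) {
      amp_genes <- unique(unlist(
        res$peaks$genes[res$peaks$direction == "amplification"]
      ))
      if (length(amp_genes) > 0) {
        res$pathways <- run_stage("pathways", pathway_enrichment(
          amp_genes, gene_sets,
          universe = genes$gene_id,
          n_perm = config$perm_fdr_n, size_bounds = config$set_size,
          seed = config$seed
        ))
      }
    }
    res$network <- run_stage("network", {
      corr <- pairwise_correlations(auto_cn)
      graph <- edge_graph(corr, config$r_threshold, unlinked_only = TRUE)
      list(
        edges = igraph::as_data_frame(graph, "edges") %>% as_tibble(),
        degrees = degree_distribution(graph),
        null = randomization_null(
          auto_cn,
          n_perm = config$network_n_perm,
          r_threshold = config$r_threshold, seed = config$seed
        )
      )
    })
  }

  if (!is.null(clinical) && all(c("os_time", "os_event") %in% names(clinical))) {
    regions <- bind_rows(
      res$mcrs %>% select("chrom", "start", "end", "direction"),
      res$peaks %>% select("chrom", "start", "end", "direction")
    )
    if (nrow(regions) > 0) {
      res$survival <- run_stage("survival", suppressWarnings(scan_regions(
        regions, segments, clinical,
        p_cutoff = config$survival_p
      )))
    }
  }

  counts <- map_int(res, function(x) {
    if (is.data.frame(x)) nrow(x) else NA_integer_
  })
  res$manifest <- tibble(
    stage = names(counts), rows = unname(counts), seed = config$seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- c(seed = config$seed, package = "tidycna")
    for (nm in names(res)) {
      x <- res[[nm]]
      if (nm == "network") {
        write_result_table(x$edges, file.path(out_dir, "network_edges.tsv"), meta)
        write_result_table(x$degrees$degrees, file.path(out_dir, "network_degrees.tsv"), meta)
        next
      }
      if (nm == "gscore") x <- as_tibble(x)
      if (is.data.frame(x)) {
        write_result_table(
          x %>% select(-any_of("class_summary")),
          file.path(out_dir, paste0(nm, ".tsv")), meta
        )
      }
    }
    write_seg(segments, file.path(out_dir, "segments.seg"))
  }
  invisible(res)
}
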