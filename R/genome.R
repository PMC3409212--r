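# Miniature genome used by the synthetic cohort generator and the focal
# (arm-level) decomposition. Chromosome proportions follow the human genome
# (NCBI build 36 sizes scaled down), so arm-level and focal events keep their
# relative scales while a full cohort simulates in seconds.

# Approximate NCBI36 chromosome lengths and centromere midpoints (bp).
HUMAN_CHROM_BP <- tibble::tribble(
  ~chrom, ~length, ~centromere,
  "1", 247249719, 124300000,
  "2", 242951149, 93300000,
  "3", 199501827, 91700000,
  "4", 191273063, 50400000,
  "5", 180857866, 47700000,
  "6", 170899992, 60500000,
  "7", 158821424, 59100000,
  "8", 146274826, 45200000,
  "9", 140273252, 51400000,
  "10", 135374737, 40300000,
  "11", 134452384, 52900000,
  "12", 132349534, 35400000,
  "13", 114142980, 17900000,
  "14", 106368585, 17600000,
  "15", 100338915, 19000000,
  "16", 88827254, 36600000,
  "17", 78774742, 24000000,
  "18", 76117153, 17200000,
  "19", 63811651, 26500000,
  "20", 62435964, 27500000,
  "21", 46944323, 13200000,
  "22", 49691432, 14700000,
  "X", 154913754, 60600000,
  "Y", 57772954, 12300000
)

#' Build a (miniature) reference genome
#'
#' Returns a per-chromosome table of lengths and centromere positions with the
#' human chromosome proportions, scaled by `scale`. The default `scale = 1/20`
#' with 25 kb probe spacing gives roughly 6,000 probes genome-wide — small
#' enough that a several-hundred-sample cohort segments in seconds, while the
#' smallest simulated events still span at least ~20 probes, mirroring real
#' molecular-inversion-probe arrays where a megabase event covers hundreds of
#' probes. All 22 autosomes plus X keep realistic relative arm sizes.
#'
#' @param scale Linear scale factor applied to human chromosome lengths.
#' @param spacing Probe spacing in bp (on the scaled genome).
#' @param include_y Include chromosome Y (default `FALSE`; the generator
#'   models sex chromosomes as copy-neutral and downstream stages exclude
#'   them, so Y adds nothing by default).
#' @return A tibble with columns `chrom`, `length`, `centromere`, `is_sex`,
#'   carrying the probe `spacing` as an attribute.
#' @examples
#' g <- default_genome()
#' sum(floor(g$length / attr(g, "spacing")))
#' @export
default_genome <- function(scale = 1 / 20, spacing = 2.5e4, include_y = FALSE) {
  g <- HUMAN_CHROM_BP %>%
    filter(include_y | .data$chrom != "Y") %>%
    mutate(
      length = floor(.data$length * scale),
      centromere = floor(.data$centromere * scale),
      is_sex = is_sex_chrom(.data$chrom)
    )
  attr(g, "spacing") <- spacing
  g
}

#' Probe map for a genome
#'
#' Lays a regular probe grid over each chromosome. Positions are internal
#' 0-based coordinates.
#'
#' @param genome A genome table from [default_genome()].
#' @return Tibble with `probe_id`, `chrom`, `pos`.
#' @export
probe_map <- function(genome) {
  spacing <- attr(genome, "spacing") %||% 5e4
  genome %>%
    mutate(pos = map(.data$length, ~ seq(0, .x - 1, by = spacing))) %>%
    select("chrom", "pos") %>%
    unnest("pos") %>%
    group_by(.data$chrom) %>%
    mutate(probe_id = paste0("p", .data$chrom, "_", row_number())) %>%
    ungroup() %>%
    select("probe_id", "chrom", "pos")
}

#' Chromosome-arm table for a genome
#'
#' @param genome A genome table from [default_genome()].
#' @return Tibble with `chrom`, `arm` ("p"/"q"), `start`, `end`
#'   (0-based half-open).
#' @export
chrom_arms <- function(genome) {
  bind_rows(
    genome %>% transmute(.data$chrom, arm = "p", start = 0, end = .data$centromere),
    genome %>% transmute(.data$chrom, arm = "q", start = .data$centromere, end = .data$length)
  ) %>%
    arrange(chrom_factor(.data$chrom), .data$start)
}

#' Locate an arm by name (e.g. "20q") in a genome
#' @keywords internal
arm_interval <- function(genome, arm_name) {
  chrom <- sub("[pq]$", "", arm_name)
  arm <- sub("^.*([pq])$", "\\1", arm_name)
  if (!grepl("[pq]$", arm_name)) {
    row <- genome[genome$chrom == arm_name, ]
    if (nrow(row) == 0) abort(paste0("Unknown chromosome: ", arm_name))
    return(tibble(chrom = arm_name, start = 0, end = row$length))
  }
  arms <- chrom_arms(genome)
  row <- arms[arms$chrom == chrom & arms$arm == arm, ]
  if (nrow(row) == 0) abort(paste0("Unknown arm: ", arm_name))
  tibble(chrom = chrom, start = row$start, end = row$end)
}
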