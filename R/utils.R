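# Shared validation helpers and small utilities.

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")

#' Order chromosomes canonically (1..22, X, Y)
#'
#' @param chrom Character vector of chromosome names (without "chr" prefix).
#' @return Factor with canonical level order.
#' @keywords internal
chrom_factor <- function(chrom) {
  factor(as.character(chrom), levels = CHROM_LEVELS)
}

#' Strip an optional "chr" prefix and validate chromosome labels
#' @keywords internal
normalize_chrom <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  bad <- setdiff(unique(ch), CHROM_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("Unknown chromosome label(s): ", paste(bad, collapse = ", ")))
  }
  ch
}

#' Is a chromosome a sex chromosome?
#' @keywords internal
is_sex_chrom <- function(chrom) as.character(chrom) %in% c("X", "Y")

#' Extract the sample columns of a wide profile/matrix tibble
#'
#' Wide cohort tables carry annotation columns (probe/gene, chrom, pos, ...)
#' followed by one numeric column per sample.
#' @keywords internal
sample_cols <- function(x, annotation = c(
                          "probe_id", "gene_id", "symbol",
                          "chrom", "pos", "start", "end"
                        )) {
  setdiff(names(x), annotation)
}

#' Stop unless a data frame has the named columns
#' @keywords internal
check_columns <- function(x, cols, what = "input") {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Seed an RNG stream deterministically from a base seed and a stream label
#'
#' Stage-scoped seeding: every stochastic stage derives its own substream so
#' stages can be re-run in isolation. Kept below 2^31 - 1.
#' @keywords internal
derive_seed <- function(seed, stream) {
  offsets <- c(
    cohort = 11L, carriers = 23L, background = 37L, noise = 41L,
    expression = 53L, survival = 67L, cbs = 71L, stac = 83L,
    gistic = 97L, fdr = 101L, network = 113L
  )
  off <- offsets[[stream]] %||% 127L
  as.integer((as.numeric(seed) * 1103L + off) %% 2147483647L)
}

#' Run code with a local RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

new_tidycna_tbl <- function(x, subclass) {
  class(x) <- c(subclass, class(tibble()))
  x
}
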