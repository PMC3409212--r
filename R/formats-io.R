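# File-format boundary. Everything on disk is 1-based (SEG inclusive,
# probe positions 1-based, GMT/BED as their standards define); everything
# internal is 0-based half-open. Copy number is absolute copies internally
# (diploid = 2.0); log2-ratio SEG input is converted at this boundary.

#' Read a probe-level copy-number matrix
#'
#' Tab-delimited with header `probe`, `chrom`, `pos`, then one numeric column
#' per sample. Positions in the file are 1-based and are converted to the
#' internal 0-based convention; probes are re-sorted by chromosome then
#' position.
#'
#' @param path Path to the tab-delimited file.
#' @return A wide tibble: `probe_id`, `chrom`, `pos` (0-based), one column per
#'   sample.
#' @export
read_probe_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("probe", "chrom", "pos"), "probe matrix")
  samples <- setdiff(names(x), c("probe", "chrom", "pos"))
  if (length(samples) == 0) abort("probe matrix has no sample columns")
  for (s in samples) {
    if (!is.numeric(x[[s]])) {
      abort(paste0("sample column '", s, "' is not numeric"))
    }
    if (anyNA(x[[s]])) {
      row <- which(is.na(x[[s]]))[1]
      abort(paste0(
        "missing/non-numeric copy-number value at row ", row,
        " (probe ", x$probe[row], "), sample '", s, "'"
      ))
    }
  }
  out <- x %>%
    rename(probe_id = "probe") %>%
    mutate(chrom = normalize_chrom(.data$chrom), pos = .data$pos - 1) %>%
    arrange(chrom_factor(.data$chrom), .data$pos)
  dup <- out %>%
    count(.data$chrom, .data$pos) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    probes <- out$probe_id[out$chrom == dup$chrom[1] & out$pos == dup$pos[1]]
    abort(paste0(
      "duplicate probe position on chromosome ", dup$chrom[1],
      " (probes ", paste(probes, collapse = ", "), ")"
    ))
  }
  out
}

#' Write a probe-level copy-number matrix
#'
#' Inverse of [read_probe_matrix()]: internal 0-based positions are written
#' 1-based.
#'
#' @param profiles Wide profile tibble (`probe_id`, `chrom`, `pos`, samples).
#' @param path Output path.
#' @export
write_probe_matrix <- function(profiles, path) {
  profiles %>%
    rename(probe = "probe_id") %>%
    mutate(pos = .data$pos + 1) %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read a SEG segment file
#'
#' Standard 6-column SEG dialect: `sample`, `chrom`, `start`, `end`,
#' `n_probes`, `value`, 1-based inclusive coordinates. Values are either
#' absolute copies (default) or log2 ratios, converted to copies via
#' CN = 2 * 2^log2ratio.
#'
#' @param path Path to the SEG file.
#' @param value Scale of the `value` column: `"copies"` or `"log2"`.
#' @return Segment tibble: `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_probes`, `mean_cn` (copies).
#' @export
read_seg <- function(path, value = c("copies", "log2")) {
  is_log2 <- match.arg(value) == "log2"
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("sample", "chrom", "start", "end", "n_probes", "value"), "SEG file")
  if (any(x$start > x$end)) {
    row <- which(x$start > x$end)[1]
    abort(paste0("SEG row ", row, ": start > end"))
  }
  out <- x %>%
    transmute(
      sample_id = as.character(.data$sample),
      chrom = normalize_chrom(.data$chrom),
      start = .data$start - 1,
      end = as.numeric(.data$end),
      n_probes = .data$n_probes,
      mean_cn = if (is_log2) 2 * 2^.data$value else .data$value
    ) %>%
    arrange(.data$sample_id, chrom_factor(.data$chrom), .data$start)
  overlap <- out %>%
    group_by(.data$sample_id, .data$chrom) %>%
    filter(row_number() > 1 & .data$start < lag(.data$end)) %>%
    ungroup()
  if (nrow(overlap) > 0) {
    abort(paste0(
      "overlapping segments for sample ", overlap$sample_id[1],
      " on chromosome ", overlap$chrom[1]
    ))
  }
  out
}

#' Write segments as SEG
#'
#' Internal 0-based half-open coordinates are written 1-based inclusive, in
#' absolute copies.
#'
#' @param segments Segment tibble as returned by [read_seg()] or
#'   [cbs_segment()].
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  check_columns(segments, c("sample_id", "chrom", "start", "end", "n_probes", "mean_cn"))
  segments %>%
    transmute(
      sample = .data$sample_id,
      chrom = .data$chrom,
      start = .data$start + 1,
      end = .data$end,
      n_probes = .data$n_probes,
      value = .data$mean_cn
    ) %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read a BED4 gene model
#'
#' BED coordinates are already 0-based half-open and are kept as-is.
#'
#' @param path Path to a 4-column BED file (chrom, start, end, name); no
#'   header.
#' @return Tibble `gene_id`, `symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_model <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name"),
    show_col_types = FALSE, progress = FALSE
  )
  if (any(x$start >= x$end)) {
    abort(paste0("BED line ", which(x$start >= x$end)[1], ": start >= end"))
  }
  if (anyDuplicated(x$name)) {
    abort(paste0("duplicate gene identifier: ", x$name[duplicated(x$name)][1]))
  }
  x %>%
    transmute(
      gene_id = as.character(.data$name), symbol = as.character(.data$name),
      chrom = normalize_chrom(.data$chrom), start = .data$start, end = .data$end
    ) %>%
    arrange(chrom_factor(.data$chrom), .data$start)
}

#' Write a gene model as BED4
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param path Output path.
#' @export
write_gene_model <- function(genes, path) {
  genes %>%
    transmute(.data$chrom, .data$start, .data$end, name = .data$gene_id) %>%
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' Tab-delimited with a `gene_id` column followed by one numeric column per
#' sample.
#'
#' @param path Path to the file.
#' @return Wide tibble `gene_id` + sample columns.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, "gene_id", "expression matrix")
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("duplicate gene_id: ", x$gene_id[duplicated(x$gene_id)][1]))
  }
  x
}

#' Read a clinical annotation table
#'
#' Expects `sample_id`, `msi`, `stage` and the survival columns `os_time`,
#' `os_event`, `rfs_time`, `rfs_event`; extra label columns (mutation status,
#' signature calls) are passed through. An event flag with a missing time is
#' rejected.
#'
#' @param path Path to the tab-delimited table.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, c("sample_id", "msi", "stage"), "clinical table")
  if (anyDuplicated(x$sample_id)) {
    abort(paste0("duplicate sample_id: ", x$sample_id[duplicated(x$sample_id)][1]))
  }
  for (ep in c("os", "rfs")) {
    tcol <- paste0(ep, "_time")
    ecol <- paste0(ep, "_event")
    if (all(c(tcol, ecol) %in% names(x))) {
      bad <- which(is.na(x[[tcol]]) & !is.na(x[[ecol]]) & x[[ecol]] == 1)
      if (length(bad) > 0) {
        abort(paste0(
          "sample ", x$sample_id[bad[1]], ": ", ecol,
          " = 1 but ", tcol, " is missing"
        ))
      }
      if (any(x[[tcol]] < 0, na.rm = TRUE)) abort(paste0(tcol, " must be >= 0"))
    }
  }
  x
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line — name, description, then member genes. All
#' sets load; size filtering (the 10–500 member rule) is applied downstream by
#' [pathway_enrichment()], but a `size` column is provided so undersized sets
#' are visible immediately.
#'
#' @param path Path to the GMT file.
#' @return Tibble `set`, `description`, `genes` (list-column), `size`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(paste0("GMT line ", bad[1], ": fewer than 3 fields"))
  }
  out <- tibble(
    set = map_chr(parts, 1),
    description = map_chr(parts, 2),
    genes = map(parts, ~ unique(.x[-(1:2)]))
  ) %>%
    mutate(size = lengths(.data$genes))
  if (anyDuplicated(out$set)) {
    abort(paste0("duplicate gene-set name: ", out$set[duplicated(out$set)][1]))
  }
  out
}

#' Write a result table with '#' metadata header lines
#'
#' All pipeline result tables are plain tab-delimited with optional
#' `#`-prefixed metadata lines before the header.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param meta Named character vector written as `# name: value` lines.
#' @export
write_result_table <- function(x, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  }
  # list-columns (e.g. carrier sets) are flattened to comma-separated strings
  for (nm in names(x)[vapply(x, is.list, logical(1))]) {
    x[[nm]] <- map_chr(x[[nm]], paste, collapse = ",")
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, format_tsv_col), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

format_tsv_col <- function(v) {
  if (is.numeric(v)) format(v, trim = TRUE, digits = 15, scientific = FALSE) else as.character(v)
}
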