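#' Read an amplicon design BED file
#'
#' Parses the design BED emitted by amplicon panel designers (e.g. the Ion
#' AmpliSeq Designer `designed.bed`). Coordinates are BED-style: 0-based,
#' half-open. The primer pool is taken from a `Pool=<int>` key=value pair in
#' an attribute column (the key is matched case-insensitively); a `GENE_ID=`
#' attribute supplies the gene symbol, falling back to the BED name column.
#' An optional leading `track` line is skipped.
#'
#' @param path Path to a tab-separated design BED file.
#' @return A tibble with one row per amplicon and columns `amplicon_id`,
#'   `chrom`, `start`, `end`, `gene`, `pool`.
#' @seealso [read_coverage_matrix()], [join_design_coverage()]
#' @export
read_design_bed <- function(path) {
  if (!file.exists(path)) stopf("design BED not found: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_track <- grepl("^(track|browser)\\b", lines)
  data_lines <- lines[!is_track]
  line_no <- seq_along(lines)[!is_track]
  if (length(data_lines) == 0L) {
    warnf("'%s' contains no amplicon records", path)
    return(tibble(amplicon_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  gene = character(), pool = integer()))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld < 4L)) {
    stopf("line %d of '%s' has %d fields; at least 4 (chrom, start, end, name) required",
          line_no[which(nfld < 4L)[1]], path, min(nfld))
  }
  parse_one <- function(f, ln) {
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stopf("line %d of '%s': non-integer coordinates '%s', '%s'", ln, path, f[2], f[3])
    }
    attrs <- paste(f[-(1:4)], collapse = ";")
    pool_m <- regmatches(attrs, regexpr("(?i)(?:^|;)\\s*pool=([0-9]+)", attrs, perl = TRUE))
    if (length(pool_m) == 0L) {
      stopf("line %d of '%s': no 'Pool=<int>' attribute found", ln, path)
    }
    pool <- as.integer(sub("(?i).*pool=", "", pool_m, perl = TRUE))
    gene_m <- regmatches(attrs, regexpr("(?i)(?:^|;)\\s*gene_id=([^;]+)", attrs, perl = TRUE))
    gene <- if (length(gene_m) > 0L) {
      sub("(?i).*gene_id=", "", gene_m, perl = TRUE)
    } else {
      f[4]
    }
    tibble(amplicon_id = f[4], chrom = f[1], start = start, end = end,
           gene = trimws(gene), pool = pool)
  }
  design <- bind_rows(purrr::map2(fields, line_no, parse_one))
  dup <- design$amplicon_id[duplicated(design$amplicon_id)]
  if (length(dup) > 0L) {
    stopf("duplicated amplicon_id in '%s': %s", path,
          paste(unique(dup), collapse = ", "))
  }
  if (any(design$start >= design$end)) {
    bad <- design$amplicon_id[design$start >= design$end][1]
    stopf("amplicon '%s' has start >= end", bad)
  }
  if (any(design$pool < 1L)) stopf("pool ids must be positive integers")
  design
}

#' Write an amplicon design BED file
#'
#' Inverse of [read_design_bed()]: writes `GENE_ID=<gene>;Pool=<pool>` in the
#' attribute column so that a parse/serialize round trip preserves all fields.
#'
#' @param design Design tibble as returned by [read_design_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_bed <- function(design, path) {
  check_cols(design, c("amplicon_id", "chrom", "start", "end", "gene", "pool"),
             "write_design_bed")
  lines <- sprintf("%s\t%d\t%d\t%s\t.\tGENE_ID=%s;Pool=%d",
                   design$chrom, design$start, design$end,
                   design$amplicon_id, design$gene, design$pool)
  writeLines(lines, path)
  invisible(path)
}

#' Read a barcode/amplicon coverage matrix
#'
#' Reads the per-amplicon read-depth table produced by coverage-analysis
#' tooling (one row per amplicon, one column per barcoded sample). Two header
#' dialects are accepted: `Gene<tab>Target<tab><barcodes...>` (the Torrent
#' coverage-analysis bcmatrix layout, where `Target` holds the amplicon id)
#' and a plain `amplicon_id<tab><barcodes...>` layout.
#'
#' @param path Path to a tab-separated coverage matrix.
#' @return A wide tibble: column `amplicon_id` then one numeric column per
#'   sample, in the header's sample order.
#' @export
read_coverage_matrix <- function(path) {
  if (!file.exists(path)) stopf("coverage matrix not found: '%s'", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stopf("'%s': header has fewer than 2 columns", path)
  gene_dialect <- length(header) >= 3L &&
    tolower(header[1]) == "gene" && tolower(header[2]) == "target"
  id_cols <- if (gene_dialect) 2L else 1L
  samples <- header[-seq_len(if (gene_dialect) 2L else 1L)]
  if (anyDuplicated(samples)) {
    stopf("'%s': duplicated barcode column(s): %s", path,
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  ids <- raw[[id_cols]]
  if (anyDuplicated(ids)) {
    stopf("'%s': duplicated amplicon row(s): %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  depth_chr <- raw[samples]
  depth <- suppressWarnings(
    purrr::map(depth_chr, ~ as.numeric(.x))
  )
  for (j in seq_along(depth)) {
    bad <- which(is.na(depth[[j]]) & !is.na(depth_chr[[j]]))
    if (length(bad) > 0L) {
      stopf("'%s': non-numeric depth at amplicon '%s', barcode '%s'",
            path, ids[bad[1]], samples[j])
    }
    if (any(depth[[j]] < 0, na.rm = TRUE)) {
      stopf("'%s': negative depth in barcode '%s'", path, samples[j])
    }
  }
  out <- tibble(amplicon_id = ids)
  out[samples] <- depth
  out
}

#' Write a coverage matrix
#'
#' @param coverage Wide coverage tibble (`amplicon_id` + one column per
#'   sample), as returned by [read_coverage_matrix()] or [simulate_batch()].
#' @param path Output path.
#' @param dialect `"plain"` writes `amplicon_id` first; `"gene_target"`
#'   writes the Torrent-style `Gene`/`Target` leading columns (`gene` must be
#'   supplied).
#' @param gene Optional character vector of gene labels (parallel to rows)
#'   for the `"gene_target"` dialect.
#' @return `path`, invisibly.
#' @export
write_coverage_matrix <- function(coverage, path,
                                  dialect = c("plain", "gene_target"),
                                  gene = NULL) {
  dialect <- match.arg(dialect)
  check_cols(coverage, "amplicon_id", "write_coverage_matrix")
  out <- coverage
  if (dialect == "gene_target") {
    if (is.null(gene)) stopf("dialect 'gene_target' needs the 'gene' labels")
    out <- dplyr::bind_cols(tibble(Gene = gene, Target = coverage$amplicon_id),
                            coverage[setdiff(names(coverage), "amplicon_id")])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Join an amplicon design with a coverage matrix
#'
#' Intersects the design's amplicons with the coverage matrix rows, warns
#' about records present on only one side, and returns a long, genomically
#' sorted tibble (chr1..chr22, chrX, chrY ordering, then start, then
#' amplicon id) — the input to [normalize_batch()].
#'
#' @param design Design tibble from [read_design_bed()].
#' @param coverage Wide coverage tibble from [read_coverage_matrix()].
#' @return A long tibble with columns `amplicon_id`, `chrom`, `start`, `end`,
#'   `gene`, `pool`, `sample_id` (factor in original barcode order), `depth`.
#' @export
join_design_coverage <- function(design, coverage) {
  check_cols(design, c("amplicon_id", "chrom", "start", "end", "gene", "pool"),
             "join_design_coverage")
  check_cols(coverage, "amplicon_id", "join_design_coverage")
  samples <- setdiff(names(coverage), "amplicon_id")
  if (length(samples) == 0L) stopf("coverage matrix has no sample columns")
  shared <- intersect(design$amplicon_id, coverage$amplicon_id)
  if (length(shared) == 0L) {
    stopf("no amplicons shared between design (%d) and coverage matrix (%d)",
          nrow(design), nrow(coverage))
  }
  only_design <- setdiff(design$amplicon_id, shared)
  only_cov <- setdiff(coverage$amplicon_id, shared)
  if (length(only_design) > 0L) {
    warnf("%d amplicon(s) in the design but not the coverage matrix: %s",
          length(only_design), paste(head(only_design, 5L), collapse = ", "))
  }
  if (length(only_cov) > 0L) {
    warnf("%d amplicon(s) in the coverage matrix but not the design: %s",
          length(only_cov), paste(head(only_cov, 5L), collapse = ", "))
  }
  long <- coverage |>
    filter(.data$amplicon_id %in% shared) |>
    tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                        values_to = "depth") |>
    mutate(sample_id = factor(.data$sample_id, levels = samples))
  design |>
    filter(.data$amplicon_id %in% shared) |>
    left_join(long, by = "amplicon_id") |>
    sort_genomic()
}

#' Write CNV calls to a tab-separated file
#'
#' Columns, in order: `sample_id`, `chrom`, `gene`, `first_amplicon`,
#' `last_amplicon`, `start`, `end` (1-based inclusive, the convention of
#' clinical reports), `n_amplicons`, `copy_state`, `mean_norm_depth`,
#' `sd_flag`, `t_p_value`. Floats are written with 6 decimals. An empty call
#' set produces a header-only file.
#'
#' @param calls Calls tibble from [call_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  cols <- c("sample_id", "chrom", "gene", "first_amplicon", "last_amplicon",
            "start", "end", "n_amplicons", "copy_state", "mean_norm_depth",
            "sd_flag", "t_p_value")
  check_cols(calls, cols, "write_cnv_calls")
  out <- calls |>
    select(all_of(cols)) |>
    mutate(mean_norm_depth = sprintf("%.6f", .data$mean_norm_depth),
           t_p_value = ifelse(is.na(.data$t_p_value), "NA",
                              sprintf("%.6f", .data$t_p_value)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read a normalized depth matrix
#'
#' The normalized matrix is written wide (`amplicon_id` + one column per
#' sample) with 6 decimal places, so a write/read round trip reproduces the
#' values to 1e-6. Masked (low-coverage) amplicons are written as `NA`.
#'
#' @param data Normalized profile tibble from [normalize_batch()].
#' @param path Output path.
#' @return `path` invisibly for the writer; a long tibble (`amplicon_id`,
#'   `sample_id`, `norm_depth`) for the reader.
#' @export
write_normalized_matrix <- function(data, path) {
  check_cols(data, c("amplicon_id", "sample_id", "norm_depth"),
             "write_normalized_matrix")
  vals <- data
  if ("retained" %in% names(data)) {
    vals <- mutate(vals, norm_depth = ifelse(.data$retained, .data$norm_depth, NA_real_))
  }
  wide <- vals |>
    mutate(norm_depth = ifelse(is.na(.data$norm_depth), NA_character_,
                               sprintf("%.6f", .data$norm_depth))) |>
    select(all_of(c("amplicon_id", "sample_id", "norm_depth"))) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "norm_depth")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_normalized_matrix
#' @export
read_normalized_matrix <- function(path) {
  if (!file.exists(path)) stopf("normalized matrix not found: '%s'", path)
  wide <- readr::read_tsv(path, col_types = readr::cols(
    amplicon_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  samples <- setdiff(names(wide), "amplicon_id")
  wide |>
    tidyr::pivot_longer(all_of(samples), names_to = "sample_id",
                        values_to = "norm_depth") |>
    mutate(sample_id = factor(.data$sample_id, levels = samples))
}
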