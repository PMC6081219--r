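#' Natural chromosome ordering
#'
#' Orders chromosome names the way targeted-panel reports present them:
#' chr1 through chr22, then chrX, chrY, then anything else lexicographically.
#' Names with or without a `chr` prefix are handled; the prefix is kept as-is
#' in the output levels.
#'
#' @param chroms Character vector of chromosome names.
#' @return The unique chromosome names, sorted naturally.
#' @examples
#' chrom_sort_levels(c("chrX", "chr2", "chr10", "chr1"))
#' @export
chrom_sort_levels <- function(chroms) {
  u <- unique(as.character(chroms))
  core <- sub("^chr", "", u, ignore.case = TRUE)
  rank <- suppressWarnings(as.numeric(core))
  rank[toupper(core) == "X"] <- 23
  rank[toupper(core) == "Y"] <- 24
  known <- !is.na(rank)
  c(u[known][order(rank[known])], sort(u[!known]))
}

chrom_factor <- function(chroms) {
  factor(as.character(chroms), levels = chrom_sort_levels(chroms))
}

#' @noRd
sort_genomic <- function(data) {
  data |>
    mutate(.chrom_ord = chrom_factor(.data$chrom)) |>
    arrange(.data$.chrom_ord, .data$start, .data$amplicon_id) |>
    select(-".chrom_ord")
}

# population (divide-by-N) standard deviation; the default for the +/-1 SD
# candidate rule because the batch is the whole population of interest
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# required-column check for the long coverage tibble contracts
check_cols <- function(data, cols, fn) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    stopf("%s(): input is missing column(s) %s", fn,
          paste0("'", miss, "'", collapse = ", "))
  }
  invisible(data)
}

# amplicon order (genomic) and sample order as stored in the long tibble
amplicon_levels <- function(data) {
  unique(as.character(data$amplicon_id))
}

sample_levels <- function(data) {
  if (is.factor(data$sample_id)) levels(data$sample_id)
  else unique(as.character(data$sample_id))
}

# long tibble -> amplicons x samples matrix of one value column.
# Assumes data is sorted genomically and complete (one row per pair).
value_matrix <- function(data, col) {
  amps <- amplicon_levels(data)
  smps <- sample_levels(data)
  m <- matrix(NA_real_, nrow = length(amps), ncol = length(smps),
              dimnames = list(amps, smps))
  m[cbind(match(as.character(data$amplicon_id), amps),
          match(as.character(data$sample_id), smps))] <- data[[col]]
  m
}

# per-amplicon annotation (one row per amplicon, genomic order)
amplicon_table <- function(data) {
  data |>
    distinct(.data$amplicon_id, .data$chrom, .data$start, .data$end,
             .data$gene, .data$pool) |>
    sort_genomic()
}
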