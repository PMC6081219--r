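#' Per-sample, per-pool mean read depths
#'
#' Multiplex amplicon libraries mix several primer pools, possibly in unequal
#' proportions, so depth must be scaled within each pool of each sample. This
#' computes the arithmetic mean raw depth of each (sample, pool) cell and the
#' number of amplicons per pool.
#'
#' @param data Long coverage tibble from [join_design_coverage()] (or
#'   [simulate_batch()]'s `$data`).
#' @return A tibble with columns `sample_id`, `pool`, `n_amplicons`,
#'   `mean_depth`, `analyzable` (`FALSE` when the pool mean is 0, i.e. the
#'   pool produced no reads for that sample).
#' @export
pool_mean_depths <- function(data) {
  check_cols(data, c("sample_id", "pool", "depth"), "pool_mean_depths")
  data |>
    group_by(.data$sample_id, .data$pool) |>
    summarise(n_amplicons = dplyr::n(),
              mean_depth = mean(.data$depth),
              .groups = "drop") |>
    mutate(analyzable = .data$mean_depth > 0)
}

#' Relative depths: amplicon depth over its pool mean
#'
#' Divides every raw depth by the mean depth of the amplicon's primer pool in
#' the same sample, making samples (and pools within a sample) comparable.
#' By construction the relative depths of one pool in one sample average to
#' exactly 1. Where a pool mean is 0 the relative depth is undefined and
#' recorded as `NA` (never silently 0 — a true 0 means homozygous loss).
#'
#' @inheritParams pool_mean_depths
#' @param pool_means Optional precomputed result of [pool_mean_depths()].
#' @return `data` with an added `rel_depth` column.
#' @export
relative_depths <- function(data, pool_means = NULL) {
  check_cols(data, c("sample_id", "pool", "depth"), "relative_depths")
  pm <- pool_means %||% pool_mean_depths(data)
  if (any(!pm$analyzable)) {
    bad <- pm |> filter(!.data$analyzable)
    warnf("pool mean is 0 for %d (sample, pool) cell(s) (e.g. sample '%s', pool %d); their relative depths are undefined",
          nrow(bad), as.character(bad$sample_id[1]), bad$pool[1])
  }
  data |>
    left_join(select(pm, all_of(c("sample_id", "pool", "mean_depth"))),
              by = c("sample_id", "pool")) |>
    mutate(rel_depth = ifelse(.data$mean_depth > 0,
                              .data$depth / .data$mean_depth, NA_real_)) |>
    select(-"mean_depth")
}

#' Batch reference: mean relative depth of each amplicon across samples
#'
#' The population-based reference that absorbs per-amplicon amplification
#' efficiency: for each amplicon, the arithmetic mean of its relative depth
#' over all samples of the batch (all samples sequenced in one run). Samples
#' with undefined relative depth for an amplicon are excluded from its mean.
#'
#' @inheritParams relative_depths
#' @param by_sex Optional tibble (`sample_id`, `sex`) — when supplied, the
#'   reference is computed within sex groups (`male`/`female`; anything else
#'   falls back to the whole-batch mean). Off by default; see
#'   [normalize_batch()]'s `sex_aware`.
#' @return A tibble with `amplicon_id` (plus `sex` when `by_sex` is used),
#'   `ref_depth`, `n_samples`.
#' @export
batch_reference <- function(data, by_sex = NULL) {
  check_cols(data, c("amplicon_id", "sample_id", "rel_depth"), "batch_reference")
  n_smp <- dplyr::n_distinct(as.character(data$sample_id))
  if (n_smp < 2L) stopf("batch_reference(): need at least 2 samples, got %d", n_smp)
  if (is.null(by_sex)) {
    data |>
      group_by(.data$amplicon_id) |>
      summarise(ref_depth = if (all(is.na(.data$rel_depth))) NA_real_
                else mean(.data$rel_depth, na.rm = TRUE),
                n_samples = sum(!is.na(.data$rel_depth)),
                .groups = "drop")
  } else {
    check_cols(by_sex, c("sample_id", "sex"), "batch_reference")
    joined <- data |>
      mutate(sample_chr = as.character(.data$sample_id)) |>
      left_join(by_sex |> mutate(sample_chr = as.character(.data$sample_id)) |>
                  select(all_of(c("sample_chr", "sex"))),
                by = "sample_chr")
    joined |>
      mutate(sex = ifelse(.data$sex %in% c("male", "female"), .data$sex, "unknown")) |>
      group_by(.data$amplicon_id, .data$sex) |>
      summarise(ref_depth = if (all(is.na(.data$rel_depth))) NA_real_
                else mean(.data$rel_depth, na.rm = TRUE),
                n_samples = sum(!is.na(.data$rel_depth)),
                .groups = "drop")
  }
}

#' Normalized relative depth (copy-dosage scale)
#'
#' Twice the ratio of a sample's relative depth to the batch reference of the
#' same amplicon: diploid amplicons land near 2, a one-copy loss near 1, a
#' one-copy gain near 3, and a homozygous loss at 0. By construction the mean
#' normalized depth of every amplicon across the batch is exactly 2.
#'
#' @inheritParams relative_depths
#' @param reference Optional precomputed [batch_reference()] result.
#' @param leave_one_out If `TRUE`, the reference for sample *q* excludes *q*
#'   itself (reduces the carrier's pull on its own reference; the literal
#'   batch mean includes all samples and is the default).
#' @return `data` with added `ref_depth` and `norm_depth` columns
#'   (`norm_depth = 2 * rel_depth / ref_depth`; `NA` where undefined).
#' @export
normalize_depths <- function(data, reference = NULL, leave_one_out = FALSE) {
  check_cols(data, c("amplicon_id", "sample_id", "rel_depth"), "normalize_depths")
  if (leave_one_out) {
    out <- data |>
      group_by(.data$amplicon_id) |>
      mutate(.sum = sum(.data$rel_depth, na.rm = TRUE),
             .n = sum(!is.na(.data$rel_depth)),
             ref_depth = ifelse(.data$.n - !is.na(.data$rel_depth) >= 1L,
                                (.data$.sum - dplyr::coalesce(.data$rel_depth, 0)) /
                                  (.data$.n - !is.na(.data$rel_depth)),
                                NA_real_)) |>
      ungroup() |>
      select(-".sum", -".n")
  } else {
    ref <- reference %||% batch_reference(data)
    if ("sex" %in% names(ref)) {
      stopf("normalize_depths(): pass sex-stratified references via normalize_batch(sex_aware = TRUE)")
    }
    out <- data |>
      left_join(select(ref, all_of(c("amplicon_id", "ref_depth"))),
                by = "amplicon_id")
  }
  out |>
    mutate(norm_depth = ifelse(!is.na(.data$ref_depth) & .data$ref_depth > 0,
                               2 * .data$rel_depth / .data$ref_depth,
                               NA_real_))
}

#' Mask low-coverage amplicons
#'
#' Amplicons whose batch-mean relative depth is at or below `threshold`
#' (default 0.1, i.e. amplifying at a tenth of the pool average or worse) are
#' dominated by ratio noise and are masked out of all downstream statistics
#' and plots. Amplicons with an undefined reference are masked too.
#'
#' @param data Tibble with `ref_depth` (from [normalize_depths()]).
#' @param threshold Non-negative mask threshold on the batch-mean relative
#'   depth (masked when `ref_depth <= threshold`).
#' @return `data` with a logical `retained` column.
#' @export
filter_low_coverage <- function(data, threshold = 0.1) {
  check_cols(data, "ref_depth", "filter_low_coverage")
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stopf("filter_low_coverage(): 'threshold' must be a single non-negative number")
  }
  mutate(data, retained = !is.na(.data$ref_depth) & .data$ref_depth > threshold)
}

#' Run the full depth-normalization pipeline on a batch
#'
#' Chains [pool_mean_depths()], [relative_depths()], [batch_reference()],
#' [normalize_depths()] and [filter_low_coverage()]: raw depths are scaled by
#' their primer-pool mean within each sample, referenced against the batch
#' average of each amplicon, doubled onto the copy-dosage scale (diploid = 2),
#' and low-coverage amplicons are masked.
#'
#' @inheritParams pool_mean_depths
#' @param outlier_threshold Mask threshold on the batch-mean relative depth
#'   (default 0.1).
#' @param sex_aware If `TRUE`, compute the batch reference within sex groups
#'   given in `meta`, so chrX dosage is referenced against same-sex samples
#'   (default `FALSE`: the reference pools all samples, and chrX values land
#'   near 1.3 for males / 2.7 for females in a balanced batch).
#' @param meta Optional sample metadata tibble (`sample_id`, `sex`), required
#'   when `sex_aware = TRUE`.
#' @param leave_one_out Exclude each sample from its own reference (default
#'   `FALSE`, the literal batch mean).
#' @return A `cnv_profile` tibble: the input plus `rel_depth`, `ref_depth`,
#'   `norm_depth`, `retained`.
#' @examples
#' sim <- simulate_batch(sim_config(n_samples = 6, noise = "none", seed = 1))
#' prof <- normalize_batch(sim$data)
#' dplyr::count(prof, retained)
#' @export
normalize_batch <- function(data, outlier_threshold = 0.1, sex_aware = FALSE,
                            meta = NULL, leave_one_out = FALSE) {
  check_cols(data, c("amplicon_id", "chrom", "start", "gene", "pool",
                     "sample_id", "depth"), "normalize_batch")
  rel <- relative_depths(data)
  if (sex_aware) {
    if (is.null(meta)) stopf("normalize_batch(): sex_aware = TRUE needs 'meta' (sample_id, sex)")
    ref <- batch_reference(rel, by_sex = meta)
    rel2 <- rel |>
      mutate(sample_chr = as.character(.data$sample_id)) |>
      left_join(meta |> mutate(sample_chr = as.character(.data$sample_id)) |>
                  select(all_of(c("sample_chr", "sex"))), by = "sample_chr") |>
      mutate(sex = ifelse(.data$sex %in% c("male", "female"), .data$sex, "unknown"))
    out <- rel2 |>
      left_join(ref |> rename(ref_depth_sex = "ref_depth"),
                by = c("amplicon_id", "sex")) |>
      mutate(ref_depth = .data$ref_depth_sex,
             norm_depth = ifelse(!is.na(.data$ref_depth) & .data$ref_depth > 0,
                                 2 * .data$rel_depth / .data$ref_depth, NA_real_)) |>
      select(-"ref_depth_sex", -"sample_chr", -"n_samples")
  } else {
    out <- normalize_depths(rel, leave_one_out = leave_one_out)
  }
  out <- filter_low_coverage(out, threshold = outlier_threshold) |>
    sort_genomic()
  class(out) <- c("cnv_profile", class(out))
  attr(out, "outlier_threshold") <- outlier_threshold
  out
}
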