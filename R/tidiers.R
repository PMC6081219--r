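#' Tidy a normalized CNV profile
#'
#' Returns the profile as a plain tibble of per-(amplicon, sample) records —
#' the long table behind the plots — dropping nothing.
#'
#' @param x A `cnv_profile` from [normalize_batch()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cnv_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "cnv_profile")
  out
}

#' Glance at a normalized CNV profile
#'
#' One row summarizing the batch: sample and amplicon counts, how many
#' amplicons the low-coverage filter masked, and the batch-wide dispersion of
#' normalized depths.
#'
#' @inheritParams tidy.cnv_profile
#' @return A one-row tibble with `n_samples`, `n_amplicons`, `n_masked`,
#'   `outlier_threshold`, `median_norm_depth`, `mad_norm_depth`.
#' @export
glance.cnv_profile <- function(x, ...) {
  amps <- x |> distinct(.data$amplicon_id, .data$retained)
  tibble(
    n_samples = length(sample_levels(x)),
    n_amplicons = nrow(amps),
    n_masked = sum(!amps$retained),
    outlier_threshold = attr(x, "outlier_threshold") %||% NA_real_,
    median_norm_depth = stats::median(x$norm_depth[x$retained], na.rm = TRUE),
    mad_norm_depth = mad(x$norm_depth[x$retained], na.rm = TRUE)
  )
}

#' Tidy / glance CNV calls
#'
#' `tidy()` returns the calls as a plain tibble; `glance()` gives a one-row
#' batch summary (number of calls, carriers, and calls per copy state).
#'
#' @param x A `cnv_calls` tibble from [call_segments()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cnv_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "cnv_calls")
  out
}

#' @rdname tidy.cnv_calls
#' @export
glance.cnv_calls <- function(x, ...) {
  tibble(
    n_calls = nrow(x),
    n_carriers = dplyr::n_distinct(x$sample_id[seq_len(nrow(x))]),
    n_loss = sum(x$copy_state < 2),
    n_gain = sum(x$copy_state > 2)
  )
}
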