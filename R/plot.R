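#' Plot a sample's normalized depth profile
#'
#' Reproduces the review plot the method was designed around: per-amplicon
#' normalized depths as blue points in genomic order, the five-amplicon
#' smoothed curve as a red line, and grey horizontal reference lines at
#' dosage 1, 2 and 3. Masked amplicons are omitted. Grouping can be per
#' gene, per chromosome, or the whole panel in one figure (with gene
#' boundaries marked).
#'
#' @param data A `cnv_profile` tibble (smoothed on the fly if needed).
#' @param sample_id The sample to plot.
#' @param group `"per_gene"`, `"per_chromosome"`, or `"whole_panel"`.
#' @param ymax Upper y-axis limit of the dosage scale (default 4).
#' @param path Optional output directory: one PNG per grouping unit is
#'   written, named `<sample>_<group unit>.<format>`, and the file paths are
#'   returned invisibly. With `path = NULL` (default) the ggplot objects are
#'   returned (a named list, or a single plot for `"whole_panel"`).
#' @param format `"png"` (default) or `"svg"`.
#' @param dpi Raster resolution for PNG output (default 150).
#' @return ggplot object(s), or file paths invisibly when `path` is given.
#' @export
plot_profile <- function(data, sample_id,
                         group = c("per_gene", "per_chromosome", "whole_panel"),
                         ymax = 4, path = NULL, format = c("png", "svg"),
                         dpi = 150) {
  group <- match.arg(group)
  format <- match.arg(format)
  if (!is.numeric(ymax) || ymax <= 0) stopf("plot_profile(): 'ymax' must be positive")
  check_cols(data, c("amplicon_id", "chrom", "gene", "sample_id",
                     "norm_depth", "retained"), "plot_profile")
  if (!sample_id %in% sample_levels(data)) {
    stopf("sample '%s' not present in the profile", sample_id)
  }
  if (!"smooth_depth" %in% names(data)) data <- smooth_profile(data)
  df <- data |>
    filter(.data$sample_id == !!sample_id, .data$retained) |>
    sort_genomic() |>
    mutate(idx = seq_len(dplyr::n()),
           unit = switch(group,
                         per_gene = .data$gene,
                         per_chromosome = as.character(.data$chrom),
                         whole_panel = "panel"))
  units <- unique(df$unit)
  build_one <- function(u) {
    d <- df |> filter(.data$unit == u) |> mutate(x = seq_len(dplyr::n()))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x)) +
      ggplot2::geom_hline(yintercept = c(1, 2, 3), colour = "grey80",
                          linewidth = 0.3) +
      ggplot2::geom_point(ggplot2::aes(y = .data$norm_depth),
                          colour = "blue", size = 0.9, na.rm = TRUE) +
      ggplot2::geom_line(ggplot2::aes(y = .data$smooth_depth),
                         colour = "red", linewidth = 0.6, na.rm = TRUE) +
      ggplot2::coord_cartesian(ylim = c(0, ymax)) +
      ggplot2::labs(x = "amplicon (genomic order)",
                    y = "normalized relative depth",
                    title = sprintf("%s - %s", sample_id, u)) +
      ggplot2::theme_bw()
    if (group != "per_gene") {
      bounds <- d |>
        group_by(.data$gene) |>
        summarise(at = min(.data$x), mid = mean(.data$x), .groups = "drop")
      p <- p +
        ggplot2::geom_vline(xintercept = bounds$at[-1] - 0.5,
                            colour = "grey60", linetype = "dashed",
                            linewidth = 0.3) +
        ggplot2::scale_x_continuous(breaks = bounds$mid, labels = bounds$gene) +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           vjust = 0.5, size = 7))
    }
    p
  }
  plots <- setNames(lapply(units, build_one), units)
  if (is.null(path)) {
    return(if (group == "whole_panel") plots[[1]] else plots)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(units, function(u) {
    f <- file.path(path, sprintf("%s_%s.%s", sample_id, u, format))
    ggplot2::ggsave(f, plots[[u]], width = 8, height = 4, dpi = dpi,
                    device = format, bg = "white")
    f
  }, character(1))
  invisible(files)
}

#' Scatter two samples' depths against each other
#'
#' The pool-imbalance diagnostic: before normalization, a pair of samples
#' with unequal pool mixing shows two pool-specific trends in the raw-depth
#' scatter; after the within-pool relative-depth transform the pools
#' collapse onto a single trend. Both panels are drawn side by side (points
#' colored by primer pool, identity line in grey).
#'
#' @param data Long tibble with `depth` (and `rel_depth` for the
#'   post-normalization panel; computed on the fly if absent).
#' @param sample_a,sample_b Sample ids to compare.
#' @param allow_self Permit `sample_a == sample_b` (identity-line check).
#' @return A patchwork of two ggplots (raw and relative).
#' @export
plot_sample_correlation <- function(data, sample_a, sample_b,
                                    allow_self = FALSE) {
  check_cols(data, c("amplicon_id", "pool", "sample_id", "depth"),
             "plot_sample_correlation")
  if (identical(sample_a, sample_b) && !allow_self) {
    stopf("sample_a and sample_b are identical; set allow_self = TRUE if intended")
  }
  for (s in unique(c(sample_a, sample_b))) {
    if (!s %in% sample_levels(data)) stopf("sample '%s' not present", s)
  }
  if (!"rel_depth" %in% names(data)) data <- relative_depths(data)
  wide <- data |>
    filter(.data$sample_id %in% c(sample_a, sample_b)) |>
    select(all_of(c("amplicon_id", "pool", "sample_id", "depth", "rel_depth"))) |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = c("depth", "rel_depth"))
  panel <- function(xcol, ycol, lab) {
    ggplot2::ggplot(wide, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]],
                                       colour = factor(.data$pool))) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
      ggplot2::geom_point(size = 0.8, alpha = 0.7, na.rm = TRUE) +
      ggplot2::labs(x = sprintf("%s (%s)", sample_a, lab),
                    y = sprintf("%s (%s)", sample_b, lab),
                    colour = "pool", title = lab) +
      ggplot2::theme_bw()
  }
  xa <- paste0("depth_", sample_a); ya <- paste0("depth_", sample_b)
  xr <- paste0("rel_depth_", sample_a); yr <- paste0("rel_depth_", sample_b)
  if (identical(sample_a, sample_b)) {
    xa <- ya <- paste0("depth_", sample_a)
    xr <- yr <- paste0("rel_depth_", sample_a)
  }
  patchwork::wrap_plots(panel(xa, ya, "raw depth"),
                        panel(xr, yr, "relative depth"), ncol = 2L)
}

#' @describeIn plot_profile `autoplot` method: the whole-panel profile figure
#'   for one sample.
#' @param object A `cnv_profile` tibble.
#' @param ... Passed on to [plot_profile()].
#' @export
autoplot.cnv_profile <- function(object, sample_id, ...) {
  plot_profile(object, sample_id = sample_id, group = "whole_panel", ...)
}
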