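#' Five-amplicon moving-mean smoothing of a normalized profile
#'
#' Smooths each sample's normalized depths with a centered moving mean over
#' `window` amplicons, computed in genomic order within each (chromosome,
#' gene) group over retained amplicons only — the window never spans two
#' genes or two chromosomes (targeted panels have megabase gaps between
#' genes). At group edges the window is truncated to the amplicons the gene
#' offers (an edge value averages at least `(window + 1) / 2` amplicons), so
#' smoothing a constant profile returns the constant.
#'
#' @param data A `cnv_profile` tibble from [normalize_batch()].
#' @param window Odd positive window width (default 5 amplicons).
#' @return `data` with an added `smooth_depth` column (`NA` on masked
#'   amplicons).
#' @export
smooth_profile <- function(data, window = 5L) {
  check_cols(data, c("amplicon_id", "chrom", "gene", "sample_id",
                     "norm_depth", "retained"), "smooth_profile")
  if (!is.numeric(window) || length(window) != 1L || window < 1L ||
      window %% 2L == 0L) {
    stopf("smooth_profile(): 'window' must be a positive odd integer, got %s",
          deparse(window))
  }
  data <- sort_genomic(as_tibble(data))
  amp <- amplicon_table(data)
  keep <- amp$amplicon_id[amp$amplicon_id %in%
                            unique(data$amplicon_id[data$retained])]
  m <- value_matrix(filter(data, .data$retained), "norm_depth")[keep, , drop = FALSE]
  grp <- paste(amp$chrom, amp$gene, sep = "\r")[match(keep, amp$amplicon_id)]
  sm <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  half <- (window - 1L) %/% 2L
  for (g in unique(grp)) {
    rows <- which(grp == g)
    sm[rows, ] <- roll_mean_clip(m[rows, , drop = FALSE], half)
  }
  sm_long <- as_tibble(sm, rownames = "amplicon_id") |>
    tidyr::pivot_longer(-"amplicon_id", names_to = "sample_id",
                        values_to = "smooth_depth")
  out <- data |>
    select(-dplyr::any_of("smooth_depth")) |>
    mutate(sample_chr = as.character(.data$sample_id)) |>
    left_join(sm_long |> rename(sample_chr = "sample_id"),
              by = c("amplicon_id", "sample_chr")) |>
    select(-"sample_chr")
  class(out) <- class(data)
  out
}

# centered moving mean, window truncated at block edges; NA-tolerant
roll_mean_clip <- function(m, half) {
  r <- nrow(m)
  if (r == 0L) return(m)
  vals <- ifelse(is.na(m), 0, m)
  cnt <- !is.na(m) + 0
  cs_v <- rbind(0, apply(vals, 2L, cumsum))
  cs_n <- rbind(0, apply(cnt, 2L, cumsum))
  out <- matrix(NA_real_, r, ncol(m))
  for (i in seq_len(r)) {
    lo <- max(1L, i - half)
    hi <- min(r, i + half)
    s <- cs_v[hi + 1L, ] - cs_v[lo, ]
    n <- cs_n[hi + 1L, ] - cs_n[lo, ]
    out[i, ] <- ifelse(n > 0, s / n, NA_real_)
  }
  out
}

#' Flag amplicons beyond one standard deviation of the sample
#'
#' The candidate screen: per sample, amplicons whose normalized depth lies
#' more than `multiplier` standard deviations from that sample's mean over
#' all retained amplicons are flagged as CNV candidates. The standard
#' deviation uses the population formula (divide by N) by default — the
#' batch's retained amplicons are the entire population screened — with the
#' sample formula available via `sd_type`.
#'
#' @inheritParams smooth_profile
#' @param multiplier Number of standard deviations (default 1).
#' @param sd_type `"population"` (divide by N, default) or `"sample"`
#'   (divide by N-1).
#' @return `data` with a logical `sd_flag` column (`NA` on masked amplicons).
#' @export
flag_sd_candidates <- function(data, multiplier = 1,
                               sd_type = c("population", "sample")) {
  check_cols(data, c("sample_id", "norm_depth", "retained"),
             "flag_sd_candidates")
  sd_type <- match.arg(sd_type)
  sd_fun <- if (sd_type == "population") sd_pop else function(x) sd(x, na.rm = TRUE)
  out <- data |>
    group_by(.data$sample_id) |>
    mutate(.n_ret = sum(.data$retained & !is.na(.data$norm_depth)),
           .mu = mean(.data$norm_depth[.data$retained], na.rm = TRUE),
           .sigma = sd_fun(.data$norm_depth[.data$retained]),
           sd_flag = ifelse(.data$retained & !is.na(.data$norm_depth) & .data$.n_ret >= 2L,
                            abs(.data$norm_depth - .data$.mu) > multiplier * .data$.sigma,
                            NA)) |>
    ungroup()
  starved <- out |>
    filter(.data$.n_ret < 2L) |>
    distinct(.data$sample_id)
  if (nrow(starved) > 0L) {
    warnf("sample(s) with <2 retained amplicons get no SD flags: %s",
          paste(starved$sample_id, collapse = ", "))
  }
  out <- select(out, -".n_ret", -".mu", -".sigma")
  class(out) <- class(data)
  out
}

#' Sliding-window t-test of local depth against the sample background
#'
#' For every run of `window` contiguous retained amplicons within a
#' chromosome, tests whether the window's normalized depths differ from the
#' sample's remaining retained amplicons. The default is a two-sample Welch
#' test with the window excluded from the background (excluding it keeps a
#' large CNV from contaminating its own null); `mode = "one_sample"` instead
#' tests the window mean against the sample's overall mean, and
#' `exclude_window = FALSE` leaves the window in the background. The
#' two-sided p-value is assigned to the window's center amplicon.
#'
#' @inheritParams smooth_profile
#' @param mode `"two_sample"` (Welch, default) or `"one_sample"`.
#' @param exclude_window Drop the window's values from the background set
#'   (default `TRUE`).
#' @param bh Apply Benjamini-Hochberg correction across a sample's windows
#'   (default `FALSE`; the screen is an inspection aid, not an inference).
#' @return `data` with a `t_p` column: the p-value at window centers, `NA`
#'   elsewhere.
#' @export
window_t_test <- function(data, window = 5L,
                          mode = c("two_sample", "one_sample"),
                          exclude_window = TRUE, bh = FALSE) {
  check_cols(data, c("amplicon_id", "chrom", "sample_id", "norm_depth",
                     "retained"), "window_t_test")
  mode <- match.arg(mode)
  if (!is.numeric(window) || length(window) != 1L || window < 2L) {
    stopf("window_t_test(): 'window' must be an integer >= 2")
  }
  window <- as.integer(window)
  data <- sort_genomic(as_tibble(data))
  amp <- amplicon_table(data)
  keep <- amp$amplicon_id[amp$amplicon_id %in%
                            unique(data$amplicon_id[data$retained])]
  m <- value_matrix(filter(data, .data$retained), "norm_depth")[keep, , drop = FALSE]
  chrom <- amp$chrom[match(keep, amp$amplicon_id)]
  pmat <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (nrow(m) < window) {
    warnf("fewer retained amplicons (%d) than the window (%d); no windows tested",
          nrow(m), window)
  } else {
    vals <- ifelse(is.na(m), 0, m)
    nobs <- (!is.na(m)) + 0
    tot1 <- colSums(vals)
    tot2 <- colSums(vals^2)
    totn <- colSums(nobs)
    cs1 <- rbind(0, apply(vals, 2L, cumsum))
    cs2 <- rbind(0, apply(vals^2, 2L, cumsum))
    csn <- rbind(0, apply(nobs, 2L, cumsum))
    half <- window %/% 2L
    for (i in seq_len(nrow(m) - window + 1L)) {
      j <- i + window - 1L
      if (chrom[i] != chrom[j]) next
      w1 <- cs1[j + 1L, ] - cs1[i, ]
      w2 <- cs2[j + 1L, ] - cs2[i, ]
      wn <- csn[j + 1L, ] - csn[i, ]
      if (mode == "two_sample") {
        if (exclude_window) {
          b1 <- tot1 - w1; b2 <- tot2 - w2; bn <- totn - wn
        } else {
          b1 <- tot1; b2 <- tot2; bn <- totn
        }
        pmat[i + half, ] <- welch_p(w1, w2, wn, b1, b2, bn)
      } else {
        mu_all <- ifelse(totn > 0, tot1 / totn, NA_real_)
        pmat[i + half, ] <- one_sample_p(w1, w2, wn, mu_all)
      }
    }
    if (bh) pmat <- apply(pmat, 2L, function(p) {
      ok <- !is.na(p); p[ok] <- p.adjust(p[ok], method = "BH"); p
    })
  }
  p_long <- as_tibble(pmat, rownames = "amplicon_id") |>
    tidyr::pivot_longer(-"amplicon_id", names_to = "sample_id",
                        values_to = "t_p")
  out <- data |>
    select(-dplyr::any_of("t_p")) |>
    mutate(sample_chr = as.character(.data$sample_id)) |>
    left_join(p_long |> rename(sample_chr = "sample_id"),
              by = c("amplicon_id", "sample_chr")) |>
    select(-"sample_chr")
  class(out) <- class(data)
  out
}

# vectorized two-sided Welch p from group sums/sums-of-squares/counts;
# zero pooled SE: p = 1 when means equal, 0 otherwise (limit convention)
welch_p <- function(s1, q1, n1, s2, q2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- pmax(0, (q1 - s1^2 / n1) / (n1 - 1))
  v2 <- pmax(0, (q2 - s2^2 / n2) / (n2 - 1))
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, length(s1))
  zero <- ok & se2 <= 0
  p[zero] <- ifelse(abs(m1[zero] - m2[zero]) <= .Machine$double.eps^0.5, 1, 0)
  pos <- ok & se2 > 0
  tstat <- (m1[pos] - m2[pos]) / sqrt(se2[pos])
  df <- se2[pos]^2 / (v1[pos]^2 / (n1[pos]^2 * (n1[pos] - 1)) +
                        v2[pos]^2 / (n2[pos]^2 * (n2[pos] - 1)))
  df[!is.finite(df)] <- pmax(n1[pos], n2[pos])[!is.finite(df)]
  p[pos] <- 2 * pt(-abs(tstat), df)
  p
}

one_sample_p <- function(s1, q1, n1, mu0) {
  ok <- n1 >= 2 & !is.na(mu0)
  m1 <- s1 / n1
  v1 <- pmax(0, (q1 - s1^2 / n1) / (n1 - 1))
  p <- rep(NA_real_, length(s1))
  zero <- ok & v1 <= 0
  p[zero] <- ifelse(abs(m1[zero] - mu0[zero]) <= .Machine$double.eps^0.5, 1, 0)
  pos <- ok & v1 > 0
  tstat <- (m1[pos] - mu0[pos]) / sqrt(v1[pos] / n1[pos])
  p[pos] <- 2 * pt(-abs(tstat), n1[pos] - 1)
  p
}

# membership test used by boundary refinement: the band edge nearest diploid
# is kept, the far edge is dropped for gains (count noise scales with dosage,
# so a true 3-copy amplicon overshoots 3.5 as easily as a diploid one drifts
# over 2.5)
ext_band <- function(x, st) {
  if (is.na(x)) return(FALSE)
  switch(as.character(st),
         "0" = x < 0.5,
         "1" = x >= 0.5 & x < 1.5,
         "3" = x > 2.5,
         "4" = x > 3.5,
         FALSE)
}

# gaussian model cost of values under one copy state (spread scales with the
# state mean; used for changepoint refinement and overlap arbitration).
# mu overrides the model mean with a segment's empirical level.
state_cost <- function(x, st, sigma2, mu = st) {
  sig <- max(sigma2 * max(st, 0.5) / 2, sigma2 / 4)
  n <- sum(!is.na(x))
  sum(((x - mu) / sig)^2, na.rm = TRUE) + 2 * n * log(sig)
}

# clamp an empirical segment level to its copy-state band so a contaminated
# seed cannot drag the model mean across a band edge
clamp_band <- function(mu, st) {
  lims <- switch(as.character(st),
                 "0" = c(0, 0.5), "1" = c(0.5, 1.5),
                 "3" = c(2.5, 3.5), "4" = c(3.5, Inf), c(1.5, 2.5))
  min(max(mu, lims[1]), lims[2])
}

# local weighted least-squares changepoint fit for both edges of a segment
# [i, j] in state st; returns the refined c(i, j). sigma2 is the sample's
# dosage-2 noise scale; each side's spread scales with its model mean.
ls_refine <- function(band_raw, chrom, i, j, st, sigma2, radius = 4L) {
  n <- length(band_raw)
  mu_ev <- clamp_band(stats::median(band_raw[i:j], na.rm = TRUE), st)
  cost_split <- function(ks, b, event_leq) {
    ev <- if (event_leq) ks <= b else ks >= b
    state_cost(band_raw[ks][ev], st, sigma2, mu = mu_ev) +
      state_cost(band_raw[ks][!ev], 2, sigma2)
  }
  # left edge: candidate b = first event amplicon
  lo <- i
  while (lo > 1L && i - lo < radius && chrom[lo - 1L] == chrom[i]) lo <- lo - 1L
  hi <- min(i + radius, j)
  ks <- lo:hi
  cand <- lo:hi
  costs <- vapply(cand, function(b) cost_split(ks, b, event_leq = FALSE),
                  numeric(1))
  i_new <- cand[which.min(costs)]
  # right edge: candidate b = last event amplicon
  hi2 <- j
  while (hi2 < n && hi2 - j < radius && chrom[hi2 + 1L] == chrom[j]) hi2 <- hi2 + 1L
  lo2 <- max(j - radius, i_new)
  ks2 <- lo2:hi2
  cand2 <- lo2:hi2
  costs2 <- vapply(cand2, function(b) cost_split(ks2, b, event_leq = TRUE),
                   numeric(1))
  j_new <- cand2[which.min(costs2)]
  c(i_new, j_new)
}

# copy-state band of a dosage value: 0 [0,0.5), 1 [0.5,1.5), diploid (NA)
# [1.5,2.5], 3 (2.5,3.5], 4 above. NA in -> NA out.
copy_state_band <- function(x) {
  state <- rep(NA_integer_, length(x))
  state[!is.na(x) & x < 0.5] <- 0L
  state[!is.na(x) & x >= 0.5 & x < 1.5] <- 1L
  state[!is.na(x) & x > 2.5 & x <= 3.5] <- 3L
  state[!is.na(x) & x > 3.5] <- 4L
  state
}

#' Call copy-number segments from a smoothed profile
#'
#' The explicit, reproducible surrogate for manual inspection of the depth
#' plots: per sample, maximal runs of contiguous retained amplicons (within a
#' chromosome, across gene boundaries) whose smoothed depth falls in one
#' non-diploid copy-state band become calls when at least `min_run` amplicons
#' long. Bands sit at the dosage midpoints: state 0 below 0.5, state 1 in
#' \[0.5, 1.5), diploid (no call) in \[1.5, 2.5\], state 3 in (2.5, 3.5\],
#' state 4 (i.e. 4 or more copies) above. Because smoothing blurs event
#' edges, each run boundary is then refined against the unsmoothed values:
#' the run extends over adjacent amplicons whose raw normalized depth lies in
#' the same band. Each call carries the run's mean normalized depth, whether
#' at least half its amplicons carry the ±1 SD candidate flag, and the
#' minimum window t-test p-value over the run.
#'
#' Missing upstream columns (`smooth_depth`, `sd_flag`, `t_p`) are computed
#' on the fly with default parameters, so
#' `normalize_batch(x) |> call_segments()` works directly.
#'
#' @inheritParams smooth_profile
#' @param min_run Minimum number of amplicons in a callable run (default 3).
#' @param refine_boundaries Extend run edges over adjacent amplicons whose
#'   raw value sits in the called band (default `TRUE`).
#' @param recenter Rescale each sample's profile by its median over retained
#'   amplicons before band assignment (default `TRUE`). A large CNV shifts
#'   its carrier's own pool mean (Eq.-level behavior of the pool-relative
#'   normalization), sliding the whole profile off the diploid = 2 baseline;
#'   the median restores it while most of the panel is diploid. Reported
#'   `mean_norm_depth` stays on the unrescaled normalized scale.
#' @param merge_gap Merge same-state runs on one chromosome separated by at
#'   most this many amplicons (default 3). At a 15% depth coefficient of
#'   variation, a pair of adjacent gain amplicons drifts below the band edge
#'   often enough to punch short holes in a long true event (a
#'   whole-chromosome trisomy in particular); bridging holes up to 3
#'   amplicons repairs those splits while leaving well-separated events
#'   distinct.
#' @param window Smoothing / t-test window used when those columns must be
#'   computed here.
#' @return A `cnv_calls` tibble: `sample_id`, `chrom`, `gene` (comma-joined
#'   when a run spans genes), `first_amplicon`, `last_amplicon`, `start`,
#'   `end` (1-based inclusive), `n_amplicons`, `copy_state`,
#'   `mean_norm_depth`, `sd_flag`, `t_p_value`. Zero rows when the batch is
#'   all-diploid.
#' @examples
#' cfg <- sim_config(n_samples = 8, noise = "none", seed = 2,
#'                   events = list(cnv_event("S03", copies = 1, gene = "GENE05",
#'                                           first = 3, last = 12)))
#' sim <- simulate_batch(cfg)
#' normalize_batch(sim$data) |> call_segments()
#' @export
call_segments <- function(data, min_run = 3L, refine_boundaries = TRUE,
                          merge_gap = 3L, recenter = TRUE, window = 5L) {
  check_cols(data, c("amplicon_id", "chrom", "start", "end", "gene",
                     "sample_id", "norm_depth", "retained"), "call_segments")
  if (!"smooth_depth" %in% names(data)) data <- smooth_profile(data, window = window)
  if (!"sd_flag" %in% names(data)) data <- flag_sd_candidates(data)
  if (!"t_p" %in% names(data)) {
    data <- suppressWarnings(window_t_test(data, window = window))
  }
  data <- sort_genomic(as_tibble(data))
  amp <- amplicon_table(data)
  keep <- amp$amplicon_id[amp$amplicon_id %in%
                            unique(data$amplicon_id[data$retained])]
  ret <- filter(data, .data$retained)
  raw <- value_matrix(ret, "norm_depth")[keep, , drop = FALSE]
  smo <- value_matrix(ret, "smooth_depth")[keep, , drop = FALSE]
  flg <- value_matrix(mutate(ret, sd_flag = as.numeric(.data$sd_flag)),
                      "sd_flag")[keep, , drop = FALSE]
  pvl <- value_matrix(ret, "t_p")[keep, , drop = FALSE]
  ainfo <- amp[match(keep, amp$amplicon_id), ]
  calls <- purrr::map(colnames(raw), function(s) {
    segment_one_sample(raw[, s], smo[, s], flg[, s], pvl[, s], ainfo,
                       sample_id = s, min_run = min_run,
                       refine = refine_boundaries, merge_gap = merge_gap,
                       recenter = recenter)
  }) |> bind_rows()
  if (nrow(calls) == 0L) {
    calls <- tibble(sample_id = character(), chrom = character(),
                    gene = character(), first_amplicon = character(),
                    last_amplicon = character(), start = integer(),
                    end = integer(), n_amplicons = integer(),
                    copy_state = integer(), mean_norm_depth = double(),
                    sd_flag = logical(), t_p_value = double())
  }
  calls$sample_id <- factor(calls$sample_id, levels = sample_levels(data))
  class(calls) <- c("cnv_calls", class(calls))
  calls
}

segment_one_sample <- function(raw, smo, flg, pvl, ainfo, sample_id,
                               min_run, refine, merge_gap = 3L,
                               recenter = TRUE) {
  # a large event inflates (gain) or deflates (loss) the carrier's own pool
  # mean, shifting the whole profile off the diploid = 2 baseline. The
  # baseline is recovered from the autosomal median (chrX dosage is sex-
  # dependent by design and would bias it), tightened by a second pass over
  # values the first pass places in the diploid band so that a large event
  # (e.g. a trisomy block) cannot drag the centre either.
  chrom_raw <- as.character(ainfo$chrom)
  autosomal <- !toupper(sub("^chr", "", chrom_raw, ignore.case = TRUE)) %in% c("X", "Y")
  scale <- 1
  if (recenter) {
    med <- stats::median(raw[autosomal], na.rm = TRUE)
    if (is.finite(med) && med > 0) {
      v <- raw / (med / 2)
      dip <- autosomal & !is.na(v) & v >= 1.5 & v <= 2.5
      med2 <- if (sum(dip) >= 10L) stats::median(v[dip]) else 2
      scale <- (med / 2) * (med2 / 2)
    }
  }
  band_raw <- raw / scale
  state <- copy_state_band(smo / scale)
  chrom <- as.character(ainfo$chrom)
  # encode diploid/NA as distinct run-breaking codes; break runs at chromosome
  # changes by folding the chromosome into the run key
  code <- ifelse(is.na(smo), "na", ifelse(is.na(state), "dip", state))
  key <- paste(chrom, code)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  callable <- grepl(" [0-9]+$", r$values) & r$lengths >= min_run
  if (!any(callable)) return(NULL)
  segs <- purrr::map(which(callable), function(k) {
    i <- starts[k]; j <- ends[k]
    st <- state[i]
    if (refine) {
      n_amp <- length(raw)
      # one out-of-band amplicon may be stepped over, but only when the two
      # amplicons beyond it both continue the run (prevents a lone stray
      # diploid value from dragging the boundary outward by two)
      while (i > 1L && chrom[i - 1L] == chrom[i]) {
        if (ext_band(band_raw[i - 1L], st)) i <- i - 1L
        else if (i > 3L && chrom[i - 3L] == chrom[i] &&
                 ext_band(band_raw[i - 2L], st) &&
                 ext_band(band_raw[i - 3L], st)) i <- i - 2L
        else break
      }
      while (j < n_amp && chrom[j + 1L] == chrom[j]) {
        if (ext_band(band_raw[j + 1L], st)) j <- j + 1L
        else if (j < n_amp - 2L && chrom[j + 3L] == chrom[j] &&
                 ext_band(band_raw[j + 2L], st) &&
                 ext_band(band_raw[j + 3L], st)) j <- j + 2L
        else break
      }
    }
    tibble(i = i, j = j, copy_state = st)
  }) |> bind_rows()
  # boundary refinement can make same-state runs touch or overlap, and an
  # unsmoothed gene-edge amplicon can punch a 1-amplicon hole in a real run:
  # merge same-state runs separated by <= merge_gap amplicons
  segs <- segs |> arrange(.data$i, .data$j)
  merged <- list()
  for (k in seq_len(nrow(segs))) {
    cur <- segs[k, ]
    last <- if (length(merged) > 0L) merged[[length(merged)]] else NULL
    if (!is.null(last) && cur$copy_state == last$copy_state &&
        chrom[cur$i] == chrom[last$j] && cur$i <= last$j + 1L + merge_gap) {
      merged[[length(merged)]]$j <- max(last$j, cur$j)
    } else {
      merged[[length(merged) + 1L]] <- cur
    }
  }
  if (refine) {
    # final boundary placement by local weighted least squares: near each
    # edge, every candidate changepoint is scored with the flank modelled at
    # dosage 2 and the segment at the called state, the spread of each side
    # scaling with its mean (count noise is multiplicative); this pools the
    # evidence of all amplicons near the edge instead of thresholding them
    # one at a time
    sigma2 <- max(mad(band_raw[autosomal], center = 2, na.rm = TRUE), 0.05)
    merged <- purrr::map(merged, function(sg) {
      b <- ls_refine(band_raw, chrom, sg$i, sg$j, sg$copy_state, sigma2)
      sg$i <- b[1]; sg$j <- b[2]
      sg
    })
    # refinement can leave neighbours overlapping; same-state neighbours are
    # folded into one, different-state claims on the same amplicons are
    # resolved by model cost over the disputed stretch (a smoothing window
    # straddling a sharp event edge seeds a short run of an intermediate
    # state, which then loses the contested amplicons to the true state)
    if (length(merged) > 1L) {
      folded <- list(merged[[1L]])
      for (k in 2L:length(merged)) {
        cur <- merged[[k]]
        last <- folded[[length(folded)]]
        if (cur$copy_state == last$copy_state && chrom[cur$i] == chrom[last$j] &&
            cur$i <= last$j + 1L) {
          folded[[length(folded)]]$j <- max(last$j, cur$j)
        } else {
          if (cur$i <= last$j && chrom[cur$i] == chrom[last$j]) {
            ov <- cur$i:last$j
            if (state_cost(band_raw[ov], cur$copy_state, sigma2) <
                state_cost(band_raw[ov], last$copy_state, sigma2)) {
              folded[[length(folded)]]$j <- cur$i - 1L
            } else {
              cur$i <- last$j + 1L
            }
          }
          folded[[length(folded) + 1L]] <- cur
        }
      }
      merged <- purrr::keep(folded, ~ .x$j >= .x$i)
    }
    # changepoint-penalized gap arbitration: two same-state segments with a
    # short ambiguous stretch between them are one event if modelling the
    # gap at the event level costs less than modelling it diploid plus the
    # two extra changepoints a split implies (BIC-style penalty)
    if (length(merged) > 1L) {
      lambda <- 2 * log(sum(!is.na(band_raw)))
      bridged <- list(merged[[1L]])
      for (k in 2L:length(merged)) {
        cur <- merged[[k]]
        last <- bridged[[length(bridged)]]
        joinable <- cur$copy_state == last$copy_state &&
          chrom[cur$i] == chrom[last$j]
        if (joinable) {
          gap <- if (cur$i > last$j + 1L) (last$j + 1L):(cur$i - 1L) else integer(0)
          mu_ev <- clamp_band(
            stats::median(band_raw[c(last$i:last$j, cur$i:cur$j)], na.rm = TRUE),
            cur$copy_state)
          merge_cost <- state_cost(band_raw[gap], cur$copy_state, sigma2, mu = mu_ev)
          split_cost <- state_cost(band_raw[gap], 2, sigma2) + 2 * lambda
          if (merge_cost < split_cost) {
            bridged[[length(bridged)]]$j <- cur$j
            next
          }
        }
        bridged[[length(bridged) + 1L]] <- cur
      }
      merged <- bridged
    }
    # after refinement a segment must still be a callable run: long enough
    # and non-diploid on average
    merged <- purrr::keep(merged, function(sg) {
      sg$j - sg$i + 1L >= min_run &&
        !is.na(copy_state_band(mean(band_raw[sg$i:sg$j], na.rm = TRUE)))
    })
  }
  purrr::map(merged, function(sg) {
    i <- sg$i; j <- sg$j
    idx <- i:j
    pv <- pvl[idx]
    tibble(
      sample_id = sample_id,
      chrom = chrom[i],
      gene = paste(unique(as.character(ainfo$gene[idx])), collapse = ","),
      first_amplicon = ainfo$amplicon_id[i],
      last_amplicon = ainfo$amplicon_id[j],
      start = ainfo$start[i] + 1L,  # report 1-based inclusive
      end = ainfo$end[j],
      n_amplicons = length(idx),
      copy_state = sg$copy_state,
      mean_norm_depth = mean(raw[idx], na.rm = TRUE),
      sd_flag = mean(flg[idx], na.rm = TRUE) >= 0.5,
      t_p_value = if (all(is.na(pv))) NA_real_ else min(pv, na.rm = TRUE)
    )
  }) |> bind_rows()
}

#' Per-sample batch quality control
#'
#' Some libraries cannot be analyzed: large imbalances between primer pools
#' leave one pool at very low absolute depth, whose count noise scatters the
#' whole normalized profile. This reports, per sample, the scaled median
#' absolute deviation (MAD) of the retained normalized depths as a dispersion
#' statistic, the raw pool-mean ratio (pool 1 over pool 2 for two-pool
#' panels; max over min otherwise), and an `analyzable` verdict
#' (`MAD <= qc_threshold`).
#'
#' @inheritParams smooth_profile
#' @param qc_threshold Maximum acceptable MAD of the normalized depths
#'   (default 0.5 — a quarter of the diploid level).
#' @return A tibble with `sample_id`, `mad_norm`, `pool_ratio`, `analyzable`.
#' @export
batch_qc <- function(data, qc_threshold = 0.5) {
  check_cols(data, c("sample_id", "pool", "depth", "norm_depth", "retained"),
             "batch_qc")
  disp <- data |>
    group_by(.data$sample_id) |>
    summarise(mad_norm = mad(.data$norm_depth[.data$retained], na.rm = TRUE),
              .groups = "drop")
  ratio <- data |>
    group_by(.data$sample_id, .data$pool) |>
    summarise(mean_depth = mean(.data$depth), .groups = "drop") |>
    group_by(.data$sample_id) |>
    summarise(pool_ratio = if (dplyr::n() == 1L) NA_real_
              else if (all(sort(unique(.data$pool)) == c(1L, 2L)))
                .data$mean_depth[.data$pool == 1L] / .data$mean_depth[.data$pool == 2L]
              else max(.data$mean_depth) / min(.data$mean_depth),
              .groups = "drop")
  disp |>
    left_join(ratio, by = "sample_id") |>
    mutate(analyzable = !is.na(.data$mad_norm) & .data$mad_norm <= qc_threshold)
}
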