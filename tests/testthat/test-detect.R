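# builds a profile tibble directly (norm_depth given), bypassing
# normalization, so smoothing/flagging arithmetic can be checked by hand
manual_profile <- function(values, design = tiny_design(length(values)),
                           retained = TRUE) {
  prof <- tiny_dataset(matrix(1, nrow(design), 1), design) |>
    dplyr::mutate(rel_depth = NA_real_, ref_depth = 1,
                  norm_depth = values, retained = retained)
  class(prof) <- c("cnv_profile", class(prof))
  prof
}

test_that("smoothing reproduces hand-computed moving means", {
  # constant profile stays constant
  p <- smooth_profile(manual_profile(rep(2, 9)))
  expect_equal(p$smooth_depth, rep(2, 9))
  # one-copy-loss run: centre of the run is the plain 5-mean
  vals <- c(2, 2, 1, 1, 1, 1, 1, 2, 2)
  p <- smooth_profile(manual_profile(vals))
  expect_equal(p$smooth_depth[5], 1)                     # mean(1,1,1,1,1)
  expect_equal(p$smooth_depth[3], mean(c(2, 2, 1, 1, 1)))
  expect_equal(p$smooth_depth[2], mean(vals[1:4]))       # truncated window
  expect_equal(p$smooth_depth[1], mean(vals[1:3]))
  # 3-amplicon gene with window 5: every value is the mean of the 3
  p3 <- smooth_profile(manual_profile(c(1, 2, 3), tiny_design(3L)))
  expect_equal(p3$smooth_depth, rep(2, 3))
})

test_that("smoothing never crosses gene or chromosome boundaries", {
  design <- tiny_design(6L, chrom = c(rep("chr1", 3), rep("chr2", 3)),
                        gene = c(rep("GA", 3), rep("GB", 3)))
  vals <- c(0, 0, 0, 4, 4, 4)
  p <- smooth_profile(manual_profile(vals, design))
  expect_equal(p$smooth_depth, vals)  # each gene is constant within itself
  expect_error(smooth_profile(manual_profile(rep(2, 6)), window = 4),
               "odd")
  # masked amplicons are skipped, not averaged in
  pm <- smooth_profile(manual_profile(c(2, 99, 2, 2, 2, 2),
                                      retained = c(TRUE, FALSE, rep(TRUE, 4))))
  expect_true(all(pm$smooth_depth[pm$retained] == 2))
  expect_true(is.na(pm$smooth_depth[2]))
})

test_that("smoothing is range-bounded (never widens the value range)", {
  set.seed(31)
  vals <- runif(30, 0, 4)
  p <- smooth_profile(manual_profile(vals, tiny_design(30L)))
  expect_true(all(p$smooth_depth >= min(vals) - 1e-12))
  expect_true(all(p$smooth_depth <= max(vals) + 1e-12))
})

test_that("SD candidate flags use the population formula and a strict rule", {
  prof <- manual_profile(c(2, 2, 2, 2, 0))
  f <- flag_sd_candidates(prof)
  # mu = 1.6, population sigma = 0.8: only the zero deviates by more
  expect_equal(f$sd_flag, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # sigma = 0 -> nothing flagged
  f0 <- flag_sd_candidates(manual_profile(rep(2, 5)))
  expect_false(any(f0$sd_flag))
  # sample-SD variant widens sigma, still flags only the outlier
  fs <- flag_sd_candidates(prof, sd_type = "sample")
  expect_equal(fs$sd_flag[5], TRUE)
})

test_that("a single outlier in a long near-constant profile is the only flag", {
  set.seed(8)
  vals <- 2 + rnorm(400, sd = 0.01)
  vals[123] <- 0.4
  design <- tiny_design(400L, gene = rep(sprintf("G%02d", 1:20), each = 20))
  f <- flag_sd_candidates(manual_profile(vals, design))
  expect_equal(which(f$sd_flag), 123L)
})

test_that("flag count is invariant under amplicon relabeling", {
  set.seed(12)
  vals <- c(rnorm(20, 2, 0.2), rnorm(4, 0.9, 0.1))
  perm <- sample(24)
  f1 <- flag_sd_candidates(manual_profile(vals, tiny_design(24L)))
  f2 <- flag_sd_candidates(manual_profile(vals[perm], tiny_design(24L)))
  expect_equal(sum(f1$sd_flag), sum(f2$sd_flag))
})

test_that("windowed Welch p-values agree with stats::t.test to 1e-10", {
  set.seed(77)
  vals <- rnorm(40, 2, 0.3)
  design <- tiny_design(40L)
  prof <- window_t_test(manual_profile(vals, design))
  w <- 5L; half <- w %/% 2L
  for (c_idx in c(3, 10, 25, 38)) {
    i <- c_idx - half
    if (i < 1 || i + w - 1 > 40) next
    win <- vals[i:(i + w - 1)]
    bg <- vals[-(i:(i + w - 1))]
    expect_equal(prof$t_p[c_idx], stats::t.test(win, bg)$p.value,
                 tolerance = 1e-10)
  }
  # one-sample mode against the global mean
  prof1 <- window_t_test(manual_profile(vals, design), mode = "one_sample")
  win <- vals[9:13]
  expect_equal(prof1$t_p[11],
               stats::t.test(win, mu = mean(vals))$p.value, tolerance = 1e-10)
  # include-all background
  prof2 <- window_t_test(manual_profile(vals, design), exclude_window = FALSE)
  expect_equal(prof2$t_p[11], stats::t.test(vals[9:13], vals)$p.value,
               tolerance = 1e-10)
})

test_that("window t-test null and signal behave as expected", {
  # a clearly shifted window is strongly significant
  vals <- c(rnorm(20, 2, 0.05), rep(1, 5), rnorm(20, 2, 0.05))
  set.seed(2)
  prof <- window_t_test(manual_profile(vals, tiny_design(45L)))
  expect_lt(prof$t_p[23], 0.01)
  # zero variance in both groups: p = 1 when means equal, 0 otherwise
  flat <- window_t_test(manual_profile(rep(2, 12), tiny_design(12L)))
  expect_true(all(flat$t_p[3:10] == 1))
  step <- window_t_test(manual_profile(c(rep(1, 5), rep(2, 7)), tiny_design(12L)))
  expect_equal(step$t_p[3], 0)
  # window larger than the panel: warning, no p-values
  expect_warning(small <- window_t_test(manual_profile(rep(2, 3), tiny_design(3L))),
                 "fewer retained")
  expect_true(all(is.na(small$t_p)))
})

test_that("BH correction is monotone and only rescales upward", {
  set.seed(5)
  vals <- rnorm(60, 2, 0.3)
  p_raw <- window_t_test(manual_profile(vals, tiny_design(60L)))
  p_bh <- window_t_test(manual_profile(vals, tiny_design(60L)), bh = TRUE)
  ok <- !is.na(p_raw$t_p)
  expect_true(all(p_bh$t_p[ok] >= p_raw$t_p[ok] - 1e-12))
})

test_that("noiseless events are called with exact boundaries and states", {
  events <- list(cnv_event("S02", 1, gene = "GENE03", first = 3, last = 12),
                 cnv_event("S03", 0, gene = "GENE05", first = 3, last = 12),
                 cnv_event("S04", 3, gene = "GENE07", first = 3, last = 12),
                 cnv_event("S05", 3, chrom = "chr21"))
  cfg <- sim_config(n_samples = 8, noise = "none", sexes = "female",
                    events = events, seed = 1)
  sim <- simulate_batch(cfg)
  calls <- call_segments(normalize_batch(sim$data))
  expect_s3_class(calls, "cnv_calls")
  # no chrX dosage signal in an all-female batch, so only the 4 events call
  expect_equal(nrow(calls), 4L)
  idx <- stats::setNames(seq_len(nrow(sim$design)), sim$design$amplicon_id)
  got <- calls |>
    dplyr::mutate(fi = idx[first_amplicon], li = idx[last_amplicon]) |>
    dplyr::arrange(fi)
  tr <- dplyr::arrange(sim$truth, first_index)
  expect_equal(got$fi, tr$first_index, ignore_attr = TRUE)
  expect_equal(got$li, tr$last_index, ignore_attr = TRUE)
  expect_equal(got$copy_state, tr$copies)
  expect_equal(as.character(got$sample_id), tr$sample_id)
  # the trisomy call spans both chr21 genes
  expect_match(got$gene[got$chrom == "chr21"], "GENE17,GENE18")
  # evidence columns: losses/gains are SD-flagged and their windows unlikely
  expect_true(all(got$sd_flag[got$copy_state != 3 | got$chrom == "chr21"]))
  expect_true(all(got$t_p_value < 0.01, na.rm = TRUE))
  # reported coordinates are 1-based inclusive
  a_first <- sim$design[idx[got$first_amplicon[1]], ]
  expect_equal(got$start[1], a_first$start + 1L)
})

test_that("an all-diploid batch yields no calls", {
  sim <- simulate_batch(sim_config(n_samples = 6, noise = "none",
                                   sexes = "female", seed = 10))
  calls <- call_segments(normalize_batch(sim$data))
  expect_equal(nrow(calls), 0L)
})

test_that("batch QC separates clean from imbalanced/overdispersed libraries", {
  clean <- simulate_batch(sim_config(n_samples = 10, seed = 21))
  qc_clean <- batch_qc(normalize_batch(clean$data))
  expect_true(all(qc_clean$analyzable))
  # ratio reflects only the pools' efficiency asymmetry, not a library bias
  expect_true(all(qc_clean$pool_ratio > 0.7 & qc_clean$pool_ratio < 1.5))

  messy <- simulate_batch(sim_config(n_samples = 10, seed = 22,
                                     pool_imbalance = 8, nb_size = 4))
  qc_messy <- batch_qc(normalize_batch(messy$data))
  expect_true(mean(qc_messy$analyzable) < 0.5)
  expect_true(all(qc_messy$pool_ratio < 0.3))  # pool 2 boosted 8x

  # noiseless diploid sample: MAD exactly 0
  quiet <- simulate_batch(sim_config(n_samples = 4, noise = "none",
                                     sexes = "female", seed = 23))
  qc_quiet <- batch_qc(normalize_batch(quiet$data))
  expect_equal(qc_quiet$mad_norm, rep(0, 4))

  # pool ratio is mean(pool1 depths) / mean(pool2 depths)
  ds <- tiny_dataset(cbind(c(100, 50), c(200, 100)),
                     tiny_design(2L, pools = c(1L, 2L)))
  qc <- batch_qc(normalize_batch(ds))
  expect_equal(qc$pool_ratio, c(2, 2))
})
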