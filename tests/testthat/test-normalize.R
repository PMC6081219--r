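test_that("pool means are per-sample, per-pool arithmetic means", {
  depth <- cbind(c(100, 200, 300, 7), c(10, 20, 30, 40))
  ds <- tiny_dataset(depth, tiny_design(4L, pools = c(1L, 1L, 1L, 2L)))
  pm <- pool_mean_depths(ds)
  expect_equal(pm$mean_depth[pm$sample_id == "S01" & pm$pool == 1], 200)
  expect_equal(pm$mean_depth[pm$sample_id == "S01" & pm$pool == 2], 7)
  expect_equal(pm$n_amplicons[pm$pool == 1], c(3L, 3L))
  expect_true(all(pm$analyzable))
})

test_that("an all-zero pool is flagged and its relative depths are NA", {
  depth <- cbind(c(100, 0, 200, 0), c(100, 50, 200, 80))
  ds <- tiny_dataset(depth, tiny_design(4L, pools = c(1L, 2L, 1L, 2L)))
  pm <- pool_mean_depths(ds)
  expect_false(pm$analyzable[pm$sample_id == "S01" & pm$pool == 2])
  expect_warning(rel <- relative_depths(ds, pm), "pool mean is 0")
  bad <- dplyr::filter(rel, sample_id == "S01", pool == 2)
  expect_true(all(is.na(bad$rel_depth)))
  ok <- dplyr::filter(rel, sample_id == "S01", pool == 1)
  expect_equal(ok$rel_depth, c(100, 200) / 150)
})

test_that("relative depth identities hold", {
  # depth equal to the pool mean -> 1; uniform pool -> all 1
  depth <- cbind(c(400, 200, 300, 300), c(50, 50, 80, 80))
  ds <- tiny_dataset(depth, tiny_design(4L, pools = c(1L, 1L, 2L, 2L)))
  rel <- relative_depths(ds)
  s1 <- dplyr::filter(rel, sample_id == "S01")
  expect_equal(s1$rel_depth, c(400 / 300, 200 / 300, 1, 1))
  s2 <- dplyr::filter(rel, sample_id == "S02")
  expect_equal(s2$rel_depth, rep(1, 4))
})

test_that("batch reference averages relative depths across samples", {
  depth <- cbind(c(100, 50), c(300, 150), c(200, 100))
  ds <- tiny_dataset(depth, tiny_design(2L, pools = c(1L, 1L)))
  rel <- relative_depths(ds)
  ref <- batch_reference(rel)
  # every sample has the same composition, so the reference is the composition
  expect_equal(ref$ref_depth[ref$amplicon_id == "AMP01"], 100 / 75)
  expect_equal(ref$ref_depth[ref$amplicon_id == "AMP02"], 50 / 75)
  expect_equal(ref$n_samples, c(3L, 3L))
  expect_error(batch_reference(dplyr::filter(rel, sample_id == "S01")),
               "at least 2 samples")
})

test_that("normalization follows the closed form when one value is halved", {
  depth <- cbind(c(100, 100, 100, 100), c(100, 50, 100, 100),
                 c(100, 100, 100, 100))
  ds <- tiny_dataset(depth, tiny_design(4L, pools = rep(1L, 4)))
  prof <- normalize_batch(ds)
  expect_true(all(prof$retained))
  # hand-derived: S02's pool mean is 87.5, so its relative depths are 8/7
  # (untouched) and 4/7 (halved); references are 22/21 and 6/7
  v2 <- dplyr::filter(prof, amplicon_id == "AMP02")
  expect_equal(v2$norm_depth[v2$sample_id == "S02"], 4 / 3, tolerance = 1e-12)
  expect_equal(v2$norm_depth[v2$sample_id == "S01"], 7 / 3, tolerance = 1e-12)
  v1 <- dplyr::filter(prof, amplicon_id == "AMP01")
  expect_equal(v1$norm_depth[v1$sample_id == "S01"], 21 / 11, tolerance = 1e-12)
  expect_equal(v1$norm_depth[v1$sample_id == "S02"], 24 / 11, tolerance = 1e-12)
})

test_that("conservation and batch-mean-2 invariants hold on noisy batches", {
  for (seed in c(5, 17)) {
    sim <- simulate_batch(sim_config(n_samples = 10, seed = seed))
    prof <- normalize_batch(sim$data)
    bypool <- prof |>
      dplyr::group_by(sample_id, pool) |>
      dplyr::summarise(m = mean(rel_depth), .groups = "drop")
    expect_true(all(abs(bypool$m - 1) < 1e-9))
    byamp <- prof |>
      dplyr::filter(retained) |>
      dplyr::group_by(amplicon_id) |>
      dplyr::summarise(m = mean(norm_depth), .groups = "drop")
    expect_true(all(abs(byamp$m - 2) < 1e-9))
  }
})

test_that("per-sample scaling and pool-wide bias cancel out", {
  sim <- simulate_batch(sim_config(n_samples = 6, seed = 9))
  base <- normalize_batch(sim$data)
  # scale one sample's every depth by c > 0: its relative and normalized
  # depths must not move
  scaled <- sim$data |>
    dplyr::mutate(depth = ifelse(as.character(sample_id) == "S03",
                                 depth * 3.7, depth))
  prof_s <- normalize_batch(scaled)
  expect_equal(prof_s$rel_depth, base$rel_depth, tolerance = 1e-12)
  expect_equal(prof_s$norm_depth, base$norm_depth, tolerance = 1e-12)
  # multiplicative bias on pool 2 across all samples: invisible after Eq. 2
  biased <- sim$data |>
    dplyr::mutate(depth = ifelse(pool == 2L, depth * 2.4, depth))
  prof_b <- normalize_batch(biased)
  expect_equal(prof_b$norm_depth, base$norm_depth, tolerance = 1e-12)
})

test_that("vectorized pipeline equals the naive loop oracle to 1e-12", {
  set.seed(42)
  for (k in 1:10) {
    n_amp <- sample(2:5, 1); n_smp <- sample(2:5, 1)
    depth <- matrix(sample(0:500, n_amp * n_smp, replace = TRUE), n_amp)
    pools <- sample(1:2, n_amp, replace = TRUE)
    ds <- tiny_dataset(depth, tiny_design(n_amp, pools = pools))
    oracle <- naive_normalize(depth, pools)
    prof <- suppressWarnings(normalize_batch(ds, outlier_threshold = 0))
    got <- value_mat <- matrix(prof$norm_depth[order(match(prof$amplicon_id,
                                                           sprintf("AMP%02d", 1:n_amp)),
                                                     as.integer(prof$sample_id))],
                               n_amp, n_smp, byrow = TRUE)
    expect_equal(got, oracle$norm, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("the low-coverage mask is a <= rule at the threshold", {
  # AMP02's batch-mean relative depth is exactly 0.1 by construction
  ds <- tiny_dataset(cbind(c(190, 10), c(380, 20)),
                     tiny_design(2L, pools = c(1L, 1L)))
  prof <- normalize_batch(ds, outlier_threshold = 0.1)
  amp <- dplyr::distinct(prof, amplicon_id, ref_depth, retained)
  expect_equal(amp$ref_depth[amp$amplicon_id == "AMP02"], 0.1)
  expect_false(amp$retained[amp$amplicon_id == "AMP02"])   # 0.1 exactly: removed
  expect_true(amp$retained[amp$amplicon_id == "AMP01"])
  expect_error(normalize_batch(ds, outlier_threshold = -0.2), "non-negative")
})

test_that("reference 0.05 is masked, 0.5 retained", {
  sim <- simulate_batch(sim_config(n_samples = 5, noise = "none", seed = 2))
  data <- sim$data |>
    dplyr::mutate(depth = ifelse(amplicon_id == "AMPL_GENE01_001",
                                 depth * 0.05, depth))
  prof <- normalize_batch(data)
  amp <- dplyr::distinct(prof, amplicon_id, ref_depth, retained)
  low <- dplyr::filter(amp, amplicon_id == "AMPL_GENE01_001")
  expect_lt(low$ref_depth, 0.1)
  expect_false(low$retained)
  expect_true(all(dplyr::filter(amp, amplicon_id != "AMPL_GENE01_001")$retained))
})

test_that("leave-one-out reference excludes the carrier from its own baseline", {
  cfg <- sim_config(n_samples = 5, noise = "none", sexes = "female", seed = 4,
                    events = list(cnv_event("S01", 1, gene = "GENE03",
                                            first = 3, last = 12)))
  sim <- simulate_batch(cfg)
  inc <- normalize_batch(sim$data)
  loo <- normalize_batch(sim$data, leave_one_out = TRUE)
  ev_amp <- sim$design$amplicon_id[sim$design$gene == "GENE03"][3]
  v_inc <- dplyr::filter(inc, amplicon_id == ev_amp, sample_id == "S01")$norm_depth
  v_loo <- dplyr::filter(loo, amplicon_id == ev_amp, sample_id == "S01")$norm_depth
  # including the carrier inflates its own value above the true dosage 1;
  # leave-one-out removes the reference share of that bias (a small residual
  # remains because the event also deflates the carrier's own pool mean)
  expect_gt(v_inc, v_loo)
  expect_lt(abs(v_loo - 1), 0.05)
  expect_gt(v_inc - 1, (v_loo - 1) * 2)
})

test_that("sex-aware referencing restores chrX to the diploid scale", {
  cfg <- sim_config(n_samples = 8, noise = "none",
                    sexes = rep(c("male", "female"), 4), seed = 6)
  sim <- simulate_batch(cfg)
  prof <- normalize_batch(sim$data, sex_aware = TRUE, meta = sim$meta)
  x <- dplyr::filter(prof, chrom == "chrX")
  expect_true(all(abs(x$norm_depth - 2) < 1e-9))
  auto <- dplyr::filter(prof, chrom != "chrX")
  expect_true(all(abs(auto$norm_depth - 2) < 1e-9))
})
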