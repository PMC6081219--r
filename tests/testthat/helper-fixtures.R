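# fixtures are built in code: a tiny panel/coverage pair in the long-tibble
# layout join_design_coverage() produces, plus a naive loop implementation of
# the pool-mean / relative-depth / batch-reference / dosage equations used as
# the independent oracle.

tiny_design <- function(n_amplicons = 6L, pools = rep(c(1L, 2L), length.out = n_amplicons),
                        chrom = "chr1", gene = "GENE_A") {
  tibble::tibble(
    amplicon_id = sprintf("AMP%02d", seq_len(n_amplicons)),
    chrom = rep_len(chrom, n_amplicons),
    start = 1000L + (seq_len(n_amplicons) - 1L) * 300L,
    end = 1000L + (seq_len(n_amplicons) - 1L) * 300L + 150L,
    gene = rep_len(gene, n_amplicons),
    pool = pools
  )
}

# depth: amplicons x samples matrix -> long dataset tibble
tiny_dataset <- function(depth, design = tiny_design(nrow(depth)),
                         sample_ids = sprintf("S%02d", seq_len(ncol(depth)))) {
  stopifnot(nrow(depth) == nrow(design))
  long <- tidyr::expand_grid(a = seq_len(nrow(depth)), s = seq_len(ncol(depth)))
  dplyr::bind_cols(design[long$a, ],
                   tibble::tibble(
                     sample_id = factor(sample_ids[long$s], levels = sample_ids),
                     depth = depth[cbind(long$a, long$s)]
                   ))
}

# independent oracle: the four normalization equations as explicit loops
naive_normalize <- function(depth, pool) {
  n_amp <- nrow(depth); n_smp <- ncol(depth)
  rel <- matrix(NA_real_, n_amp, n_smp)
  for (s in seq_len(n_smp)) {
    for (p in unique(pool)) {
      idx <- which(pool == p)
      m <- 0
      for (a in idx) m <- m + depth[a, s]
      m <- m / length(idx)
      for (a in idx) rel[a, s] <- if (m > 0) depth[a, s] / m else NA_real_
    }
  }
  ref <- numeric(n_amp)
  for (a in seq_len(n_amp)) {
    vals <- rel[a, ]
    vals <- vals[!is.na(vals)]
    ref[a] <- if (length(vals) > 0) sum(vals) / length(vals) else NA_real_
  }
  norm <- matrix(NA_real_, n_amp, n_smp)
  for (a in seq_len(n_amp)) {
    for (s in seq_len(n_smp)) {
      if (!is.na(ref[a]) && ref[a] > 0 && !is.na(rel[a, s])) {
        norm[a, s] <- 2 * rel[a, s] / ref[a]
      }
    }
  }
  list(rel = rel, ref = ref, norm = norm)
}

# norm_depth values for one sample from a profile tibble, in genomic order
profile_values <- function(prof, sample, col = "norm_depth") {
  d <- dplyr::filter(prof, as.character(sample_id) == sample)
  d[[col]]
}
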