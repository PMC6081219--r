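#' Generate a synthetic amplicon panel design
#'
#' Builds a multiplex panel layout for simulation: `n_genes` genes with
#' `amplicons_per_gene` amplicons each, assigned round-robin to `n_pools`
#' primer pools (so every gene mixes pools, as real designs do). Autosomal
#' genes are laid out two per chromosome from chr1 upward; `trisomy_genes`
#' genes are placed together on chr21 (the whole-chromosome gain positive
#' control) and `chrx_genes` genes on chrX (the sex-dosage control).
#'
#' @param n_genes Total genes (default 20).
#' @param amplicons_per_gene Amplicons per gene (default 15).
#' @param n_pools Primer pools (default 2).
#' @param chrx_genes Genes placed on chrX (default 2).
#' @param trisomy_genes Genes placed on chr21 (default 2).
#' @return A design tibble in the [read_design_bed()] layout.
#' @export
sim_panel <- function(n_genes = 20L, amplicons_per_gene = 15L, n_pools = 2L,
                      chrx_genes = 2L, trisomy_genes = 2L) {
  if (n_genes < chrx_genes + trisomy_genes + 1L) {
    stopf("sim_panel(): need more genes than the chrX + chr21 placements")
  }
  n_auto <- n_genes - chrx_genes - trisomy_genes
  auto_chroms <- paste0("chr", rep(seq_len(ceiling(n_auto / 2)), each = 2L))[seq_len(n_auto)]
  auto_chroms <- setdiff_chr21(auto_chroms)
  chroms <- c(auto_chroms, rep("chr21", trisomy_genes), rep("chrX", chrx_genes))
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  purrr::map(seq_len(n_genes), function(g) {
    idx <- seq_len(amplicons_per_gene)
    # second gene on a chromosome sits 1 Mb downstream of the first
    gene_offset <- 1e6 * (cumsum(chroms == chroms[g])[g] - 1L)
    start <- as.integer(5e6 + gene_offset + (idx - 1L) * 300L)
    tibble(
      amplicon_id = sprintf("AMPL_%s_%03d", genes[g], idx),
      chrom = chroms[g],
      start = start,
      end = start + 150L,
      gene = genes[g],
      pool = as.integer((idx - 1L) %% n_pools + 1L)
    )
  }) |> bind_rows() |> sort_genomic()
}

# keep the generic autosome sequence clear of the dedicated trisomy chromosome
setdiff_chr21 <- function(chroms) {
  ifelse(chroms == "chr21", "chr22", chroms)
}

#' Describe a simulated CNV event
#'
#' Either a within-gene event (`gene` plus `first`/`last` amplicon indices in
#' that gene, 1-based) or a whole-chromosome event (`chrom`, e.g. trisomy).
#' `copies` is the absolute copy number (0 homozygous loss, 1 heterozygous
#' loss, 3 one-copy gain, ...); it applies to that sample only.
#'
#' @param sample_id Carrier sample id (e.g. `"S03"`).
#' @param copies Integer copy number, not 2.
#' @param gene,first,last Gene-level event location.
#' @param chrom Whole-chromosome event location (exclusive with `gene`).
#' @return A `cnv_event` list.
#' @export
cnv_event <- function(sample_id, copies, gene = NULL, first = NULL,
                      last = NULL, chrom = NULL) {
  if (!is.numeric(copies) || length(copies) != 1L || copies < 0 ||
      copies != round(copies) || copies == 2) {
    stopf("cnv_event(): 'copies' must be a non-negative integer other than 2")
  }
  if (is.null(gene) == is.null(chrom)) {
    stopf("cnv_event(): give exactly one of 'gene' or 'chrom'")
  }
  if (!is.null(gene) && (is.null(first) || is.null(last) || first > last || first < 1L)) {
    stopf("cnv_event(): gene events need 1 <= first <= last amplicon indices")
  }
  structure(list(sample_id = sample_id, copies = as.integer(copies),
                 gene = gene, first = first, last = last, chrom = chrom),
            class = "cnv_event")
}

#' Simulation configuration for a sequencing batch
#'
#' Defines the study conditions for one simulated batch: 45 samples (one
#' sequencer run, the batch size the normalization references against),
#' a 2-pool panel, log-normal per-amplicon amplification efficiency,
#' optional per-sample primer-pool imbalance, and negative-binomial count
#' noise sized to a ~15% coefficient of variation at 500x depth.
#'
#' @param n_samples Samples in the batch (default 45).
#' @param panel Design tibble (default [sim_panel()]).
#' @param mean_depth Mean per-amplicon depth per sample; scalar or length
#'   `n_samples` (default 500 reads).
#' @param sigma_eff Log-normal sdlog of per-amplicon amplification efficiency
#'   (default 0.5; 0 gives a uniform panel).
#' @param pool_imbalance Multiplicative factor applied to the depths of pools
#'   2..k; scalar or per sample (default 1 = balanced libraries).
#' @param noise `"negative_binomial"` (default), `"poisson"`, or `"none"`
#'   (deterministic expected depths, used for closed-form checks).
#' @param nb_size Negative-binomial size parameter (default 50: CV
#'   `sqrt(1/mu + 1/50)` ~ 15% at 500x).
#' @param sexes Character vector (`"male"`/`"female"`), scalar or per sample;
#'   default alternates male/female so batches are near-balanced, as the
#'   X-dosage interpretation assumes. Males carry one chrX copy.
#' @param events List of [cnv_event()] objects.
#' @param seed Integer seed; a fixed seed makes the batch byte-identical.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 45L, panel = sim_panel(), mean_depth = 500,
                       sigma_eff = 0.5, pool_imbalance = 1,
                       noise = c("negative_binomial", "poisson", "none"),
                       nb_size = 50, sexes = NULL, events = list(),
                       seed = 1L) {
  noise <- match.arg(noise)
  if (n_samples < 2L) stopf("sim_config(): need at least 2 samples")
  if (inherits(events, "cnv_event")) events <- list(events)
  sexes <- sexes %||% rep_len(c("male", "female"), n_samples)
  sexes <- rep_len(sexes, n_samples)
  if (!all(sexes %in% c("male", "female", "unknown"))) {
    stopf("sim_config(): sexes must be 'male', 'female' or 'unknown'")
  }
  cfg <- structure(list(
    n_samples = as.integer(n_samples), panel = panel,
    mean_depth = rep_len(mean_depth, n_samples),
    sigma_eff = sigma_eff,
    pool_imbalance = rep_len(pool_imbalance, n_samples),
    noise = noise, nb_size = nb_size, sexes = sexes,
    events = events, seed = as.integer(seed)
  ), class = "sim_config")
  validate_events(cfg)
  cfg
}

validate_events <- function(cfg) {
  ids <- sim_sample_ids(cfg$n_samples)
  per_gene <- table(cfg$panel$gene)
  for (ev in cfg$events) {
    if (!inherits(ev, "cnv_event")) stopf("events must be cnv_event objects")
    if (!ev$sample_id %in% ids) {
      stopf("event sample '%s' not in the batch (samples %s..%s)",
            ev$sample_id, ids[1], ids[length(ids)])
    }
    if (!is.null(ev$gene)) {
      if (!ev$gene %in% names(per_gene)) {
        stopf("event gene '%s' not in the panel", ev$gene)
      }
      if (ev$last > per_gene[[ev$gene]]) {
        stopf("event on '%s' ends at amplicon %d but the gene has %d",
              ev$gene, ev$last, per_gene[[ev$gene]])
      }
    } else if (!ev$chrom %in% cfg$panel$chrom) {
      stopf("event chromosome '%s' not in the panel", ev$chrom)
    }
  }
  invisible(cfg)
}

sim_sample_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate an amplicon coverage batch with known CNV truth
#'
#' The expected depth of amplicon *a* in sample *s* is
#' `mean_depth[s] * efficiency[a] * pool_factor[s, pool(a)] * dosage[a, s] / 2`,
#' where dosage is 2 for autosomal diploid amplicons, the event's copy number
#' inside simulated CNVs, and 1 (male) or 2 (female) on chrX. Observed depths
#' are drawn from the configured count distribution (`"none"` returns the
#' expected values themselves, so closed-form identities hold exactly).
#'
#' @param config A [sim_config()] object.
#' @return A `cnv_sim` list: `design` (tibble), `coverage` (wide tibble),
#'   `meta` (`sample_id`, `sex`), `truth` (one row per event with amplicon
#'   bounds), and `data` — the joined long tibble ready for
#'   [normalize_batch()].
#' @examples
#' sim <- simulate_batch(sim_config(n_samples = 4, noise = "none", seed = 7))
#' head(sim$data)
#' @export
simulate_batch <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- sort_genomic(config$panel)
  n_amp <- nrow(panel)
  n_smp <- config$n_samples
  ids <- sim_sample_ids(n_smp)
  withr::with_seed(config$seed, {
    eff <- rlnorm(n_amp, meanlog = 0, sdlog = config$sigma_eff)
    dosage <- matrix(2, n_amp, n_smp)
    on_x <- toupper(sub("^chr", "", panel$chrom)) == "X"
    dosage[on_x, config$sexes == "male"] <- 1
    for (ev in config$events) {
      s <- match(ev$sample_id, ids)
      rows <- if (!is.null(ev$gene)) {
        gidx <- which(panel$gene == ev$gene)
        gidx[ev$first:ev$last]
      } else {
        which(panel$chrom == ev$chrom)
      }
      dosage[rows, s] <- ev$copies
    }
    pool_fac <- matrix(1, n_amp, n_smp)
    pool_fac[panel$pool >= 2L, ] <- rep(config$pool_imbalance, each = sum(panel$pool >= 2L))
    mu <- eff * pool_fac * dosage / 2
    mu <- sweep(mu, 2L, config$mean_depth, `*`)
    depth <- switch(config$noise,
      none = mu,
      poisson = matrix(rpois(length(mu), mu), n_amp, n_smp),
      negative_binomial = matrix(rnbinom(length(mu), mu = mu, size = config$nb_size),
                                 n_amp, n_smp)
    )
  })
  coverage <- tibble(amplicon_id = panel$amplicon_id)
  coverage[ids] <- as.data.frame(depth)
  meta <- tibble(sample_id = ids, sex = config$sexes)
  truth <- purrr::map(config$events, function(ev) {
    rows <- if (!is.null(ev$gene)) {
      gidx <- which(panel$gene == ev$gene)
      gidx[ev$first:ev$last]
    } else {
      which(panel$chrom == ev$chrom)
    }
    tibble(sample_id = ev$sample_id,
           chrom = panel$chrom[rows[1]],
           gene = paste(unique(panel$gene[rows]), collapse = ","),
           first_amplicon = panel$amplicon_id[rows[1]],
           last_amplicon = panel$amplicon_id[rows[length(rows)]],
           first_index = rows[1], last_index = rows[length(rows)],
           copies = ev$copies)
  }) |> bind_rows()
  if (nrow(truth) == 0L) {
    truth <- tibble(sample_id = character(), chrom = character(),
                    gene = character(), first_amplicon = character(),
                    last_amplicon = character(), first_index = integer(),
                    last_index = integer(), copies = integer())
  }
  structure(list(design = panel, coverage = coverage, meta = meta,
                 truth = truth,
                 data = suppressWarnings(join_design_coverage(panel, coverage))),
            class = "cnv_sim")
}

#' Write the canonical simulated fixture suite
#'
#' Writes six batches covering the pipeline's positive and negative controls:
#' a clean diploid batch, a heterozygous (1-copy) and a homozygous (0-copy)
#' STRC-like loss, a 1-copy gain, a whole-chromosome trisomy, and a severely
#' pool-imbalanced overdispersed batch expected to fail QC. Each batch gets a
#' design BED, a coverage TSV, a sample-metadata TSV and a truth TSV.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; batch b uses `seed + b`, so the suite is fully
#'   reproducible.
#' @param n_samples Samples per batch (default 45).
#' @return Invisibly, a tibble of the written files per batch.
#' @export
make_fixture_suite <- function(outdir, seed = 1L, n_samples = 45L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  carrier <- "S05"
  batches <- list(
    clean = list(events = list()),
    het_loss = list(events = list(cnv_event(carrier, 1, gene = "GENE03",
                                            first = 3, last = 12))),
    hom_loss = list(events = list(cnv_event(carrier, 0, gene = "GENE03",
                                            first = 3, last = 12))),
    gain = list(events = list(cnv_event(carrier, 3, gene = "GENE07",
                                        first = 3, last = 12))),
    trisomy = list(events = list(cnv_event(carrier, 3, chrom = "chr21"))),
    unanalyzable = list(events = list(), pool_imbalance = 8, nb_size = 4)
  )
  files <- purrr::imap(batches, function(b, name) {
    cfg <- sim_config(
      n_samples = n_samples,
      events = b$events,
      pool_imbalance = b$pool_imbalance %||% 1,
      nb_size = b$nb_size %||% 50,
      seed = seed + match(name, names(batches))
    )
    sim <- simulate_batch(cfg)
    paths <- file.path(outdir, paste0(name, c("_design.bed", "_coverage.tsv",
                                              "_meta.tsv", "_truth.tsv")))
    write_design_bed(sim$design, paths[1])
    write_coverage_matrix(sim$coverage, paths[2])
    readr::write_tsv(sim$meta, paths[3], progress = FALSE)
    readr::write_tsv(sim$truth, paths[4], progress = FALSE)
    tibble(batch = name, design = paths[1], coverage = paths[2],
           meta = paths[3], truth = paths[4])
  }) |> bind_rows()
  invisible(files)
}
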