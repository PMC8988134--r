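test_that("the generator is deterministic given the config seed", {
  cfg <- sim_config(n_genes = 120, seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$rna$counts, b$rna$counts)
  expect_identical(a$atac$peaks, b$atac$peaks)
  expect_identical(a$seqs$sequences, b$seqs$sequences)
  d <- simulate_dataset(sim_config(n_genes = 120, seed = 6))
  expect_false(identical(a$rna$counts, d$rna$counts))
})

test_that("class sampling follows the configured proportions", {
  cfg0 <- sim_config(n_genes = 100,
                     class_proportions = setNames(rep(0, 10), class_levels()),
                     seed = 1)
  truth0 <- simulate_truth(cfg0)
  expect_true(all(is.na(truth0$genes$class)))

  # full-strength proportions at the reference partition size: the largest
  # class should land within multinomial error of its expected share
  cfg <- sim_config(n_genes = 4257, n_chroms = 8,
                    class_proportions = default_class_proportions(responsive = 1),
                    seed = 11)
  truth <- simulate_truth(cfg)
  n6 <- sum(truth$genes$class == "VI", na.rm = TRUE)
  p6 <- default_class_proportions(1)[["VI"]]
  expect_lt(abs(n6 - 4257 * p6), 4 * sqrt(4257 * p6 * (1 - p6)))
  expect_equal(nrow(truth$genes), nrow(truth$tss))
})

test_that("simulated counts have negative-binomial moments", {
  base_cfg <- function(alpha) {
    sim_config(n_genes = 10000, n_chroms = 8, chrom_length = 8e7,
               class_proportions = setNames(rep(0, 10), class_levels()),
               baseline_meanlog = log(100), baseline_sdlog = 0,
               size_factor_sdlog = 0, dispersion = alpha, n_replicates = 3,
               seed = 21)
  }
  # alpha = 0.05, mu = 100: Var = mu + alpha mu^2 = 600
  sim <- simulate_rna_counts(simulate_truth(base_cfg(0.05)), base_cfg(0.05))
  x <- as.vector(as_count_matrix(sim$counts))
  expect_equal(mean(x), 100, tolerance = 0.02)
  expect_equal(var(x), 600, tolerance = 0.05)
  # Poisson limit: alpha -> 0 gives variance ~ mean
  simp <- simulate_rna_counts(simulate_truth(base_cfg(0)), base_cfg(0))
  xp <- as.vector(as_count_matrix(simp$counts))
  expect_equal(var(xp) / mean(xp), 1, tolerance = 0.05)
})

test_that("null genes show no fold change at large replicate counts", {
  cfg <- sim_config(n_genes = 300, n_replicates = 12,
                    class_proportions = setNames(rep(0, 10), class_levels()),
                    seed = 31)
  sim <- simulate_dataset(cfg)
  w <- wald_contrast(sim$rna$counts, sim$rna$design, "unstim", "LPS")
  expect_lt(abs(median(w$log2FC)), 0.05)
})

test_that("simulated peaks satisfy their construction invariants", {
  sim <- memo("sim_midsize", simulate_dataset(sim_config(n_genes = 700, seed = 41)))
  peaks <- sim$atac$peaks
  tp <- sim$atac$truth_peaks
  expect_true(all(peaks$start < peaks$end))
  expect_true(all(peaks$start >= 0 & peaks$end <= sim$config$chrom_length))
  expect_identical(nrow(peaks), nrow(tp))

  # every gene's promoter peak overlaps its -1000/+100 TSS window
  prom <- peaks[tp$type == "promoter", ]
  lab <- oracle_annotate(prom, sim$tss)
  expect_true(all(lab == "promoter"))

  # every planted DAR lies within +/-25 kb of its linked gene's TSS
  dar <- peaks[tp$is_dar, ]
  dar$gene <- tp$gene[tp$is_dar]
  tss_of <- sim$tss$tss[match(dar$gene, sim$tss$gene)]
  expect_true(all(dar$start <= tss_of + 25000 - 1 & dar$end - 1 >= tss_of - 25000))
  # and DARs are planted only on distal peaks
  expect_true(all(tp$type[tp$is_dar] == "distal"))
})

test_that("a zero dar_rate produces a calibrated null for the DAR caller", {
  cfg <- sim_config(n_genes = 400, dar_rate = 0, seed = 51)
  sim <- simulate_dataset(cfg)
  w <- wald_contrast(sim$atac$counts, sim$atac$design, "unstim", "LPS")
  fp_raw <- mean(w$p < 0.05, na.rm = TRUE)
  expect_gt(fp_raw, 0.02)
  expect_lt(fp_raw, 0.08)
  dars <- call_dars(w)
  expect_lt(mean(dars$is_dar), 0.005)
})

test_that("simulated sequences match peaks, GC target and planted motifs", {
  sim <- memo("sim_midsize", simulate_dataset(sim_config(n_genes = 700, seed = 41)))
  seqs <- sim$seqs$sequences
  expect_identical(seqs$peak, sim$atac$peaks$peak)
  expect_identical(nchar(seqs$sequence),
                   as.integer(sim$atac$peaks$end - sim$atac$peaks$start))

  all_bases <- strsplit(paste(seqs$sequence, collapse = ""), "")[[1]]
  expect_gt(length(all_bases), 1e6)
  gc <- mean(all_bases %in% c("G", "C"))
  expect_lt(abs(gc - sim$config$gc_content), 0.01)

  tm <- sim$seqs$truth_motifs
  expect_gt(nrow(tm), 0)
  motif <- sim$config$motif_consensus
  hit <- vapply(seq_len(nrow(tm)), function(i) {
    s <- seqs$sequence[seqs$peak == tm$peak[i]]
    grepl(motif, s, fixed = TRUE) || grepl(revcomp(motif), s, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
  # recorded offsets point at the planted instance
  i <- 1
  s <- seqs$sequence[seqs$peak == tm$peak[i]]
  frag <- substr(s, tm$offset[i], tm$offset[i] + nchar(motif) - 1)
  expect_true(frag == motif || frag == revcomp(motif))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(class_proportions = c(I = 0.9, VI = 0.2)), "sum")
  expect_error(sim_config(n_genes = 5000, n_chroms = 1, chrom_length = 1e6),
               "spacing")
  bad_prof <- default_profiles()
  bad_prof$r_lps[bad_prof$class == "VI"] <- 0.5  # would classify as VIII/X
  expect_error(sim_config(fold_change_profiles = bad_prof), "classifies as")
})

test_that("write_simulation emits a readable plain-text bundle", {
  sim <- simulate_dataset(sim_config(n_genes = 60, seed = 61))
  dir <- tempfile("simout")
  files <- write_simulation(sim, dir)
  expect_true(all(c("rna_counts.tsv", "peaks.bed", "peaks.fa", "config.yaml") %in%
                    basename(files)))
  back <- read_pipeline_inputs(list(
    rna_counts = file.path(dir, "rna_counts.tsv"),
    rna_design = file.path(dir, "rna_design.tsv"),
    atac_counts = file.path(dir, "atac_counts.tsv"),
    atac_design = file.path(dir, "atac_design.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    tss = file.path(dir, "tss.tsv"),
    fasta = file.path(dir, "peaks.fa")))
  expect_equal(as_count_matrix(back$rna_counts), as_count_matrix(sim$rna$counts))
  expect_identical(back$seqs$sequence, sim$seqs$sequences$sequence)
  unlink(dir, recursive = TRUE)
})
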