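#' Simulate gene annotation and ground truth
#'
#' Places `n_genes` transcription start sites on toy chromosomes (jittered
#' regular grid, random strand), assigns each gene a planted response class
#' by `class_proportions` (remainder: null genes), and derives per-condition
#' expected means from the fold-change profiles. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list: `tss` (tibble gene, chrom, tss, strand) and `genes`
#'   (tibble gene, class, baseline, one `mu_<condition>` column per
#'   condition).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene <- sprintf("gene%05d", seq_len(n))
  chrom_of <- rep(paste0("chr", seq_len(config$n_chroms)), length.out = n)
  chrom_of <- sort(chrom_of)
  per_chrom <- table(chrom_of)
  tss <- integer(n)
  for (cc in names(per_chrom)) {
    k <- per_chrom[[cc]]
    spacing <- config$chrom_length %/% (k + 1)
    pos <- spacing * seq_len(k) + sample(-2000:2000, k, replace = TRUE)
    pos <- pmin(pmax(pos, 26000L), config$chrom_length - 26000L)
    tss[chrom_of == cc] <- as.integer(pos)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)

  cp <- config$class_proportions
  probs <- c(cp, null = 1 - sum(cp))
  class <- sample(names(probs), n, replace = TRUE, prob = probs)
  class[class == "null"] <- NA_character_

  baseline <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  prof <- config$fold_change_profiles
  r_lps <- ifelse(is.na(class), 1, prof$r_lps[match(class, prof$class)])
  r_jq1 <- ifelse(is.na(class), 1, prof$r_jq1[match(class, prof$class)])

  genes <- tibble(gene = gene, class = class, baseline = baseline)
  for (cond in config$conditions) {
    mult <- switch(cond, unstim = 1, LPS = r_lps, LPS_JQ1 = r_jq1, 1)
    genes[[paste0("mu_", cond)]] <- baseline * mult
  }
  list(tss = tibble(gene = gene, chrom = chrom_of, tss = tss, strand = strand),
       genes = genes)
}

sim_design <- function(config, assay) {
  tibble(
    sample = paste0(assay, "_",
                    rep(config$conditions, each = config$n_replicates), "_r",
                    rep(seq_len(config$n_replicates), length(config$conditions))),
    condition = rep(config$conditions, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(config$conditions))
  )
}

rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) return(rpois(n, mu))
  rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate the RNA count matrix
#'
#' Draws negative-binomial counts (`Var = mu + alpha mu^2`) around each
#' gene's per-condition expected mean, multiplied by simulated log-normal
#' per-sample depth factors.
#'
#' @param truth Output of [simulate_truth()].
#' @param config The same [sim_config()].
#' @return A list: `counts` (tibble, gene column + samples), `design`
#'   (sample, condition, replicate) and `size_factors` (the planted truth).
#' @export
simulate_rna_counts <- function(truth, config) {
  set.seed(config$seed + 1L)
  design <- sim_design(config, "rna")
  mu_cols <- paste0("mu_", design$condition)
  mu <- as.matrix(truth$genes[, mu_cols])
  if (any(mu <= 0)) abort("expected means must be positive.")
  sf <- rlnorm(nrow(design), 0, config$size_factor_sdlog)
  m <- matrix(0L, nrow(mu), ncol(mu), dimnames = list(truth$genes$gene, design$sample))
  for (j in seq_len(ncol(mu))) {
    m[, j] <- rnb(nrow(mu), mu[, j] * sf[j], config$dispersion)
  }
  list(counts = bind_cols(tibble(gene = rownames(m)), as_tibble(m)),
       design = design,
       size_factors = tibble(sample = design$sample, size_factor = sf))
}

#' Simulate the ATAC peak set and count matrix
#'
#' Plants one promoter peak per gene (overlapping the -1000/+100 TSS
#' window), `n_distal_per_gene` distal peaks within +/-25 kb of each TSS,
#' and unlinked background peaks placed uniformly outside all +/-25 kb
#' windows. A per-class fraction (`dar_rate`) of linked distal peaks is made
#' differentially accessible: their expected accessibility rises
#' `atac_lps_ratio`-fold under LPS and only `atac_jq1_ratio`-fold under
#' LPS + BET inhibition. Counts are NB with the same dispersion model as RNA.
#'
#' @param truth Output of [simulate_truth()].
#' @param config The same [sim_config()].
#' @return A list: `peaks` (tibble peak, chrom, start, end; BED-style
#'   0-based half-open), `counts`, `design`, `truth_peaks` (peak, type,
#'   gene, is_dar, direction).
#' @export
simulate_atac <- function(truth, config) {
  set.seed(config$seed + 2L)
  w <- config$peak_width
  tss <- truth$tss
  n <- nrow(tss)

  # promoter peak centered on the TSS
  prom <- tibble(peak = paste0("prom_", tss$gene), chrom = tss$chrom,
                 start = tss$tss - w %/% 2, end = tss$tss - w %/% 2 + w,
                 type = "promoter", gene = tss$gene)

  # distal peaks: offsets in +/- [2 kb, 24.5 kb] from the TSS
  nd <- config$n_distal_per_gene
  off_mag <- matrix(sample(2000:24500 - w %/% 2, n * nd, replace = TRUE), n, nd)
  off_sign <- matrix(sample(c(-1, 1), n * nd, replace = TRUE), n, nd)
  dist <- purrr::map_dfr(seq_len(nd), function(k) {
    centre <- tss$tss + off_sign[, k] * off_mag[, k]
    tibble(peak = paste0("dist", k, "_", tss$gene), chrom = tss$chrom,
           start = centre - w %/% 2, end = centre + w - w %/% 2,
           type = "distal", gene = tss$gene)
  })

  # background peaks uniformly outside every +/-25 kb window
  nb <- config$n_background_peaks
  bg <- tibble()
  if (nb > 0) {
    cand_n <- nb * 20
    cc <- sample(paste0("chr", seq_len(config$n_chroms)), cand_n, replace = TRUE)
    pos <- sample.int(config$chrom_length - w, cand_n, replace = TRUE)
    ok <- rep(TRUE, cand_n)
    for (ch in unique(cc)) {
      idx <- which(cc == ch)
      t_ch <- tss$tss[tss$chrom == ch]
      if (length(t_ch) == 0) next
      near <- vapply(pos[idx], function(p) {
        any(p + w > t_ch - 25000 & p < t_ch + 25000)
      }, logical(1))
      ok[idx][near] <- FALSE
    }
    keep <- which(ok)[seq_len(min(nb, sum(ok)))]
    if (length(keep) < nb) warn("fewer background peaks placed than requested.")
    bg <- tibble(peak = paste0("bg_", seq_along(keep)), chrom = cc[keep],
                 start = pos[keep], end = pos[keep] + w,
                 type = "background", gene = NA_character_)
  }

  all_peaks <- bind_rows(prom, dist, bg)
  clip <- all_peaks$start < 0 | all_peaks$end > config$chrom_length
  if (any(clip)) {
    warn(paste0(sum(clip), " peak(s) clipped at chromosome edges."))
    all_peaks$start <- pmax(all_peaks$start, 0L)
    all_peaks$end <- pmin(all_peaks$end, config$chrom_length)
  }

  # DAR planting on distal peaks of classed genes
  cls <- truth$genes$class[match(all_peaks$gene, truth$genes$gene)]
  rate <- ifelse(all_peaks$type == "distal", dar_rate_for(config, cls), 0)
  is_dar <- runif(nrow(all_peaks)) < rate
  direction <- ifelse(is_dar, 1L, 0L)

  design <- sim_design(config, "atac")
  base <- rlnorm(nrow(all_peaks), log(100), 0.5)
  mult <- matrix(1, nrow(all_peaks), length(config$conditions),
                 dimnames = list(NULL, config$conditions))
  if ("LPS" %in% config$conditions) mult[is_dar, "LPS"] <- config$atac_lps_ratio
  if ("LPS_JQ1" %in% config$conditions) mult[is_dar, "LPS_JQ1"] <- config$atac_jq1_ratio
  sf <- rlnorm(nrow(design), 0, config$size_factor_sdlog)
  m <- matrix(0L, nrow(all_peaks), nrow(design),
              dimnames = list(all_peaks$peak, design$sample))
  for (j in seq_len(nrow(design))) {
    m[, j] <- rnb(nrow(all_peaks), base * mult[, design$condition[j]] * sf[j],
                  config$dispersion)
  }

  list(peaks = all_peaks[, c("peak", "chrom", "start", "end")],
       counts = bind_cols(tibble(peak = rownames(m)), as_tibble(m)),
       design = design,
       truth_peaks = tibble(peak = all_peaks$peak, type = all_peaks$type,
                            gene = all_peaks$gene, is_dar = is_dar,
                            direction = direction))
}

#' Simulate peak sequences with planted motif instances
#'
#' Generates one i.i.d. random sequence per peak at the configured GC
#' content. In `motif_plant_rate` of the differentially accessible peaks the
#' consensus motif (or its reverse complement, random strand) is inserted at
#' a recorded offset. Peaks shorter than the motif are skipped with a
#' warning.
#'
#' @param atac Output of [simulate_atac()].
#' @param config The same [sim_config()].
#' @return A list: `sequences` (tibble peak, sequence) and `truth_motifs`
#'   (peak, motif, offset, strand) for planted instances.
#' @export
simulate_sequences <- function(atac, config) {
  set.seed(config$seed + 3L)
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  widths <- atac$peaks$end - atac$peaks$start
  seqs <- vapply(widths, function(wd) {
    paste(sample(names(base_probs), wd, replace = TRUE, prob = base_probs),
          collapse = "")
  }, character(1))

  motif <- config$motif_consensus
  mw <- nchar(motif)
  plant <- atac$truth_peaks$is_dar & runif(nrow(atac$peaks)) < config$motif_plant_rate
  short <- plant & widths < mw
  if (any(short)) {
    warn(paste0(sum(short), " peak(s) shorter than the motif; not planted."))
    plant[short] <- FALSE
  }
  offs <- rep(NA_integer_, length(seqs))
  strands <- rep(NA_character_, length(seqs))
  for (i in which(plant)) {
    o <- sample.int(widths[i] - mw + 1L, 1L)
    s <- sample(c("+", "-"), 1L)
    ins <- if (s == "+") motif else revcomp(motif)
    substr(seqs[i], o, o + mw - 1L) <- ins
    offs[i] <- o
    strands[i] <- s
  }
  list(sequences = tibble(peak = atac$peaks$peak, sequence = seqs),
       truth_motifs = tibble(peak = atac$peaks$peak[plant],
                             motif = motif, offset = offs[plant],
                             strand = strands[plant]))
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper running [simulate_truth()], [simulate_rna_counts()],
#' [simulate_atac()] and [simulate_sequences()] from one config.
#'
#' @param config A [sim_config()].
#' @return An `lps_sim` list with elements `config`, `tss`, `genes`, `rna`,
#'   `atac`, `seqs`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  rna <- simulate_rna_counts(truth, config)
  atac <- simulate_atac(truth, config)
  seqs <- simulate_sequences(atac, config)
  structure(list(config = config, tss = truth$tss, genes = truth$genes,
                 rna = rna, atac = atac, seqs = seqs),
            class = "lps_sim")
}

#' @export
print.lps_sim <- function(x, ...) {
  cat("<lps_sim> ", nrow(x$genes), " genes, ", nrow(x$atac$peaks), " peaks, ",
      sum(x$atac$truth_peaks$is_dar), " planted DARs, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the standard interchange files: counts and design TSVs for both
#' assays, BED6 peak intervals (0-based half-open), a TSS table, a FASTA of
#' peak sequences, truth tables, and a YAML echo of the configuration.
#'
#' @param sim An `lps_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tsv <- function(x, f) write.table(x, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(sim$rna$counts, "rna_counts.tsv")
  tsv(sim$rna$design, "rna_design.tsv")
  tsv(sim$atac$counts, "atac_counts.tsv")
  tsv(sim$atac$design, "atac_design.tsv")
  tsv(sim$tss, "tss.tsv")
  tsv(sim$genes, "truth_genes.tsv")
  tsv(sim$atac$truth_peaks, "truth_peaks.tsv")
  bed <- tibble(chrom = sim$atac$peaks$chrom, start = sim$atac$peaks$start,
                end = sim$atac$peaks$end, name = sim$atac$peaks$peak,
                score = 0L, strand = ".")
  write.table(bed, p("peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(paste0(">", sim$seqs$sequences$peak, "\n", sim$seqs$sequences$sequence),
             p("peaks.fa"))
  cfg <- sim$config
  cfg$fold_change_profiles <- as.data.frame(cfg$fold_change_profiles)
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(list.files(dir, full.names = TRUE))
}
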