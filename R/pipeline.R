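default_pipeline_config <- function() {
  list(
    sim = NULL, inputs = NULL,
    baseline = "unstim", lps = "LPS", jq1 = "LPS_JQ1",
    rules = rule_table(),
    dar_alpha = 0.05, dar_thresholds = c(0.5, 1),
    upstream = 1000, downstream = 100, window = 25000,
    motif_fdr = 0.10, score_fraction = 0.8, background_ratio = 10,
    library = NULL, seed = 1L
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks threshold ranges and condition names, and enforces
#' that exactly one input source (a simulation config or real input paths)
#' is present. Unknown keys produce warnings rather than errors.
#'
#' @param config A named list; see [run_pipeline()] for recognized fields.
#' @return The normalized config with an attribute `"warnings"` (character
#'   vector).
#' @export
validate_config <- function(config = list()) {
  if (inherits(config, "sim_config")) config <- list(sim = config)
  defaults <- default_pipeline_config()
  warnings <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    warnings <- c(warnings, paste0("ignoring unknown config keys: ",
                                   paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])
  if (is.null(cfg$sim) && is.null(cfg$inputs)) {
    cfg$sim <- sim_config(seed = cfg$seed)
    warnings <- c(warnings, "no input source given; using the default simulation.")
  }
  if (!is.null(cfg$sim) && !is.null(cfg$inputs)) {
    abort("`sim` and `inputs` are mutually exclusive; supply exactly one.")
  }
  if (!is.null(cfg$sim) && !inherits(cfg$sim, "sim_config")) {
    cfg$sim <- do.call(sim_config, cfg$sim)
  }
  if (!is.null(cfg$inputs)) {
    missing <- !vapply(unlist(cfg$inputs), file.exists, logical(1))
    if (any(missing)) {
      abort(paste0("input file(s) not found: ",
                   paste(unlist(cfg$inputs)[missing], collapse = ", ")))
    }
  }
  if (!inherits(cfg$rules, "rule_table")) cfg$rules <- do.call(rule_table, cfg$rules)
  check_prob(cfg$dar_alpha, "dar_alpha")
  check_prob(cfg$motif_fdr, "motif_fdr")
  check_prob(cfg$score_fraction, "score_fraction")
  if (!is.null(cfg$sim)) {
    conds <- cfg$sim$conditions
    for (f in c("baseline", "lps", "jq1")) {
      if (!cfg[[f]] %in% conds) {
        abort(paste0("condition `", cfg[[f]], "` (", f, ") not in the design."))
      }
    }
  }
  if (length(warnings) == 0 && length(config) == 0) {
    warnings <- "empty config: all defaults in effect."
  }
  attr(cfg, "warnings") <- warnings
  cfg
}

#' Run the integrated RNA + ATAC analysis pipeline
#'
#' Orchestrates all stages on one configuration: data simulation (or
#' loading), size-factor and dispersion estimation, the three pairwise Wald
#' contrasts and the LRT on gene counts, class assignment, peak annotation
#' and +/-25 kb linkage, DAR calling on the LPS contrast of peak counts,
#' per-class DAR enrichment, and known-motif enrichment of central DAR
#' windows against sampled non-DAR windows, followed by clustering of the
#' enriched motifs. On synthetic input the report additionally carries
#' truth-recovery metrics.
#'
#' @param config A config list accepted by [validate_config()], a
#'   [sim_config()], or nothing for the packaged default simulation.
#' @param out_dir Optional directory; when given, stage outputs and the JSON
#'   report are written there.
#' @return An `lps_report` list: `summary` (class summary), `assignment`,
#'   `contrasts`, `dars`, `links`, `dar_enrichment`, `motif_enrichment`,
#'   `motif_clusters`, `recovery` (synthetic runs), `counts` (per-stage
#'   record counts), `config_hash`, `version`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  for (w in attr(cfg, "warnings")) warn(w)

  if (!is.null(cfg$sim)) {
    sim <- simulate_dataset(cfg$sim)
    rna_counts <- sim$rna$counts
    rna_design <- sim$rna$design
    atac_counts <- sim$atac$counts
    atac_design <- sim$atac$design
    peaks <- sim$atac$peaks
    tss <- sim$tss
    seqs <- sim$seqs$sequences
  } else {
    inp <- read_pipeline_inputs(cfg$inputs)
    sim <- NULL
    rna_counts <- inp$rna_counts; rna_design <- inp$rna_design
    atac_counts <- inp$atac_counts; atac_design <- inp$atac_design
    peaks <- inp$peaks; tss <- inp$tss; seqs <- inp$seqs
  }

  # --- RNA differential testing and classification
  rna_m <- as_count_matrix(rna_counts)
  sf <- size_factors(rna_m)
  disp <- estimate_dispersion(rna_m, rna_design, factors = sf)
  wald_a <- wald_contrast(rna_m, rna_design, cfg$baseline, cfg$lps,
                          factors = sf, dispersion = disp)
  wald_b <- wald_contrast(rna_m, rna_design, cfg$baseline, cfg$jq1,
                          factors = sf, dispersion = disp)
  wald_c <- wald_contrast(rna_m, rna_design, cfg$lps, cfg$jq1,
                          factors = sf, dispersion = disp)
  lrt <- lrt_test(rna_m, rna_design, factors = sf, dispersion = disp)
  assignment <- assign_classes(wald_a, wald_b, wald_c, lrt, rules = cfg$rules)
  summary <- class_summary(assignment)

  # --- chromatin
  annotation <- annotate_peaks(peaks, tss, cfg$upstream, cfg$downstream)
  links <- link_distal_peaks(peaks, tss, cfg$window, annotation)
  atac_m <- as_count_matrix(atac_counts)
  atac_sf <- size_factors(atac_m)
  atac_disp <- estimate_dispersion(atac_m, atac_design, factors = atac_sf)
  peak_wald <- wald_contrast(atac_m, atac_design, cfg$baseline, cfg$lps,
                             factors = atac_sf, dispersion = atac_disp)
  dars <- call_dars(peak_wald, alpha = cfg$dar_alpha,
                    thresholds = cfg$dar_thresholds)
  dar_enr <- dar_class_enrichment(dars, links, assignment)

  # --- motifs on central DAR windows vs sampled non-DAR windows
  library <- cfg$library %||% example_motif_library()
  dar_ids <- dars$feature[dars$is_dar]
  windows <- central_window(peaks)
  seq_of <- setNames(seqs$sequence, seqs$peak)
  clip_seq <- function(ids) {
    sub <- windows[windows$peak %in% ids, , drop = FALSE]
    full <- peaks[match(sub$peak, peaks$peak), ]
    off <- sub$start - full$start
    substring(seq_of[sub$peak], off + 1, off + (sub$end - sub$start))
  }
  motif_enr <- NULL
  motif_clusters <- NULL
  if (length(dar_ids) >= 5) {
    non_dar <- setdiff(peaks$peak, dar_ids)
    set.seed(cfg$seed)
    bg_ids <- sample(non_dar, min(length(non_dar),
                                  cfg$background_ratio * length(dar_ids)))
    motif_enr <- motif_enrichment(clip_seq(dar_ids), clip_seq(bg_ids), library,
                                  score_fraction = cfg$score_fraction)
    enriched <- motif_enr$motif[!is.na(motif_enr$padj) &
                                  motif_enr$padj < cfg$motif_fdr]
    if (length(enriched) >= 2) {
      motif_clusters <- cluster_motifs(library[enriched])
    }
  }

  # --- truth recovery (synthetic runs only)
  recovery <- NULL
  if (!is.null(sim)) {
    truth_class <- sim$genes$class[match(assignment$gene, sim$genes$gene)]
    # recovery measured on eligible genes that carry a planted class; null
    # genes slipping through the LRT gate are reported separately
    pe <- assignment$eligible & !is.na(truth_class)
    recovery <- list(
      class_recovery = mean(as.character(assignment$class[pe]) == truth_class[pe]),
      cluster_recovery = mean(assignment$cluster[pe] ==
                                class_cluster(truth_class[pe])),
      n_eligible = sum(assignment$eligible),
      n_false_eligible = sum(assignment$eligible & is.na(truth_class)),
      dar_recall = {
        truth_dar <- sim$atac$truth_peaks$peak[sim$atac$truth_peaks$is_dar]
        if (length(truth_dar) > 0) mean(truth_dar %in% dar_ids) else NA_real_
      }
    )
  }

  report <- structure(list(
    summary = summary, assignment = assignment,
    contrasts = list(A = wald_a, B = wald_b, C = wald_c, lrt = lrt),
    size_factors = sf, dispersion = disp,
    annotation = annotation, links = links, dars = dars,
    dar_enrichment = dar_enr, motif_enrichment = motif_enr,
    motif_clusters = motif_clusters, recovery = recovery,
    counts = list(genes = nrow(rna_m), samples = ncol(rna_m),
                  peaks = nrow(peaks), links = nrow(links),
                  dars = length(dar_ids),
                  eligible = summary$n_eligible,
                  ineligible = summary$n_ineligible,
                  unassigned = summary$n_unassigned),
    config_hash = rlang::hash(cfg[sort(names(cfg))]),
    version = as.character(utils::packageVersion("lpsclass"))
  ), class = "lps_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.lps_report <- function(x, ...) {
  cat("<lps_report> v", x$version, ", config ", x$config_hash, "\n", sep = "")
  cat("genes: ", x$counts$genes, " (", x$counts$eligible, " eligible); peaks: ",
      x$counts$peaks, " (", x$counts$dars, " DARs, ", x$counts$links,
      " links)\n", sep = "")
  if (!is.null(x$recovery)) {
    cat("truth recovery: class ", round(100 * x$recovery$class_recovery, 1),
        "%, cluster ", round(100 * x$recovery$cluster_recovery, 1), "%\n", sep = "")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$assignment, "class_assignment.tsv")
  tsv(report$dars, "dars.tsv")
  tsv(report$links, "peak_gene_links.tsv")
  tsv(report$dar_enrichment, "dar_class_enrichment.tsv")
  if (!is.null(report$motif_enrichment)) tsv(report$motif_enrichment, "motif_enrichment.tsv")
  js <- list(counts = report$counts,
             classes = as.data.frame(report$summary$classes),
             clusters = as.data.frame(report$summary$clusters),
             recovery = report$recovery,
             config_hash = report$config_hash, version = report$version)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read pipeline inputs from plain-text interchange files
#'
#' Loads the file bundle consumed by [run_pipeline()] in real-input mode:
#' counts and design TSVs for both assays, a BED6 peak file (0-based
#' half-open), a TSS table and a FASTA of peak sequences.
#'
#' @param inputs Named list of paths: `rna_counts`, `rna_design`,
#'   `atac_counts`, `atac_design`, `peaks`, `tss`, `fasta`.
#' @return A named list of tibbles matching the simulator's output layout.
#' @export
read_pipeline_inputs <- function(inputs) {
  need <- c("rna_counts", "rna_design", "atac_counts", "atac_design",
            "peaks", "tss", "fasta")
  missing <- setdiff(need, names(inputs))
  if (length(missing) > 0) {
    abort(paste0("missing input paths: ", paste(missing, collapse = ", ")))
  }
  tsv <- function(f) as_tibble(read.table(f, header = TRUE, sep = "\t",
                                          stringsAsFactors = FALSE,
                                          check.names = FALSE))
  bed <- read.table(inputs$peaks, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  fa <- Biostrings::readDNAStringSet(inputs$fasta)
  list(
    rna_counts = tsv(inputs$rna_counts), rna_design = tsv(inputs$rna_design),
    atac_counts = tsv(inputs$atac_counts), atac_design = tsv(inputs$atac_design),
    peaks = tibble(peak = bed[[4]], chrom = bed[[1]], start = bed[[2]],
                   end = bed[[3]]),
    tss = tsv(inputs$tss),
    seqs = tibble(peak = names(fa), sequence = unname(as.character(fa)))
  )
}
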