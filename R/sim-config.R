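#' Default planted fold-change profiles
#'
#' Expected per-class expression ratios (LPS / unstimulated and LPS+BETi /
#' unstimulated) used by the simulator. Profiles are chosen so that each
#' class's expected log2 fold changes satisfy its own decision-table
#' predicate with clear margin — planted truth must be decisively
#' classifiable for recovery tests to be meaningful.
#'
#' @return A tibble with columns `class`, `r_lps`, `r_jq1`.
#' @export
default_profiles <- function() {
  tibble(
    class = class_levels(),
    r_lps = c(1.5, 0.4, 0.15, 0.62, 1.0, 8, 4, 0.35, 4, 1.0),
    r_jq1 = c(4, 3, 0.45, 1.05, 3, 3, 0.4, 0.14, 0.85, 0.5)
  )
}

#' Default class proportions
#'
#' Proportional to the per-class gene counts reported for the reference
#' ten-class partition (203, 50, 415, 760, 108, 1422, 116, 385, 235, 563 out
#' of 4257 eligible genes), scaled by `responsive`: the fraction of simulated
#' genes carrying a planted response. The remainder are null genes with no
#' condition effect, emulating that LPS-responsive genes are embedded in a
#' majority-unchanged transcriptome — a majority of stable features is also
#' what median-of-ratios normalization assumes, so `responsive` near 1 makes
#' depth estimation ill-posed.
#'
#' @param responsive Fraction of genes with a planted class (default 0.5).
#' @return Named numeric vector over `class_levels()`.
#' @export
default_class_proportions <- function(responsive = 0.5) {
  check_prob(responsive, "responsive")
  sizes <- c(I = 203, II = 50, III = 415, IV = 760, V = 108,
             VI = 1422, VII = 116, VIII = 385, IX = 235, X = 563)
  responsive * sizes / sum(sizes)
}

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator: genome layout,
#' experimental design, planted expression classes, count-model parameters,
#' accessibility and motif planting rates, and the random seed. Validated at
#' construction; in particular every class with nonzero proportion must have
#' a fold-change profile that the default decision table assigns to that
#' class in expectation.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_chroms Number of toy chromosomes (default 4).
#' @param chrom_length Chromosome length in bases (default 3e7).
#' @param conditions Ordered condition labels
#'   (default `c("unstim", "LPS", "LPS_JQ1")`).
#' @param n_replicates Replicates per condition (default 3).
#' @param class_proportions Named vector over classes, summing to <= 1; the
#'   remainder of genes are nulls with no condition effect.
#' @param fold_change_profiles Tibble `class`, `r_lps`, `r_jq1` of expected
#'   expression ratios versus unstimulated.
#' @param dispersion NB dispersion alpha (`Var = mu + alpha mu^2`),
#'   default 0.01 (biological triplicate cell culture).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   means (default `log(400)`, 0.6).
#' @param size_factor_sdlog Log-normal sigma of simulated per-sample depth
#'   factors (default 0.2).
#' @param n_distal_per_gene Distal peaks planted within +/-25 kb of each TSS
#'   (default 2).
#' @param n_background_peaks Unlinked peaks placed outside all +/-25 kb
#'   windows (default `n_genes / 2`).
#' @param dar_rate Named per-class fraction of linked distal peaks made
#'   differentially accessible; unnamed scalar applies to all classes.
#'   Default 0.5 for class VI and 0.1 elsewhere (planted enrichment near the
#'   strongly LPS-induced class).
#' @param atac_lps_ratio,atac_jq1_ratio Accessibility ratios applied to
#'   planted DARs (default 4 and 1.5: opening under LPS, attenuated under
#'   BET inhibition).
#' @param motif_plant_rate Fraction of DAR sequences receiving a planted
#'   motif instance (default 0.8).
#' @param motif_consensus Planted consensus (default AP-1 `"TGACTCA"`).
#' @param gc_content Background GC fraction (default 0.41, mouse-like).
#' @param peak_width Simulated peak width in bases (default 500).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_chroms = 4,
                       chrom_length = 3e7,
                       conditions = c("unstim", "LPS", "LPS_JQ1"),
                       n_replicates = 3,
                       class_proportions = default_class_proportions(),
                       fold_change_profiles = default_profiles(),
                       dispersion = 0.01,
                       baseline_meanlog = log(400),
                       baseline_sdlog = 0.6,
                       size_factor_sdlog = 0.2,
                       n_distal_per_gene = 2,
                       n_background_peaks = NULL,
                       dar_rate = c(VI = 0.5),
                       atac_lps_ratio = 4,
                       atac_jq1_ratio = 1.5,
                       motif_plant_rate = 0.8,
                       motif_consensus = "TGACTCA",
                       gc_content = 0.41,
                       peak_width = 500,
                       seed = 1L) {
  if (n_genes < 1 || n_chroms < 1 || n_replicates < 1) {
    abort("n_genes, n_chroms and n_replicates must be positive.")
  }
  if (length(conditions) < 2 || anyDuplicated(conditions)) {
    abort("`conditions` must be >=2 distinct labels.")
  }
  cp <- class_proportions
  if (is.null(names(cp)) || !all(names(cp) %in% class_levels())) {
    abort("`class_proportions` must be named with class labels I..X.")
  }
  if (any(cp < 0) || sum(cp) > 1 + 1e-9) {
    abort("`class_proportions` must be non-negative and sum to <= 1.")
  }
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  prof <- as_tibble(fold_change_profiles)
  if (any(prof$r_lps <= 0) || any(prof$r_jq1 <= 0)) abort("profile ratios must be > 0.")
  # consistency: each planted profile must be classifiable as its own class
  # in expectation under the default rule table
  for (cl in names(cp)[cp > 0]) {
    row <- prof[prof$class == cl, ]
    if (nrow(row) != 1) abort(paste0("no fold-change profile for class ", cl, "."))
    got <- expected_class(log2(row$r_lps), log2(row$r_jq1))
    if (got != cl) {
      abort(paste0("profile for class ", cl, " classifies as ", got,
                   " in expectation; adjust the ratios."))
    }
  }
  # genome must hold all genes with spacing for the 50 kb windows
  spacing <- floor(n_chroms * chrom_length / (n_genes + n_chroms))
  if (spacing < 52000) {
    abort("chromosomes too short: genes need >= 52 kb spacing for +/-25 kb windows.")
  }
  if (is.null(n_background_peaks)) n_background_peaks <- ceiling(n_genes / 2)
  check_prob(motif_plant_rate + 1e-12, "motif_plant_rate")
  if (gc_content <= 0 || gc_content >= 1) abort("`gc_content` must be in (0,1).")
  structure(list(
    n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), conditions = conditions,
    n_replicates = as.integer(n_replicates), class_proportions = cp,
    fold_change_profiles = prof, dispersion = dispersion,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    size_factor_sdlog = size_factor_sdlog,
    n_distal_per_gene = as.integer(n_distal_per_gene),
    n_background_peaks = as.integer(n_background_peaks),
    dar_rate = dar_rate, atac_lps_ratio = atac_lps_ratio,
    atac_jq1_ratio = atac_jq1_ratio, motif_plant_rate = motif_plant_rate,
    motif_consensus = toupper(motif_consensus), gc_content = gc_content,
    peak_width = as.integer(peak_width), seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes, ", length(x$conditions),
      " conditions x ", x$n_replicates, " replicates, seed ", x$seed, "\n", sep = "")
  cat("classes:", paste0(names(x$class_proportions), "=",
                         signif(x$class_proportions, 3), collapse = " "), "\n")
  invisible(x)
}

dar_rate_for <- function(config, classes) {
  r <- config$dar_rate
  if (is.null(names(r))) return(rep(r[1], length(classes)))
  default <- if ("" %in% names(r)) r[[""]] else 0.1
  out <- rep(default, length(classes))
  hit <- classes %in% names(r)
  out[hit] <- r[classes[hit]]
  out[is.na(classes)] <- default
  out
}
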