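#' Assign genes to response clusters and classes
#'
#' Implements the two-cluster / ten-class annotation of LPS-response genes
#' from three pairwise NB contrasts and one likelihood-ratio test:
#'
#' * A = LPS vs unstimulated,
#' * B = LPS+BETi vs unstimulated,
#' * C = LPS+BETi vs LPS,
#' * `lrt` = any-condition-effect test gating eligibility.
#'
#' A gene is eligible when `lrt$padj < alpha_sig` and
#' `lrt$baseMean >= base_mean_min`. Eligible genes fall in Cluster 1 when
#' contrast C has positive log2FC (higher expression under BET inhibition
#' during LPS stimulation), otherwise Cluster 2 (ties go to Cluster 2).
#' Within each cluster the class predicates are evaluated in a fixed order
#' ("sig" means `padj < alpha_sig`, `L` is `lfc_strong`, `d` is
#' `lfc_minimal`):
#'
#' | Class | Cluster | Predicate |
#' |-------|---------|-----------|
#' | II  | 1 | B sig and B.lfc > L and A sig and A.lfc < 0 |
#' | V   | 1 | B sig and B.lfc > L and abs(A.lfc) <= d |
#' | I   | 1 | B sig and B.lfc > L (residual of the above) |
#' | III | 1 | A.lfc <= 0 and B.lfc <= 0 and A sig and A.lfc < -L |
#' | IV  | 1 | residual |
#' | VI  | 2 | A sig and A.lfc > L and B.lfc > 0 |
#' | VII | 2 | A sig and A.lfc > 0 and B sig and B.lfc < 0 |
#' | IX  | 2 | A sig and A.lfc > 0 and B not sig |
#' | VIII| 2 | A sig and A.lfc < 0 |
#' | X   | 2 | residual |
#'
#' With the residual rules the classes partition the eligible set, so no
#' eligible gene is left unassigned under the default table.
#'
#' @param contrast_a,contrast_b,contrast_c [wald_contrast()] results for the
#'   three pairwise comparisons (same gene set).
#' @param lrt [lrt_test()] result on the same genes.
#' @param rules A [rule_table()].
#' @return A `class_assignment` tibble: `gene`, `eligible`, `cluster`
#'   (1, 2 or NA), `class` (roman label or NA for ineligible genes).
#' @export
assign_classes <- function(contrast_a, contrast_b, contrast_c, lrt,
                           rules = rule_table()) {
  genes <- contrast_a$feature
  for (x in list(contrast_b, contrast_c, lrt)) {
    if (!identical(sort(x$feature), sort(genes))) {
      abort("all contrast results must cover the same gene set.")
    }
  }
  a <- contrast_a[match(genes, contrast_a$feature), ]
  b <- contrast_b[match(genes, contrast_b$feature), ]
  cc <- contrast_c[match(genes, contrast_c$feature), ]
  l <- lrt[match(genes, lrt$feature), ]

  eligible <- !is.na(l$padj) & l$padj < rules$alpha_sig &
    !is.na(l$baseMean) & l$baseMean >= rules$base_mean_min
  sig_a <- !is.na(a$padj) & a$padj < rules$alpha_sig
  sig_b <- !is.na(b$padj) & b$padj < rules$alpha_sig
  lfc_a <- ifelse(is.na(a$log2FC), 0, a$log2FC)
  lfc_b <- ifelse(is.na(b$log2FC), 0, b$log2FC)
  lfc_c <- ifelse(is.na(cc$log2FC), 0, cc$log2FC)

  class <- rep(NA_character_, length(genes))
  idx <- which(eligible)
  class[idx] <- vapply(idx, function(i) {
    classify_one(lfc_a[i], lfc_b[i], lfc_c[i], sig_a[i], sig_b[i], rules)
  }, character(1))
  cluster <- ifelse(is.na(class), NA_integer_, class_cluster(class))

  out <- tibble(gene = genes, eligible = eligible,
                cluster = cluster,
                class = factor(class, levels = class_levels()))
  structure(out, class = c("class_assignment", class(out)), rules = rules)
}

#' Summarise a class assignment
#'
#' Counts genes per class and per cluster and reports the partition: cluster
#' totals equal the sum of their member classes, and the grand total equals
#' cluster 1 + cluster 2 + unassigned eligible genes + ineligible genes.
#'
#' @param assignment A `class_assignment` tibble from [assign_classes()] (or
#'   any data frame with columns `gene`, `eligible`, `cluster`, `class`).
#' @return A list of class `class_summary`: `classes` (tibble class, cluster,
#'   n), `clusters` (tibble cluster, n), `n_eligible`, `n_unassigned`,
#'   `n_ineligible`, `n_total`.
#' @export
class_summary <- function(assignment) {
  cls <- factor(assignment$class, levels = class_levels())
  classes <- tibble(class = factor(class_levels(), levels = class_levels()),
                    cluster = class_cluster(class_levels()),
                    n = as.integer(table(cls)))
  clusters <- classes |>
    group_by(.data$cluster) |>
    summarise(n = sum(.data$n), .groups = "drop")
  n_eligible <- sum(assignment$eligible)
  n_unassigned <- sum(assignment$eligible & is.na(cls))
  structure(list(classes = classes, clusters = clusters,
                 n_eligible = n_eligible, n_unassigned = n_unassigned,
                 n_ineligible = sum(!assignment$eligible),
                 n_total = nrow(assignment)),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("<class_summary> ", x$n_total, " genes: ", x$n_eligible, " eligible (",
      x$n_unassigned, " unassigned), ", x$n_ineligible, " ineligible\n", sep = "")
  print(x$classes)
  print(x$clusters)
  invisible(x)
}

#' @export
tidy.class_summary <- function(x, ...) x$classes

#' @export
glance.class_summary <- function(x, ...) {
  tibble(n_total = x$n_total, n_eligible = x$n_eligible,
         n_unassigned = x$n_unassigned,
         cluster1 = x$clusters$n[x$clusters$cluster == 1],
         cluster2 = x$clusters$n[x$clusters$cluster == 2])
}

#' Per-replicate log2 fold changes against a baseline condition
#'
#' Normalizes counts by size factors and expresses every non-baseline sample
#' as `log2((n + c) / (baseline_mean + c))` where `baseline_mean` is the
#' per-gene mean of normalized counts across baseline samples and `c` is a
#' pseudocount keeping ratios finite.
#'
#' @param counts Count table (feature ids first column) or matrix.
#' @param design Data frame with `sample`, `condition`.
#' @param baseline Baseline condition label (e.g. `"unstim"`).
#' @param factors Optional size factors; estimated if missing.
#' @param pseudocount Added to numerator and denominator (default 1).
#' @return A tibble: `gene` column plus one column per non-baseline sample.
#' @export
replicate_log2fc <- function(counts, design, baseline,
                             factors = NULL, pseudocount = 1) {
  m <- as_count_matrix(counts)
  design <- check_design(m, design)
  cond <- as.character(design$condition)
  if (!baseline %in% cond) abort(paste0("baseline condition `", baseline, "` not in design."))
  if (is.null(factors)) factors <- size_factors(m)
  f <- sf_vector(factors, m)
  nrm <- sweep(m, 2, f, "/")
  base_mean <- rowMeans(nrm[, cond == baseline, drop = FALSE])
  rest <- nrm[, cond != baseline, drop = FALSE]
  v <- log2(sweep(rest + pseudocount, 1, base_mean + pseudocount, "/"))
  bind_cols(tibble(gene = rownames(m)), as_tibble(v))
}

#' Row-wise z-scores
#'
#' Centers each row at its mean and scales by the sample standard deviation.
#' Constant rows map to all zeros. Used on replicate log2 fold changes before
#' heatmap display.
#'
#' @param x Data frame (feature-id column first) or numeric matrix with >=2
#'   value columns.
#' @return Same layout as the input, z-scored per row.
#' @export
zscore_rows <- function(x) {
  m <- if (is.data.frame(x)) as.matrix(x[, -1, drop = FALSE]) else x
  if (ncol(m) < 2) abort("z-scoring needs >=2 columns.")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  if (is.data.frame(x)) {
    return(bind_cols(x[, 1, drop = FALSE], as_tibble(z)))
  }
  z
}
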