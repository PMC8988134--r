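#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_hline
#'   labs theme_minimal scale_color_manual coord_flip
NULL

#' @export
ggplot2::autoplot

#' Plot PCA sample scores
#'
#' @param object An `lps_pca` from [pca_top_features()].
#' @param design Optional design table (`sample`, `condition`) for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lps_pca <- function(object, design = NULL, ...) {
  df <- object$scores
  if (!is.null(design)) {
    df <- left_join(df, design, by = "sample")
  }
  ve <- round(100 * object$var_explained[1:2], 1)
  p <- ggplot(df, aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(design)) p + geom_point(aes(color = .data$condition), size = 3)
  else p + geom_point(size = 3)
  p + labs(x = paste0("PC1 (", ve[1], "%)"), y = paste0("PC2 (", ve[2], "%)")) +
    theme_minimal()
}

#' Plot class sizes per cluster
#'
#' @param object A `class_summary` from [class_summary()].
#' @param ... Unused.
#' @return A ggplot bar chart of genes per class.
#' @export
autoplot.class_summary <- function(object, ...) {
  ggplot(object$classes,
         aes(x = .data$class, y = .data$n, fill = factor(.data$cluster))) +
    geom_col() +
    labs(x = "response class", y = "genes", fill = "cluster") +
    theme_minimal()
}

#' Volcano plot of a differential-accessibility result
#'
#' @param object A `dar_set` from [call_dars()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dar_set <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$p), ]
  ggplot(df, aes(x = .data$log2FC, y = -log10(.data$padj),
                 color = .data$is_dar)) +
    geom_point(alpha = 0.5, size = 0.8) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "log2 fold change", y = "-log10 FDR", color = "DAR") +
    theme_minimal()
}

#' Plot motif enrichment results
#'
#' @param object A `motif_enrichment` from [motif_enrichment()].
#' @param fdr Reference line (default 0.10).
#' @param top Show the `top` most enriched motifs (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_enrichment <- function(object, fdr = 0.10, top = 20, ...) {
  df <- head(arrange(as_tibble(object), .data$p), top)
  df$motif <- factor(df$motif, levels = rev(df$motif))
  ggplot(df, aes(x = .data$motif, y = -log10(.data$padj))) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "-log10 FDR") +
    theme_minimal()
}
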