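peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    peak = peaks$peak
  )
}

#' Classify peaks as promoter or distal
#'
#' A peak is a promoter peak when it overlaps (by >= 1 bp) the
#' strand-oriented window around any TSS: `[TSS - upstream, TSS + downstream]`
#' on the plus strand, mirrored on the minus strand. All other peaks are
#' distal. Coordinates are BED-style 0-based half-open; the TSS is a single
#' 0-based base.
#'
#' @param peaks Data frame with `peak`, `chrom`, `start`, `end`.
#' @param tss Data frame with `gene`, `chrom`, `tss`, `strand`.
#' @param upstream,downstream Window extent in bases (defaults 1000 and 100).
#' @return A tibble `peak`, `label` (`"promoter"` or `"distal"`).
#' @export
annotate_peaks <- function(peaks, tss, upstream = 1000, downstream = 100) {
  bad <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(bad) > 0) {
    abort(paste0("peak chromosomes absent from the TSS table: ",
                 paste(bad, collapse = ", ")))
  }
  plus <- tss$strand != "-"
  win_start <- ifelse(plus, tss$tss - upstream, tss$tss - downstream)
  win_end <- ifelse(plus, tss$tss + downstream, tss$tss + upstream)
  windows <- GenomicRanges::GRanges(tss$chrom,
                                    IRanges::IRanges(win_start + 1L, win_end + 1L))
  gr <- peaks_granges(peaks)
  hit <- GenomicRanges::countOverlaps(gr, windows, minoverlap = 1L) > 0
  tibble(peak = peaks$peak, label = ifelse(hit, "promoter", "distal"))
}

#' Link distal peaks to genes within a TSS window
#'
#' Links every distal peak to each gene whose `[TSS - window, TSS + window)`
#' interval it overlaps by >= 1 bp (the 50 kb window semantics of
#' window-overlap interval tools; not strand-aware). A peak may link to
#' several genes and a gene may have no linked peaks.
#'
#' @inheritParams annotate_peaks
#' @param window Half-width of the association window in bases
#'   (default 25000).
#' @param annotation Promoter/distal labels from [annotate_peaks()]; computed
#'   from `peaks` and `tss` when missing.
#' @return A tibble `peak`, `gene` with one row per link.
#' @export
link_distal_peaks <- function(peaks, tss, window = 25000,
                              annotation = annotate_peaks(peaks, tss)) {
  distal <- peaks[peaks$peak %in% annotation$peak[annotation$label == "distal"], ,
                  drop = FALSE]
  if (nrow(distal) == 0) return(tibble(peak = character(), gene = character()))
  gr <- peaks_granges(distal)
  wins <- GenomicRanges::GRanges(tss$chrom,
                                 IRanges::IRanges(tss$tss - window + 1L,
                                                  tss$tss + window))
  ov <- GenomicRanges::findOverlaps(gr, wins, minoverlap = 1L)
  tibble(peak = distal$peak[S4Vectors::queryHits(ov)],
         gene = tss$gene[S4Vectors::subjectHits(ov)])
}

#' Flag differentially accessible regions
#'
#' Annotates a peak-level contrast with DAR flags: significance at
#' `padj < alpha`, direction from the sign of the log2 fold change, and two
#' magnitude bins (`|log2FC|` above `thresholds[1]` and `thresholds[2]`).
#'
#' @param peak_contrast An [wald_contrast()] result computed on peak counts.
#' @param alpha FDR cutoff (default 0.05).
#' @param thresholds Mid and high `|log2FC|` thresholds
#'   (default `c(0.5, 1)`).
#' @return A `dar_set` tibble: the contrast columns plus `is_dar`,
#'   `direction` (-1/0/+1), `mid_magnitude`, `high_magnitude`.
#' @export
call_dars <- function(peak_contrast, alpha = 0.05, thresholds = c(0.5, 1)) {
  check_prob(alpha, "alpha")
  if (length(thresholds) != 2 || thresholds[1] > thresholds[2]) {
    abort("`thresholds` must be (mid, high) with mid <= high.")
  }
  out <- if (inherits(peak_contrast, "lps_contrast")) {
    as_tibble(tidy(peak_contrast))
  } else {
    as_tibble(peak_contrast)
  }
  out$is_dar <- !is.na(out$padj) & out$padj < alpha
  out$direction <- ifelse(out$is_dar, sign(out$log2FC), 0)
  out$mid_magnitude <- out$is_dar & abs(out$log2FC) > thresholds[1]
  out$high_magnitude <- out$is_dar & abs(out$log2FC) > thresholds[2]
  structure(out, class = c("dar_set", class(out)), alpha = alpha,
            thresholds = thresholds)
}

#' Central window of each peak
#'
#' Replaces each interval wider than `width` by the `width`-bp window centred
#' on its midpoint (floor); narrower peaks are returned unchanged. Used to
#' focus motif scans on the accessible core of DARs.
#'
#' @param peaks Data frame with `peak`, `chrom`, `start`, `end`.
#' @param width Window width in bases (default 500).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping.
#' @return The peak tibble with adjusted `start`/`end`.
#' @export
central_window <- function(peaks, width = 500, chrom_lengths = NULL) {
  mid <- (peaks$start + peaks$end) %/% 2L
  wide <- (peaks$end - peaks$start) > width
  start <- ifelse(wide, mid - width %/% 2L, peaks$start)
  end <- ifelse(wide, mid - width %/% 2L + width, peaks$end)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[peaks$chrom]
    end <- pmin(end, lim)
  }
  out <- as_tibble(peaks)
  out$start <- as.integer(start)
  out$end <- as.integer(end)
  out
}
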