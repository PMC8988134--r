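#' Upper-tail hypergeometric enrichment test
#'
#' Given `k` successes among `n` draws from a universe of `N` items of which
#' `K` are successes, computes the one-sided enrichment p-value
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` and the fold enrichment
#' `(k/n) / (K/N)`.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @return A tibble with `k`, `K`, `n`, `N`, `fold`, `p`.
#' @examples
#' hypergeom_enrichment(k = 4, K = 5, n = 4, N = 10)  # p = 5/210
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(n, K)) {
    abort("inconsistent counts: need 0 <= k <= min(n, K) and K, n <= N.")
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  tibble(k = k, K = K, n = n, N = N, fold = fold, p = p)
}

#' Enrichment of DARs around genes of each response class
#'
#' Tests whether differentially accessible regions concentrate near the
#' genes of an expression class. The universe is all linked distal peaks
#' (`N`), of which the DARs are the successes (`K`); the draw is the peaks
#' linked to the class's genes (`n`), with `k` DARs among them. One
#' hypergeometric upper-tail p-value per class; a peak linked to several
#' genes counts once per class it touches.
#'
#' @param dars A [call_dars()] result (needs `feature`, `is_dar`).
#' @param links Peak-gene links from [link_distal_peaks()].
#' @param classes A [assign_classes()] result (needs `gene`, `class`).
#' @param class_id Classes to test (default: all ten).
#' @return A tibble with one row per class: counts, `fold`, `p` and BH
#'   `padj` across the tested classes. Classes without linked peaks give NA
#'   with a warning.
#' @export
dar_class_enrichment <- function(dars, links, classes, class_id = class_levels()) {
  universe <- links |> distinct(.data$peak)
  dar_peaks <- dars$feature[dars$is_dar]
  N <- nrow(universe)
  K <- sum(universe$peak %in% dar_peaks)
  res <- purrr::map_dfr(class_id, function(cl) {
    genes <- classes$gene[!is.na(classes$class) & classes$class == cl]
    cl_peaks <- unique(links$peak[links$gene %in% genes])
    n <- length(cl_peaks)
    if (n == 0) {
      warn(paste0("class ", cl, " has no linked peaks; enrichment is NA."))
      return(tibble(class = cl, k = NA_integer_, K = K, n = 0L, N = N,
                    fold = NA_real_, p = NA_real_))
    }
    k <- sum(cl_peaks %in% dar_peaks)
    bind_cols(tibble(class = cl), hypergeom_enrichment(k, K, n, N))
  })
  res$padj <- bh_adjust(res$p)
  res
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction by default (large-count regime); the Yates
#' correction is available via `correct = TRUE`. Zero margins are an error.
#'
#' @param tab A 2x2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A tibble with `statistic`, `df`, `p`.
#' @examples
#' chisq_2x2(matrix(c(10, 20, 20, 10), 2))
#' @export
chisq_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) {
    abort("`tab` must be a 2x2 matrix of non-negative counts.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all margins of the 2x2 table must be positive.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Signed-rank test on paired differences; zero differences are dropped. The
#' exact null distribution is used for up to 25 informative pairs without
#' ties, otherwise the normal approximation with tie correction. If every
#' difference is zero the test is uninformative and `p = 1` is returned.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A tibble with `statistic` (V), `p`, `n_pairs` (informative pairs).
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must be paired vectors of equal length >= 2.")
  }
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    return(tibble(statistic = NA_real_, p = 1, n_pairs = 0L))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- length(d) <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = !exact))
  tibble(statistic = unname(wt$statistic), p = wt$p.value,
         n_pairs = length(d))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values. Returns `NA` for constant
#' input.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation coefficient rho.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}
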