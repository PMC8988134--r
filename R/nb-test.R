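#' Benjamini-Hochberg adjustment with NA passthrough
#'
#' Step-up FDR adjustment. `NA` entries are passed through unchanged and are
#' not counted in the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

new_contrast_result <- function(tbl, type, contrast, df = NA_real_) {
  structure(tbl, class = c("lps_contrast", class(tbl)),
            type = type, contrast = contrast, df = df)
}

#' @export
print.lps_contrast <- function(x, ...) {
  cat("<lps_contrast> ", attr(x, "type"), ": ", attr(x, "contrast"), "\n", sep = "")
  NextMethod()
}

#' Negative-binomial Wald contrast between two conditions
#'
#' Fits a per-feature NB model with a group mean for each condition
#' (log link, size-factor offsets, fixed method-of-moments dispersion) and
#' tests the log2 fold change of `condition_b` over `condition_a` with a Wald
#' statistic. The standard error comes from the observed Fisher information.
#' Because the plug-in dispersion is estimated on few residual degrees of
#' freedom, p-values are by default referred to a t distribution with the
#' dispersion's residual df, which keeps the test calibrated in small designs;
#' `stat_dist = "normal"` gives the asymptotic N(0,1) reference.
#'
#' @param counts Count table (feature ids first column) or matrix.
#' @param design Data frame with columns `sample`, `condition`.
#' @param condition_a Reference (denominator) condition label.
#' @param condition_b Treatment (numerator) condition label.
#' @param factors Optional size factors; estimated from `counts` if missing.
#' @param dispersion Optional tibble from [estimate_dispersion()]; estimated
#'   on the full design if missing.
#' @param stat_dist `"t"` (default) or `"normal"` reference for the Wald
#'   statistic.
#' @return An `lps_contrast` tibble: `feature`, `baseMean`, `log2FC`, `SE`,
#'   `stat`, `p`, `padj`. Features with zero counts everywhere get NA rows and
#'   are excluded from the BH adjustment.
#' @export
wald_contrast <- function(counts, design, condition_a, condition_b,
                          factors = NULL, dispersion = NULL,
                          stat_dist = c("t", "normal")) {
  stat_dist <- match.arg(stat_dist)
  m <- as_count_matrix(counts)
  design <- check_design(m, design)
  cond <- as.character(design$condition)
  for (cc in c(condition_a, condition_b)) {
    if (sum(cond == cc) < 2) abort(paste0("condition `", cc, "` needs >=2 replicates."))
  }
  if (is.null(factors)) factors <- size_factors(m)
  f <- sf_vector(factors, m)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(m, design, factors = f)
  alpha <- dispersion$dispersion[match(rownames(m), dispersion$feature)]
  df <- attr(dispersion, "df") %||% NA_real_

  iA <- cond == condition_a
  iB <- cond == condition_b
  mA <- nb_group_mean(m[, iA, drop = FALSE], f[iA], alpha)
  mB <- nb_group_mean(m[, iB, drop = FALSE], f[iB], alpha)
  base_mean <- rowMeans(sweep(m[, iA | iB, drop = FALSE], 2, f[iA | iB], "/"))

  eps <- 1e-8
  lfc <- log2(pmax(mB, eps)) - log2(pmax(mA, eps))
  info <- function(mm, ss) {
    mu <- outer(pmax(mm, eps), ss)
    rowSums(mu / (1 + alpha * mu))
  }
  se <- sqrt(1 / info(mA, f[iA]) + 1 / info(mB, f[iB])) / log(2)
  stat <- lfc / se
  p <- if (stat_dist == "t" && is.finite(df) && df > 0) {
    2 * pt(abs(stat), df = df, lower.tail = FALSE)
  } else {
    2 * pnorm(abs(stat), lower.tail = FALSE)
  }
  na <- base_mean == 0
  lfc[na] <- se[na] <- stat[na] <- p[na] <- NA_real_
  out <- tibble(feature = rownames(m), baseMean = base_mean, log2FC = lfc,
                SE = se, stat = stat, p = p, padj = bh_adjust(p))
  new_contrast_result(out, "wald", paste0(condition_b, " vs ", condition_a), df)
}

#' Negative-binomial likelihood-ratio test over conditions
#'
#' Compares a full per-condition-mean NB model against an intercept-only
#' reduced model feature by feature, with size-factor offsets and fixed
#' method-of-moments dispersion. The statistic is twice the log-likelihood
#' difference; with `stat_dist = "f"` (default) `stat/df` is referred to an
#' F(df, residual df) distribution, which compensates for the estimated
#' dispersion in small designs; `"chisq"` gives the asymptotic chi-squared
#' reference.
#'
#' @inheritParams wald_contrast
#' @param conditions Conditions forming the full model (default: all in
#'   `design`).
#' @param stat_dist `"f"` (default) or `"chisq"`.
#' @return An `lps_contrast` tibble with `feature`, `baseMean`, `stat`, `df`,
#'   `p`, `padj` (plus `log2FC` of the last vs first condition for reference).
#' @export
lrt_test <- function(counts, design, conditions = NULL,
                     factors = NULL, dispersion = NULL,
                     stat_dist = c("f", "chisq")) {
  stat_dist <- match.arg(stat_dist)
  m <- as_count_matrix(counts)
  design <- check_design(m, design)
  cond <- as.character(design$condition)
  if (is.null(conditions)) conditions <- unique(cond)
  if (length(conditions) < 2) abort("the full model needs >=2 conditions.")
  keep <- cond %in% conditions
  m <- m[, keep, drop = FALSE]
  design <- design[keep, , drop = FALSE]
  cond <- cond[keep]
  if (is.null(factors)) factors <- size_factors(m)
  f <- sf_vector(factors, m)
  if (is.null(dispersion)) dispersion <- estimate_dispersion(m, design, factors = f)
  alpha <- dispersion$dispersion[match(rownames(m), dispersion$feature)]
  rdf <- attr(dispersion, "df") %||% NA_real_

  ll_full <- rep(0, nrow(m))
  group_means <- list()
  for (cc in conditions) {
    idx <- cond == cc
    mg <- nb_group_mean(m[, idx, drop = FALSE], f[idx], alpha)
    group_means[[cc]] <- mg
    ll_full <- ll_full + nb_loglik(m[, idx, drop = FALSE], f[idx], mg, alpha)
  }
  m0 <- nb_group_mean(m, f, alpha)
  ll_red <- nb_loglik(m, f, m0, alpha)
  stat <- pmax(2 * (ll_full - ll_red), 0)
  df <- length(conditions) - 1
  p <- if (stat_dist == "f" && is.finite(rdf) && rdf > 0) {
    pf(stat / df, df1 = df, df2 = rdf, lower.tail = FALSE)
  } else {
    pchisq(stat, df = df, lower.tail = FALSE)
  }
  base_mean <- rowMeans(sweep(m, 2, f, "/"))
  na <- base_mean == 0
  stat[na] <- p[na] <- NA_real_
  lfc <- log2(pmax(group_means[[length(conditions)]], 1e-8)) -
    log2(pmax(group_means[[1]], 1e-8))
  lfc[na] <- NA_real_
  out <- tibble(feature = rownames(m), baseMean = base_mean, log2FC = lfc,
                stat = stat, df = df, p = p, padj = bh_adjust(p))
  new_contrast_result(out, "lrt",
                      paste0(paste(conditions, collapse = "+"), " vs intercept"), rdf)
}

#' PCA on the most variable features
#'
#' Selects the `k` features with the largest row variance, centers each row,
#' and decomposes with SVD. Mirrors the usual VST-counts PCA used for sample
#' overview plots.
#'
#' @param x Feature-by-sample data frame (feature-id column first) or matrix,
#'   typically VST-transformed.
#' @param k Number of top-variance features to keep.
#' @return An object of class `lps_pca`: list with `scores` (tibble, one row
#'   per sample), `loadings`, `var_explained`, and the retained feature ids.
#' @export
pca_top_features <- function(x, k = 1000) {
  m <- if (is.data.frame(x)) {
    mm <- as.matrix(x[, -1, drop = FALSE]); rownames(mm) <- as.character(x[[1]]); mm
  } else x
  if (k <= 0) abort("`k` must be positive.")
  k <- min(k, nrow(m))
  rv <- apply(m, 1, var)
  keep <- order(rv, decreasing = TRUE)[seq_len(k)]
  xc <- m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])
  sv <- svd(xc)
  npc <- min(ncol(m) - 1L, length(sv$d))
  scores <- sv$v[, seq_len(npc), drop = FALSE] %*% diag(sv$d[seq_len(npc)], npc)
  colnames(scores) <- paste0("PC", seq_len(npc))
  ve <- sv$d[seq_len(npc)]^2 / sum(sv$d^2)
  structure(list(
    scores = bind_cols(tibble(sample = colnames(m)), as_tibble(scores)),
    loadings = sv$u[, seq_len(npc), drop = FALSE],
    var_explained = ve,
    features = rownames(m)[keep]
  ), class = "lps_pca")
}

#' @export
print.lps_pca <- function(x, ...) {
  cat("<lps_pca> ", length(x$features), " features, ",
      nrow(x$scores), " samples\n", sep = "")
  cat("variance explained:", paste0(round(100 * x$var_explained, 1), "%"), "\n")
  invisible(x)
}

#' @rdname tidy.lps_contrast
#' @export
glance.lps_contrast <- function(x, alpha = 0.05, ...) {
  tibble(type = attr(x, "type"), contrast = attr(x, "contrast"),
         n_features = nrow(x), n_tested = sum(!is.na(x$p)),
         n_significant = sum(x$padj < alpha, na.rm = TRUE))
}

#' Tidy differential-test results
#'
#' `tidy()` returns the per-feature table as a plain tibble; `glance()`
#' returns a one-row summary (features tested, significant at `alpha`).
#'
#' @param x An `lps_contrast` object.
#' @param alpha FDR threshold used by `glance()`.
#' @param ... Unused.
#' @export
tidy.lps_contrast <- function(x, ...) {
  class(x) <- setdiff(class(x), "lps_contrast")
  as_tibble(x)
}
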