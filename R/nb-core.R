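#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample correcting for sequencing
#' depth, using the median-of-ratios method: each count is divided by its
#' feature's geometric mean across samples, and the per-sample median of those
#' ratios is the factor. Factors are rescaled to geometric mean 1. Features
#' containing any zero are excluded from the reference; if no feature is
#' nonzero in every sample, geometric means are computed over positive counts
#' only (with a warning).
#'
#' @param counts Count table (feature-id column first) or matrix.
#' @return A tibble with columns `sample` and `size_factor`.
#' @examples
#' counts <- tibble::tibble(gene = c("a", "b", "c"),
#'                          s1 = c(10, 30, 90), s2 = c(20, 60, 180))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  ref <- rowSums(m == 0) == 0
  if (!any(ref)) {
    warn("no feature is nonzero in every sample; using positive counts only for geometric means.")
    ref <- rowSums(m > 0) > 0
    gm <- apply(m[ref, , drop = FALSE], 1, geomean_pos)
  } else {
    gm <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  }
  ratios <- m[ref, , drop = FALSE] / gm
  f <- apply(ratios, 2, function(col) median(col[col > 0]))
  f <- f / exp(mean(log(f)))
  tibble(sample = colnames(m) %||% paste0("s", seq_along(f)), size_factor = unname(f))
}

sf_vector <- function(factors, m) {
  if (is.data.frame(factors)) {
    f <- factors$size_factor[match(colnames(m), factors$sample)]
  } else {
    f <- factors
  }
  if (length(f) != ncol(m) || any(!is.finite(f)) || any(f <= 0)) {
    abort("size factors must be positive and match the samples.")
  }
  f
}

#' Shifted-log variance-stabilizing transform
#'
#' Computes `log2(count / size_factor + 1)` per entry. This is a monotone
#' proxy for a variance-stabilizing transform, adequate for PCA and
#' rank-based correlation where only variance/rank structure matters.
#'
#' @param counts Count table or matrix.
#' @param factors Size factors as returned by [size_factors()] (tibble) or a
#'   numeric vector; defaults to estimating them from `counts`.
#' @return Same layout as the input (tibble in, tibble out) with transformed
#'   values.
#' @export
vst_transform <- function(counts, factors = size_factors(counts)) {
  m <- as_count_matrix(counts)
  f <- sf_vector(factors, m)
  out <- log2(sweep(m, 2, f, "/") + 1)
  if (is.data.frame(counts)) {
    res <- as_tibble(out)
    res <- bind_cols(tibble(!!names(counts)[1] := rownames(out)), res)
    return(res)
  }
  out
}

#' Method-of-moments per-feature dispersion
#'
#' For each feature, the negative-binomial dispersion `alpha` in
#' `Var = mu + alpha * mu^2` is estimated from normalized counts by pooling
#' within-condition residual variance: `alpha = max(floor, (s2 - m) / m^2)`
#' with `m` the overall normalized mean and `s2` the pooled within-condition
#' sample variance. No shrinkage toward a trend is applied.
#'
#' @param counts Count table or matrix.
#' @param design Data frame with columns `sample`, `condition`.
#' @param factors Size factors (tibble or vector); estimated if missing.
#' @param floor Lower bound for the estimate (default `1e-8`).
#' @return A tibble with columns `feature`, `mean`, `dispersion`, plus the
#'   residual degrees of freedom as attribute `"df"`.
#' @export
estimate_dispersion <- function(counts, design, factors = size_factors(counts),
                                floor = 1e-8) {
  m <- as_count_matrix(counts)
  design <- check_design(m, design)
  f <- sf_vector(factors, m)
  cond <- as.character(design$condition)
  reps <- table(cond)
  if (all(reps < 2)) abort("dispersion estimation needs >=2 replicates in some condition.")
  use <- cond %in% names(reps)[reps >= 2]
  nrm <- sweep(m, 2, f, "/")
  nb <- nrm[, use, drop = FALSE]
  cu <- cond[use]
  k <- length(unique(cu))
  df <- ncol(nb) - k
  # pooled within-condition sum of squares
  ss <- matrix(0, nrow(nb), 1)
  for (cc in unique(cu)) {
    sub <- nb[, cu == cc, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  s2 <- as.vector(ss) / df
  mbar <- rowMeans(nrm)
  alpha <- ifelse(mbar > 0, pmax(floor, (s2 - mbar) / mbar^2), floor)
  out <- tibble(feature = rownames(m), mean = unname(mbar),
                dispersion = unname(alpha))
  attr(out, "df") <- df
  out
}

# Newton solve for the NB group mean with offsets (size factors) and fixed
# dispersion; vectorized over features. y: features x samples matrix for one
# group, s: size factors, alpha: per-feature dispersion.
nb_group_mean <- function(y, s, alpha, iter = 25L, tol = 1e-10) {
  m <- rowSums(y) / sum(s)
  pos <- m > 0
  if (!any(pos)) return(m)
  for (i in seq_len(iter)) {
    sm <- outer(m, s)                     # mu_ij = s_j * m_i
    d <- 1 + alpha * sm
    f <- rowSums((y - sm) / d)
    fp <- -rowSums(sweep(1 + alpha * y, 2, s, "*") / d^2)
    step <- f / fp
    step[!pos | !is.finite(step)] <- 0
    m_new <- pmax(m - step, m * 1e-3)
    if (max(abs(m_new - m) / pmax(m, 1e-8)) < tol) { m <- m_new; break }
    m <- m_new
  }
  m
}

# NB log-likelihood for fitted group means; mu_ij = s_j * m_i. alpha floor
# keeps dnbinom stable (size = 1/alpha).
nb_loglik <- function(y, s, m, alpha) {
  mu <- outer(pmax(m, 1e-12), s)
  size <- 1 / pmax(alpha, 1e-12)
  rowSums(dnbinom(y, size = size, mu = mu, log = TRUE))
}
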