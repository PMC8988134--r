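#' Similarity between two PWMs
#'
#' Slides motif `b` (and its reverse complement) along motif `a` over every
#' ungapped offset whose aligned width is at least `w_min`, computes the
#' Pearson correlation `r` of the flattened aligned probability columns, and
#' the width-normalized correlation `Ncor = r * w / max(W_a, W_b)`. The
#' alignment maximizing `Ncor` is returned. Alignments where either side has
#' zero variance (e.g. a uniform motif) are skipped; if no valid alignment
#' exists both similarities are 0.
#'
#' @param a,b [pwm()] objects.
#' @param w_min Minimum aligned width (default 5).
#' @return A one-row tibble: `r`, `ncor`, `offset` (start of `b` relative to
#'   `a`, 0 = aligned starts), `orientation` (`"+"`/`"-"`), `w`.
#' @export
motif_similarity <- function(a, b, w_min = 5) {
  wa <- pwm_width(a)
  wb <- pwm_width(b)
  best <- tibble(r = 0, ncor = 0, offset = NA_integer_,
                 orientation = NA_character_, w = NA_integer_)
  found <- FALSE
  for (orient in c("+", "-")) {
    bm <- if (orient == "+") b$mat else pwm_revcomp(b)$mat
    for (d in seq(-(wb - w_min), wa - w_min)) {
      ia <- max(1, d + 1):min(wa, d + wb)
      w <- length(ia)
      if (w < w_min) next
      ib <- ia - d
      va <- as.vector(a$mat[, ia, drop = FALSE])
      vb <- as.vector(bm[, ib, drop = FALSE])
      if (sd(va) == 0 || sd(vb) == 0) next
      r <- cor(va, vb)
      ncor <- r * w / max(wa, wb)
      if (!found || ncor > best$ncor) {
        best <- tibble(r = r, ncor = ncor, offset = d,
                       orientation = orient, w = w)
        found <- TRUE
      }
    }
  }
  best
}

#' Cluster a motif library by similarity
#'
#' Builds a graph with an edge between two motifs whenever their best
#' alignment satisfies `r >= r_min`, `Ncor >= ncor_min` and aligned width
#' `>= w_min`, and reports connected components as clusters. Cluster labels
#' are the lexicographically smallest member id, making the result invariant
#' to input order.
#'
#' @param library A `pwm_list` (or list of [pwm()]).
#' @param r_min Minimum Pearson correlation (default 0.7).
#' @param ncor_min Minimum width-normalized correlation (default 0.4).
#' @param w_min Minimum aligned width (default 5).
#' @return A tibble `motif`, `cluster`, sorted by motif id.
#' @export
cluster_motifs <- function(library, r_min = 0.7, ncor_min = 0.4, w_min = 5) {
  library <- as_pwm_list(library)
  ids <- names(library)
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- motif_similarity(library[[i]], library[[j]], w_min = w_min)
        adj[i, j] <- adj[j, i] <- !is.na(s$w) && s$w >= w_min &&
          s$r >= r_min && s$ncor >= ncor_min
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  label <- vapply(seq_len(max(comp)), function(k) min(ids[comp == k]), character(1))
  out <- tibble(motif = ids, cluster = label[comp])
  arrange(out, .data$motif)
}
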