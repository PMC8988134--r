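seq_codes <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA)  # N and others -> NA
}

# log2-odds score matrix against a 0-order background, pseudocount-regularized
pwm_score_mat <- function(x, background = rep(0.25, 4), pseudo = 1e-3) {
  p <- sweep(x$mat + pseudo, 2, colSums(x$mat + pseudo), "/")
  q <- (background + pseudo) / sum(background + pseudo)
  log2(p / q)
}

# per-offset scores of one coded sequence for one score matrix;
# windows containing N give NA
slide_scores <- function(codes, smat) {
  w <- ncol(smat)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  na <- logical(n_off)
  for (j in seq_len(w)) {
    v <- smat[cbind(codes[j:(j + n_off - 1L)], j)]
    na <- na | is.na(v)
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc[na] <- NA_real_
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every offset of the sequence on both strands with the log2-odds
#' matrix of the PWM against a 0-order background and reports hits scoring
#' at least `score_fraction` of the maximum achievable score. Windows
#' containing `N` are skipped. Offsets are 1-based positions of the window
#' start on the forward strand.
#'
#' @param x A [pwm()].
#' @param sequence A single sequence over A/C/G/T/N.
#' @param score_fraction Hit threshold as a fraction of the maximum score
#'   (default 0.8).
#' @param background Base composition A, C, G, T (default uniform).
#' @return A tibble with `offset`, `strand`, `score`, sorted by offset.
#' @export
scan_pwm <- function(x, sequence, score_fraction = 0.8,
                     background = rep(0.25, 4)) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    abort("`sequence` must be one non-empty string.")
  }
  if (pwm_width(x) > nchar(sequence)) {
    return(tibble(offset = integer(), strand = character(), score = double()))
  }
  codes <- seq_codes(sequence)
  fwd <- pwm_score_mat(x, background)
  rev <- pwm_score_mat(pwm_revcomp(x), background)
  thr <- score_fraction * sum(apply(fwd, 2, max))
  sf <- slide_scores(codes, fwd)
  sr <- slide_scores(codes, rev)
  hits <- bind_rows(
    tibble(offset = which(!is.na(sf) & sf >= thr), strand = "+",
           score = sf[!is.na(sf) & sf >= thr]),
    tibble(offset = which(!is.na(sr) & sr >= thr), strand = "-",
           score = sr[!is.na(sr) & sr >= thr])
  )
  arrange(hits, .data$offset, .data$strand)
}

get_sequences <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"sequence" %in% names(x)) {
      abort(paste0("`", what, "` data frame needs a `sequence` column."))
    }
    return(as.character(x$sequence))
  }
  as.character(x)
}

base_composition <- function(seqs) {
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                      levels = DNA))
  n <- sum(tab)
  if (n == 0) rep(0.25, 4) else as.numeric(tab) / n
}

# fraction of sequences with >= 1 hit; batch implementation grouping
# sequences of equal length into matrices
presence_hits <- function(x, seqs, score_fraction, background) {
  fwd <- pwm_score_mat(x, background)
  rev <- pwm_score_mat(pwm_revcomp(x), background)
  w <- ncol(fwd)
  thr <- score_fraction * sum(apply(fwd, 2, max))
  out <- logical(length(seqs))
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (L < w) next
    cm <- matrix(match(unlist(strsplit(toupper(seqs[idx]), ""), use.names = FALSE),
                       DNA), nrow = length(idx), byrow = TRUE)
    n_off <- L - w + 1L
    hit <- logical(length(idx))
    for (sm in list(fwd, rev)) {
      sc <- matrix(0, length(idx), n_off)
      na <- matrix(FALSE, length(idx), n_off)
      for (j in seq_len(w)) {
        v <- matrix(sm[cbind(as.vector(cm[, j:(j + n_off - 1L)]),
                             rep(j, length(idx) * n_off))],
                    nrow = length(idx))
        na <- na | is.na(v)
        v[is.na(v)] <- 0
        sc <- sc + v
      }
      sc[na] <- -Inf
      hit <- hit | apply(sc, 1, max) >= thr
    }
    out[idx] <- hit
  }
  out
}

#' Known-motif enrichment in target versus background sequences
#'
#' For each motif in a library, counts the sequences containing at least one
#' hit (both strands, [scan_pwm()] semantics) in the target and background
#' sets and tests over-representation with a one-sided hypergeometric test
#' on the pooled 2x2 presence table (a binomial alternative uses the
#' background hit rate). The log-odds background is the 0-order base
#' composition of the background set. P-values are BH-adjusted across the
#' library and rows sorted by p.
#'
#' @param targets,background Sequence sets: character vectors or data frames
#'   with a `sequence` column. Both must be non-empty.
#' @param library A `pwm_list` (or list of [pwm()]).
#' @param score_fraction Hit threshold (default 0.8 of the maximum score).
#' @param method `"hypergeometric"` (default) or `"binomial"`.
#' @return A `motif_enrichment` tibble: `motif`, `name`, `target_hits`,
#'   `target_n`, `bg_hits`, `bg_n`, `fold`, `p`, `padj`.
#' @export
motif_enrichment <- function(targets, background, library,
                             score_fraction = 0.8,
                             method = c("hypergeometric", "binomial")) {
  method <- match.arg(method)
  library <- as_pwm_list(library)
  if (length(library) == 0) abort("`library` is empty.")
  t_seqs <- get_sequences(targets, "targets")
  b_seqs <- get_sequences(background, "background")
  if (length(t_seqs) == 0 || length(b_seqs) == 0) {
    abort("both sequence sets must be non-empty.")
  }
  comp <- base_composition(b_seqs)
  res <- purrr::map_dfr(library, function(m) {
    th <- sum(presence_hits(m, t_seqs, score_fraction, comp))
    bh <- sum(presence_hits(m, b_seqs, score_fraction, comp))
    nt <- length(t_seqs)
    nb <- length(b_seqs)
    if (method == "hypergeometric") {
      hg <- hypergeom_enrichment(k = th, K = th + bh, n = nt, N = nt + nb)
      p <- hg$p
      fold <- hg$fold
    } else {
      rate <- max(bh / nb, 1e-12)
      p <- stats::pbinom(th - 1, nt, rate, lower.tail = FALSE)
      fold <- (th / nt) / rate
    }
    tibble(motif = m$id, name = m$name, target_hits = th, target_n = nt,
           bg_hits = bh, bg_n = nb, fold = fold, p = p)
  })
  res$padj <- bh_adjust(res$p)
  res <- arrange(res, .data$p)
  structure(res, class = c("motif_enrichment", class(res)), method = method)
}
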