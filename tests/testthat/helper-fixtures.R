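# Shared fixtures, memoized so expensive simulations run once per suite.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# default-condition synthetic study used by recovery and enrichment tests
default_report <- function() {
  memo("default_report", run_pipeline(list(sim = sim_config(seed = 101))))
}

# an all-null simulation (no planted classes) for calibration checks
null_sim <- function(n_genes = 2000, seed = 202) {
  memo(paste0("null_sim_", n_genes, "_", seed), {
    cfg <- sim_config(n_genes = n_genes,
                      class_proportions = setNames(rep(0, 10), class_levels()),
                      seed = seed)
    simulate_dataset(cfg)
  })
}

# tiny deterministic count table for hand-checked examples
toy_counts <- function() {
  tibble::tibble(gene = c("g1", "g2", "g3"),
                 s1 = c(10, 30, 90), s2 = c(20, 60, 180))
}

random_seq <- function(n, len, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

plant_motif <- function(seqs, motif, rate = 1) {
  for (i in seq_along(seqs)) {
    if (runif(1) > rate) next
    o <- sample.int(nchar(seqs[i]) - nchar(motif) + 1, 1)
    ins <- if (runif(1) < 0.5) motif else revcomp(motif)
    substr(seqs[i], o, o + nchar(motif) - 1) <- ins
  }
  seqs
}

# brute-force strand-aware promoter/distal annotation (quadratic oracle)
oracle_annotate <- function(peaks, tss, upstream = 1000, downstream = 100) {
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    hit <- FALSE
    for (j in seq_len(nrow(tss))) {
      t <- tss[j, ]
      if (t$chrom != p$chrom) next
      if (t$strand == "-") {
        ws <- t$tss - downstream; we <- t$tss + upstream
      } else {
        ws <- t$tss - upstream; we <- t$tss + downstream
      }
      # window covers bases ws..we inclusive; peak covers start..end-1
      if (p$start <= we && p$end - 1 >= ws) { hit <- TRUE; break }
    }
    if (hit) "promoter" else "distal"
  }, character(1))
}

# brute-force +/-window linkage oracle (window half-open on the right)
oracle_links <- function(peaks, tss, window = 25000) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    for (j in seq_len(nrow(tss))) {
      t <- tss[j, ]
      if (t$chrom != p$chrom) next
      ws <- t$tss - window; we <- t$tss + window - 1
      if (p$start <= we && p$end - 1 >= ws) {
        out[[length(out) + 1]] <- data.frame(peak = p$peak, gene = t$gene)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(peak = character(), gene = character()))
  }
  do.call(rbind, out)
}

# naive per-offset PWM rescoring oracle (both strands)
oracle_scan <- function(x, sequence, score_fraction = 0.8,
                        background = rep(0.25, 4)) {
  score_one <- function(mat, chars, off) {
    s <- 0
    for (j in seq_len(ncol(mat))) {
      b <- chars[off + j - 1]
      if (!b %in% c("A", "C", "G", "T")) return(NA_real_)
      s <- s + mat[b, j]
    }
    s
  }
  smat_f <- lpsclass:::pwm_score_mat(x, background)
  smat_r <- lpsclass:::pwm_score_mat(pwm_revcomp(x), background)
  thr <- score_fraction * sum(apply(smat_f, 2, max))
  chars <- strsplit(toupper(sequence), "")[[1]]
  w <- pwm_width(x)
  rows <- list()
  for (off in seq_len(length(chars) - w + 1)) {
    for (st in c("+", "-")) {
      sc <- score_one(if (st == "+") smat_f else smat_r, chars, off)
      if (!is.na(sc) && sc >= thr) {
        rows[[length(rows) + 1]] <- data.frame(offset = off, strand = st, score = sc)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(offset = integer(), strand = character(), score = double()))
  }
  do.call(rbind, rows)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  p <- mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
  p
}
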