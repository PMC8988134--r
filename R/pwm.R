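DNA <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences over A/C/G/T/N.
#' @return The reverse complement(s).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Position weight matrix
#'
#' A PWM is a 4 x W column-stochastic matrix of base probabilities (rows
#' A, C, G, T). Raw count or unnormalized matrices are regularized with a
#' small pseudocount and renormalized on construction.
#'
#' @param mat 4 x W numeric matrix (counts or probabilities), rows in
#'   A, C, G, T order.
#' @param id Motif identifier.
#' @param name Human-readable name (default `id`).
#' @param pseudocount Added to each cell before normalization
#'   (default 1e-4 of the column sum, at least 1e-8).
#' @return An object of class `pwm`.
#' @export
pwm <- function(mat, id, name = id, pseudocount = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4 || ncol(mat) < 1 || any(mat < 0)) {
    abort("`mat` must be a 4 x W matrix of non-negative values.")
  }
  rownames(mat) <- DNA
  cs <- colSums(mat)
  if (any(cs == 0)) abort("every PWM column needs positive mass.")
  if (is.null(pseudocount)) pseudocount <- pmax(1e-4 * cs, 1e-8)
  mat <- sweep(mat, 2, pseudocount, "+")
  mat <- sweep(mat, 2, colSums(mat), "/")
  structure(list(id = id, name = name, mat = mat), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$id, " (", x$name, "), width ", ncol(x$mat), "\n", sep = "")
  print(round(x$mat, 3))
  invisible(x)
}

#' @rdname pwm
#' @param width `pwm_width()` returns the number of columns.
#' @param x A `pwm`.
#' @export
pwm_width <- function(x) ncol(x$mat)

#' Reverse-complement a PWM
#'
#' Reverses the columns and swaps complementary base rows.
#'
#' @param x A [pwm()].
#' @return A `pwm` modelling the reverse-complement motif.
#' @export
pwm_revcomp <- function(x) {
  m <- x$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(x$mat))), drop = FALSE]
  rownames(m) <- DNA
  out <- x
  out$mat <- m
  out
}

#' Build a sharp PWM from a consensus sequence
#'
#' Each column gives probability `p` to the consensus base and splits the
#' remainder equally; `N` positions are uniform.
#'
#' @param consensus Consensus string over A/C/G/T/N.
#' @param id Motif id (default: the consensus).
#' @param p Probability of the consensus base (default 0.85).
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(consensus, id = consensus, p = 0.85) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  m <- vapply(bases, function(b) {
    if (b == "N") rep(0.25, 4)
    else {
      col <- rep((1 - p) / 3, 4)
      col[match(b, DNA)] <- p
      col
    }
  }, numeric(4))
  pwm(m, id = id, name = id)
}

#' Read a JASPAR-format PWM file
#'
#' Parses the raw-count JASPAR text format (`>ID NAME` header followed by
#' four `A [ ... ]` style rows).
#'
#' @param path File path.
#' @return A named list of [pwm()] objects (class `pwm_list`).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort("no JASPAR records found.")
  out <- list()
  for (i in seq_along(heads)) {
    hdr <- sub("^>", "", lines[heads[i]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else id
    rows <- lines[(heads[i] + 1):(heads[i] + 4)]
    vals <- lapply(rows, function(r) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(r))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1) {
      abort(paste0("ragged matrix for motif ", id, "."))
    }
    out[[id]] <- pwm(do.call(rbind, vals), id = id, name = name)
  }
  structure(out, class = "pwm_list")
}

#' Read a MEME minimal-format motif file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#'
#' @param path File path.
#' @return A named list of [pwm()] objects (class `pwm_list`).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) abort("no MEME motifs found.")
  out <- list()
  for (s in starts) {
    parts <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- parts[2]
    name <- if (length(parts) > 2) parts[3] else id
    hdr <- grep("letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    m <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                  numeric(4)))
    out[[id]] <- pwm(t(m), id = id, name = name)
  }
  structure(out, class = "pwm_list")
}

#' @export
print.pwm_list <- function(x, ...) {
  cat("<pwm_list> ", length(x), " motifs: ",
      paste(head(names(x), 8), collapse = ", "),
      if (length(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_pwm_list <- function(x) {
  if (inherits(x, "pwm")) x <- list(x)
  if (!inherits(x, "pwm_list")) {
    if (!all(vapply(x, inherits, logical(1), "pwm"))) {
      abort("`library` must be a pwm, a list of pwm, or a pwm_list.")
    }
    names(x) <- vapply(x, `[[`, character(1), "id")
    class(x) <- "pwm_list"
  }
  x
}

#' The packaged example motif library
#'
#' A small synthetic known-motif library shipped with the package: idealized
#' consensus-derived matrices for AP-1, ISRE/IRF, NF-kB, PU.1 (ETS) and
#' C/EBP plus unrelated decoy motifs. These are constructed stand-ins for a
#' curated database, adequate for planted-motif simulations and examples,
#' not for annotating real data.
#'
#' @return A `pwm_list`.
#' @export
example_motif_library <- function() {
  read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                          package = "lpsclass", mustWork = TRUE))
}
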