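#' Convert a tidy count table to a numeric matrix
#'
#' Throughout the package a count table is a data frame whose first column
#' holds feature identifiers (genes or peaks) and whose remaining columns hold
#' one sample each. This helper converts that layout to the matrix used
#' internally.
#'
#' @param counts A data frame: first column feature ids, other columns counts.
#' @return A numeric matrix with feature ids as rownames.
#' @export
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    return(counts)
  }
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort("`counts` must be a data frame with a feature-id column plus >=1 sample column.")
  }
  ids <- as.character(counts[[1]])
  if (anyDuplicated(ids)) abort("feature ids (first column of `counts`) must be unique.")
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("sample columns of `counts` must be numeric.")
  if (any(m < 0, na.rm = TRUE)) abort("counts must be non-negative.")
  rownames(m) <- ids
  m
}

check_design <- function(m, design) {
  if (!is.data.frame(design) || !all(c("sample", "condition") %in% names(design))) {
    abort("`design` must be a data frame with columns `sample` and `condition`.")
  }
  missing <- setdiff(colnames(m), design$sample)
  if (length(missing) > 0) {
    abort(paste0("samples absent from `design`: ", paste(missing, collapse = ", ")))
  }
  design[match(colnames(m), design$sample), , drop = FALSE]
}

# validate a probability-like scalar
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1) {
    abort(paste0("`", name, "` must be a probability in (0, 1]."))
  }
  x
}

geomean_pos <- function(x) exp(mean(log(x[x > 0])))

#' Roman class labels used by the response classification
#'
#' @return Character vector `c("I", ..., "X")`.
#' @export
class_levels <- function() c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
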