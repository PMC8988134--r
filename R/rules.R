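#' Decision thresholds for the ten-class response classification
#'
#' The classification assigns each eligible gene to one of two clusters and
#' ten classes from three pairwise contrasts:
#' A = LPS vs unstimulated, B = LPS+BETi vs unstimulated, and
#' C = LPS+BETi vs LPS. This object holds the tunable thresholds of the
#' decision table; the predicates themselves are documented in
#' [assign_classes()]. The exact per-class thresholds of the original study's
#' supplementary table are not reproduced here; this default table is
#' reconstructed from the prose class descriptions and is fully configurable.
#'
#' @param alpha_sig FDR cutoff declaring a contrast significant (default 0.05).
#' @param lfc_strong Strong log2-fold-change threshold (default 1).
#' @param lfc_minimal Half-width of the "minimal response" band on log2FC
#'   (default 0.25).
#' @param base_mean_min Minimum base mean for eligibility (default 10).
#' @return A `rule_table` object (list with the four thresholds).
#' @export
rule_table <- function(alpha_sig = 0.05, lfc_strong = 1,
                       lfc_minimal = 0.25, base_mean_min = 10) {
  check_prob(alpha_sig, "alpha_sig")
  if (lfc_strong <= 0 || lfc_minimal < 0 || base_mean_min < 0) {
    abort("thresholds must be positive (lfc_minimal, base_mean_min may be 0).")
  }
  structure(list(alpha_sig = alpha_sig, lfc_strong = lfc_strong,
                 lfc_minimal = lfc_minimal, base_mean_min = base_mean_min),
            class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  cat("<rule_table> alpha_sig=", x$alpha_sig, ", lfc_strong=", x$lfc_strong,
      ", lfc_minimal=", x$lfc_minimal, ", base_mean_min=", x$base_mean_min,
      "\n", sep = "")
  invisible(x)
}

#' @export
as.list.rule_table <- function(x, ...) unclass(x)

#' Evaluate the class decision table on true (noise-free) log2 fold changes
#'
#' Used to check that a planted fold-change profile would, in expectation, be
#' assigned the intended class: significance is idealized as
#' `|log2FC| > lfc_minimal`. Returns the class label the table assigns.
#'
#' @param lfc_a,lfc_b Expected log2 fold changes of contrasts A and B.
#' @param rules A [rule_table()].
#' @return A class label in `class_levels()`.
#' @export
expected_class <- function(lfc_a, lfc_b, rules = rule_table()) {
  sig_a <- abs(lfc_a) > rules$lfc_minimal
  sig_b <- abs(lfc_b) > rules$lfc_minimal
  classify_one(lfc_a, lfc_b, lfc_b - lfc_a, sig_a, sig_b, rules)
}

# The decision table proper. Predicates evaluated in a fixed order inside each
# cluster so that overlaps resolve deterministically (II before V before I;
# VI before VII before IX before VIII). C-tie (log2FC exactly 0) falls in
# cluster 2.
classify_one <- function(lfc_a, lfc_b, lfc_c, sig_a, sig_b, rules) {
  ls <- rules$lfc_strong
  dm <- rules$lfc_minimal
  if (lfc_c > 0) {  # cluster 1: relatively higher with BET inhibition
    if (sig_b && lfc_b > ls && sig_a && lfc_a < 0) return("II")
    if (sig_b && lfc_b > ls && abs(lfc_a) <= dm) return("V")
    if (sig_b && lfc_b > ls) return("I")
    if (lfc_a <= 0 && lfc_b <= 0 && sig_a && lfc_a < -ls) return("III")
    return("IV")
  } else {          # cluster 2: relatively lower with BET inhibition
    if (sig_a && lfc_a > ls && lfc_b > 0) return("VI")
    if (sig_a && lfc_a > 0 && sig_b && lfc_b < 0) return("VII")
    if (sig_a && lfc_a > 0 && !sig_b) return("IX")
    if (sig_a && lfc_a < 0) return("VIII")
    return("X")
  }
}

class_cluster <- function(class) ifelse(class %in% c("I", "II", "III", "IV", "V"), 1L, 2L)
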