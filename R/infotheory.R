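#' Shannon entropy of a discrete distribution (plug-in, bits)
#'
#' `H = -sum p log2 p` over the non-zero cells of a count vector, with
#' `p = count / N` and the convention `0 * log 0 = 0`. This is the
#' maximum-likelihood (plug-in) estimator; no small-sample bias correction
#' is applied.
#'
#' @param counts Non-negative counts; must not all be zero.
#' @return Entropy in bits, in `[0, log2(#nonzero cells)]`.
#' @export
shannon_entropy <- function(counts) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Mutual information of a joint contingency table (bits)
#'
#' `I(G; O) = H(G) + H(O) - H(G, O)` computed from the plug-in entropies of
#' the margins and the joint table. Non-negative, symmetric in the margins,
#' and bounded by `min(H(G), H(O))`.
#'
#' @param joint Matrix (or table) of non-negative joint counts; rows index
#'   one variable, columns the other.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  stopifnot(all(joint >= 0), sum(joint) > 0)
  h_row <- shannon_entropy(rowSums(joint))
  h_col <- shannon_entropy(colSums(joint))
  h_joint <- shannon_entropy(as.vector(joint))
  max(h_row + h_col - h_joint, 0)
}

#' Mutual-information fitness of a response table
#'
#' Computes `I(G; O_j)` between the labels and each oscillator's maxima
#' counts; the oscillator with the highest mutual information is selected
#' as the network output and its MI is the network fitness. Ties are broken
#' by the lowest oscillator index.
#'
#' @param table A response table from [respond_batch()] with columns `g` and
#'   `o1`, `o2`, ... .
#' @return An object of class `fitness_report`: list with `mi` (bits, per
#'   oscillator), `output` (selected oscillator index) and `fitness`
#'   (the maximum MI).
#' @export
network_fitness <- function(table) {
  stopifnot(nrow(table) >= 1L, "g" %in% names(table))
  ocols <- grep("^o[0-9]+$", names(table), value = TRUE)
  stopifnot(length(ocols) >= 1L)
  mi <- vapply(ocols, function(cn) {
    joint <- base::table(table$g, table[[cn]])
    mutual_information(joint)
  }, numeric(1))
  best <- which.max(mi)  # which.max returns the first maximum: lowest index
  structure(list(mi = mi, output = as.integer(sub("^o", "", ocols[best])),
                 fitness = unname(mi[best])),
            class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat("<fitness_report> fitness =", format(x$fitness, digits = 4),
      "bits at oscillator", x$output, "\n")
  cat("  per-oscillator MI:",
      paste(sprintf("%s=%.4f", names(x$mi), x$mi), collapse = " "), "\n")
  invisible(x)
}
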