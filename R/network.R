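#' Symmetrize a PAE matrix
#'
#' PAE matrices are asymmetric: aligning on residue j gives a different
#' error for residue i than the converse. The edge-weight transform needs a
#' single value per residue pair, so the two directions are averaged.
#'
#' @param pae A [pae_matrix].
#' @return A [pae_matrix] with `values[i, j] == values[j, i]` exactly.
#' @export
symmetrize_pae <- function(pae) {
  stopifnot(inherits(pae, "pae_matrix"))
  pae$values <- (pae$values + t(pae$values)) / 2
  pae
}

#' Logistic contrast transform of PAE values into edge weights
#'
#' Maps a PAE value (Angstrom) to an edge weight in (0, 1) via
#' `w = 1 / (1 + exp(pae - threshold))`. The contrast threshold is the
#' midpoint of the transform and acts as a soft cut-off: pairs with PAE well
#' below it get weights near 1 (confident relative placement), pairs well
#' above it get weights near 0. The transform is strictly decreasing in the
#' PAE value and computed in a branch-stable form, so very large PAE values
#' underflow towards 0 rather than producing NaN.
#'
#' @param pae_value Numeric vector of PAE values (Angstrom), each >= 0.
#' @param threshold Contrast threshold in Angstrom (finite). Default 2,
#'   the recommended starting point; values between 0 and 4 are the usual
#'   exploration range.
#' @return Edge weights in (0, 1), same shape as `pae_value`.
#' @examples
#' logistic_weight(2, threshold = 2) # exactly 0.5
#' logistic_weight(0, threshold = 2) # ~0.881
#' @export
logistic_weight <- function(pae_value, threshold = 2) {
  if (!is.numeric(pae_value) || any(pae_value < 0)) {
    stop_domain("`pae_value` must be numeric and non-negative")
  }
  if (!is_scalar_number(threshold)) stop_config("`threshold` must be a single finite number")
  # plogis(q) = 1/(1 + exp(-q)); with q = threshold - pae this is the
  # logistic transform in its numerically stable form.
  stats::plogis(threshold - pae_value)
}

#' Build the weighted residue graph from a PAE matrix
#'
#' Constructs the fully connected residue network: nodes are residues,
#' and the weight of edge (i, j) is the logistic contrast transform of the
#' symmetrized PAE between i and j. Self-loops are excluded (diagonal 0).
#'
#' @param pae A [pae_matrix].
#' @param threshold Contrast threshold in Angstrom; see [logistic_weight()].
#' @param prune_below Optional efficiency knob: edges with weight strictly
#'   below this value are dropped from the graph. Default 0 (keep the graph
#'   fully connected, as the method specifies).
#' @return An object of class `residue_graph` with fields `n`, `weights`
#'   (symmetric n-by-n matrix, zero diagonal), `pae_sym` (the symmetrized
#'   PAE, kept for downstream disorder filtering), `threshold`.
#' @export
build_residue_graph <- function(pae, threshold = 2, prune_below = 0) {
  stopifnot(inherits(pae, "pae_matrix"))
  if (pae$n < 2L) stop_shape("need at least 2 residues to build a graph")
  sym <- symmetrize_pae(pae)
  w <- logistic_weight(sym$values, threshold)
  diag(w) <- 0
  if (prune_below > 0) w[w < prune_below] <- 0
  structure(
    list(n = pae$n, weights = w, pae_sym = sym$values, threshold = threshold),
    class = "residue_graph"
  )
}

#' @export
print.residue_graph <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf(
    "<residue_graph> %d residues, %d edges, threshold %g Angstrom\n",
    x$n, sum(off > 0), x$threshold
  ))
  cat(sprintf("  weight range: %.3g - %.3g\n", min(off), max(off)))
  invisible(x)
}

# igraph view of the weight matrix; zero-weight entries are simply absent
# edges, which is equivalent for every quality function used here.
graph_as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
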