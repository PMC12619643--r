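#' Intersection over Union of two domains
#'
#' Both domains must be expressed over the same residue numbering; each is
#' given as a vector of residue identifiers (indices or author labels).
#'
#' @param a,b Vectors of residue identifiers.
#' @return `|a intersect b| / |a union b|`, in `[0, 1]`.
#' @examples
#' domain_iou(1:100, 51:150) # 50 / 150
#' @export
domain_iou <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Residue identifier sets per domain, in domain order.
domain_sets <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  res <- seg$residues
  keep <- !is.na(res$domain)
  id <- if (seg$multi_chain) paste0(res$chain, ":", res$label) else res$label
  split(id[keep], res$domain[keep])
}

#' Score a predicted segmentation against a reference
#'
#' Matches predicted to reference domains one-to-one so that the summed
#' Intersection over Union is maximal (optimal assignment on the bipartite
#' IoU graph), then averages over `max(n_pred, n_ref)` so that unmatched
#' domains on either side count as zero -- over- and under-segmentation are
#' penalized symmetrically. Unassigned residues take part in no
#' intersection or union.
#'
#' @param pred,ref `segmentation` objects over the same residue numbering.
#' @return An object of class `iou_report`: list with `per_pair` (tibble of
#'   matched pairs and their IoU), `mean_iou`, `n_pred`, `n_ref`.
#' @export
score_segmentation <- function(pred, ref) {
  sets_p <- domain_sets(pred)
  sets_r <- domain_sets(ref)
  np <- length(sets_p)
  nr <- length(sets_r)
  empty <- tibble(pred_domain = integer(), ref_domain = integer(), iou = numeric())
  if (np == 0L && nr == 0L) {
    return(new_iou_report(empty, 1, 0L, 0L))
  }
  if (np == 0L || nr == 0L) {
    return(new_iou_report(empty, 0, np, nr))
  }
  iou <- matrix(0, np, nr)
  for (i in seq_len(np)) {
    for (j in seq_len(nr)) iou[i, j] <- domain_iou(sets_p[[i]], sets_r[[j]])
  }
  pairs <- optimal_assignment(iou)
  per_pair <- tibble(
    pred_domain = pairs[, 1], ref_domain = pairs[, 2],
    iou = iou[pairs]
  )
  new_iou_report(per_pair, sum(per_pair$iou) / max(np, nr), np, nr)
}

new_iou_report <- function(per_pair, mean_iou, n_pred, n_ref) {
  structure(
    list(per_pair = per_pair, mean_iou = mean_iou,
         n_pred = as.integer(n_pred), n_ref = as.integer(n_ref)),
    class = "iou_report"
  )
}

# Maximum-weight one-to-one assignment on a non-negative score matrix,
# via igraph's weighted bipartite matching. Zero-score pairs are never
# matched (they contribute nothing).
optimal_assignment <- function(score) {
  np <- nrow(score)
  nr <- ncol(score)
  idx <- which(score > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(cbind(integer(), integer()))
  g <- igraph::make_empty_graph(n = np + nr, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, np), rep(TRUE, nr))
  g <- igraph::add_edges(g, rbind(idx[, 1], np + idx[, 2]))
  igraph::E(g)$weight <- score[idx]
  m <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                   weights = igraph::E(g)$weight)
  mate <- m$matching[seq_len(np)]
  matched <- which(!is.na(mate))
  cbind(pred = matched, ref = as.integer(mate[matched]) - np)
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf(
    "<iou_report> mean IoU %.4f (%d predicted vs %d reference domains)\n",
    x$mean_iou, x$n_pred, x$n_ref
  ))
  if (nrow(x$per_pair)) print(x$per_pair)
  invisible(x)
}

#' @describeIn score_segmentation matched domain pairs and their IoU.
#' @param x An `iou_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.iou_report <- function(x, ...) x$per_pair

#' @describeIn score_segmentation one-row summary.
#' @exportS3Method generics::glance
glance.iou_report <- function(x, ...) {
  tibble(
    mean_iou = x$mean_iou, n_pred = x$n_pred, n_ref = x$n_ref,
    n_matched = nrow(x$per_pair)
  )
}
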