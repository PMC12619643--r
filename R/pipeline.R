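#' Segment a protein into domains from its PAE matrix
#'
#' The full pipeline in one call: symmetrize the PAE matrix, apply the
#' logistic contrast transform to obtain the weighted residue network,
#' partition it with Leiden clustering, and map clusters back to (possibly
#' discontinuous) residue intervals with small-cluster and disorder
#' filtering. Defaults are the recommended starting parameters: contrast
#' threshold 2 Angstrom and resolution 0.7.
#'
#' @param pae A [pae_matrix] (or anything [read_pae()] accepts).
#' @param residues Optional residue tibble from [read_structure()]; adds
#'   author numbering, chain ids, and pLDDT to the output.
#' @inheritParams build_residue_graph
#' @inheritParams cluster_residues
#' @inheritParams segment_clusters
#' @return A `segmentation`; its `params` record every parameter used plus
#'   the cluster count and quality.
#' @examples
#' fx <- generate_planted(planted_spec(c(30, 30), seed = 1))
#' seg <- segment_domains(fx$pae)
#' chopping_string(seg)
#' @export
segment_domains <- function(pae, residues = NULL, threshold = 2,
                            resolution = 0.7, objective = "modularity",
                            n_iterations = 10, seed = 0, min_size = 10,
                            disorder_pae = 15, prune_below = 0) {
  if (!inherits(pae, "pae_matrix")) pae <- read_pae(pae)
  if (!is.null(residues)) residues <- reconcile_residues(pae, residues)
  graph <- build_residue_graph(pae, threshold = threshold, prune_below = prune_below)
  partition <- cluster_residues(graph, resolution = resolution,
                                objective = objective,
                                n_iterations = n_iterations, seed = seed)
  segment_clusters(partition, graph = graph, residues = residues,
                   min_size = min_size, disorder_pae = disorder_pae)
}

#' Segment at several resolutions
#'
#' Runs the pipeline once per resolution (same seed, same graph) and
#' returns one row per resolution with the resulting segmentation, its
#' domain count, and chopping string. This is the multi-solution mode:
#' comparing rows shows how the protein decomposes at coarser and finer
#' granularity.
#'
#' @inheritParams segment_domains
#' @param resolutions Non-empty vector of positive resolutions.
#' @return A tibble with columns `resolution`, `k` (cluster count before
#'   filtering), `n_domains`, `quality`, `chopping`, `segmentation`
#'   (list-column).
#' @export
sweep_domains <- function(pae, resolutions, residues = NULL, threshold = 2,
                          objective = "modularity", n_iterations = 10,
                          seed = 0, min_size = 10, disorder_pae = 15,
                          prune_below = 0) {
  if (!inherits(pae, "pae_matrix")) pae <- read_pae(pae)
  if (!is.null(residues)) residues <- reconcile_residues(pae, residues)
  graph <- build_residue_graph(pae, threshold = threshold, prune_below = prune_below)
  sweep <- sweep_resolutions(graph, resolutions, objective = objective,
                             n_iterations = n_iterations, seed = seed)
  segs <- purrr::map(sweep$partition, function(p) {
    segment_clusters(p, graph = graph, residues = residues,
                     min_size = min_size, disorder_pae = disorder_pae)
  })
  sweep |>
    dplyr::mutate(
      n_domains = purrr::map_int(segs, ~ nrow(.x$domains)),
      chopping = purrr::map_chr(segs, chopping_string),
      segmentation = segs
    ) |>
    dplyr::select("resolution", "k", "n_domains", "quality", "chopping",
                  "segmentation")
}
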