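#' Plot a PAE matrix, optionally with domain boundaries
#'
#' Heatmap of the PAE matrix in the AlphaFold DB orientation: residue 1 at
#' the top-left, scored residue on the x axis, colour running from dark
#' green (PAE 0, confident) to white (the declared maximum). When a
#' segmentation is supplied, domain boundaries are drawn as lines on both
#' axes.
#'
#' @param object A [pae_matrix].
#' @param segmentation Optional `segmentation` whose boundaries to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pae_matrix <- function(object, segmentation = NULL, ...) {
  n <- object$n
  df <- tibble(
    scored = rep(seq_len(n), each = n),
    aligned = rep(seq_len(n), times = n),
    pae = as.vector(object$values)
  )
  lim <- c(0, object$max_pae %||% max(object$values))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scored, y = .data$aligned,
                                        fill = .data$pae)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_gradient(low = "#0f6d3f", high = "white",
                                 limits = lim, name = "PAE (Å)") +
    ggplot2::labs(x = "Scored residue", y = "Aligned residue") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(segmentation)) {
    b <- domain_boundaries(segmentation)
    if (length(b)) {
      p <- p +
        ggplot2::geom_vline(xintercept = b + 0.5, linewidth = 0.3) +
        ggplot2::geom_hline(yintercept = b + 0.5, linewidth = 0.3)
    }
  }
  p
}

# Residue positions after which the domain assignment changes (unassigned
# counts as a change); for k continuous domains this is the k-1 internal
# boundaries.
domain_boundaries <- function(seg) {
  d <- seg$residues$domain
  key <- ifelse(is.na(d), -1L, d)
  which(diff(key) != 0L)
}

#' @rdname autoplot.pae_matrix
#' @param pae A [pae_matrix].
#' @export
plot_pae <- function(pae, segmentation = NULL) {
  autoplot.pae_matrix(pae, segmentation = segmentation)
}
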