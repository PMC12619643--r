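#' Specification for a synthetic PAE matrix with planted domains
#'
#' Describes the block structure of a simulated Predicted Aligned Error
#' matrix: residue pairs inside a planted domain draw low PAE values,
#' pairs across domains draw high ones, and optional disordered linker
#' stretches draw high PAE against everything (the high-PAE band pattern
#' that disordered segments produce in real PAE plots). A small
#' independent jitter makes the matrix asymmetric, as real PAE matrices
#' are. Values are capped at 31.75 Angstrom, the maximum AlphaFold DB
#' declares.
#'
#' @param domain_lengths Positive integer vector of planted domain sizes.
#' @param intra_range Range (Angstrom) for intra-domain PAE draws;
#'   default `c(1, 4)`, the confident regime.
#' @param inter_range Range for inter-domain (and linker) draws; default
#'   `c(22, 30)`, the no-confident-placement regime. Must lie strictly
#'   above `intra_range` so the planted structure is separable.
#' @param linker_positions List of `c(start, length)` pairs marking
#'   disordered stretches (residue positions, 1-based); their rows and
#'   columns draw from `inter_range` regardless of block. Must not
#'   overlap each other.
#' @param asymmetry_jitter Maximum Angstrom of independent noise added to
#'   (i, j) versus (j, i); default 1.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `planted_spec`.
#' @export
planted_spec <- function(domain_lengths, intra_range = c(1, 4),
                         inter_range = c(22, 30), linker_positions = list(),
                         asymmetry_jitter = 1, seed = 0) {
  if (length(domain_lengths) == 0L || any(domain_lengths < 1)) {
    stop_generate("`domain_lengths` must be positive integers")
  }
  check_range <- function(r, name) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] > PAE_CAP) {
      stop_generate(sprintf("`%s` must be an increasing range within [0, %g]",
                            name, PAE_CAP))
    }
  }
  check_range(intra_range, "intra_range")
  check_range(inter_range, "inter_range")
  if (intra_range[2] >= inter_range[1]) {
    stop_generate("intra_range must lie strictly below inter_range (separability)")
  }
  n <- sum(domain_lengths)
  if (length(linker_positions)) {
    spans <- lapply(linker_positions, function(lp) {
      if (length(lp) != 2L || lp[1] < 1 || lp[2] < 1 || lp[1] + lp[2] - 1 > n) {
        stop_generate("each linker must be c(start, length) within the protein")
      }
      seq.int(lp[1], lp[1] + lp[2] - 1)
    })
    if (anyDuplicated(unlist(spans))) stop_generate("linkers must not overlap")
  }
  structure(
    list(
      domain_lengths = as.integer(domain_lengths),
      intra_range = as.numeric(intra_range),
      inter_range = as.numeric(inter_range),
      linker_positions = linker_positions,
      asymmetry_jitter = as.numeric(asymmetry_jitter),
      seed = as.integer(seed)
    ),
    class = "planted_spec"
  )
}

PAE_CAP <- 31.75

#' Generate a synthetic PAE matrix with planted domain structure
#'
#' Draws a PAE matrix according to a [planted_spec()] and returns it with
#' the ground-truth segmentation: each planted block is one domain
#' (discontinuous if a linker interrupts it) and linker residues are
#' unassigned.
#'
#' @param spec A [planted_spec()].
#' @return A list with elements `pae` (a [pae_matrix], `max_pae` 31.75),
#'   `truth` (a `segmentation`), and `spec`.
#' @examples
#' fx <- generate_planted(planted_spec(c(30, 40), seed = 1))
#' fx$truth
#' @export
generate_planted <- function(spec) {
  generate_core(spec, sub_split = NULL, mid_range = NULL)
}

#' Generate a two-level (hierarchical) planted PAE matrix
#'
#' Splits each planted domain into sub-blocks whose cross-sub-block PAE
#' draws from `mid_range`, intermediate between the intra- and inter-domain
#' regimes. Clustering at low resolution then recovers the coarse domains
#' and at high resolution the fine sub-blocks -- the multi-solution
#' behaviour that makes the resolution parameter useful.
#'
#' @param spec A [planted_spec()].
#' @param sub_split Fractions each domain is split into (default
#'   `c(0.5, 0.5)`); either one numeric vector applied to every domain or a
#'   list with one vector per domain. Each vector must sum to 1. Use `1`
#'   for no split.
#' @param mid_range PAE range (Angstrom) for pairs across sub-blocks of the
#'   same domain; must lie strictly between `intra_range` and
#'   `inter_range`. Default `c(4.5, 6.5)`, a moderate-confidence regime
#'   whose logistic weights at the default threshold are small but
#'   non-negligible, placing the coarse-to-fine transition inside the
#'   usual resolution exploration range.
#' @return A list with `pae`, `truth_coarse`, `truth_fine`, and `spec`.
#' @export
generate_hierarchical <- function(spec, sub_split = c(0.5, 0.5),
                                  mid_range = c(4.5, 6.5)) {
  if (!is.list(sub_split)) sub_split <- rep(list(sub_split), length(spec$domain_lengths))
  if (length(sub_split) != length(spec$domain_lengths)) {
    stop_generate("`sub_split` must give one fraction vector per domain")
  }
  trivial <- all(vapply(sub_split, length, integer(1)) == 1L)
  if (!trivial) {
    if (length(mid_range) != 2L || mid_range[1] > mid_range[2]) {
      stop_generate("`mid_range` must be an increasing range")
    }
    if (mid_range[1] <= spec$intra_range[2] || mid_range[2] >= spec$inter_range[1]) {
      stop_generate("`mid_range` must lie strictly between intra_range and inter_range")
    }
  }
  for (f in sub_split) {
    if (any(f <= 0) || abs(sum(f) - 1) > 1e-8) {
      stop_generate("each `sub_split` vector must be positive fractions summing to 1")
    }
  }
  generate_core(spec, sub_split = sub_split, mid_range = mid_range)
}

# Shared generator. Draw order is fixed (inter background, intra blocks,
# mid-range sub-block pairs, linker bands, jitter) so that a trivial
# sub_split consumes the same random number stream as generate_planted().
generate_core <- function(spec, sub_split, mid_range) {
  stopifnot(inherits(spec, "planted_spec"))
  n <- sum(spec$domain_lengths)
  coarse <- rep(seq_along(spec$domain_lengths), spec$domain_lengths)
  fine <- coarse
  if (!is.null(sub_split)) {
    fine <- integer(n)
    nxt <- 1L
    pos <- 0L
    for (d in seq_along(spec$domain_lengths)) {
      len <- spec$domain_lengths[d]
      cuts <- round(cumsum(sub_split[[d]]) * len)
      cuts[length(cuts)] <- len
      sizes <- diff(c(0L, cuts))
      if (any(sizes < 1)) stop_generate("sub_split produces an empty sub-block")
      fine[pos + seq_len(len)] <- rep(nxt + seq_along(sizes) - 1L, sizes)
      nxt <- nxt + length(sizes)
      pos <- pos + len
    }
  }
  withr::with_seed(spec$seed, {
    s <- matrix(0, n, n)
    ut <- upper.tri(s)
    m <- sum(ut)
    s[ut] <- runif(m, spec$inter_range[1], spec$inter_range[2])
    same_coarse <- outer(coarse, coarse, "==") & ut
    s[same_coarse] <- runif(sum(same_coarse), spec$intra_range[1], spec$intra_range[2])
    if (!is.null(sub_split)) {
      mid <- same_coarse & outer(fine, fine, "!=")
      if (any(mid)) s[mid] <- runif(sum(mid), mid_range[1], mid_range[2])
    }
    linker_res <- integer()
    for (lp in spec$linker_positions) {
      span <- seq.int(lp[1], lp[1] + lp[2] - 1)
      linker_res <- c(linker_res, span)
      band <- ut & (row(s) %in% span | col(s) %in% span)
      s[band] <- runif(sum(band), spec$inter_range[1], spec$inter_range[2])
    }
    s <- s + t(s) - diag(diag(s))
    values <- s
    if (spec$asymmetry_jitter > 0) {
      jit <- matrix(runif(n * n, 0, spec$asymmetry_jitter), n, n)
      diag(jit) <- 0
      values <- values + jit
    }
    values <- pmin(values, PAE_CAP)
    diag(values) <- 0
    pae <- pae_matrix(values, dialect = "afdb", max_pae = PAE_CAP)

    truth_labels <- function(block) {
      lab <- block
      lab[linker_res] <- NA_integer_
      segmentation_from_labels(lab, params = list(source = "planted_truth"))
    }
    if (is.null(sub_split)) {
      list(pae = pae, truth = truth_labels(coarse), spec = spec)
    } else {
      list(pae = pae, truth_coarse = truth_labels(coarse),
           truth_fine = truth_labels(fine), spec = spec)
    }
  })
}
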