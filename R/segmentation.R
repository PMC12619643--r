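#' Segmentation objects
#'
#' A `segmentation` is an ordered set of domains over the residues of one
#' protein (or multimer). Each domain is a set of 1-based inclusive residue
#' intervals; discontinuous domains (multiple intervals) are allowed.
#' Residues in no domain are unassigned, the convention for flexible
#' linkers and low-confidence regions.
#'
#' @name segmentation
#' @keywords internal
NULL

# Build a segmentation from a per-residue domain vector (NA = unassigned).
# Domains are renumbered 1..d in order of first residue. `residues` supplies
# author numbering/chains; when absent residues are numbered 1..n.
segmentation_from_labels <- function(labels, residues = NULL, params = list()) {
  n <- length(labels)
  if (is.null(residues)) residues <- default_residues(n)
  if (nrow(residues) != n) {
    stop_reconcile(sprintf(
      "labels describe %d residues but the residue table has %d", n, nrow(residues)
    ))
  }
  labels <- as.integer(labels)
  assigned <- which(!is.na(labels))
  domain <- rep(NA_integer_, n)
  if (length(assigned)) {
    domain[assigned] <- match(labels[assigned], unique(labels[assigned]))
  }
  res <- residues
  res$domain <- domain
  obj <- structure(
    list(
      residues = res,
      domains = NULL,
      n = n,
      multi_chain = length(unique(res$chain)) > 1L,
      params = params
    ),
    class = "segmentation"
  )
  obj$domains <- domain_table(obj)
  obj
}

# Maximal runs of consecutive residues (file order) sharing a domain.
segment_runs <- function(seg) {
  res <- seg$residues
  d <- res$domain
  if (all(is.na(d))) {
    return(tibble(domain = integer(), chain = character(),
                  start_label = character(), end_label = character(),
                  start_index = integer(), end_index = integer()))
  }
  # A run breaks when the domain id changes (NA counts as a change) or the
  # chain changes.
  key <- paste(ifelse(is.na(d), "NA", d), res$chain)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(d[starts])
  tibble(
    domain = d[starts[keep]],
    chain = res$chain[starts[keep]],
    start_label = res$label[starts[keep]],
    end_label = res$label[ends[keep]],
    start_index = starts[keep],
    end_index = ends[keep]
  )
}

domain_table <- function(seg) {
  runs <- segment_runs(seg)
  if (nrow(runs) == 0L) {
    return(tibble(domain = integer(), n_segments = integer(),
                  n_residues = integer(), chopping = character()))
  }
  runs |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      n_residues = sum(.data$end_index - .data$start_index + 1L),
      chopping = paste(
        paste0(
          if (seg$multi_chain) paste0(.data$chain, ":") else "",
          .data$start_label, "-", .data$end_label
        ),
        collapse = "_"
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$domain)
}

#' Map a residue clustering to a domain segmentation
#'
#' Converts cluster labels into domains: maximal runs of consecutive
#' residues sharing a cluster become segments, and all segments of one
#' cluster form one (possibly discontinuous) domain. Two filters decide
#' which residues end up unassigned:
#' \itemize{
#'   \item \emph{Disorder filter}: a residue whose mean symmetrized PAE to
#'     the rest of its cluster exceeds `disorder_pae` has no confident
#'     placement relative to its own cluster (the grey-residue situation of
#'     disordered linkers) and is unassigned. Requires `graph`; disabled
#'     with `disorder_pae = Inf`.
#'   \item \emph{Size filter}: clusters retaining fewer than `min_size`
#'     residues are unassigned wholesale; fragments that small are not
#'     structurally meaningful domains.
#' }
#' Remaining domains are renumbered in order of their first residue.
#'
#' @param partition A [cluster_residues()] result.
#' @param graph The [build_residue_graph()] the partition was computed on
#'   (needed for the disorder filter; optional otherwise).
#' @param residues Optional residue tibble from [read_structure()]; when
#'   supplied, output uses author residue numbering and chain ids.
#' @param min_size Minimum residues per reported domain (default 10).
#' @param disorder_pae Mean intra-cluster PAE (Angstrom) above which a
#'   residue is considered unplaceable and unassigned (default 15).
#' @return A `segmentation` object.
#' @export
segment_clusters <- function(partition, graph = NULL, residues = NULL,
                             min_size = 10, disorder_pae = 15) {
  stopifnot(inherits(partition, "residue_partition"))
  if (min_size < 1) stop_config("`min_size` must be >= 1")
  labels <- partition$labels
  n <- length(labels)
  if (!is.null(residues)) {
    if (nrow(residues) != n) {
      stop_reconcile(sprintf(
        "partition covers %d residues but the structure has %d", n, nrow(residues)
      ))
    }
  }
  keep <- rep(TRUE, n)
  if (!is.null(graph) && is.finite(disorder_pae)) {
    stopifnot(inherits(graph, "residue_graph"), graph$n == n)
    p <- graph$pae_sym
    for (idx in split(seq_len(n), labels)) {
      if (length(idx) < 2L) next
      mean_pae <- rowSums(p[idx, idx, drop = FALSE]) / (length(idx) - 1L)
      keep[idx[mean_pae > disorder_pae]] <- FALSE
    }
  }
  filtered <- ifelse(keep, labels, NA_integer_)
  sizes <- table(filtered)
  small <- as.integer(names(sizes)[sizes < min_size])
  filtered[filtered %in% small] <- NA_integer_
  segmentation_from_labels(
    filtered, residues,
    params = list(
      resolution = partition$resolution, objective = partition$objective,
      n_iterations = partition$n_iterations, seed = partition$seed,
      k_clusters = partition$k, quality = partition$quality,
      threshold = if (!is.null(graph)) graph$threshold else NA_real_,
      min_size = min_size, disorder_pae = disorder_pae
    )
  )
}

#' @export
print.segmentation <- function(x, ...) {
  nd <- nrow(x$domains)
  cat(sprintf(
    "<segmentation> %d residues, %d domain%s, %d unassigned\n",
    x$n, nd, if (nd == 1) "" else "s", sum(is.na(x$residues$domain))
  ))
  if (nd > 0) {
    for (i in seq_len(nd)) {
      cat(sprintf("  domain %d: %s (%d residues)\n",
                  x$domains$domain[i], x$domains$chopping[i],
                  x$domains$n_residues[i]))
    }
  }
  invisible(x)
}

#' @describeIn segment_clusters per-domain tibble (`domain`, `n_segments`,
#'   `n_residues`, `chopping`).
#' @param x A `segmentation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.segmentation <- function(x, ...) x$domains

#' @describeIn segment_clusters per-residue tibble with the `domain`
#'   assignment column (NA = unassigned).
#' @exportS3Method generics::augment
augment.segmentation <- function(x, ...) x$residues

#' @describeIn segment_clusters one-row summary.
#' @exportS3Method generics::glance
glance.segmentation <- function(x, ...) {
  tibble(
    n_residues = x$n,
    n_domains = nrow(x$domains),
    n_unassigned = sum(is.na(x$residues$domain)),
    resolution = x$params$resolution %||% NA_real_,
    threshold = x$params$threshold %||% NA_real_,
    objective = x$params$objective %||% NA_character_,
    quality = x$params$quality %||% NA_real_
  )
}

#' Serialize a segmentation as a chopping string
#'
#' The canonical CATH-style text form: domains joined by `","`, segments of
#' a discontinuous domain joined by `"_"`, each segment `"start-end"` in
#' author residue numbering (with insertion codes attached, e.g. `"52A"`).
#' A `"chain:"` prefix is emitted only for multi-chain inputs. An
#' all-unassigned segmentation serializes to `""`.
#'
#' @param seg A `segmentation`.
#' @return A single string.
#' @examples
#' seg <- parse_chopping("1-3_6-7,4-5")
#' chopping_string(seg)
#' @export
chopping_string <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  if (nrow(seg$domains) == 0L) return("")
  paste(seg$domains$chopping, collapse = ",")
}

#' Parse a chopping string into a segmentation
#'
#' Inverse of [chopping_string()] on canonical strings. Without a residue
#' table, ranges are expanded arithmetically over plain residue numbers;
#' with one, range endpoints are looked up as author labels (insertion
#' codes allowed) and expanded by file order.
#'
#' @param text A chopping string, e.g. `"1-3_6-7,4-5"`.
#' @param residues Optional residue tibble from [read_structure()].
#' @param n Total residue count when known (used to size the unassigned
#'   remainder); defaults to the largest residue seen.
#' @return A `segmentation`.
#' @export
parse_chopping <- function(text, residues = NULL, n = NULL) {
  if (length(text) != 1L || !is.character(text)) {
    stop_parse("`text` must be a single chopping string")
  }
  text <- trimws(text)
  if (!is.null(residues)) {
    return(parse_chopping_with_table(text, residues))
  }
  doms <- if (nzchar(text)) strsplit(text, ",", fixed = TRUE)[[1]] else character()
  parsed <- lapply(doms, function(dom) {
    segs <- strsplit(dom, "_", fixed = TRUE)[[1]]
    out <- lapply(segs, function(tok) {
      tok2 <- sub("^[^:]*:", "", tok)
      m <- regmatches(tok2, regexec("^([0-9]+)-([0-9]+)$", tok2))[[1]]
      if (length(m) != 3L) {
        stop_parse(sprintf("malformed chopping segment '%s'", tok))
      }
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (a > b) {
        stop_parse(sprintf("chopping segment '%s' has start > end", tok))
      }
      seq.int(a, b)
    })
    unlist(out)
  })
  all_res <- unlist(parsed)
  if (anyDuplicated(all_res)) {
    stop_parse(sprintf(
      "residue %d appears in more than one domain", all_res[duplicated(all_res)][1]
    ))
  }
  n <- n %||% if (length(all_res)) max(all_res) else 0L
  labels <- rep(NA_integer_, n)
  for (d in seq_along(parsed)) labels[parsed[[d]]] <- d
  segmentation_from_labels(labels, params = list(source = "chopping"))
}

parse_chopping_with_table <- function(text, residues) {
  n <- nrow(residues)
  labels <- rep(NA_integer_, n)
  doms <- if (nzchar(text)) strsplit(text, ",", fixed = TRUE)[[1]] else character()
  for (d in seq_along(doms)) {
    segs <- strsplit(doms[d], "_", fixed = TRUE)[[1]]
    for (tok in segs) {
      has_chain <- grepl(":", tok, fixed = TRUE)
      chain <- if (has_chain) sub(":.*$", "", tok) else NULL
      tok2 <- sub("^[^:]*:", "", tok)
      m <- regmatches(tok2, regexec("^([0-9]+[A-Za-z]*)-([0-9]+[A-Za-z]*)$", tok2))[[1]]
      if (length(m) != 3L) stop_parse(sprintf("malformed chopping segment '%s'", tok))
      pool <- if (is.null(chain)) seq_len(n) else which(residues$chain == chain)
      i1 <- pool[match(m[2], residues$label[pool])]
      i2 <- pool[match(m[3], residues$label[pool])]
      if (is.na(i1) || is.na(i2)) {
        stop_parse(sprintf("chopping segment '%s' names residues absent from the structure", tok))
      }
      if (i1 > i2) stop_parse(sprintf("chopping segment '%s' has start > end", tok))
      span <- seq.int(i1, i2)
      if (any(!is.na(labels[span]))) {
        stop_parse(sprintf("chopping segment '%s' overlaps another domain", tok))
      }
      labels[span] <- d
    }
  }
  segmentation_from_labels(labels, residues, params = list(source = "chopping"))
}

#' Write a structure annotated with domain assignments
#'
#' Copies the structure with every atom's B-factor replaced by its
#' residue's domain index (unassigned residues get -1), so any molecular
#' viewer can colour the segmentation. Output is always PDB format.
#'
#' @param structure_path Input PDB or mmCIF file; residue count must match
#'   the segmentation.
#' @param seg A `segmentation`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
annotate_structure <- function(structure_path, seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  format <- if (grepl("\\.(cif|mmcif)$", structure_path, ignore.case = TRUE)) "cif" else "pdb"
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(structure_path) else bio3d::read.pdb(structure_path)
    ),
    error = function(e) stop_format(sprintf(
      "could not read '%s': %s", structure_path, conditionMessage(e)
    ))
  )
  atoms <- parsed$atom
  poly <- atoms$type == "ATOM"
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  key <- paste(atoms$chain, atoms$resno, ins, sep = "\r")
  res_index <- rep(NA_integer_, nrow(atoms))
  res_index[poly] <- match(key[poly], unique(key[poly]))
  n_struct <- max(res_index, na.rm = TRUE)
  if (n_struct != seg$n) {
    stop_reconcile(sprintf(
      "structure has %d residues but the segmentation covers %d", n_struct, seg$n
    ))
  }
  dom <- seg$residues$domain
  b <- rep(-1, nrow(atoms))
  b[poly] <- ifelse(is.na(dom[res_index[poly]]), -1, dom[res_index[poly]])
  parsed$atom$b <- b
  bio3d::write.pdb(parsed, file = path, b = b)
  invisible(path)
}

#' Write per-domain and per-residue tables
#'
#' `write_domains_tsv()` writes one row per domain with columns
#' `domain_index`, `n_segments`, `chopping`, `n_residues`.
#' `write_residues_csv()` writes one row per residue with columns
#' `residue`, `chain`, `author_number`, `plddt`, `domain`.
#'
#' @param seg A `segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domains_tsv <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  out <- seg$domains |>
    dplyr::transmute(
      domain_index = .data$domain,
      n_segments = .data$n_segments,
      chopping = .data$chopping,
      n_residues = .data$n_residues
    )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_domains_tsv
#' @export
write_residues_csv <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  out <- seg$residues |>
    dplyr::transmute(
      residue = .data$index,
      chain = .data$chain,
      author_number = .data$label,
      plddt = .data$plddt,
      domain = .data$domain
    )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
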