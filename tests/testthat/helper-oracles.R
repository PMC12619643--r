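# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (brute force, double loops) so it
# cannot share a bug with the implementation it checks.

# All set partitions of n items as canonical label vectors (restricted
# growth strings). Bell(8) = 4140, Bell(10) = 115975.
enumerate_partitions <- function(n) {
  out <- list()
  grow <- function(labels, max_label) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(max_label + 1L)) {
      grow(c(labels, lab), max(max_label, lab))
    }
  }
  grow(integer(), 0L)
  out
}

# CPM quality by pairwise summation: sum over same-cluster pairs of
# (w_ij - resolution). Used to grade every enumerated partition.
cpm_by_pairs <- function(weights, labels, resolution) {
  n <- length(labels)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) s <- s + weights[i, j] - resolution
    }
  }
  s
}

best_cpm_partition <- function(weights, resolution) {
  parts <- enumerate_partitions(nrow(weights))
  quals <- vapply(parts, function(p) cpm_by_pairs(weights, p, resolution), numeric(1))
  list(quality = max(quals), labels = parts[[which.max(quals)]])
}

# Double-loop modularity oracle matching the documented definition.
modularity_by_loops <- function(weights, labels, resolution) {
  w_tot <- sum(weights) / 2
  if (w_tot == 0) return(0)
  s <- rowSums(weights)
  n <- length(labels)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + weights[i, j] - resolution * s[i] * s[j] / (2 * w_tot)
      }
    }
  }
  q / (2 * w_tot)
}

# Brute-force optimal assignment over all injections of the smaller domain
# set into the larger (feasible up to 6x6).
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_permutations(v[-i]), function(p) c(v[i], p))
  }))
}

brute_force_mean_iou <- function(iou) {
  np <- nrow(iou)
  nr <- ncol(iou)
  if (np == 0L || nr == 0L) return(0)
  if (np <= nr) {
    best <- max(vapply(all_permutations(seq_len(nr)), function(p) {
      sum(iou[cbind(seq_len(np), p[seq_len(np)])])
    }, numeric(1)))
  } else {
    best <- max(vapply(all_permutations(seq_len(np)), function(p) {
      sum(iou[cbind(p[seq_len(nr)], seq_len(nr))])
    }, numeric(1)))
  }
  best / max(np, nr)
}

# Residue graph straight from a weight matrix (bypasses the PAE transform;
# for quality-function and clustering fixtures).
graph_from_weights <- function(w, threshold = NA_real_) {
  diag(w) <- 0
  structure(
    list(n = nrow(w), weights = w, pae_sym = matrix(0, nrow(w), ncol(w)),
         threshold = threshold),
    class = "residue_graph"
  )
}

# Partition object with given labels (for exercising segment_clusters
# without running Leiden).
partition_from_labels <- function(labels, resolution = 0.7,
                                  objective = "modularity") {
  labels <- match(labels, unique(labels))
  structure(
    list(labels = labels, k = max(labels), quality = NA_real_,
         resolution = resolution, objective = objective,
         n_iterations = 10, seed = 0),
    class = "residue_partition"
  )
}

# PAE matrix whose graph at threshold 2 is two k-cliques of edge weight
# ~0.881 joined by edges of weight ~1e-9.
two_clique_pae <- function(k = 5) {
  n <- 2 * k
  weak <- 2 + log(1e9 - 1)   # logistic weight exactly 1e-9 at T = 2
  m <- matrix(weak, n, n)
  m[seq_len(k), seq_len(k)] <- 0
  m[k + seq_len(k), k + seq_len(k)] <- 0
  diag(m) <- 0
  pae_matrix(m)
}

# Minimal PDB writer for structure-IO fixtures: one CA atom per residue.
write_toy_pdb <- function(path, chain, resno, b, ins = rep("", length(resno))) {
  lines <- vapply(seq_along(resno), function(i) {
    sprintf("ATOM  %5d  CA  ALA %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, chain[i], resno[i], ifelse(nzchar(ins[i]), ins[i], " "),
            i * 1.0, 0, 0, 1, b[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# Minimal mmCIF writer (full standard _atom_site layout), one atom/residue.
write_toy_cif <- function(path, chain, resno, b) {
  header <- c(
    "data_toy", "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  rows <- vapply(seq_along(resno), function(i) {
    sprintf("ATOM %d C CA . ALA %s 1 %d ? %.3f 0.000 0.000 1.00 %.2f ? %d ALA %s CA 1",
            i, chain[i], resno[i], i * 1.0, b[i], resno[i], chain[i])
  }, character(1))
  writeLines(c(header, rows, "#"), path)
  path
}

# Random segmentation labels: runs of domains with unassigned gaps.
random_labels <- function(n, max_domains = 5) {
  k <- sample.int(max_domains, 1)
  labs <- sample(c(seq_len(k), NA_integer_), n, replace = TRUE)
  if (all(is.na(labs))) labs[1] <- 1L
  labs
}

cli_path <- function() system.file("cli", "paeseg.R", package = "paeseg")

run_cli <- function(args, dir = ".") {
  withr::with_dir(dir, {
    out <- suppressWarnings(system2(
      file.path(R.home("bin"), "Rscript"), c(cli_path(), args),
      stdout = TRUE, stderr = TRUE
    ))
    status <- attr(out, "status") %||% 0L
    list(status = status, output = out)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random chopping over n residues: up to k consecutive-interval domains,
# some intervals randomly left unassigned.
naive_random_chopping <- function(n, k) {
  bpts <- if (k > 1) sort(sample(seq_len(n - 1), k - 1)) else integer()
  starts <- c(1L, bpts + 1L)
  ends <- c(bpts, n)
  keep <- runif(k) < 0.8
  if (!any(keep)) keep[1] <- TRUE
  paste(sprintf("%d-%d", starts[keep], ends[keep]), collapse = ",")
}

# Independent serializer: canonical chopping text straight from a label
# vector (first-occurrence domain order, run-length segments).
naive_chopping_from_labels <- function(d) {
  d <- match(d, unique(stats::na.omit(d)))
  if (all(is.na(d))) return("")
  r <- rle(ifelse(is.na(d), -1L, d))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  doms <- unique(r$values[r$values > 0])
  paste(vapply(doms, function(dom) {
    sel <- r$values == dom
    paste(sprintf("%d-%d", starts[sel], ends[sel]), collapse = "_")
  }, character(1)), collapse = ",")
}
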