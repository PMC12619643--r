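test_that("CPM quality matches direct substitution on simple labellings", {
  w <- matrix(1, 3, 3)
  g <- graph_from_weights(w)
  # all singletons: no intra edges, no intra pairs
  expect_identical(partition_quality(g, 1:3, 0.5, "cpm"), 0)
  # one 3-clique of unit weights: 3 edges - 0.5 * 3 pairs
  expect_identical(partition_quality(g, c(1, 1, 1), 0.5, "cpm"), 1.5)
})

test_that("both quality functions agree with naive double-loop oracles", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      w <- matrix(runif(36), 6, 6)
      w <- (w + t(w)) / 2
      g <- graph_from_weights(w)
      labels <- sample(1:3, 6, replace = TRUE)
      res <- runif(1, 0.1, 2)
      expect_equal(partition_quality(g, labels, res, "cpm"),
                   cpm_by_pairs(g$weights, labels, res))
      expect_equal(partition_quality(g, labels, res, "modularity"),
                   modularity_by_loops(g$weights, labels, res))
    }
  })
})

test_that("unknown objectives are a configuration error", {
  g <- graph_from_weights(matrix(1, 3, 3))
  expect_error(partition_quality(g, 1:3, 0.5, "potts"),
               class = "paeseg_config_error")
  expect_error(cluster_residues(g, objective = "potts"),
               class = "paeseg_config_error")
})

test_that("Leiden recovers the CPM optimum on small clique fixtures", {
  # two 4-cliques weakly joined: enumeration over all 4140 partitions of 8
  g <- build_residue_graph(two_clique_pae(4), threshold = 2)
  part <- cluster_residues(g, resolution = 0.7, objective = "cpm")
  best <- best_cpm_partition(g$weights, 0.7)
  expect_identical(part$k, 2L)
  expect_identical(part$labels, rep(1:2, each = 4))
  expect_equal(part$quality, best$quality, tolerance = 1e-9)

  # a single 4-clique of unit weights stays together at resolution 0.5
  g4 <- graph_from_weights(matrix(1, 4, 4))
  part4 <- cluster_residues(g4, resolution = 0.5, objective = "cpm")
  best4 <- best_cpm_partition(g4$weights, 0.5)
  expect_identical(part4$k, 1L)
  expect_equal(part4$quality, best4$quality, tolerance = 1e-9)
})

test_that("an extreme resolution dissolves every cluster into singletons", {
  g <- build_residue_graph(two_clique_pae(4), threshold = 2)
  part <- cluster_residues(g, resolution = 1e6, objective = "cpm")
  expect_identical(part$k, 8L)
  expect_identical(part$labels, 1:8)
})

test_that("reported quality always equals a recomputation from the labels", {
  fx <- generate_planted(planted_spec(c(25, 35), seed = 4))
  g <- build_residue_graph(fx$pae)
  for (obj in c("modularity", "cpm")) {
    part <- cluster_residues(g, resolution = 0.7, objective = obj)
    expect_equal(part$quality,
                 partition_quality(g, part$labels, 0.7, obj),
                 tolerance = 1e-9)
  }
})

test_that("clustering is deterministic for a fixed seed", {
  fx <- generate_planted(planted_spec(c(30, 30, 30), seed = 5))
  g <- build_residue_graph(fx$pae)
  p1 <- cluster_residues(g, seed = 7)
  p2 <- cluster_residues(g, seed = 7)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$quality, p2$quality)
})

test_that("labels are canonical: first occurrences appear in order", {
  fx <- generate_planted(planted_spec(c(20, 20, 20), seed = 6))
  g <- build_residue_graph(fx$pae)
  labels <- cluster_residues(g)$labels
  firsts <- match(unique(labels), labels)
  expect_identical(labels[1], 1L)
  expect_identical(unique(labels), seq_len(max(labels)))
  expect_true(all(diff(firsts) > 0))
})

test_that("node relabelling permutes the partition but not its structure", {
  g <- build_residue_graph(two_clique_pae(4), threshold = 2)
  perm <- c(5L, 1L, 6L, 2L, 7L, 3L, 8L, 4L)
  gp <- graph_from_weights(g$weights[perm, perm])
  p1 <- cluster_residues(g, resolution = 0.7, objective = "cpm")
  p2 <- cluster_residues(gp, resolution = 0.7, objective = "cpm")
  # same partition up to the node permutation (compare co-membership)
  same1 <- outer(p1$labels[perm], p1$labels[perm], "==")
  same2 <- outer(p2$labels, p2$labels, "==")
  expect_identical(same1, same2)
})

test_that("a resolution sweep matches individual runs, in input order", {
  fx <- generate_planted(planted_spec(c(30, 30), seed = 9))
  g <- build_residue_graph(fx$pae)
  single <- sweep_resolutions(g, 0.7)
  expect_identical(nrow(single), 1L)
  expect_identical(single$partition[[1]]$labels, cluster_residues(g, 0.7)$labels)

  thrice <- sweep_resolutions(g, c(0.7, 0.7, 0.7))
  expect_identical(thrice$partition[[1]]$labels, thrice$partition[[2]]$labels)
  expect_identical(thrice$partition[[2]]$labels, thrice$partition[[3]]$labels)

  expect_error(sweep_resolutions(g, numeric()), class = "paeseg_config_error")
})

test_that("cluster counts grow weakly with resolution on the planted fixture", {
  fx <- generate_planted(planted_spec(c(80, 120, 100), seed = 0))
  g <- build_residue_graph(fx$pae)
  sw <- sweep_resolutions(g, c(0.4, 0.7, 1.5))
  expect_false(is.unsorted(sw$k))
})
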