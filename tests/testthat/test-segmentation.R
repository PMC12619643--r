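test_that("runs of shared labels become segments; discontinuity is preserved", {
  part <- partition_from_labels(c(1, 1, 1, 2, 2, 1, 1))
  seg <- segment_clusters(part, min_size = 1)
  expect_identical(chopping_string(seg), "1-3_6-7,4-5")
  expect_identical(nrow(seg$domains), 2L)
  expect_identical(seg$domains$n_segments, c(2L, 1L))
  expect_identical(seg$domains$n_residues, c(5L, 2L))
})

test_that("clusters below min_size are moved wholly to unassigned", {
  part <- partition_from_labels(c(1, 1, 1, 1, 1, 2))
  seg <- segment_clusters(part, min_size = 3)
  expect_identical(chopping_string(seg), "1-5")
  expect_identical(seg$residues$domain[6], NA_integer_)
})

test_that("planted block labels map back to the planted boundaries", {
  fx <- generate_planted(planted_spec(c(80, 120, 100), seed = 0))
  g <- build_residue_graph(fx$pae)
  part <- cluster_residues(g)
  seg <- segment_clusters(part, graph = g)
  expect_identical(chopping_string(seg), chopping_string(fx$truth))
  expect_identical(chopping_string(seg), "1-80,81-200,201-300")
})

test_that("chopping strings parse back to the segmentation that wrote them", {
  seg <- parse_chopping("1-3_6-7,4-5")
  expect_identical(nrow(seg$domains), 2L)
  expect_identical(seg$domains$n_segments[1], 2L)
  expect_identical(chopping_string(seg), "1-3_6-7,4-5")

  one <- parse_chopping("10-20")
  expect_identical(nrow(one$domains), 1L)
  expect_identical(one$domains$n_residues, 11L)

  empty <- parse_chopping("", n = 5)
  expect_identical(nrow(empty$domains), 0L)
  expect_identical(chopping_string(empty), "")
})

test_that("malformed choppings raise parse errors naming the token", {
  expect_error(parse_chopping("20-10"), regexp = "20-10",
               class = "paeseg_parse_error")
  expect_error(parse_chopping("1-x"), regexp = "1-x",
               class = "paeseg_parse_error")
  expect_error(parse_chopping("1-5,3-8"), class = "paeseg_parse_error")
})

test_that("serialize/parse round-trips hold for random segmentations", {
  # independent mini-serializer: renumber domains by first occurrence and
  # join run-length segments by hand
  naive_chopping <- function(d) {
    d <- match(d, unique(stats::na.omit(d)))
    if (all(is.na(d))) return("")
    r <- rle(ifelse(is.na(d), -1L, d))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- split(
      sprintf("%d-%d", starts[r$values > 0], ends[r$values > 0]),
      r$values[r$values > 0]
    )
    paste(vapply(unique(r$values[r$values > 0]), function(dom) {
      paste(segs[[as.character(dom)]], collapse = "_")
    }, character(1)), collapse = ",")
  }
  withr::with_seed(31, {
    for (rep in 1:200) {
      labels <- random_labels(sample(5:40, 1))
      text <- naive_chopping(labels)
      seg <- parse_chopping(text, n = length(labels))
      expect_identical(seg$residues$domain,
                       match(labels, unique(stats::na.omit(labels))))
      expect_identical(chopping_string(seg), text)
    }
  })
})

test_that("every residue lands in exactly one domain or in unassigned", {
  withr::with_seed(32, {
    for (rep in 1:25) {
      part <- partition_from_labels(sample(1:4, 30, replace = TRUE))
      seg <- segment_clusters(part, min_size = sample(1:8, 1))
      counted <- sum(seg$domains$n_residues) + sum(is.na(seg$residues$domain))
      expect_identical(counted, 30L)
    }
  })
})

test_that("raising min_size never increases the number of domains", {
  withr::with_seed(33, {
    part <- partition_from_labels(sample(1:5, 60, replace = TRUE))
    counts <- vapply(c(1, 3, 5, 10, 20, 60), function(ms) {
      nrow(segment_clusters(part, min_size = ms)$domains)
    }, numeric(1))
    expect_false(is.unsorted(rev(counts)))
  })
})

test_that("author numbering and chain prefixes drive the chopping text", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, chain = c(rep("A", 4), rep("B", 3)),
                resno = c(10:13, 5:7), b = rep(90, 7))
  res <- read_structure(path)
  part <- partition_from_labels(c(1, 1, 1, 1, 2, 2, 2))
  seg <- segment_clusters(part, residues = res, min_size = 1)
  expect_identical(chopping_string(seg), "A:10-13,B:5-7")
  back <- parse_chopping("A:10-13,B:5-7", residues = res)
  expect_identical(back$residues$domain, seg$residues$domain)
})

test_that("insertion-coded residues are addressed by label, not arithmetic", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, chain = rep("A", 4), resno = c(51, 52, 52, 53),
                b = rep(90, 4), ins = c("", "", "A", ""))
  res <- read_structure(path)
  part <- partition_from_labels(c(1, 1, 1, 2))
  seg <- segment_clusters(part, residues = res, min_size = 1)
  expect_identical(chopping_string(seg), "51-52A,53-53")
  back <- parse_chopping("51-52A,53-53", residues = res)
  expect_identical(back$residues$domain, c(1L, 1L, 1L, 2L))
})

test_that("annotated structures carry the domain index in the B-factor", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, chain = rep("A", 6), resno = 1:6, b = rep(90, 6))
  res <- read_structure(path)
  part <- partition_from_labels(c(1, 1, 1, 2, 2, 2))
  seg <- segment_clusters(part, residues = res, min_size = 1)
  out <- withr::local_tempfile(fileext = ".pdb")
  annotate_structure(path, seg, out)
  back <- read_structure(out)
  expect_setequal(unique(back$plddt), c(1, 2))
  expect_identical(back$plddt, as.numeric(seg$residues$domain))

  # all unassigned -> every B-factor is -1
  seg0 <- segment_clusters(part, min_size = 10, residues = res)
  annotate_structure(path, seg0, out)
  expect_identical(unique(read_structure(out)$plddt), -1)

  # residue-count mismatch is a reconciliation error
  short <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(short, chain = rep("A", 4), resno = 1:4, b = rep(90, 4))
  expect_error(annotate_structure(short, seg, out),
               class = "paeseg_reconcile_error")
})

test_that("the disorder filter unassigns residues with no confident cluster context", {
  fx <- generate_planted(planted_spec(c(40, 40), linker_positions = list(c(41, 12)),
                                      seed = 13))
  g <- build_residue_graph(fx$pae)
  part <- cluster_residues(g)
  seg <- segment_clusters(part, graph = g)
  linker <- 41:52
  expect_true(all(is.na(seg$residues$domain[linker])))
  expect_true(all(!is.na(seg$residues$domain[-linker])))
})

test_that("domain and residue tables are written with the documented columns", {
  part <- partition_from_labels(c(1, 1, 1, 2, 2, 2))
  seg <- segment_clusters(part, min_size = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_domains_tsv(seg, tsv)
  write_residues_csv(seg, csv)
  dom <- utils::read.delim(tsv)
  expect_identical(names(dom), c("domain_index", "n_segments", "chopping", "n_residues"))
  expect_identical(dom$chopping, c("1-3", "4-6"))
  res <- utils::read.csv(csv)
  expect_identical(names(res), c("residue", "chain", "author_number", "plddt", "domain"))
  expect_identical(res$domain, c(1L, 1L, 1L, 2L, 2L, 2L))
})
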