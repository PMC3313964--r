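test_that("three leaves resolve with the exact closed-form lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  phy <- nj_tree(d)
  co <- ape::cophenetic.phylo(phy)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-12)
})

test_that("a four-leaf additive matrix is reconstructed exactly", {
  # unrooted tree: A-X=1, B-X=2, X-Y=1, C-Y=3, D-Y=1
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  phy <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(phy)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
  # split AB|CD and nothing else
  keys <- barcodegap:::tree_bipartition_keys(phy)
  expect_equal(keys, "C|D")
})

test_that("ties are broken deterministically on a degenerate matrix", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  p1 <- nj_tree(d)
  p2 <- nj_tree(d)
  expect_identical(ape::write.tree(p1), ape::write.tree(p2))
  # lowest (row, col) pair joins first: A and B form a cherry
  expect_equal(barcodegap:::tree_bipartition_keys(p1), "C|D")
})

test_that("input guards reject degenerate matrices", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "asymmetric")
})

test_that("undefined entries are imputed with the matrix maximum", {
  d <- matrix(c(0, 1, NA, 4,
                1, 0, 2, 4,
                NA, 2, 0, 4,
                4, 4, 4, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_warning(phy <- nj_tree(d), "imputed with the maximum")
  expect_equal(attr(phy, "n_imputed"), 1L)
  expect_setequal(phy$tip.label, LETTERS[1:4])
  phy2 <- nj_tree(d, impute = "drop")
  expect_lt(ape::Ntip(phy2), 4L)
})

test_that("bipartitions are invariant under leaf-order permutation", {
  set.seed(41)
  tr <- ape::rtree(9)
  d <- ape::cophenetic.phylo(tr)
  k1 <- sort(barcodegap:::tree_bipartition_keys(nj_tree(d)))
  perm <- sample(9)
  k2 <- sort(barcodegap:::tree_bipartition_keys(
    nj_tree(d[perm, perm])))
  expect_identical(k1, k2)
})

test_that("newick serialization preserves topology, lengths and supports", {
  set.seed(42)
  aln <- two_clade_alignment(4, 250)
  bs <- bootstrap_support(aln, B = 30, seed = 9, min_overlap = 20)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(bs$tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, bs$tree$tip.label)
  expect_identical(sort(barcodegap:::tree_bipartition_keys(back)),
                   sort(barcodegap:::tree_bipartition_keys(bs$tree)))
  expect_equal(sort(back$edge.length), sort(bs$tree$edge.length),
               tolerance = 1e-6)
  expect_identical(sort(back$node.label), sort(bs$tree$node.label))
})

test_that("bootstrap saturates on clean signal and is reproducible", {
  set.seed(43)
  aln <- two_clade_alignment(4, 300)
  bs <- bootstrap_support(aln, B = 50, seed = 7, min_overlap = 20)
  expect_equal(bs$effective_B, 50L)
  # the clade split between the two groups is fixed by many sites
  split_key <- paste(sort(grep("^b", sample_ids(aln), value = TRUE)),
                     collapse = "|")
  expect_equal(unname(bs$support[split_key]), 100)
  bs2 <- bootstrap_support(aln, B = 50, seed = 7, min_overlap = 20)
  expect_identical(bs$support, bs2$support)
  # B = 1 can only yield 0 or 100
  bs1 <- bootstrap_support(aln, B = 1, seed = 3, min_overlap = 20)
  expect_true(all(bs1$support %in% c(0, 100)))
})

test_that("pure-noise alignments yield bounded, reproducible supports", {
  set.seed(44)
  aln <- locus_alignment(random_sequences(8, 200), "noise")
  bs <- bootstrap_support(aln, B = 40, seed = 11, min_overlap = 20)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  bs2 <- bootstrap_support(aln, B = 40, seed = 11, min_overlap = 20)
  expect_identical(bs$support, bs2$support)
})

test_that("outgroup rooting preserves bipartitions and supports", {
  set.seed(45)
  aln <- two_clade_alignment(4, 250)
  bs <- bootstrap_support(aln, B = 20, seed = 1, min_overlap = 20)
  rooted <- root_at_outgroup(bs$tree, "a01", bs$support)
  expect_true(ape::is.rooted(rooted))
  expect_equal(attr(rooted, "rooting"), "outgroup")
  expect_setequal(barcodegap:::tree_bipartition_keys(rooted),
                  barcodegap:::tree_bipartition_keys(bs$tree))
  expect_error(root_at_outgroup(bs$tree, "ghost"), "unknown leaf")
  mid <- root_at_outgroup(bs$tree, NULL)
  expect_equal(attr(mid, "rooting"), "midpoint")
  expect_true(ape::is.rooted(mid))
})

test_that("NJ agrees with an established implementation on random matrices", {
  set.seed(46)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    d <- ape::cophenetic.phylo(tr)
    mine <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})
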