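test_that("species trees are ultrametric with monophyletic sections", {
  set.seed(71)
  p <- sim_params(n_sections = 3L, species_per_section = c(4L, 3L, 5L),
                  seed = 71L)
  st <- simulate_species_tree(p)
  tr <- st$tree
  # ultrametric: all root-to-tip path lengths equal
  depths <- ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  # each section's species form a clade
  for (sec in setdiff(unique(st$sections$section), "outgroup")) {
    sp <- st$sections$species[st$sections$section == sec]
    if (length(sp) < 2L) next
    expect_true(ape::is.monophyletic(tr, sp))
  }
  # outgroup attaches above the ingroup
  expect_true("outgrp" %in% tr$tip.label)
})

test_that("the collapse limit reproduces the species tree", {
  set.seed(72)
  p <- sim_params(n_sections = 2L, species_per_section = 3L,
                  samples_per_species = c(2L, 2L), theta = 0, ils = 0,
                  seed = 72L)
  st <- simulate_species_tree(p)
  samples <- setNames(rep(st$sections$species, each = 2L),
                      sprintf("%s_%02d", rep(st$sections$species, each = 2L),
                              rep(1:2, times = nrow(st$sections))))
  gt <- simulate_gene_tree(st$tree, st$sections, samples, theta = 0,
                           ils = 0)
  expect_equal(nrow(gt$host_moves), 0L)
  # with zero within-species depth, conspecific samples are zero-distance
  co <- ape::cophenetic.phylo(gt$tree)
  for (sp in st$sections$species) {
    ids <- names(samples)[samples == sp]
    if (length(ids) == 2L) expect_lt(co[ids[1L], ids[2L]], 1e-6)
  }
  # and each species' samples are monophyletic
  for (sp in unique(samples)) {
    ids <- names(samples)[samples == sp]
    if (length(ids) >= 2L)
      expect_true(ape::is.monophyletic(gt$tree, ids))
  }
})

test_that("ILS produces species non-monophyly at a rate that grows", {
  nonmono <- function(ils, seed) {
    set.seed(seed)
    p <- sim_params(n_sections = 2L, species_per_section = 6L,
                    samples_per_species = c(4L, 4L), theta = 0.001,
                    ils = ils, seed = seed)
    st <- simulate_species_tree(p)
    sp_names <- st$sections$species[st$sections$section != "outgroup"]
    samples <- setNames(rep(sp_names, each = 4L),
                        sprintf("%s_%02d", rep(sp_names, each = 4L),
                                rep(1:4, times = length(sp_names))))
    gt <- simulate_gene_tree(st$tree, st$sections, samples, theta = 0.001,
                             ils = ils)
    mean(vapply(sp_names, function(sp) {
      !ape::is.monophyletic(gt$tree, names(samples)[samples == sp])
    }, logical(1L)))
  }
  lo <- mean(vapply(1:5, function(s) nonmono(0, s), numeric(1L)))
  hi <- mean(vapply(1:5, function(s) nonmono(0.5, s), numeric(1L)))
  expect_equal(lo, 0)
  expect_gt(hi, 0)
})

test_that("a zero-length tree yields identical sequences", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  aln <- evolve_sequences(tr, list(name = "x", length = 200, rel_rate = 1,
                                   coding = TRUE), kappa = 2)$alignment
  s <- alignment_strings(aln)
  expect_equal(s[["a"]], s[["b"]])
  expect_equal(s[["a"]], s[["c"]])
})

test_that("datasets are byte-identical under the same seed", {
  p <- preset_params("gapped", seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(p), d1)
  write_dataset(generate_dataset(p), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("presets load and emit the documented study conditions", {
  p <- preset_params("fraxinus_like", seed = 1)
  expect_equal(p$n_sections, 6L)
  expect_equal(sum(rep_len(p$species_per_section, p$n_sections)), 56L)
  expect_equal(sum(p$sample_counts), 253L)
  expect_equal(sum(p$sample_counts == 1L), 7L)
  expect_equal(range(p$sample_counts), c(1L, 28L))
  expect_equal(vapply(p$loci, function(l) l$length, integer(1L)),
               c(698L, 1023L))
  ds <- generate_dataset(p)
  expect_equal(nrow(ds$metadata), 254L)  # 253 ingroup + outgroup
  expect_equal(length(unique(ds$metadata$species)) -
                 ("outgrp" %in% ds$metadata$species), 56)
  # missing loci exist but nobody is absent everywhere
  seen <- unique(unlist(lapply(ds$alignments, sample_ids)))
  expect_setequal(seen, ds$metadata$sample_id)
})

test_that("the generator's ledger accounts for every emitted sample", {
  ds <- generate_dataset(preset_params("gapped", seed = 13))
  expect_setequal(ds$ledger$true_species$sample_id, ds$metadata$sample_id)
  for (nm in names(ds$alignments)) {
    gt <- ape::read.tree(text = ds$ledger$gene_trees[[nm]])
    expect_setequal(gt$tip.label, sample_ids(ds$alignments[[nm]]))
  }
})

test_that("realized distances match the regime the preset encodes", {
  # loose two-sided envelope around the published regime values (mean
  # intraspecific 1.0 and interspecific 2.0 per 100 sites), averaged over
  # ten seeds
  stats <- vapply(1:10, function(s) {
    ds <- generate_dataset(preset_params("fraxinus_like", seed = s))
    aln <- ds$alignments$spacer698
    ing <- setdiff(sample_ids(aln), ds$outgroup_id)
    dm <- k2p_distance_matrix(barcodegap:::subset_alignment(aln, ing))
    part <- partition_distances(dm, ds$metadata)
    c(mean(part$intra$d), mean(part$inter$d)) * 100
  }, numeric(2L))
  expect_gt(mean(stats[1, ]), 0.5)
  expect_lt(mean(stats[1, ]), 1.5)
  expect_gt(mean(stats[2, ]), 1.0)
  expect_lt(mean(stats[2, ]), 3.0)
})

test_that("discrimination rises with interspecific divergence", {
  disc_at <- function(depth, seed) {
    p <- sim_params(n_sections = 2L, species_per_section = 4L,
                    samples_per_species = c(3L, 3L), tree_depth = depth,
                    min_split_frac = 0.3, theta = 0.002, ils = 0,
                    loci = list(list(name = "x", length = 500,
                                     rel_rate = 1, coding = FALSE,
                                     indel_rate = 0, indel_mean_len = 5)),
                    seed = seed)
    ds <- generate_dataset(p)
    dm <- k2p_distance_matrix(ds$alignments$x)
    del <- delineate(root_at_outgroup(nj_tree(dm), ds$outgroup_id),
                     ds$metadata)
    del <- del[del$species != "outgrp", ]
    count_discriminated(del) / sum(!del$singleton)
  }
  lo <- mean(vapply(1:4, function(s) disc_at(0.004, s), numeric(1L)))
  hi <- mean(vapply(1:4, function(s) disc_at(0.08, s), numeric(1L)))
  expect_gte(hi, lo)
  expect_equal(hi, 1)
})
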