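test_that("K2P matches the closed form on constructed counts", {
  # identical sequences
  s <- paste(rep("ACGT", 25), collapse = "")
  r <- k2p(s, s, min_overlap = 10)
  expect_equal(r$d, 0)
  expect_equal(r$P, 0)
  expect_equal(r$Q, 0)

  # 100 comparable columns, 10 transitions, 5 transversions:
  # d = -1/2 ln(0.75 * sqrt(0.90))
  a <- rep("A", 100)
  b <- rep("A", 100)
  b[1:10] <- "G"   # transitions
  b[11:15] <- "C"  # transversions
  r <- k2p(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75 * sqrt(0.90)), tolerance = 1e-15)

  # log-domain boundary: P = 0.5, Q = 0 is saturated
  b2 <- a; b2[1:50] <- "G"
  r2 <- k2p(paste(a, collapse = ""), paste(b2, collapse = ""))
  expect_true(is.na(r2$d))
  expect_equal(r2$reason, "saturated")

  expect_error(k2p("ACGT", "ACG"), "length mismatch")
  r3 <- k2p("----", "ACGT", min_overlap = 1)
  expect_true(is.na(r3$d))
  expect_equal(r3$reason, "insufficient_overlap")
})

test_that("K2P agrees with a brute-force counting oracle on random pairs", {
  set.seed(31)
  for (rep in 1:50) {
    m <- related_sequences(2, 150, p = runif(1, 0.01, 0.25))
    if (runif(1) < 0.5) m[1, sample(150, 10)] <- "-"
    if (runif(1) < 0.5) m[2, sample(150, 8)] <- "N"
    a <- paste(m[1, ], collapse = ""); b <- paste(m[2, ], collapse = "")
    mine <- k2p(a, b, min_overlap = 20)
    oracle <- r_k2p_oracle(a, b, min_overlap = 20)
    expect_equal(mine$n_compared, oracle$n)
    if (is.na(oracle$d)) expect_true(is.na(mine$d))
    else expect_equal(mine$d, oracle$d, tolerance = 1e-12)
  }
})

test_that("K2P is symmetric, permutation-invariant, and never below P+Q", {
  set.seed(32)
  m <- related_sequences(2, 300, p = 0.1)
  a <- paste(m[1, ], collapse = ""); b <- paste(m[2, ], collapse = "")
  r <- k2p(a, b)
  expect_equal(r$d, k2p(b, a)$d)
  perm <- sample(300)
  r2 <- k2p(paste(m[1, perm], collapse = ""),
            paste(m[2, perm], collapse = ""))
  expect_equal(r$d, r2$d)
  expect_gte(r$d, r$P + r$Q)
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(33)
  aln <- locus_alignment(related_sequences(10, 200, p = 0.08), "x")
  dm <- k2p_distance_matrix(aln, min_overlap = 20)
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 10))
  expect_true(all(dm$d[!is.na(dm$d)] >= 0))
  # identical rows give the zero matrix
  m0 <- matrix(rep(strsplit(paste(rep("ACGT", 30), collapse = ""), "")[[1L]],
                   each = 3), nrow = 3,
               dimnames = list(c("a", "b", "c"), NULL))
  dm0 <- k2p_distance_matrix(locus_alignment(m0, "z"))
  expect_true(all(dm0$d == 0))
})

test_that("concatenated distances use only mutually present columns", {
  set.seed(34)
  a <- locus_alignment(related_sequences(4, 120, p = 0.05,
                                         ids = sprintf("x%d", 1:4)), "locA")
  bmat <- related_sequences(3, 80, p = 0.05, ids = sprintf("x%d", 1:3))
  b <- locus_alignment(bmat, "locB")
  cc <- concatenate_loci(list(a, b))
  dm <- k2p_distance_matrix(cc, min_overlap = 20)
  # x4 lacks locB: its distance to x1 must equal the locA-only distance
  direct <- k2p(alignment_strings(a)["x4"], alignment_strings(a)["x1"],
                min_overlap = 20)
  expect_equal(dm$d["x4", "x1"], direct$d)
  # pairs with both loci combine the slices
  both <- k2p(paste0(alignment_strings(a)["x1"], alignment_strings(b)["x1"]),
              paste0(alignment_strings(a)["x2"], alignment_strings(b)["x2"]),
              min_overlap = 20)
  expect_equal(dm$d["x1", "x2"], both$d)
})

test_that("distance partition reconciles all pairs and excludes singletons", {
  set.seed(35)
  aln <- locus_alignment(related_sequences(7, 150, p = 0.07), "x")
  md <- toy_metadata(sample_ids(aln),
                     c("spA", "spA", "spA", "spB", "spB", "spC", "spD"))
  dm <- k2p_distance_matrix(aln, min_overlap = 20)
  part <- partition_distances(dm, md)
  expect_setequal(part$excluded_singletons, c("spC", "spD"))
  expect_equal(nrow(part$intra) + nrow(part$inter) + part$n_undefined,
               choose(7, 2))
  expect_equal(nrow(part$intra), choose(3, 2) + choose(2, 2))
  expect_error(partition_distances(dm, md[-1, ]), "unlabeled")
})

test_that("barcode gap statistics behave at the two extremes", {
  # perfect barcode: every intra below every inter
  part <- structure(list(
    intra = data.frame(species = c("a", "a", "b"), id_a = "x", id_b = "y",
                       d = c(0.001, 0.002, 0.001)),
    inter = data.frame(species_a = "a", species_b = "b", id_a = "x",
                       id_b = "y", d = c(0.02, 0.03, 0.05, 0.04)),
    excluded_singletons = character(), n_undefined = 0L, n_pairs = 7L),
    class = "dist_partition")
  g <- barcode_gap(part)
  expect_equal(g$overlap_fraction, 0)
  expect_true(all(g$local_gaps$local_gap > 0))
  # degenerate: identical distributions overlap completely
  part2 <- part
  part2$inter$d <- c(0.001, 0.002, 0.001, 0.002)
  g2 <- barcode_gap(part2)
  expect_equal(g2$overlap_fraction, 1)
  # all-singleton partition: gap undefined
  part3 <- part
  part3$intra <- part$intra[0, ]
  g3 <- barcode_gap(part3)
  expect_false(g3$defined)
  expect_true(is.na(g3$overlap_fraction))
  # histogram masses sum to one per series
  expect_equal(sum(g$histogram$intra_freq), 1)
  expect_equal(sum(g$histogram$inter_freq), 1)
})

test_that("planted gap size is recovered on simulated data", {
  ds <- generate_dataset(preset_params("gapped", seed = 4))
  aln <- ds$alignments$locusA
  ing <- setdiff(sample_ids(aln), ds$outgroup_id)
  dm <- k2p_distance_matrix(barcodegap:::subset_alignment(aln, ing))
  part <- partition_distances(dm, ds$metadata)
  g <- barcode_gap(part)
  expect_equal(g$overlap_fraction, 0)
  expect_true(min(g$local_gaps$local_gap, na.rm = TRUE) > 0)
})

test_that("dataset summary mirrors its inputs exactly", {
  set.seed(36)
  aln <- locus_alignment(related_sequences(8, 180, p = 0.06), "x")
  md <- toy_metadata(sample_ids(aln), rep(c("spA", "spB"), each = 4))
  dm <- k2p_distance_matrix(aln, min_overlap = 20)
  part <- partition_distances(dm, md)
  sites <- classify_sites(aln)
  row <- summarize_dataset(aln, dm, part, sites, md)
  expect_equal(row$n_species, 2L)
  expect_equal(row$n_samples, 8L)
  expect_equal(row$mean_intra,
               barcodegap:::round_half_up(mean(part$intra$d) * 100))
  expect_equal(row$mean_inter,
               barcodegap:::round_half_up(mean(part$inter$d) * 100))
  expect_equal(row$variable_pct,
               barcodegap:::round_half_up(100 * row$variable_sites / 180))
  expect_true(row$intra_min <= row$mean_intra &
                row$mean_intra <= row$intra_max)
  # an all-identical alignment zeroes every distance field
  m0 <- matrix(rep(strsplit(paste(rep("ACGT", 50), collapse = ""),
                            "")[[1L]], each = 4), nrow = 4,
               dimnames = list(sprintf("s%d", 1:4), NULL))
  aln0 <- locus_alignment(m0, "z")
  md0 <- toy_metadata(sample_ids(aln0), rep(c("spA", "spB"), each = 2))
  dm0 <- k2p_distance_matrix(aln0)
  row0 <- summarize_dataset(aln0, dm0, partition_distances(dm0, md0),
                            classify_sites(aln0), md0)
  expect_equal(row0$variable_sites, 0L)
  expect_equal(row0$mean_intra, 0)
  expect_equal(row0$max_rate, 0)
})

test_that("K2P distances agree with an established implementation", {
  set.seed(37)
  m <- related_sequences(6, 250, p = 0.1)
  dm <- k2p_distance_matrix(locus_alignment(m, "x"), min_overlap = 10)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "K80",
                                 pairwise.deletion = TRUE))
  ok <- !is.na(dm$d)
  expect_equal(dm$d[ok], ref[rownames(dm$d), colnames(dm$d)][ok],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("estimated K2P converges to the true branch length", {
  set.seed(38)
  tr <- ape::read.tree(text = "(a:0.04,b:0.04);")
  est <- replicate(30, {
    aln <- evolve_sequences(tr, list(name = "x", length = 3000,
                                     rel_rate = 1, coding = TRUE),
                            kappa = 2)$alignment
    s <- alignment_strings(aln)
    k2p(s[["a"]], s[["b"]])$d
  })
  expect_equal(mean(est), 0.08, tolerance = 0.05)
})
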