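test_that("variable and informative sites follow the parsimony definitions", {
  m <- rbind(c("A", "A", "A", "A"),
             c("A", "A", "A", "T"),
             c("T", "A", "-", "G"),
             c("T", "T", "-", "C"))
  rownames(m) <- sprintf("s%d", 1:4)
  sc <- classify_sites(locus_alignment(m, "x"))
  # col1: A,A,T,T -> variable + informative; col2: A,A,A,T -> variable only;
  # col3: A,A,-,- -> single unambiguous state; col4: all different ->
  # variable, no state carried twice
  expect_equal(sc$variable_sites, c(1L, 2L, 4L))
  expect_equal(sc$informative_sites, 1L)
  expect_true(all(sc$informative_sites %in% sc$variable_sites))
  expect_error(classify_sites(locus_alignment(m[1, , drop = FALSE], "y")),
               "at least 2")
})

test_that("ambiguity codes never contribute states", {
  m <- rbind(c("A", "R"), c("A", "G"), c("N", "R"), c("A", "G"))
  rownames(m) <- sprintf("s%d", 1:4)
  sc <- classify_sites(locus_alignment(m, "x"))
  expect_equal(sc$variable_sites, integer(0))
  expect_equal(unname(colSums(sc$state_counts)), c(3, 2))
})

test_that("site counts bound each other on arbitrary alignments", {
  set.seed(21)
  for (rep in 1:5) {
    aln <- locus_alignment(related_sequences(12, 150, p = 0.1), "x")
    sc <- classify_sites(aln)
    expect_lte(length(sc$informative_sites), length(sc$variable_sites))
    expect_lte(length(sc$variable_sites), sc$n_columns)
  }
})

test_that("indel catalogue groups by exact span and classifies carriers", {
  set.seed(5)
  m <- related_sequences(8, 80, p = 0.02,
                         ids = c(sprintf("spA_%d", 1:3),
                                 sprintf("spB_%d", 1:3),
                                 sprintf("spC_%d", 1:1), "out_1"))
  md <- toy_metadata(rownames(m),
                     c(rep("spA", 3), rep("spB", 3), "spC", "outg"),
                     c(rep("sect_1", 3), rep("sect_2", 3), "sect_2",
                       "outgroup"))
  # autapomorphic run
  m["spA_1", 10:12] <- "-"
  # clade-diagnostic: all of spB, nobody else
  m[sprintf("spB_%d", 1:3), 30:35] <- "-"
  # shared across species, not a full species set
  m[c("spA_2", "spB_1"), 50:52] <- "-"
  # identical-span grouping is exact: overlapping-but-different span is
  # a separate event
  m["spA_3", 50:53] <- "-"
  cat <- indel_catalogue(locus_alignment(m, "spacer"), md)
  expect_equal(nrow(cat), 4L)
  a <- cat[cat$start == 10, ]
  expect_equal(a$classification, "autapomorphic")
  expect_equal(a$n_members, 1L)
  expect_equal(a$length, 3L)
  b <- cat[cat$start == 30, ]
  expect_equal(b$classification, "clade_diagnostic")
  expect_equal(sum(cat$start == 50), 2L)
  expect_setequal(cat$classification[cat$start == 50],
                  c("shared", "autapomorphic"))
})

test_that("an ingroup-wide gap against an ungapped outgroup is polarized", {
  set.seed(6)
  m <- related_sequences(5, 60, p = 0.01,
                         ids = c(sprintf("in_%d", 1:4), "outg_1"))
  m[sprintf("in_%d", 1:4), 20:30] <- "-"
  md <- toy_metadata(rownames(m), c(rep("spA", 2), rep("spB", 2), "outg"),
                     c("s1", "s1", "s2", "s2", "outgroup"))
  cat <- indel_catalogue(locus_alignment(m, "spacer"), md,
                         outgroup_id = "outg_1")
  expect_equal(nrow(cat), 1L)
  expect_match(cat$note, "outgroup lacks state")
  expect_equal(cat$length, 11L)
})

test_that("terminal gap tails are excluded from the catalogue", {
  set.seed(7)
  m <- related_sequences(4, 50, p = 0.01)
  m[1, 1:6] <- "-"     # leading tail
  m[2, 45:50] <- "-"   # trailing tail
  m[3, 20:22] <- "-"   # genuine interior indel
  cat <- indel_catalogue(locus_alignment(m, "spacer"), NULL)
  expect_equal(nrow(cat), 1L)
  expect_equal(c(cat$start, cat$end), c(20, 22))
})

test_that("planted indel events are recovered exactly from the ledger", {
  set.seed(8)
  tr <- ape::rcoal(12, tip.label = sprintf("t%02d", 1:12))
  tr$edge.length <- tr$edge.length * 0.02
  members <- barcodegap:::tips_below(tr, 15L)
  ev <- evolve_sequences(
    tr, list(name = "spacer", length = 400, rel_rate = 1, coding = FALSE,
             indel_rate = 0, indel_mean_len = 8), kappa = 2,
    forced_events = list(list(type = "deletion", start = 101L,
                              length = 92L, members = members)))
  led <- ev$indel_ledger
  expect_equal(nrow(led), 1L)
  cat <- indel_catalogue(ev$alignment, NULL)
  hit <- cat[cat$start == led$start & cat$end == led$end, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length, 92L)
  expect_setequal(strsplit(hit$members, ",")[[1L]],
                  strsplit(led$members, ",")[[1L]])
})

test_that("random indel planting matches the generator's event ledger", {
  set.seed(9)
  tr <- ape::rcoal(10, tip.label = sprintf("t%02d", 1:10))
  tr$edge.length <- tr$edge.length * 0.01
  ev <- evolve_sequences(
    tr, list(name = "spacer", length = 500, rel_rate = 1, coding = FALSE,
             indel_rate = 5, indel_mean_len = 6), kappa = 2)
  led <- ev$indel_ledger
  del <- led[led$type == "deletion", , drop = FALSE]
  cat <- indel_catalogue(ev$alignment, NULL)
  for (i in seq_len(nrow(del))) {
    hit <- cat[cat$start == del$start[i] & cat$end == del$end[i], ]
    expect_equal(nrow(hit), 1L)
    expect_setequal(strsplit(hit$members, ",")[[1L]],
                    strsplit(del$members[i], ",")[[1L]])
  }
  # insertions appear as gap spans carried by the complement
  ins <- led[led$type == "insertion", , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    hit <- cat[cat$start == ins$start[i] & cat$end == ins$end[i], ]
    expect_equal(nrow(hit), 1L)
    expect_setequal(
      strsplit(hit$members, ",")[[1L]],
      setdiff(sample_ids(ev$alignment),
              strsplit(ins$members[i], ",")[[1L]]))
  }
})
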