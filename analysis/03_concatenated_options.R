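#!/usr/bin/env Rscript

# Step 3: multilocus barcode "options" on a reduced-style dataset.
#
# Emulates the standard two-option plastid barcode protocol: three coding
# loci (option 1) versus two coding loci plus a spacer (option 2),
# concatenated with tolerance for samples missing a locus. Coding loci are
# cleaned of autapomorphic indels before concatenation.

suppressPackageStartupMessages(library(barcodegap))

p <- sim_params(
  n_sections = 4L, species_per_section = c(6L, 6L, 6L, 5L),
  samples_per_species = c(1L, 4L),
  tree_depth = 0.010, min_split_frac = 0.02, theta = 0.0038, ils = 0.35,
  kappa = 2, mislabel_rate = 0.01, locus_missing_rate = 0.12,
  loci = list(
    list(name = "rpoC1_like", length = 520, rel_rate = 0.35,
         coding = TRUE, indel_rate = 0, indel_mean_len = 5),
    list(name = "rpoB_like", length = 460, rel_rate = 0.35,
         coding = TRUE, indel_rate = 0, indel_mean_len = 5),
    list(name = "matK_like", length = 720, rel_rate = 0.6,
         coding = TRUE, indel_rate = 0, indel_mean_len = 5),
    list(name = "spacer_like", length = 700, rel_rate = 1.0,
         coding = FALSE, indel_rate = 8, indel_mean_len = 8)),
  seed = 2305L)
ds <- generate_dataset(p)

rep <- run_evaluation(
  ds$alignments, ds$metadata,
  datasets = list(
    option1 = c("rpoC1_like", "rpoB_like", "matK_like"),
    option2 = c("rpoC1_like", "matK_like", "spacer_like"),
    matK_like = "matK_like"),
  coding_loci = c("rpoC1_like", "rpoB_like", "matK_like"),
  outgroup_id = ds$outgroup_id, B = 1000, seed = 1)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(rep$summary, "results/tables/03_concatenated_options.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_report(rep, "scratch/evaluation/options")

cat("multilocus options (distances per 100 sites):\n")
print(rep$summary[, c("dataset", "n_columns", "variable_pct",
                      "mean_intra", "mean_inter", "overlap_fraction",
                      "nj_species")], row.names = FALSE)
cat("Adding the spacer (option 2) raises variability relative to the\n")
cat("all-coding option 1, but the overlap persists in both options.\n")
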