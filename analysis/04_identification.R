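#!/usr/bin/env Rscript

# Step 4: leave-one-out identification on the most variable locus of the
# low-divergence dataset (run analysis/01_simulate.R first).
#
# Every sequence is queried against all others with the seed-and-extend
# local aligner; the species of the best hit(s) is compared against the
# query's label. Per-species and per-section summaries go to
# results/tables/, full hit tables to scratch/evaluation/.

suppressPackageStartupMessages(library(barcodegap))

data_dir <- "scratch/data/fraxinus_like"
stopifnot(file.exists(file.path(data_dir, "metadata.tsv")))
md <- read_metadata(file.path(data_dir, "metadata.tsv"))
aln <- read_fasta_alignment(file.path(data_dir, "spacer698.fasta"),
                            "spacer698")
ing <- setdiff(sample_ids(aln), "outgrp_01")
aln_in <- structure(list(locus = aln$locus,
                         matrix = as.matrix(aln)[ing, , drop = FALSE],
                         n_columns = aln$n_columns),
                    class = "locus_alignment")

loo <- loo_identify(aln_in, md)
idsum <- identification_summary(loo)
print(idsum)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(idsum$per_species,
            "results/tables/04_identification_per_species.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(idsum$per_section,
            "results/tables/04_identification_per_section.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
counts <- data.frame(
  statistic = c("species_total", "all_correct_top1", "all_correct_top3",
                "majority_top1", "majority_top3", "unidentifiable_queries",
                "section_avg_unweighted_pct", "section_avg_weighted_pct"),
  value = c(idsum$counts$n_species, idsum$counts$all_correct_top1,
            idsum$counts$all_correct_top3, idsum$counts$majority_top1,
            idsum$counts$majority_top3, idsum$n_unidentifiable,
            round(idsum$section_avg_unweighted, 1),
            round(idsum$section_avg_weighted, 1)))
write.table(counts, "results/tables/04_identification_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
dir.create("scratch/evaluation", recursive = TRUE, showWarnings = FALSE)
write_hit_table(loo, "scratch/evaluation/spacer698_loo_hits.tsv")

cat("\nBest-hit identification resolves more species than the NJ-tree\n")
cat("criterion on the same data, but still only a minority of species;\n")
cat("most assignments are only reliable at the section level.\n")
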