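# barcodegap

Tools for evaluating how well candidate DNA-barcoding loci discriminate
species in genera where interspecific divergence is low — the situation
typical of long-lived, large-population trees such as the ashes
(*Fraxinus*), where slow fixation and incomplete lineage sorting (ILS)
leave most chloroplast polymorphisms shared between species.

The package is aimed at molecular systematists who want to quantify, for a
given set of aligned sequences with species labels, whether a locus (or a
concatenation of loci) can actually identify species — and at method
developers who need a controlled synthetic regime in which that question
has a known answer.

## What it computes

* **K2P distances.** For each sequence pair, transitions `P` and
  transversions `Q` are counted over the columns where both sequences carry
  an unambiguous nucleotide (pairwise deletion of gaps, `?` and IUPAC
  ambiguity codes), and the Kimura two-parameter rate is

  d = −½ · ln( (1 − 2P − Q) · √(1 − 2Q) )

  reported per 100 sites. Saturated or low-overlap pairs are undefined and
  tracked with a reason.
* **Barcode-gap statistics.** Intra- vs interspecific distance
  distributions (singleton species excluded from the intraspecific set),
  relative-frequency histograms, a global overlap fraction (share of
  interspecific pairs at or below the maximum intraspecific distance) and
  per-species local gaps.
* **NJ trees with bootstrap.** Classic neighbor joining with deterministic
  tie-breaking, nonparametric bootstrap over alignment columns (support
  mapped onto the original tree's bipartitions), and outgroup or midpoint
  rooting.
* **Species discrimination.** A species counts as discriminated when more
  than 50% of its individuals (threshold configurable) fall in a single
  clade containing no other species; probable misidentifications can be
  flagged and excluded first.
* **Leave-one-out identification.** A seed-and-extend local aligner
  (word seeding, X-drop ungapped extension, banded affine-gap
  Smith–Waterman) ranks every other sequence for each query; top-1/top-3
  species accuracy and section-assignment rates are summarized.
* **Site statistics.** Variable and parsimony-informative (diagnostic)
  columns; an indel catalogue with span-exact grouping and
  autapomorphic / shared / clade-diagnostic classification.
* **Synthetic data.** A generator producing sectioned species trees,
  within-species coalescent variation, phenomenological ILS, K80 sequence
  evolution and planted indels/label swaps — with a truth ledger, so every
  pipeline stage can be tested against known answers. Two presets ship as
  YAML: `fraxinus_like` (56 species, 253 samples, no barcode gap) and
  `gapped` (clean positive control).

## Worked example

```r
library(barcodegap)

# positive control: deep splits, tiny within-species diversity
ds  <- generate_dataset(preset_params("gapped", seed = 1))
rep <- run_evaluation(ds$alignments, ds$metadata,
                      outgroup_id = ds$outgroup_id,
                      B = 200, seed = 1, identify = "locusA")
rep$summary
```

Key columns of the one-row summary (distances per 100 sites):

```
n_species        10      variable_pct     28.8
n_samples        30      diagnostic_pct   24.2
mean_intra       0.2     mean_inter        9.3
overlap_fraction 0.0     nj_species        8
blast_species    8
```

All 8 multi-sample species are discriminated by the NJ-tree criterion and
identified perfectly at the first hit (`blast_species` counts species with
every specimen correct at top-1); the two singleton species are reported
separately. The same pipeline under the low-divergence ILS preset
(`fraxinus_like`, locus `spacer698`, seed 1) returns

```
n_species        55      variable_pct     47.1
n_samples       236      diagnostic_pct   24.8
mean_intra       1.0     mean_inter        2.1
overlap_fraction 0.97    nj_species        7
```

— abundant variation, but almost none of it diagnostic: 97% of
interspecific pairs fall below the maximum intraspecific distance and only
7 of ~49 multi-sample species are discriminated. The contrast between the
two regimes, not either number alone, is the package's point: the failure
under the second regime is a property of the data, not of the method.

## The analysis workflow

The `analysis/` scripts run the full study on synthetic data and write
tables under `results/tables/` (datasets and large artifacts go to
`scratch/`):

1. `01_simulate.R` — generate both preset datasets (FASTA + metadata +
   truth ledger).
2. `02_single_locus_evaluation.R` — per-locus site stats, distances,
   barcode gap, NJ + 1000 bootstraps, delineation.
3. `03_concatenated_options.R` — three-locus barcode "options" with
   missing-locus tolerance and coding-locus indel cleanup.
4. `04_identification.R` — leave-one-out identification summaries.
5. `05_regime_contrast.R` — ten replicates of each regime side by side.

## Using real sequences

The pipeline consumes any aligned FASTA plus a `sample_id species section
source` metadata TSV. To evaluate the published *Fraxinus* cpDNA
benchmark: fetch the GenBank accessions GU991679–GU991721 (*rpoB*),
HM130620–HM130660 (*rpoC1*), HM171487–HM171528 (*matK*),
HM367360–HM367586 (*trnH-psbA*) and HM222716–HM222923 (*rpl32-trnL*),
align each locus (e.g. with MAFFT or ClustalW), build the metadata table
from the record annotations, run `run_evaluation()` with the outgroup
*Jasminum nudiflorum*, and compare the resulting summary against the
shipped published values with `compare_to_reference()`, which reports the
deviation for every column. Exact agreement is not expected — the
published alignments included manual adjustments — but each deviation is
made explicit.
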