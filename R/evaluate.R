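#' Run the full barcode evaluation over one or more datasets
#'
#' Orchestrates the pipeline per dataset definition (single locus or a
#' concatenation of loci): coding-locus indel cleanup, site
#' classification, K2P distances with pairwise deletion, barcode-gap
#' statistics, NJ tree with bootstrap support, outgroup rooting,
#' misidentification flagging, clade-fraction species delineation, and
#' (optionally) leave-one-out identification. The outgroup sample is kept
#' for tree building and rooting but excluded from site statistics,
#' distance summaries, delineation, and identification.
#'
#' @param alignments named list of [locus_alignment()] objects.
#' @param metadata sample metadata covering every sequence.
#' @param datasets named list: dataset name -> character vector of locus
#'   names. Defaults to one dataset per locus.
#' @param coding_loci names of coding loci (autapomorphic indels removed).
#' @param outgroup_id outgroup sample id, or `NULL` for midpoint rooting.
#' @param tau discrimination threshold.
#' @param B bootstrap replicates.
#' @param seed seed governing bootstrap resampling.
#' @param min_overlap minimum comparable columns for a defined K2P rate.
#' @param aligner an [aligner_config()].
#' @param identify dataset names on which to run leave-one-out
#'   identification.
#' @param bin_width histogram bin width, per 100 sites.
#' @return object of class `evaluation_report`: list with `summary` (one
#'   row per dataset: the variation/distance columns of
#'   [summarize_dataset()] plus `nj_species`, `n_monospecific_groups`,
#'   `blast_species`, `overlap_fraction`), `datasets` (per-dataset
#'   detail: trees, gap report, delineation, flags, identification), and
#'   `config` (full echo, so every number is recomputable).
#' @export
run_evaluation <- function(alignments, metadata,
                           datasets = NULL, coding_loci = character(),
                           outgroup_id = NULL, tau = 0.5, B = 100L,
                           seed = 1L, min_overlap = 50L,
                           aligner = aligner_config(),
                           identify = character(), bin_width = 0.5) {
  metadata <- validate_metadata(metadata)
  if (is.null(datasets)) {
    datasets <- stats::setNames(as.list(names(alignments)),
                                names(alignments))
  }
  missing_loci <- setdiff(unique(unlist(datasets)), names(alignments))
  if (length(missing_loci) > 0L)
    stop("dataset definitions name unknown loci: ",
         paste(missing_loci, collapse = ", "))

  # coding-locus cleanup once, upfront
  strip_logs <- list()
  for (lc in intersect(coding_loci, names(alignments))) {
    st <- strip_autapomorphic_indels(alignments[[lc]], coding = TRUE)
    alignments[[lc]] <- st$alignment
    strip_logs[[lc]] <- st$log
  }

  details <- list()
  rows <- list()
  for (ds_name in names(datasets)) {
    loci <- datasets[[ds_name]]
    aln <- if (length(loci) == 1L) alignments[[loci]] else
      concatenate_loci(alignments[loci])
    ingroup_ids <- setdiff(sample_ids(aln), outgroup_id)
    aln_in <- subset_alignment(aln, ingroup_ids)

    sites <- classify_sites(aln_in)
    dm_in <- k2p_distance_matrix(aln_in, min_overlap = min_overlap)
    part <- partition_distances(dm_in, metadata)
    gap <- barcode_gap(part, bin_width = bin_width)

    boot <- bootstrap_support(aln, B = B, seed = seed,
                              min_overlap = min_overlap)
    rooted <- root_at_outgroup(boot$tree, outgroup_id, boot$support)
    dm_full <- k2p_distance_matrix(aln, min_overlap = min_overlap)
    flags <- flag_misidentified(rooted, dm_full, metadata)
    tree_in <- if (!is.null(outgroup_id) &&
                   outgroup_id %in% rooted$tip.label)
      ape::drop.tip(rooted, outgroup_id) else rooted
    delin <- delineate(tree_in, metadata, tau = tau,
                       flagged = flags$sample_id)

    loo <- NULL
    idsum <- NULL
    if (ds_name %in% identify) {
      loo <- loo_identify(aln_in, metadata, cfg = aligner,
                          min_overlap = min_overlap)
      idsum <- identification_summary(loo)
    }

    row <- summarize_dataset(aln_in, dm_in, part, sites, metadata,
                             dataset = ds_name)
    row$nj_species <- count_discriminated(delin)
    row$n_monospecific_groups <- attr(delin, "n_monospecific_groups")
    row$blast_species <- if (is.null(idsum)) NA_integer_ else
      idsum$counts$all_correct_top1
    row$overlap_fraction <- gap$overlap_fraction
    rows[[ds_name]] <- row

    details[[ds_name]] <- list(
      loci = loci, sites = sites, distance_matrix = dm_in,
      partition = part, gap = gap, tree = rooted,
      bootstrap = list(support = boot$support,
                       effective_B = boot$effective_B, B = boot$B),
      flags = flags, delineation = delin, loo = loo,
      identification = idsum)
  }

  structure(list(
    summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    datasets = details,
    strip_logs = strip_logs,
    config = list(datasets = datasets, coding_loci = coding_loci,
                  outgroup_id = outgroup_id, tau = tau, B = B,
                  seed = seed, min_overlap = min_overlap,
                  aligner = unclass(aligner), bin_width = bin_width)),
    class = "evaluation_report")
}

subset_alignment <- function(aln, ids) {
  out <- aln
  out$matrix <- aln$matrix[intersect(rownames(aln$matrix), ids), ,
                           drop = FALSE]
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report over ", nrow(x$summary), " dataset(s):\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' Emits `report.tsv` and `report.json` (summary + config echo), one
#' newick tree per dataset, per-dataset histograms as TSV, and hit tables
#' where identification was run.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$summary, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, config = report$config),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (nm in names(report$datasets)) {
    det <- report$datasets[[nm]]
    write_support_tree(det$tree, file.path(dir, paste0(nm, ".nwk")))
    utils::write.table(det$gap$histogram,
                       file.path(dir, paste0(nm, "_hist.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(det$loo))
      write_hit_table(det$loo, file.path(dir, paste0(nm, "_hits.tsv")))
  }
  invisible(dir)
}

#' Plot intra/interspecific distance histograms
#'
#' Overlaid relative-frequency histograms of intraspecific and
#' interspecific K2P rates per 100 sites, with the overlap fraction in the
#' subtitle.
#'
#' @param gap a `barcode_gap` report.
#' @param title plot title.
#' @return a `ggplot` object.
#' @export
plot_distance_histograms <- function(gap, title = "barcode gap") {
  h <- gap$histogram
  long <- rbind(
    data.frame(bin_mid = h$bin_mid, freq = h$intra_freq,
               set = "intraspecific", stringsAsFactors = FALSE),
    data.frame(bin_mid = h$bin_mid, freq = h$inter_freq,
               set = "interspecific", stringsAsFactors = FALSE))
  ggplot2::ggplot(long, ggplot2::aes(x = bin_mid, y = freq, fill = set)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55,
                      width = diff(h$bin_mid[1:2])) +
    ggplot2::scale_fill_manual(values = c(intraspecific = "#3366cc",
                                          interspecific = "#cc3333")) +
    ggplot2::labs(title = title,
                  subtitle = if (isTRUE(gap$defined))
                    sprintf("overlap fraction %.2f", gap$overlap_fraction)
                  else "gap undefined (no intraspecific pairs)",
                  x = "K2P substitution rate per 100 sites",
                  y = "relative frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Published reference values for the Fraxinus cpDNA benchmark
#'
#' Ships the printed summary table of a published cpDNA barcode evaluation
#' of *Fraxinus* (five dataset configurations: two three-locus
#' concatenations and three single loci) for side-by-side comparison with
#' a pipeline run on the same sequences.
#'
#' @return data frame with the same columns as an evaluation summary.
#' @export
reference_table2 <- function() {
  path <- system.file("extdata", "fraxinus_table2_reference.tsv",
                      package = "barcodegap")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Compare an evaluation summary against reference values
#'
#' Matches datasets by name and reports, for every shared numeric column,
#' the computed value, the reference value, and their deviation.
#'
#' @param summary an evaluation summary data frame (or an
#'   `evaluation_report`).
#' @param reference a reference data frame, by default [reference_table2()].
#' @return long data frame `dataset`, `column`, `value`, `reference`,
#'   `deviation`.
#' @export
compare_to_reference <- function(summary, reference = reference_table2()) {
  if (inherits(summary, "evaluation_report")) summary <- summary$summary
  shared_ds <- intersect(summary$dataset, reference$dataset)
  cols <- setdiff(intersect(names(summary), names(reference)), "dataset")
  cols <- cols[vapply(cols, function(cc) is.numeric(reference[[cc]]) ||
                        all(is.na(reference[[cc]])), logical(1L))]
  out <- list()
  for (ds in shared_ds) {
    a <- summary[summary$dataset == ds, , drop = FALSE]
    b <- reference[reference$dataset == ds, , drop = FALSE]
    for (cc in cols) {
      v <- suppressWarnings(as.numeric(a[[cc]][1L]))
      r <- suppressWarnings(as.numeric(b[[cc]][1L]))
      out[[length(out) + 1L]] <- data.frame(
        dataset = ds, column = cc, value = v, reference = r,
        deviation = v - r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
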