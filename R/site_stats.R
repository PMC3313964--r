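#' Classify alignment columns as variable and parsimony-informative
#'
#' A column is *variable* when it carries at least two distinct unambiguous
#' nucleotide states (gaps, `?` and IUPAC ambiguity codes never contribute
#' states). It is *informative* (diagnostic) when at least two states are
#' each carried by at least two sequences, i.e. parsimony-informative.
#'
#' @param aln a [locus_alignment()] with at least two rows.
#' @return object of class `site_classification`: list with `n_columns`,
#'   sorted column vectors `variable_sites` and `informative_sites`, and a
#'   4 x n_columns `state_counts` matrix over A, C, G, T.
#' @export
classify_sites <- function(aln) {
  mat <- aln$matrix
  if (nrow(mat) < 2L) stop("site classification needs at least 2 sequences")
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  counts <- t(counts)  # 4 x n_columns
  n_states <- colSums(counts > 0)
  n_deep <- colSums(counts >= 2)
  structure(list(
    n_columns = aln$n_columns,
    variable_sites = which(n_states >= 2L),
    informative_sites = which(n_states >= 2L & n_deep >= 2L),
    state_counts = counts
  ), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("sites: ", x$n_columns, " columns, ",
      length(x$variable_sites), " variable (",
      round_half_up(100 * length(x$variable_sites) / x$n_columns), "%), ",
      length(x$informative_sites), " informative (",
      round_half_up(100 * length(x$informative_sites) / x$n_columns),
      "%)\n", sep = "")
  invisible(x)
}

# Table-style rounding: half-up to `digits` decimals (not banker's rounding)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Catalogue indel events in an alignment
#'
#' Each maximal gap run is grouped by its exact (start, end) span; all
#' samples sharing an identical span form one event. Events are classified
#' as `autapomorphic` (one carrier), `clade_diagnostic` (carriers are
#' exactly all members of one or more species, or of one section, and
#' nobody else) or `shared` otherwise. Runs touching the first or last
#' column are flagged as terminal tails (incomplete reads) and excluded.
#'
#' @param aln a [locus_alignment()].
#' @param metadata sample metadata (see [read_metadata()]); may be `NULL`,
#'   in which case classification falls back to carrier counts only.
#' @param outgroup_id optional outgroup sample id: events carried by every
#'   ingroup sample but not the outgroup get a polarity note.
#' @return data frame with columns `locus`, `start`, `end`, `length`,
#'   `n_members`, `classification`, `members` (comma-separated ids), `note`,
#'   sorted by `start`. Coordinates are 1-based inclusive.
#' @export
indel_catalogue <- function(aln, metadata = NULL, outgroup_id = NULL) {
  mat <- aln$matrix
  ids <- rownames(mat)
  spans <- list()
  for (i in seq_len(nrow(mat))) {
    for (r in split_runs(which(mat[i, ] == "-"))) {
      key <- paste(min(r), max(r), sep = ":")
      spans[[key]] <- c(spans[[key]], ids[i])
    }
  }
  if (length(spans) == 0L) return(empty_indel_catalogue(aln$locus))

  out <- lapply(names(spans), function(key) {
    se <- as.integer(strsplit(key, ":")[[1L]])
    members <- sort(spans[[key]])
    terminal <- se[1L] == 1L || se[2L] == aln$n_columns
    note <- if (terminal) "terminal_tail" else ""
    cls <- classify_indel(members, ids, metadata)
    if (!is.null(outgroup_id) && outgroup_id %in% ids) {
      ingroup <- setdiff(ids, outgroup_id)
      if (setequal(members, ingroup))
        note <- paste0(note, if (nzchar(note)) ";", "outgroup lacks state")
    }
    data.frame(locus = aln$locus, start = se[1L], end = se[2L],
               length = se[2L] - se[1L] + 1L, n_members = length(members),
               classification = cls,
               members = paste(members, collapse = ","),
               note = note, terminal = terminal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[!out$terminal, setdiff(names(out), "terminal"), drop = FALSE]
  if (nrow(out) == 0L) return(empty_indel_catalogue(aln$locus))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_indel_catalogue <- function(locus) {
  data.frame(locus = character(), start = integer(), end = integer(),
             length = integer(), n_members = integer(),
             classification = character(), members = character(),
             note = character(), stringsAsFactors = FALSE)
}

classify_indel <- function(members, all_ids, metadata) {
  if (length(members) == 1L) return("autapomorphic")
  if (is.null(metadata)) return("shared")
  md <- metadata[metadata$sample_id %in% all_ids, , drop = FALSE]
  mem_sp <- unique(md$species[md$sample_id %in% members])
  # carriers are all members of >=1 species (union of complete species)?
  full_species <- vapply(mem_sp, function(sp) {
    all(md$sample_id[md$species == sp] %in% members)
  }, logical(1L))
  covered <- all(members %in% md$sample_id[md$species %in% mem_sp])
  if (covered && all(full_species)) return("clade_diagnostic")
  mem_sec <- unique(md$section[md$sample_id %in% members])
  if (length(mem_sec) == 1L &&
      setequal(members, md$sample_id[md$section == mem_sec]))
    return("clade_diagnostic")
  "shared"
}
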