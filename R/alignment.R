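#' @useDynLib barcodegap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Construct a locus alignment
#'
#' A `locus_alignment` stores equal-length aligned sequences for one locus as
#' a character matrix (one row per sample, one column per alignment column,
#' upper-case IUPAC codes plus `-` for alignment gaps and `?` for absent
#' data). Column coordinates are 1-based and inclusive throughout the
#' package.
#'
#' @param seqs named character vector of aligned sequences (names are sample
#'   ids), or a character matrix with one row per sample.
#' @param locus locus name.
#' @return an object of class `locus_alignment`.
#' @export
locus_alignment <- function(seqs, locus = "locus") {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
      stop("sequences must carry unique sample-id names")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[lens != lens[1L]][1L]
      stop("unequal alignment lengths in locus '", locus,
           "' (first offending record: ", bad, ")")
    }
    if (lens[1L] == 0L) stop("empty sequences in locus '", locus, "'")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  bad <- matrix(!(mat %in% IUPAC_CHARS), nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-IUPAC character '", mat[idx[1L], idx[2L]], "' in record '",
         rownames(mat)[idx[1L]], "' at column ", idx[2L])
  }
  structure(list(locus = locus, matrix = mat, n_columns = ncol(mat)),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus, "': ", nrow(x$matrix), " sequences, ",
      x$n_columns, " aligned columns\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.locus_alignment <- function(x, ...) x$matrix

#' @rdname locus_alignment
#' @param x a `locus_alignment`.
#' @export
sample_ids <- function(x) rownames(x$matrix)

#' Sequences as strings
#' @param x a `locus_alignment`.
#' @return named character vector of aligned sequences.
#' @export
alignment_strings <- function(x) {
  stats::setNames(apply(x$matrix, 1L, paste, collapse = ""), sample_ids(x))
}

# integer coding used by the C++ kernels: 0 = non-comparable, 1..4 = ACGT
encode_alignment <- function(aln) {
  mat <- if (inherits(aln, "locus_alignment")) aln$matrix else aln
  code <- match(mat, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  matrix(as.integer(code), nrow = nrow(mat),
         dimnames = list(rownames(mat), NULL))
}

encode_sequence <- function(s) {
  v <- strsplit(toupper(s), "")[[1L]]
  code <- match(v, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  as.integer(code)
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file (IUPAC DNA alphabet plus `-`
#'   gaps and `?` for missing blocks).
#' @param locus_name name recorded for the locus.
#' @return a [locus_alignment()].
#' @export
read_fasta_alignment <- function(path, locus_name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!any(startsWith(readLines(path, warn = FALSE), ">")))
    stop("empty FASTA file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1L))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1L))
  locus_alignment(seqs, locus = locus_name)
}

#' Write an aligned FASTA file
#'
#' @param aln a [locus_alignment()].
#' @param path output path.
#' @param wrap line-wrap width in characters.
#' @export
write_fasta_alignment <- function(aln, path, wrap = 70L) {
  seqs <- alignment_strings(aln)
  seqinr::write.fasta(as.list(seqs), names = names(seqs),
                      file.out = path, nbchar = wrap)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab-separated table with header columns `sample_id`, `species`, `section`
#' and `source`. Source codes `A`, `W`, `H`, `S` are expanded to
#' `arboretum`, `wild`, `herbarium`, `synthetic`.
#'
#' @param path path to the TSV file.
#' @return a data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param md a data frame with the metadata columns.
#' @export
validate_metadata <- function(md) {
  need <- c("sample_id", "species", "section", "source")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  if (any(!nzchar(md$species))) stop("empty species label")
  codes <- c(A = "arboretum", W = "wild", H = "herbarium", S = "synthetic")
  md$source <- ifelse(md$source %in% names(codes),
                      codes[md$source], md$source)
  ok <- md$source %in% codes
  if (any(!ok)) stop("unknown source code: ", md$source[!ok][1L])
  two <- tapply(md$section, md$species, function(s) length(unique(s)))
  if (any(two > 1L))
    stop("species mapped to two sections: ", names(two)[two > 1L][1L])
  md
}

#' @rdname read_metadata
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove autapomorphic indels from a coding-locus alignment
#'
#' In coding loci, insertions or deletions private to a single sample are
#' treated as processing errors. A private insertion (columns where exactly
#' one sample carries residues and all others are gapped) has its columns
#' deleted; a private deletion (a maximal gap run carried by exactly one
#' sample) is logged but the alignment is left unchanged, since nothing can
#' be restored. Non-coding loci are returned untouched.
#'
#' @param aln a [locus_alignment()].
#' @param coding logical; apply the rule only when `TRUE`.
#' @return list with elements `alignment` (cleaned) and `log` (data frame
#'   `sample_id`, `locus`, `type`, `start`, `end`, `length`; 1-based
#'   inclusive columns refer to the input alignment).
#' @export
strip_autapomorphic_indels <- function(aln, coding) {
  log <- data.frame(sample_id = character(), locus = character(),
                    type = character(), start = integer(), end = integer(),
                    length = integer(), stringsAsFactors = FALSE)
  if (!coding) return(list(alignment = aln, log = log))
  mat <- aln$matrix
  n <- nrow(mat)
  gap <- mat == "-"
  drop_cols <- integer()

  # private insertions: runs of columns where exactly one (and always the
  # same) sample is ungapped
  one_res <- colSums(!gap) == 1L
  if (any(one_res)) {
    carrier <- apply(mat[, one_res, drop = FALSE], 2L,
                     function(col) which(col != "-"))
    runs <- split_runs(which(one_res))
    for (r in runs) {
      who <- carrier[match(r, which(one_res))]
      # adjacent single-carrier columns with different carriers are distinct
      # insertion events
      for (sub in unname(split(r, cumsum(c(1L, diff(who) != 0L))))) {
        w <- who[match(sub[1L], r)]
        drop_cols <- c(drop_cols, sub)
        log <- rbind(log, data.frame(
          sample_id = rownames(mat)[w], locus = aln$locus,
          type = "private_insertion", start = min(sub), end = max(sub),
          length = length(sub), stringsAsFactors = FALSE))
      }
    }
  }

  # private deletions: maximal gap runs carried by exactly one sample while
  # all other samples carry residues over the full run
  for (i in seq_len(n)) {
    runs <- split_runs(which(gap[i, ]))
    for (r in runs) {
      others <- gap[-i, r, drop = FALSE]
      if (any(others)) next
      log <- rbind(log, data.frame(
        sample_id = rownames(mat)[i], locus = aln$locus,
        type = "private_deletion", start = min(r), end = max(r),
        length = length(r), stringsAsFactors = FALSE))
    }
  }

  if (length(drop_cols) > 0L) {
    mat <- mat[, -drop_cols, drop = FALSE]
    aln <- locus_alignment(mat, locus = aln$locus)
  }
  if (nrow(log) > 0L) log <- log[order(log$start), , drop = FALSE]
  rownames(log) <- NULL
  list(alignment = aln, log = log)
}

# maximal runs of consecutive integers
split_runs <- function(idx) {
  if (length(idx) == 0L) return(list())
  unname(split(idx, cumsum(c(1L, diff(idx) != 1L))))
}

#' Concatenate locus alignments, tolerating missing loci
#'
#' Samples missing a locus are padded with `?` over that locus' block;
#' a sample appears in the result iff it is present in at least one locus.
#'
#' @param alns list of [locus_alignment()] objects.
#' @param samples optional character vector restricting/ordering the samples.
#' @return an object of class `concat_alignment`: a `locus_alignment` with
#'   extra fields `loci` (names), `blocks` (data frame of 1-based inclusive
#'   column ranges per locus) and `presence` (logical sample x locus matrix).
#' @export
concatenate_loci <- function(alns, samples = NULL) {
  if (length(alns) == 0L) stop("no loci to concatenate")
  loci <- vapply(alns, function(a) a$locus, character(1L))
  if (anyDuplicated(loci)) stop("duplicate locus names")
  all_ids <- unique(unlist(lapply(alns, sample_ids)))
  if (!is.null(samples)) {
    absent <- setdiff(samples, all_ids)
    if (length(absent) > 0L)
      warning("dropping sample(s) absent from every locus: ",
              paste(absent, collapse = ", "))
    all_ids <- intersect(samples, all_ids)
  }
  widths <- vapply(alns, function(a) a$n_columns, integer(1L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  presence <- matrix(FALSE, length(all_ids), length(alns),
                     dimnames = list(all_ids, loci))
  total <- sum(widths)
  mat <- matrix("?", length(all_ids), total, dimnames = list(all_ids, NULL))
  for (k in seq_along(alns)) {
    a <- alns[[k]]
    here <- intersect(all_ids, sample_ids(a))
    presence[here, k] <- TRUE
    mat[here, starts[k]:ends[k]] <- a$matrix[here, , drop = FALSE]
  }
  out <- locus_alignment(mat, locus = paste(loci, collapse = "+"))
  out$loci <- loci
  out$blocks <- data.frame(locus = loci, start = starts, end = ends,
                           stringsAsFactors = FALSE)
  out$presence <- presence
  class(out) <- c("concat_alignment", class(out))
  out
}
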