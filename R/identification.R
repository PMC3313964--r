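#' Configuration for the seed-and-extend local aligner
#'
#' A conventional nucleotide-BLAST-like scoring scheme. A gap of length L
#' costs `gap_open + L * gap_extend` (the first gap character pays
#' open + extend). The banded gapped extension covers every seeded diagonal
#' widened by `band_pad` on each side, so the score equals the full
#' Smith-Waterman optimum whenever the optimal local path stays inside that
#' band.
#'
#' @param word_size exact-match seed length (>= 4).
#' @param match,mismatch per-column scores (mismatch negative).
#' @param gap_open,gap_extend affine gap penalties (negative).
#' @param band_pad extra diagonals added on each side of the seeded band.
#' @param xdrop X-drop threshold for the ungapped extension stage.
#' @param max_hits hits retained per query in [loo_identify()].
#' @param both_strands also align against the reverse complement and keep
#'   the better score.
#' @return list of class `aligner_config`.
#' @export
aligner_config <- function(word_size = 11L, match = 1, mismatch = -2,
                           gap_open = -5, gap_extend = -2, band_pad = 20L,
                           xdrop = 20, max_hits = 10L,
                           both_strands = FALSE) {
  stopifnot(word_size >= 4L, mismatch < 0, gap_open < 0, gap_extend < 0,
            band_pad >= 0L, max_hits >= 1L)
  structure(list(word_size = as.integer(word_size), match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, band_pad = as.integer(band_pad),
                 xdrop = xdrop, max_hits = as.integer(max_hits),
                 both_strands = both_strands),
            class = "aligner_config")
}

revcomp_code <- function(code) {
  # 1=A,2=C,3=G,4=T; complement swaps 1<->4 and 2<->3; 0 stays 0
  comp <- c(4L, 3L, 2L, 1L)
  out <- rev(code)
  nz <- out != 0L
  out[nz] <- comp[out[nz]]
  out
}

#' Local alignment of two ungapped DNA sequences
#'
#' Seed-and-extend local alignment: exact word seeding, ungapped X-drop
#' extension, then banded affine-gap Smith-Waterman over the seeded
#' diagonal band. Gap characters are stripped before indexing; queries
#' shorter than the word size yield no hit.
#'
#' @param query,subject DNA strings (gaps/`?` are stripped).
#' @param cfg an [aligner_config()].
#' @return list with `score`, `hsp_score` (best ungapped segment),
#'   `q_span`, `s_span` (1-based inclusive, `NA` when no hit), `strand`
#'   (`"+"`/`"-"`), and `n_seeds`.
#' @export
local_align <- function(query, subject, cfg = aligner_config()) {
  q <- encode_sequence(gsub("[-?]", "", toupper(query)))
  s <- encode_sequence(gsub("[-?]", "", toupper(subject)))
  if (length(q) < cfg$word_size || length(s) < cfg$word_size)
    return(list(score = 0, hsp_score = 0, q_span = c(NA, NA),
                s_span = c(NA, NA), strand = "+", n_seeds = 0L,
                note = "query or subject shorter than word size"))
  fw <- seed_extend_align(q, s, cfg$word_size, cfg$match, cfg$mismatch,
                          cfg$gap_open, cfg$gap_extend, cfg$band_pad,
                          cfg$xdrop)
  best <- fw
  strand <- "+"
  if (isTRUE(cfg$both_strands)) {
    rv <- seed_extend_align(q, revcomp_code(s), cfg$word_size, cfg$match,
                            cfg$mismatch, cfg$gap_open, cfg$gap_extend,
                            cfg$band_pad, cfg$xdrop)
    if (rv$score > fw$score) { best <- rv; strand <- "-" }
  }
  list(score = best$score, hsp_score = best$hsp_score,
       q_span = c(best$q_start, best$q_end),
       s_span = c(best$s_start, best$s_end),
       strand = strand, n_seeds = best$n_seeds)
}

#' Leave-one-out identification over a labelled alignment
#'
#' Each sequence is queried against all others with the seed-and-extend
#' aligner (the self-hit is excluded by construction). Hits are ranked by
#' descending score, ties broken by smaller K2P distance (taken from the
#' dataset's alignment) and then lexicographic subject id. Queries with no
#' scoring hit are recorded as unidentifiable and excluded from accuracy
#' denominators.
#'
#' @param aln a [locus_alignment()] (sequences are degapped for alignment).
#' @param metadata sample metadata for every sequence.
#' @param cfg an [aligner_config()].
#' @param min_overlap passed to [k2p_distance_matrix()] for the tie-break
#'   distances.
#' @return object of class `loo_result`: list with `hits` (long data frame
#'   `query`, `subject`, `subject_species`, `subject_section`, `score`,
#'   `k2p`, `rank`) and `queries` (per-query data frame with
#'   `rank_first_conspecific`, `top1_correct`, `top3_correct`,
#'   `section_correct_at_top1`, `unidentifiable`).
#' @export
loo_identify <- function(aln, metadata, cfg = aligner_config(),
                         min_overlap = 50L) {
  ids <- sample_ids(aln)
  sp <- metadata$species[match(ids, metadata$sample_id)]
  sec <- metadata$section[match(ids, metadata$sample_id)]
  if (anyNA(sp)) stop("every sequence needs species and section labels")
  n <- length(ids)
  seqs <- lapply(alignment_strings(aln),
                 function(s) encode_sequence(gsub("[-?]", "", s)))
  dm <- k2p_distance_matrix(aln, min_overlap = min_overlap)

  # symmetric score matrix (the aligner is symmetric in its arguments)
  score <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    qi <- seqs[[i]]
    if (length(qi) < cfg$word_size) next
    for (j in (i + 1L):n) {
      sj <- seqs[[j]]
      if (length(sj) < cfg$word_size) next
      r <- seed_extend_align(qi, sj, cfg$word_size, cfg$match, cfg$mismatch,
                             cfg$gap_open, cfg$gap_extend, cfg$band_pad,
                             cfg$xdrop)
      sc <- r$score
      if (isTRUE(cfg$both_strands)) {
        rv <- seed_extend_align(qi, revcomp_code(sj), cfg$word_size,
                                cfg$match, cfg$mismatch, cfg$gap_open,
                                cfg$gap_extend, cfg$band_pad, cfg$xdrop)
        sc <- max(sc, rv$score)
      }
      score[i, j] <- score[j, i] <- sc
    }
  }

  hit_rows <- list()
  qrows <- list()
  for (i in seq_len(n)) {
    sc <- score[i, -i]
    subj <- ids[-i]
    pos <- sc > 0
    if (!any(pos)) {
      qrows[[i]] <- data.frame(
        query = ids[i], species = sp[i], section = sec[i],
        rank_first_conspecific = NA_integer_, top1_correct = NA,
        top3_correct = NA, section_correct_at_top1 = NA,
        unidentifiable = TRUE, stringsAsFactors = FALSE)
      next
    }
    subj <- subj[pos]; sc <- sc[pos]
    kd <- dm$d[ids[i], subj]
    kd[is.na(kd)] <- Inf
    o <- order(-sc, kd, subj)
    subj <- subj[o]; sc <- sc[o]; kd <- kd[o]
    keep <- seq_len(min(length(subj), cfg$max_hits))
    ssp <- sp[match(subj, ids)]
    ssec <- sec[match(subj, ids)]
    hit_rows[[i]] <- data.frame(
      query = ids[i], subject = subj[keep], subject_species = ssp[keep],
      subject_section = ssec[keep], score = sc[keep],
      k2p = ifelse(is.finite(kd[keep]), kd[keep], NA_real_),
      rank = keep, stringsAsFactors = FALSE)
    first_con <- which(ssp == sp[i])[1L]
    qrows[[i]] <- data.frame(
      query = ids[i], species = sp[i], section = sec[i],
      rank_first_conspecific = if (is.na(first_con)) NA_integer_ else
        as.integer(first_con),
      top1_correct = ssp[1L] == sp[i],
      top3_correct = any(ssp[seq_len(min(3L, length(ssp)))] == sp[i]),
      section_correct_at_top1 = ssec[1L] == sec[i],
      unidentifiable = FALSE, stringsAsFactors = FALSE)
  }
  structure(list(hits = do.call(rbind, hit_rows),
                 queries = do.call(rbind, qrows),
                 config = cfg),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  q <- x$queries[!x$queries$unidentifiable, , drop = FALSE]
  cat("loo_result: ", nrow(x$queries), " queries (",
      sum(x$queries$unidentifiable), " unidentifiable); top-1 accuracy ",
      round_half_up(100 * mean(q$top1_correct)), "%\n", sep = "")
  invisible(x)
}

#' Summarize leave-one-out identification results
#'
#' @param loo a `loo_result` from [loo_identify()].
#' @return list (class `identification_summary`) with `per_species`
#'   (fractions correct at top-1 and within top-3), `counts`
#'   (species with all specimens correct at top-1 / top-3; species with
#'   more than half of specimens correct at top-1 / top-3), `per_section`
#'   (percent of individuals ascribed to the right section at top-1),
#'   `section_avg_unweighted`, `section_avg_weighted`, and
#'   `n_unidentifiable`.
#' @export
identification_summary <- function(loo) {
  q <- loo$queries[!loo$queries$unidentifiable, , drop = FALSE]
  per_species <- do.call(rbind, lapply(split(q, q$species), function(g) {
    data.frame(species = g$species[1L], n = nrow(g),
               frac_top1 = mean(g$top1_correct),
               frac_top3 = mean(g$top3_correct), stringsAsFactors = FALSE)
  }))
  rownames(per_species) <- NULL
  counts <- list(
    n_species = nrow(per_species),
    all_correct_top1 = sum(per_species$frac_top1 == 1),
    all_correct_top3 = sum(per_species$frac_top3 == 1),
    majority_top1 = sum(per_species$frac_top1 > 0.5),
    majority_top3 = sum(per_species$frac_top3 > 0.5))
  per_section <- do.call(rbind, lapply(split(q, q$section), function(g) {
    data.frame(section = g$section[1L], n = nrow(g),
               pct_correct = 100 * mean(g$section_correct_at_top1),
               stringsAsFactors = FALSE)
  }))
  rownames(per_section) <- NULL
  structure(list(
    per_species = per_species, counts = counts, per_section = per_section,
    section_avg_unweighted = mean(per_section$pct_correct),
    section_avg_weighted = 100 * mean(q$section_correct_at_top1),
    n_unidentifiable = sum(loo$queries$unidentifiable)),
    class = "identification_summary")
}

#' @export
print.identification_summary <- function(x, ...) {
  cat("identification over ", sum(x$per_species$n), " specimens, ",
      x$counts$n_species, " species\n", sep = "")
  cat("  species with all specimens correct at top-1: ",
      x$counts$all_correct_top1, "\n", sep = "")
  cat("  species with all specimens correct within top-3: ",
      x$counts$all_correct_top3, "\n", sep = "")
  cat("  species with >50% specimens correct at top-1: ",
      x$counts$majority_top1, "\n", sep = "")
  cat("  species with >50% specimens correct within top-3: ",
      x$counts$majority_top3, "\n", sep = "")
  cat("  mean section assignment (unweighted over sections): ",
      round_half_up(x$section_avg_unweighted), "%\n", sep = "")
  invisible(x)
}

#' Write hit tables in a tab-separated outfmt-6-like layout
#'
#' @param loo a `loo_result`.
#' @param path output path.
#' @export
write_hit_table <- function(loo, path) {
  utils::write.table(loo$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
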