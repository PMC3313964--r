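#' Kimura two-parameter distance between two aligned sequences
#'
#' Transitions (`P`) and transversions (`Q`) are counted over the columns in
#' which both sequences carry an unambiguous nucleotide (pairwise deletion:
#' gaps, `?` and IUPAC ambiguity codes are non-comparable). The rate per
#' site is
#' \deqn{d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)}
#' and is undefined when either logarithm argument is non-positive
#' (saturation) or fewer than `min_overlap` comparable columns remain.
#'
#' @param seq_a,seq_b aligned sequences of equal length (strings or
#'   character vectors).
#' @param min_overlap minimum number of comparable columns.
#' @return list with `n_compared`, `P`, `Q`, `d` (`NA` when undefined) and
#'   `reason` (`"ok"`, `"insufficient_overlap"` or `"saturated"`).
#' @export
k2p <- function(seq_a, seq_b, min_overlap = 50L) {
  a <- if (length(seq_a) == 1L) encode_sequence(seq_a) else
    encode_sequence(paste(seq_a, collapse = ""))
  b <- if (length(seq_b) == 1L) encode_sequence(seq_b) else
    encode_sequence(paste(seq_b, collapse = ""))
  if (length(a) != length(b)) stop("sequence length mismatch")
  cnt <- k2p_pair_counts(rbind(a, b))
  k2p_from_counts(cnt$transitions[1L, 2L], cnt$transversions[1L, 2L],
                  cnt$n_compared[1L, 2L], min_overlap)
}

k2p_from_counts <- function(s, v, n, min_overlap) {
  if (n < min_overlap)
    return(list(n_compared = n, P = NA_real_, Q = NA_real_, d = NA_real_,
                reason = "insufficient_overlap"))
  P <- s / n
  Q <- v / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(n_compared = n, P = P, Q = Q, d = NA_real_,
                reason = "saturated"))
  list(n_compared = n, P = P, Q = Q,
       d = -0.5 * log(w1 * sqrt(w2)), reason = "ok")
}

#' Pairwise K2P distance matrix
#'
#' @param aln a [locus_alignment()] (possibly concatenated).
#' @param min_overlap minimum comparable columns per pair; pairs below it
#'   are undefined (`NA`).
#' @return object of class `k2p_dist`: list with symmetric matrix `d`
#'   (diagonal 0, `NA` for undefined entries), matrices `P`, `Q`,
#'   `n_compared`, a character `reason` matrix, and provenance attributes.
#' @export
k2p_distance_matrix <- function(aln, min_overlap = 50L) {
  coded <- encode_alignment(aln)
  if (nrow(coded) < 2L) stop("need at least 2 sequences")
  cnt <- k2p_pair_counts(coded)
  n <- cnt$n_compared
  P <- cnt$transitions / n
  Q <- cnt$transversions / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d <- matrix(NA_real_, nrow(n), ncol(n))
  d[ok] <- -0.5 * log(w1[ok] * sqrt(w2[ok]))
  reason <- matrix("ok", nrow(n), ncol(n))
  reason[!ok] <- "saturated"
  reason[n < min_overlap] <- "insufficient_overlap"
  d[n < min_overlap] <- NA_real_
  diag(d) <- 0
  diag(reason) <- "ok"
  ids <- rownames(coded)
  dimnames(d) <- dimnames(P) <- dimnames(Q) <- dimnames(n) <-
    dimnames(reason) <- list(ids, ids)
  structure(list(d = d, P = P, Q = Q, n_compared = n, reason = reason,
                 locus = aln$locus, min_overlap = min_overlap),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  nu <- sum(is.na(x$d[upper.tri(x$d)]))
  cat("k2p_dist over '", x$locus, "': ", nrow(x$d), " samples, ",
      nu, " undefined pair(s) (min_overlap = ", x$min_overlap, ")\n",
      sep = "")
  invisible(x)
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$d

#' Write a K2P matrix in square PHYLIP distance format
#'
#' Undefined entries are written as `-1.0` (a conventional sentinel; PHYLIP
#' has no missing-value marker).
#'
#' @param dm a `k2p_dist`.
#' @param path output path.
#' @export
write_phylip_dist <- function(dm, path) {
  m <- dm$d
  m[is.na(m)] <- -1
  ids <- sprintf("%-10s", substr(rownames(m), 1L, 10L))
  lines <- c(format(nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(ids[i], paste(sprintf("%.6f", m[i, ]), collapse = " "))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Partition pairwise distances into intra- and interspecific sets
#'
#' Species represented by a single sample are excluded from the
#' intraspecific set and listed in `excluded_singletons`.
#'
#' @param dm a `k2p_dist`.
#' @param metadata sample metadata covering every sample in `dm`.
#' @return object of class `dist_partition`: list with data frames `intra`
#'   (`species`, `id_a`, `id_b`, `d`) and `inter` (`species_a`,
#'   `species_b`, `id_a`, `id_b`, `d`), `excluded_singletons`, and
#'   `n_undefined` (pairs left out because `d` is undefined).
#' @export
partition_distances <- function(dm, metadata) {
  ids <- rownames(dm$d)
  sp <- metadata$species[match(ids, metadata$sample_id)]
  if (anyNA(sp))
    stop("unlabeled sample(s): ",
         paste(ids[is.na(sp)], collapse = ", "))
  n <- length(ids)
  pr <- which(upper.tri(dm$d), arr.ind = TRUE)
  d <- dm$d[pr]
  ok <- !is.na(d)
  same <- sp[pr[, 1L]] == sp[pr[, 2L]]
  tab <- table(sp)
  singletons <- names(tab)[tab == 1L]

  intra <- data.frame(species = sp[pr[ok & same, 1L]],
                      id_a = ids[pr[ok & same, 1L]],
                      id_b = ids[pr[ok & same, 2L]],
                      d = d[ok & same], stringsAsFactors = FALSE)
  inter <- data.frame(species_a = pmin(sp[pr[, 1L]], sp[pr[, 2L]])[ok & !same],
                      species_b = pmax(sp[pr[, 1L]], sp[pr[, 2L]])[ok & !same],
                      id_a = ids[pr[ok & !same, 1L]],
                      id_b = ids[pr[ok & !same, 2L]],
                      d = d[ok & !same], stringsAsFactors = FALSE)
  structure(list(intra = intra, inter = inter,
                 excluded_singletons = singletons,
                 n_undefined = sum(!ok),
                 n_pairs = nrow(pr)),
            class = "dist_partition")
}

#' @export
print.dist_partition <- function(x, ...) {
  cat("dist_partition: ", nrow(x$intra), " intraspecific, ",
      nrow(x$inter), " interspecific, ", x$n_undefined,
      " undefined pair(s); ", length(x$excluded_singletons),
      " singleton species excluded from intra\n", sep = "")
  invisible(x)
}

#' Barcode-gap report
#'
#' Summarizes the separation between intra- and interspecific distance
#' distributions: relative-frequency histograms (per 100 sites), the global
#' overlap fraction (share of interspecific pairs at or below the maximum
#' intraspecific distance), and per-species local gaps
#' (min interspecific distance involving the species minus max
#' intraspecific distance within it).
#'
#' @param part a `dist_partition`.
#' @param bin_width histogram bin width, per 100 sites.
#' @return object of class `barcode_gap`: list with `defined`,
#'   `overlap_fraction`, `max_intra`, `min_inter` (all per 100 sites where
#'   applicable), `histogram` (data frame `bin_mid`, `intra_freq`,
#'   `inter_freq`) and `local_gaps` (per-species data frame, per 100 sites).
#' @export
barcode_gap <- function(part, bin_width = 0.5) {
  if (nrow(part$inter) == 0L) stop("no interspecific distances")
  inter <- part$inter$d * 100
  if (nrow(part$intra) == 0L) {
    return(structure(list(defined = FALSE,
                          note = "all species are singletons; gap undefined",
                          overlap_fraction = NA_real_,
                          max_intra = NA_real_, min_inter = min(inter),
                          histogram = gap_histogram(numeric(), inter, bin_width),
                          local_gaps = NULL),
                     class = "barcode_gap"))
  }
  intra <- part$intra$d * 100
  max_intra <- max(intra)
  overlap <- mean(inter <= max_intra)

  species <- sort(unique(part$intra$species))
  local <- vapply(species, function(sp) {
    mi <- max(part$intra$d[part$intra$species == sp]) * 100
    involved <- part$inter$species_a == sp | part$inter$species_b == sp
    if (!any(involved)) return(NA_real_)
    min(part$inter$d[involved]) * 100 - mi
  }, numeric(1L))

  structure(list(defined = TRUE, overlap_fraction = overlap,
                 max_intra = max_intra, min_inter = min(inter),
                 histogram = gap_histogram(intra, inter, bin_width),
                 local_gaps = data.frame(species = species,
                                         local_gap = unname(local),
                                         stringsAsFactors = FALSE)),
            class = "barcode_gap")
}

gap_histogram <- function(intra, inter, bin_width) {
  top <- max(c(intra, inter, bin_width))
  breaks <- seq(0, top + bin_width, by = bin_width)
  mids <- utils::head(breaks, -1L) + bin_width / 2
  freq <- function(x) {
    if (length(x) == 0L) return(rep(0, length(mids)))
    h <- hist(x, breaks = breaks, plot = FALSE, right = FALSE,
              include.lowest = TRUE)
    h$counts / length(x)
  }
  data.frame(bin_mid = mids, intra_freq = freq(intra),
             inter_freq = freq(inter))
}

#' @export
print.barcode_gap <- function(x, ...) {
  if (!x$defined) {
    cat("barcode_gap: undefined (", x$note, ")\n", sep = "")
    return(invisible(x))
  }
  cat("barcode_gap: overlap fraction ", signif(x$overlap_fraction, 3),
      " (max intra ", signif(x$max_intra, 3), ", min inter ",
      signif(x$min_inter, 3), " per 100 sites)\n", sep = "")
  invisible(x)
}

#' Per-dataset summary of variation and distances
#'
#' Populates the standard summary columns used to compare barcoding
#' datasets: sample/species counts, variable and diagnostic sites with
#' percentages, and min/max/mean intra- and interspecific K2P rates per 100
#' sites.
#'
#' @param aln alignment the matrix was computed from.
#' @param dm a `k2p_dist` on `aln`.
#' @param part a `dist_partition` on `dm`.
#' @param sites a `site_classification` on `aln`.
#' @param metadata sample metadata.
#' @param dataset label for the dataset row.
#' @return one-row data frame (`dataset_summary`), distances per 100 sites.
#' @export
summarize_dataset <- function(aln, dm, part, sites, metadata,
                              dataset = aln$locus) {
  ids <- rownames(dm$d)
  sp <- metadata$species[match(ids, metadata$sample_id)]
  finite <- dm$d[upper.tri(dm$d)]
  finite <- finite[!is.na(finite)] * 100
  intra <- part$intra$d * 100
  inter <- part$inter$d * 100
  data.frame(
    dataset = dataset,
    n_species = length(unique(sp)),
    n_samples = length(ids),
    n_columns = aln$n_columns,
    variable_sites = length(sites$variable_sites),
    variable_pct = round_half_up(100 * length(sites$variable_sites) /
                                   sites$n_columns),
    diagnostic_sites = length(sites$informative_sites),
    diagnostic_pct = round_half_up(100 * length(sites$informative_sites) /
                                     sites$n_columns),
    min_rate = if (length(finite)) round_half_up(min(finite)) else NA_real_,
    max_rate = if (length(finite)) round_half_up(max(finite)) else NA_real_,
    mean_intra = if (length(intra)) round_half_up(mean(intra)) else NA_real_,
    intra_min = if (length(intra)) round_half_up(min(intra)) else NA_real_,
    intra_max = if (length(intra)) round_half_up(max(intra)) else NA_real_,
    mean_inter = if (length(inter)) round_half_up(mean(inter)) else NA_real_,
    inter_min = if (length(inter)) round_half_up(min(inter)) else NA_real_,
    inter_max = if (length(inter)) round_half_up(max(inter)) else NA_real_,
    stringsAsFactors = FALSE)
}
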