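#' Species delineation by the clade-fraction criterion
#'
#' For each species, finds the maximum-cardinality clade of the rooted tree
#' containing only that species' individuals; the species counts as
#' discriminated when that clade holds strictly more than `tau` of its
#' (unflagged) individuals. Singleton species trivially form pure leaves and
#' are reported separately (`singleton = TRUE`, `discriminated = NA`); they
#' are excluded from the headline count in [count_discriminated()].
#'
#' @param tree rooted `phylo` with sample ids as tip labels (node labels,
#'   if present, are read as bootstrap support).
#' @param metadata sample metadata.
#' @param tau discrimination threshold (strict `>`; default 0.5).
#' @param flagged sample ids excluded as probable misidentifications.
#' @return data frame (class `species_delineation`) with one row per
#'   species: `species`, `n_individuals`, `largest_pure_clade`, `fraction`,
#'   `discriminated`, `bootstrap`, `singleton`. The attribute
#'   `"n_monospecific_groups"` counts the maximal pure clades of two or
#'   more individuals across species.
#' @export
delineate <- function(tree, metadata, tau = 0.5, flagged = character()) {
  if (!ape::is.rooted(tree))
    stop("monophyly requires a rooted tree; root it first")
  keep <- setdiff(tree$tip.label, flagged)
  sp <- metadata$species[match(keep, metadata$sample_id)]
  if (anyNA(sp))
    stop("unlabeled tip(s): ", paste(keep[is.na(sp)], collapse = ", "))
  if (length(flagged) > 0L) {
    tree <- ape::drop.tip(tree, intersect(tree$tip.label, flagged))
    keep <- tree$tip.label
    sp <- metadata$species[match(keep, metadata$sample_id)]
  }
  n_tip <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  clade_tips <- lapply(pp, function(ix) tree$tip.label[ix])
  clade_sp <- lapply(clade_tips, function(t) unique(sp[match(t, keep)]))
  pure <- vapply(clade_sp, function(s) length(s) == 1L, logical(1L))
  labs <- tree$node.label

  species <- sort(unique(sp))
  rows <- lapply(species, function(s) {
    n_ind <- sum(sp == s)
    # candidate pure clades for this species (internal nodes + single leaf)
    cand <- which(pure & vapply(clade_sp, function(x) x[1L] == s,
                                logical(1L)))
    sizes <- vapply(cand, function(i) length(clade_tips[[i]]), integer(1L))
    best_size <- if (length(sizes)) max(sizes) else 1L
    boot <- NA_real_
    if (length(sizes) && !is.null(labs)) {
      node <- cand[which.max(sizes)]
      lab <- labs[node]
      if (length(lab) == 1L && nzchar(lab))
        boot <- suppressWarnings(as.numeric(lab))
    }
    frac <- best_size / n_ind
    data.frame(species = s, n_individuals = n_ind,
               largest_pure_clade = best_size, fraction = frac,
               discriminated = if (n_ind == 1L) NA else frac > tau,
               bootstrap = boot, singleton = n_ind == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  # maximal pure clades of size >= 2 (monospecific groups in the tree)
  mono <- 0L
  pure_int <- which(pure)
  if (length(pure_int) > 0L) {
    sets <- clade_tips[pure_int]
    is_maximal <- vapply(seq_along(sets), function(i) {
      !any(vapply(seq_along(sets), function(j) {
        j != i && all(sets[[i]] %in% sets[[j]])
      }, logical(1L)))
    }, logical(1L))
    mono <- sum(is_maximal &
                  vapply(sets, length, integer(1L)) >= 2L)
  }
  attr(out, "n_monospecific_groups") <- mono
  attr(out, "tau") <- tau
  class(out) <- c("species_delineation", class(out))
  out
}

#' Count species discriminated by the tree criterion
#'
#' @param delineations a `species_delineation` from [delineate()].
#' @return number of (multi-sample) species with `discriminated = TRUE`.
#' @export
count_discriminated <- function(delineations) {
  sum(delineations$discriminated, na.rm = TRUE)
}

#' Flag probable misidentifications
#'
#' Advisory heuristic mirroring how aberrant specimens are spotted on a
#' barcoding tree: a sample is flagged when (i) the smallest clade
#' containing it and at least one conspecific also contains individuals of
#' two or more other species, and (ii) its nearest neighbour by K2P
#' distance belongs to a different section. Samples without conspecifics
#' are never flagged.
#'
#' @param tree rooted `phylo`.
#' @param dm a `k2p_dist` over the same samples.
#' @param metadata sample metadata.
#' @return data frame `sample_id`, `reason`, `nearest_id`,
#'   `nearest_species`, `nearest_section`.
#' @export
flag_misidentified <- function(tree, dm, metadata) {
  ids <- tree$tip.label
  sp <- metadata$species[match(ids, metadata$sample_id)]
  sec <- metadata$section[match(ids, metadata$sample_id)]
  pp <- ape::prop.part(tree)
  clade_tips <- lapply(pp, function(ix) tree$tip.label[ix])
  m <- dm$d[ids, ids, drop = FALSE]
  diag(m) <- NA

  out <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    consp <- ids[sp == sp[k] & ids != id]
    if (length(consp) == 0L) next
    # smallest clade containing the sample and any conspecific
    holds <- vapply(clade_tips, function(t) {
      id %in% t && any(consp %in% t)
    }, logical(1L))
    if (!any(holds)) next
    sizes <- vapply(clade_tips, length, integer(1L))
    small <- clade_tips[[which(holds)[which.min(sizes[holds])]]]
    other_sp <- setdiff(unique(sp[match(small, ids)]), sp[k])
    if (length(other_sp) < 2L) next
    dists <- m[k, ]
    if (all(is.na(dists))) next
    # ties at the minimum distance (haplotype sharing) are resolved by
    # majority vote over the tied neighbours' sections
    tied <- which(dists <= min(dists, na.rm = TRUE) + 1e-9)
    if (mean(sec[tied] != sec[k]) <= 0.5) next
    nn <- tied[which.min(dists[tied])]
    reason <- if (length(unique(sec[match(small, ids)])) > 1L)
      "out_of_section_placement" else "distant_from_conspecifics"
    out[[length(out) + 1L]] <- data.frame(
      sample_id = id, reason = reason, nearest_id = ids[nn],
      nearest_species = sp[nn], nearest_section = sec[nn],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(), reason = character(),
                      nearest_id = character(), nearest_species = character(),
                      nearest_section = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
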