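#' Neighbor-joining tree from a K2P distance matrix
#'
#' Classic neighbor joining (iteratively join the pair minimizing the
#' Q criterion; two-point branch-length formulas). Ties in the Q criterion
#' are broken deterministically in favour of the lowest (row, col) pair
#' under the input leaf ordering. Negative branch lengths are clamped to 0
#' with the deficit transferred to the sister edge; the raw values are kept
#' in the `"raw_lengths"` attribute.
#'
#' Undefined distance entries are imputed with the maximum finite entry of
#' the matrix (with a warning), so partially sequenced samples stay in the
#' tree; set `impute = "drop"` to remove such samples instead.
#'
#' @param dm a `k2p_dist` or a symmetric numeric matrix with row/col names.
#' @param impute `"max"` (default) or `"drop"`.
#' @return unrooted `phylo` tree (branch lengths in substitutions/site).
#' @export
nj_tree <- function(dm, impute = c("max", "drop")) {
  impute <- match.arg(impute)
  m <- if (inherits(dm, "k2p_dist")) dm$d else dm
  if (is.null(rownames(m))) stop("distance matrix must have row names")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
    stop("asymmetric distance matrix")
  n_imputed <- 0L
  if (anyNA(m)) {
    if (impute == "drop") {
      while (anyNA(m)) {
        worst <- which.max(rowSums(is.na(m)))
        m <- m[-worst, -worst, drop = FALSE]
      }
    } else {
      mx <- max(m, na.rm = TRUE)
      n_imputed <- sum(is.na(m[upper.tri(m)]))
      warning(n_imputed, " undefined pair(s) imputed with the maximum ",
              "finite distance ", signif(mx, 4))
      m[is.na(m)] <- mx
    }
  }
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 leaves")
  res <- nj_cpp(m)
  phy <- nj_result_to_phylo(res, rownames(m))
  attr(phy, "raw_lengths") <- res$edge_length_raw
  attr(phy, "n_imputed") <- n_imputed
  phy
}

# turn the C++ edge list (0-based ids, tips 0..n-1) into an ape phylo via a
# newick string rooted at the trifurcating center node
nj_result_to_phylo <- function(res, labels) {
  edge <- res$edge
  len <- res$edge_length
  n <- res$n_tip
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(labels[node + 1L])
    parts <- vapply(rows, function(r) {
      paste0(build(edge[r, 2L]), ":", sprintf("%.12g", len[r]))
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(res$center), ";")
  ape::read.tree(text = txt)
}

# canonical keys for the non-trivial bipartitions of an unrooted (or rooted)
# tree: for each internal edge, the tip-label set on the side NOT containing
# the lexicographically smallest label, sorted and pasted. Invariant under
# leaf-order permutation and rooting.
tree_bipartition_keys <- function(phy) {
  n <- ape::Ntip(phy)
  anchor <- min(phy$tip.label)
  pp <- ape::prop.part(phy)
  keys <- vapply(seq_along(pp), function(i) {
    tips <- phy$tip.label[pp[[i]]]
    side <- if (anchor %in% tips) setdiff(phy$tip.label, tips) else tips
    if (length(side) < 2L || length(side) > n - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1L))
  keys[!is.na(keys)]
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes the K2P matrix
#' and NJ tree per replicate, and counts how often each internal bipartition
#' of the original tree occurs among replicate trees. Support (percent of
#' effective replicates) is attached to the original tree's internal nodes.
#' Replicates in which every pairwise distance is undefined are discarded
#' and the effective replicate count reported.
#'
#' @param aln a [locus_alignment()].
#' @param B number of bootstrap replicates.
#' @param seed RNG seed governing all resampling.
#' @param min_overlap passed to [k2p_distance_matrix()].
#' @return list with `tree` (original NJ tree, `node.label` holding support
#'   percentages), `support` (named vector keyed by bipartition),
#'   `effective_B`, and `B`.
#' @export
bootstrap_support <- function(aln, B = 1000L, seed = 1L, min_overlap = 50L) {
  set.seed(seed)
  dm <- k2p_distance_matrix(aln, min_overlap = min_overlap)
  tree <- suppressWarnings(nj_tree(dm))
  keys <- tree_bipartition_keys(tree)
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  coded <- encode_alignment(aln)
  L <- ncol(coded)
  eff <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_aln <- structure(list(locus = aln$locus,
                              matrix = aln$matrix[, idx, drop = FALSE],
                              n_columns = L),
                         class = "locus_alignment")
    rep_dm <- k2p_distance_matrix(rep_aln, min_overlap = min_overlap)
    if (all(is.na(rep_dm$d[upper.tri(rep_dm$d)]))) next
    rep_tree <- try(suppressWarnings(nj_tree(rep_dm)), silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    eff <- eff + 1L
    hit <- keys %in% tree_bipartition_keys(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  support <- if (eff > 0L) 100 * counts / eff else counts * NA_real_
  tree <- annotate_support(tree, support)
  list(tree = tree, support = support, effective_B = eff, B = B)
}

# write support values (keyed by bipartition) onto a tree's node labels
annotate_support <- function(phy, support) {
  n <- ape::Ntip(phy)
  anchor <- min(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- vapply(seq_along(pp), function(i) {
    tips <- phy$tip.label[pp[[i]]]
    side <- if (anchor %in% tips) setdiff(phy$tip.label, tips) else tips
    if (length(side) < 2L || length(side) > n - 2L) return("")
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      sprintf("%g", round(unname(support[key]))) else ""
  }, character(1L))
  phy$node.label <- labs
  phy
}

#' Root a support tree at an outgroup
#'
#' Places the root on the outgroup's pendant edge. Bootstrap supports,
#' being properties of bipartitions, are re-attached after rooting from the
#' supplied table. Without an outgroup, midpoint rooting is applied and the
#' result flagged via the `"rooting"` attribute.
#'
#' @param tree a `phylo` tree.
#' @param outgroup_id leaf label to root at, or `NULL` for midpoint rooting.
#' @param support optional named support vector from [bootstrap_support()].
#' @return rooted `phylo` with attribute `rooting` (`"outgroup"` or
#'   `"midpoint"`).
#' @export
root_at_outgroup <- function(tree, outgroup_id = NULL, support = NULL) {
  if (is.null(outgroup_id)) {
    rooted <- phangorn::midpoint(tree)
    attr(rooted, "rooting") <- "midpoint"
  } else {
    if (!outgroup_id %in% tree$tip.label)
      stop("unknown leaf: ", outgroup_id)
    rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
    attr(rooted, "rooting") <- "outgroup"
  }
  if (!is.null(support)) rooted <- annotate_support(rooted, support)
  rooted
}

#' Write a tree with supports as newick
#'
#' @param tree a `phylo` (node labels carry support, if any).
#' @param path output path.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
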