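# Independent oracles and fixture builders used across the suite.

# brute-force K2P: per-column classification in plain R, then the closed
# form; deliberately independent of the package's counting kernel
r_k2p_oracle <- function(a, b, min_overlap = 1L) {
  va <- strsplit(toupper(a), "")[[1L]]
  vb <- strsplit(toupper(b), "")[[1L]]
  stopifnot(length(va) == length(vb))
  nuc <- c("A", "C", "G", "T")
  cmp <- va %in% nuc & vb %in% nuc
  n <- sum(cmp)
  if (n < min_overlap) return(list(n = n, d = NA_real_))
  ts <- 0L; tv <- 0L
  for (i in which(cmp)) {
    if (va[i] == vb[i]) next
    pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    if (pur[va[i]] == pur[vb[i]]) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
  list(n = n, P = P, Q = Q, d = d)
}

random_sequences <- function(n, L, ids = sprintf("s%02d", seq_len(n))) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L,
              dimnames = list(ids, NULL))
  m
}

# sequences derived from a common ancestor (so pairs are related, not
# saturated): per-row independent substitutions at rate p
related_sequences <- function(n, L, p = 0.05,
                              ids = sprintf("s%02d", seq_len(n))) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- t(vapply(seq_len(n), function(i) {
    v <- anc
    hit <- runif(L) < p
    v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    v
  }, character(L)))
  rownames(m) <- ids
  m
}

mutate_sequence <- function(s, p_sub = 0.08, p_indel = 0.02) {
  v <- strsplit(s, "")[[1L]]
  hit <- runif(length(v)) < p_sub
  v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  out <- character(0)
  i <- 1L
  while (i <= length(v)) {
    r <- runif(1L)
    if (r < p_indel / 2) { i <- i + sample(1:3, 1L); next }
    if (r < p_indel)
      out <- c(out, sample(c("A", "C", "G", "T"), sample(1:3, 1L), TRUE))
    out <- c(out, v[i])
    i <- i + 1L
  }
  paste(out, collapse = "")
}

# ---- exhaustive unrooted-topology oracle -----------------------------------
# Enumerates all unrooted binary topologies on n labelled leaves by
# sequential leaf insertion, precomputing for each the pair-path edge
# incidence matrix A (rows: leaf pairs in upper-triangle order), the
# least-squares hat matrix, and the bipartition key set.

.topo_cache <- new.env(parent = emptyenv())

enumerate_unrooted <- function(n) {
  key <- as.character(n)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  stopifnot(n >= 3L, n <= 7L)
  # edges as 2-column matrices over node ids; leaves are 1..n,
  # internal nodes get ids above 100
  base <- matrix(c(101L, 1L, 101L, 2L, 101L, 3L), ncol = 2L, byrow = TRUE)
  topos <- list(base)
  next_id <- 102L
  for (leaf in seq_len(n)[-(1:3)]) {
    out <- list()
    for (tp in topos) {
      for (e in seq_len(nrow(tp))) {
        u <- tp[e, 1L]; v <- tp[e, 2L]
        w <- next_id
        nt <- rbind(tp[-e, , drop = FALSE],
                    c(u, w), c(w, v), c(w, leaf))
        out[[length(out) + 1L]] <- nt
      }
    }
    next_id <- next_id + 1L
    topos <- out
  }
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  info <- lapply(topos, function(tp) {
    nodes <- sort(unique(as.integer(tp)))
    adj <- lapply(nodes, function(x) integer())
    names(adj) <- as.character(nodes)
    for (e in seq_len(nrow(tp))) {
      u <- as.character(tp[e, 1L]); v <- as.character(tp[e, 2L])
      adj[[u]] <- c(adj[[u]], e)
      adj[[v]] <- c(adj[[v]], e)
    }
    ends <- tp
    # path edges between every leaf pair via DFS
    path_edges <- function(from, to) {
      seen <- character(0)
      found <- NULL
      rec <- function(node, path) {
        if (node == to) { found <<- path; return(TRUE) }
        seen <<- c(seen, as.character(node))
        for (e in adj[[as.character(node)]]) {
          nxt <- if (ends[e, 1L] == node) ends[e, 2L] else ends[e, 1L]
          if (as.character(nxt) %in% seen) next
          if (rec(nxt, c(path, e))) return(TRUE)
        }
        FALSE
      }
      rec(from, integer())
      found
    }
    A <- matrix(0, nrow(pairs), nrow(tp))
    for (p in seq_len(nrow(pairs))) {
      A[p, path_edges(pairs[p, 1L], pairs[p, 2L])] <- 1
    }
    # bipartition keys: leaves on the side of each internal edge not
    # containing leaf 1
    keys <- character(0)
    for (e in seq_len(nrow(tp))) {
      if (tp[e, 1L] <= n || tp[e, 2L] <= n) next
      # leaves reachable from tp[e,2] without crossing edge e
      stack <- tp[e, 2L]
      seen <- as.character(tp[e, 1L])
      leaves <- integer()
      while (length(stack)) {
        x <- stack[1L]; stack <- stack[-1L]
        seen <- c(seen, as.character(x))
        if (x <= n) { leaves <- c(leaves, x); next }
        for (ee in adj[[as.character(x)]]) {
          if (ee == e) next
          nxt <- if (ends[ee, 1L] == x) ends[ee, 2L] else ends[ee, 1L]
          if (!(as.character(nxt) %in% seen)) stack <- c(stack, nxt)
        }
      }
      side <- if (1L %in% leaves) setdiff(seq_len(n), leaves) else leaves
      if (length(side) >= 2L && length(side) <= n - 2L)
        keys <- c(keys, paste(sort(side), collapse = "|"))
    }
    qrA <- qr(A)
    list(A = A, qr = qrA, keys = sort(unique(keys)))
  })
  .topo_cache[[key]] <- list(pairs = pairs, topologies = info)
  .topo_cache[[key]]
}

# residual sum of squares of the best edge-length fit for each topology
ls_residuals <- function(d_vec, enum) {
  vapply(enum$topologies, function(tp) {
    fit <- qr.fitted(tp$qr, d_vec)
    sum((d_vec - fit)^2)
  }, numeric(1L))
}

# bipartition keys of a phylo tree with numeric-index labels "1".."n"
phylo_keys_numeric <- function(phy, n) {
  keys <- barcodegap:::tree_bipartition_keys(phy)
  vapply(strsplit(keys, "\\|"), function(side) {
    side <- sort(as.integer(side))
    full <- seq_len(n)
    if (1L %in% side) side <- setdiff(full, side)
    paste(side, collapse = "|")
  }, character(1L))
}

# small labelled alignment around two clearly separated clades
two_clade_alignment <- function(n_per = 4L, L = 300L, div = 0.15) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  other <- anc
  hit <- runif(L) < div
  other[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  jitter <- function(v) {
    h <- runif(L) < 0.005
    v[h] <- sample(c("A", "C", "G", "T"), sum(h), replace = TRUE)
    v
  }
  rows <- c(lapply(seq_len(n_per), function(i) jitter(anc)),
            lapply(seq_len(n_per), function(i) jitter(other)))
  m <- do.call(rbind, rows)
  rownames(m) <- c(sprintf("a%02d", seq_len(n_per)),
                   sprintf("b%02d", seq_len(n_per)))
  locus_alignment(m, "two_clades")
}

# cached leave-one-out run on a clean-gap dataset, shared across tests
with_gapped_loo <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(preset_params("gapped", seed = 12))
      aln <- ds$alignments$locusA
      ing <- setdiff(sample_ids(aln), ds$outgroup_id)
      cache <<- list(
        ds = ds,
        loo = loo_identify(barcodegap:::subset_alignment(aln, ing),
                           ds$metadata))
    }
    cache
  }
})

toy_metadata <- function(ids, species, section = NULL) {
  if (is.null(section)) section <- rep("sect_A", length(species))
  data.frame(sample_id = ids, species = species, section = section,
             source = "synthetic", stringsAsFactors = FALSE)
}
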