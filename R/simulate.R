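#' Simulation parameters
#'
#' Describes the generative model for a labelled multi-locus barcoding
#' dataset: an ultrametric sectioned species tree, within-species
#' coalescent variation with phenomenological incomplete lineage sorting
#' (ILS), K2P (K80) sequence evolution, indel events in non-coding loci,
#' and optional planted label swaps (misidentifications).
#'
#' @param n_sections number of sections (monophyletic in the species tree).
#' @param species_per_section integer vector (recycled) of species counts.
#' @param samples_per_species either a length-2 range from which counts are
#'   drawn uniformly, or an explicit integer vector (one entry per species,
#'   recycled); singletons (1) are allowed.
#' @param tree_depth species-tree depth `T`, expected substitutions/site
#'   from root to tip of the ingroup.
#' @param min_split_frac minimum internal-node depth as a fraction of
#'   `tree_depth` (floors the shallowest species split).
#' @param theta within-species diversity: height (substitutions/site) of
#'   the within-species coalescent subtrees (clamped below the species'
#'   pendant branch).
#' @param ils probability that a sample's lineage sorts into a different
#'   species of the same section (cross-species haplotype sharing).
#' @param loci list of locus specs: each a list with `name`, `length`,
#'   `rel_rate`, `coding` (logical), `indel_rate` (expected events per
#'   locus, non-coding only), `indel_mean_len`.
#' @param kappa transition/transversion rate ratio of the K80 process.
#' @param sample_counts optional explicit per-species sample counts
#'   (recycled over species in order); overrides `samples_per_species`.
#' @param mislabel_rate fraction of samples whose species label is swapped
#'   across sections (planted misidentifications).
#' @param locus_missing_rate per-sample, per-locus probability of a missing
#'   sequence (amplification failure); every sample keeps at least one
#'   locus.
#' @param outgroup include a distant outgroup sample (attached at
#'   `outgroup_depth_mult * tree_depth`).
#' @param outgroup_depth_mult see `outgroup`.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_sections = 2L, species_per_section = 3L,
                       samples_per_species = c(2L, 6L),
                       tree_depth = 0.02, min_split_frac = 0.05,
                       theta = 0.002, ils = 0,
                       loci = list(list(name = "locusA", length = 600L,
                                        rel_rate = 1, coding = FALSE,
                                        indel_rate = 2,
                                        indel_mean_len = 6)),
                       sample_counts = NULL,
                       kappa = 2, mislabel_rate = 0,
                       locus_missing_rate = 0,
                       outgroup = TRUE, outgroup_depth_mult = 3,
                       seed = 1L) {
  stopifnot(n_sections >= 1L, tree_depth > 0, theta >= 0,
            ils >= 0, ils <= 1, kappa > 0, mislabel_rate >= 0,
            length(loci) >= 1L, !is.null(seed))
  for (lc in loci) stopifnot(lc$length >= 100L)
  structure(list(n_sections = as.integer(n_sections),
                 species_per_section = as.integer(species_per_section),
                 samples_per_species = as.integer(samples_per_species),
                 tree_depth = tree_depth, min_split_frac = min_split_frac,
                 sample_counts = if (is.null(sample_counts)) NULL else
                   as.integer(sample_counts),
                 theta = theta, ils = ils, loci = loci, kappa = kappa,
                 mislabel_rate = mislabel_rate,
                 locus_missing_rate = locus_missing_rate,
                 outgroup = outgroup,
                 outgroup_depth_mult = outgroup_depth_mult,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Named simulation presets
#'
#' Presets are versioned YAML files shipped under `inst/presets/`.
#' `"fraxinus_like"` emulates the low-divergence, ILS-heavy regime of a
#' temperate tree genus (56 species in 6 sections, 253 samples, two spacer
#' loci, heavy intra/inter distance overlap); `"gapped"` is a clean
#' barcode-gap regime (deep species splits, tiny within-species diversity,
#' no ILS) used as a positive control.
#'
#' @param name preset name.
#' @param seed RNG seed stored into the returned parameters.
#' @return a [sim_params()] object.
#' @export
preset_params <- function(name = c("fraxinus_like", "gapped"), seed = 1L) {
  name <- match.arg(name)
  path <- system.file("presets", paste0(name, ".yaml"),
                      package = "barcodegap")
  y <- yaml::read_yaml(path)
  y$loci <- lapply(y$loci, function(lc) {
    lc$length <- as.integer(lc$length)
    lc$coding <- isTRUE(lc$coding)
    lc
  })
  do.call(sim_params, c(y, list(seed = seed)))
}

# affine rescale of an ultrametric tree's internal node depths into
# [lo, hi]; returns the tree with adjusted edge lengths
rescale_depths <- function(phy, lo, hi) {
  n <- ape::Ntip(phy)
  bt <- ape::branching.times(phy)
  if (length(bt) == 1L) {
    new_bt <- stats::setNames(hi, names(bt))
  } else {
    rng <- range(bt)
    if (diff(rng) < 1e-12) {
      new_bt <- stats::setNames(rep(hi, length(bt)), names(bt))
    } else {
      new_bt <- lo + (bt - rng[1L]) / diff(rng) * (hi - lo)
    }
  }
  depth <- c(rep(0, n), new_bt[as.character((n + 1L):(n + phy$Nnode))])
  phy$edge.length <- depth[phy$edge[, 1L]] - depth[phy$edge[, 2L]]
  phy
}

# newick fragment (no trailing ';', no root length) + height of a tree
tree_fragment <- function(phy) {
  txt <- ape::write.tree(phy)
  sub(";$", "", txt)
}

#' Simulate a sectioned ultrametric species tree
#'
#' Sections are monophyletic: a coalescent-shaped backbone over sections
#' (node depths in the top 30% of the tree) carries one coalescent-shaped
#' subtree per section (node depths between `min_split_frac * tree_depth`
#' and 60% of the depth). Uses the current RNG state.
#'
#' @param params a [sim_params()].
#' @return list with `tree` (ultrametric `phylo`, species names as tips,
#'   plus an `outgrp` tip when requested) and `sections` (data frame
#'   `species`, `section`).
#' @export
simulate_species_tree <- function(params) {
  H <- params$tree_depth
  ns <- params$n_sections
  per <- rep_len(params$species_per_section, ns)
  section_names <- sprintf("sect_%s", LETTERS[seq_len(ns)])
  species <- sprintf("sp%02d", seq_len(sum(per)))
  sec_of <- rep(section_names, times = per)

  frags <- character(ns)
  heights <- numeric(ns)
  idx <- 1L
  lo <- params$min_split_frac * H
  for (k in seq_len(ns)) {
    sp_k <- species[idx:(idx + per[k] - 1L)]
    idx <- idx + per[k]
    if (length(sp_k) == 1L) {
      frags[k] <- sp_k
      heights[k] <- 0
    } else {
      sub <- ape::rcoal(length(sp_k), tip.label = sample(sp_k))
      sub <- rescale_depths(sub, lo, 0.6 * H)
      frags[k] <- tree_fragment(sub)
      heights[k] <- max(ape::branching.times(sub))
    }
  }

  if (ns == 1L) {
    ingroup <- frags[1L]
    ingroup_height <- heights[1L]
  } else {
    bb <- ape::rcoal(ns, tip.label = section_names)
    bb <- rescale_depths(bb, 0.7 * H, H)
    bt <- ape::branching.times(bb)
    depth <- c(rep(0, ns), bt[as.character((ns + 1L):(ns + bb$Nnode))])
    build <- function(node) {
      kids <- bb$edge[bb$edge[, 1L] == node, 2L]
      if (length(kids) == 0L) {
        k <- match(bb$tip.label[node], section_names)
        list(frag = frags[k], height = heights[k])
      } else {
        parts <- vapply(kids, function(ch) {
          sub <- build(ch)
          paste0(sub$frag, ":",
                 sprintf("%.12g", depth[node] - sub$height))
        }, character(1L))
        list(frag = paste0("(", paste(parts, collapse = ","), ")"),
             height = depth[node])
      }
    }
    root <- build(ns + 1L)
    ingroup <- root$frag
    ingroup_height <- root$height
  }

  if (isTRUE(params$outgroup)) {
    og_depth <- params$outgroup_depth_mult * H
    txt <- paste0("(", ingroup, ":",
                  sprintf("%.12g", og_depth - ingroup_height),
                  ",outgrp:", sprintf("%.12g", og_depth), ");")
    sections <- rbind(data.frame(species = species, section = sec_of,
                                 stringsAsFactors = FALSE),
                      data.frame(species = "outgrp", section = "outgroup",
                                 stringsAsFactors = FALSE))
  } else {
    txt <- paste0(ingroup, ";")
    sections <- data.frame(species = species, section = sec_of,
                           stringsAsFactors = FALSE)
  }
  list(tree = ape::read.tree(text = txt), sections = sections)
}

#' Simulate a gene tree with phenomenological ILS
#'
#' Each sample's lineage is hosted by its own species, or — with
#' probability `ils`, for ingroup species with section-mates — by a
#' uniformly chosen different species of the same section (incomplete
#' lineage sorting: the lineage sorts with another species' haplotypes,
#' producing cross-species haplotype sharing). The samples hosted at each
#' species tip coalesce in a within-species subtree of height
#' `min(theta, 0.9 * pendant branch)`. Uses the current RNG state.
#'
#' @param species_tree ultrametric `phylo` from [simulate_species_tree()].
#' @param sections its section map.
#' @param sample_species named character vector: sample id -> species.
#' @param theta,ils see [sim_params()].
#' @return list with `tree` (gene tree `phylo` over sample ids) and
#'   `host_moves` (data frame of ILS reassignments: `sample_id`, `species`,
#'   `host_species`).
#' @export
simulate_gene_tree <- function(species_tree, sections, sample_species,
                               theta, ils) {
  ids <- names(sample_species)
  sec_of <- stats::setNames(sections$section, sections$species)
  host <- sample_species
  moved <- rep(FALSE, length(ids))
  for (k in seq_along(ids)) {
    sp <- sample_species[k]
    if (sec_of[sp] == "outgroup") next
    mates <- sections$species[sections$section == sec_of[sp] &
                                sections$species != sp]
    if (length(mates) > 0L && ils > 0 && stats::runif(1L) < ils) {
      host[k] <- if (length(mates) == 1L) mates else sample(mates, 1L)
      moved[k] <- TRUE
    }
  }

  hosted <- split(ids, host)
  occupied <- names(hosted)
  phy <- species_tree
  empty <- setdiff(phy$tip.label, occupied)
  if (length(empty) > 0L) phy <- ape::drop.tip(phy, empty)
  if (is.null(phy) || ape::Ntip(phy) < 2L)
    stop("gene tree needs samples hosted at >= 2 species tips")

  pend <- phy$edge.length[match(seq_len(ape::Ntip(phy)),
                                phy$edge[, 2L])]
  frag <- list()
  for (t in seq_len(ape::Ntip(phy))) {
    sp <- phy$tip.label[t]
    members <- hosted[[sp]]
    if (length(members) == 1L) {
      frag[[sp]] <- list(frag = members, height = 0)
    } else {
      # within-species coalescent height is set by theta; when it exceeds
      # the species' pendant branch the stem is compressed (deep
      # coalescence), which is the intended no-barcode-gap regime
      h <- theta
      sub <- ape::rcoal(length(members), tip.label = sample(members))
      sub <- rescale_depths(sub, 0.2 * h, h)
      frag[[sp]] <- list(frag = tree_fragment(sub), height = h)
    }
  }

  n <- ape::Ntip(phy)
  build <- function(node) {
    kids_e <- which(phy$edge[, 1L] == node)
    if (length(kids_e) == 0L) return(frag[[phy$tip.label[node]]])
    parts <- vapply(kids_e, function(e) {
      sub <- build(phy$edge[e, 2L])
      paste0(sub$frag, ":",
             sprintf("%.12g", max(phy$edge.length[e] - sub$height, 1e-9)))
    }, character(1L))
    list(frag = paste0("(", paste(parts, collapse = ","), ")"), height = 0)
  }
  # heights above are consumed at the pendant edge only; internal edges of
  # the species tree are carried over unchanged
  root <- build(n + 1L)
  gt <- ape::read.tree(text = paste0(root$frag, ";"))
  list(tree = gt,
       host_moves = data.frame(sample_id = ids[moved],
                               species = unname(sample_species[moved]),
                               host_species = unname(host[moved]),
                               stringsAsFactors = FALSE))
}

#' Evolve sequences along a gene tree
#'
#' K80 substitution process (transition/transversion ratio `kappa`,
#' equal base frequencies) along the gene tree, then indel events: random
#' events are placed on uniformly chosen edges (carriers are the tips
#' below), with geometric lengths; deletions blank the carriers' span,
#' insertions add columns carried only by the carriers. Coding loci get no
#' random indels. Explicit `forced_events` can plant specific spans. Uses
#' the current RNG state.
#'
#' @param gene_tree `phylo` with branch lengths in substitutions/site.
#' @param locus_spec one entry of the `loci` list in [sim_params()].
#' @param kappa transition/transversion rate ratio.
#' @param forced_events optional list of lists with `type`
#'   (`"deletion"`/`"insertion"`), `start` (column in the pre-indel
#'   coordinate system), `length`, and `members` (tip labels).
#' @return list with `alignment` (a [locus_alignment()]) and
#'   `indel_ledger` (data frame `locus`, `type`, `start`, `end`, `length`,
#'   `n_members`, `members` in final alignment coordinates).
#' @export
evolve_sequences <- function(gene_tree, locus_spec, kappa,
                             forced_events = NULL) {
  dat <- phangorn::simSeq(gene_tree, l = locus_spec$length,
                          Q = c(1, kappa, 1, 1, kappa, 1),
                          type = "DNA", rate = locus_spec$rel_rate)
  mat <- toupper(as.character(dat))
  rownames(mat) <- names(dat)
  L <- ncol(mat)
  ids <- rownames(mat)

  events <- list()
  if (!isTRUE(locus_spec$coding) &&
      !is.null(locus_spec$indel_rate) && locus_spec$indel_rate > 0) {
    n_ev <- stats::rpois(1L, locus_spec$indel_rate)
    for (k in seq_len(n_ev)) {
      len <- 1L + stats::rgeom(1L, 1 / max(locus_spec$indel_mean_len, 1))
      edge <- sample.int(nrow(gene_tree$edge), 1L)
      members <- tips_below(gene_tree, gene_tree$edge[edge, 2L])
      if (length(members) == length(ids)) next  # whole-tree event invisible
      type <- sample(c("deletion", "insertion"), 1L)
      events[[length(events) + 1L]] <-
        list(type = type, length = len, members = members)
    }
  }
  if (!is.null(forced_events)) {
    events <- c(events, lapply(forced_events, function(ev) {
      ev$forced <- TRUE
      ev
    }))
  }
  apply_indel_events(mat, events, locus_spec$name)
}

tips_below <- function(phy, node) {
  n <- ape::Ntip(phy)
  if (node <= n) return(phy$tip.label[node])
  todo <- node
  tips <- integer()
  while (length(todo) > 0L) {
    x <- todo[1L]
    todo <- todo[-1L]
    kids <- phy$edge[phy$edge[, 1L] == x, 2L]
    tips <- c(tips, kids[kids <= n])
    todo <- c(todo, kids[kids > n])
  }
  phy$tip.label[tips]
}

# place events without mutual overlap: deletions blank spans in the base
# matrix, insertions splice new columns (applied right-to-left); the ledger
# reports final alignment coordinates (1-based inclusive)
apply_indel_events <- function(mat, events, locus_name) {
  L <- ncol(mat)
  ids <- rownames(mat)
  ledger <- list()
  taken <- rep(FALSE, L)  # interior columns already used by an event

  planned <- list()
  for (ev in events) {
    len <- as.integer(ev$length)
    if (!is.null(ev$start)) {
      start <- as.integer(ev$start)
    } else {
      if (len >= L - 2L) next
      start <- NA_integer_
      for (try in seq_len(50L)) {
        cand <- sample.int(L - len - 1L, 1L) + 1L  # interior: avoid col 1/L
        if (!any(taken[cand:(cand + len - 1L)])) { start <- cand; break }
      }
      if (is.na(start)) next
    }
    span <- start:(min(start + len - 1L, L))
    taken[span] <- TRUE
    planned[[length(planned) + 1L]] <-
      list(type = ev$type, start = start, length = len,
           members = ev$members)
  }

  # deletions first (no coordinate changes)
  for (ev in planned) {
    if (ev$type != "deletion") next
    span <- ev$start:(ev$start + ev$length - 1L)
    span <- span[span <= ncol(mat)]
    mat[ev$members, span] <- "-"
  }
  # insertions right-to-left so earlier positions are unaffected
  ins <- Filter(function(ev) ev$type == "insertion", planned)
  if (length(ins) > 0L) {
    ord <- order(vapply(ins, function(e) e$start, integer(1L)),
                 decreasing = TRUE)
    for (ev in ins[ord]) {
      block <- matrix("-", nrow(mat), ev$length)
      block[match(ev$members, ids), ] <-
        sample(c("A", "C", "G", "T"), length(ev$members) * ev$length,
               replace = TRUE)
      mat <- cbind(mat[, seq_len(ev$start - 1L), drop = FALSE], block,
                   mat[, ev$start:ncol(mat), drop = FALSE])
    }
  }

  # final coordinates: shift each event by insertions at earlier positions
  ins_starts <- vapply(Filter(function(e) e$type == "insertion", planned),
                       function(e) e$start, integer(1L))
  ins_lens <- vapply(Filter(function(e) e$type == "insertion", planned),
                     function(e) e$length, integer(1L))
  for (ev in planned) {
    s <- ev$start + sum(ins_lens[ins_starts < ev$start])
    e <- s + ev$length - 1L
    ledger[[length(ledger) + 1L]] <- data.frame(
      locus = locus_name, type = ev$type, start = s, end = e,
      length = ev$length, n_members = length(ev$members),
      members = paste(sort(ev$members), collapse = ","),
      stringsAsFactors = FALSE)
  }
  ledger <- if (length(ledger) > 0L) do.call(rbind, ledger) else
    data.frame(locus = character(), type = character(), start = integer(),
               end = integer(), length = integer(), n_members = integer(),
               members = character(), stringsAsFactors = FALSE)
  list(alignment = locus_alignment(mat, locus = locus_name),
       indel_ledger = ledger)
}

#' Generate a full labelled multi-locus dataset
#'
#' Runs the whole generative model under the parameter set's seed: species
#' tree, per-locus gene trees, sequences with indels, per-locus missing
#' samples, and planted label swaps. Fully reproducible from the seed.
#'
#' @param params a [sim_params()].
#' @return object of class `sim_dataset`: list with `alignments` (named
#'   list of [locus_alignment()]), `metadata` (assigned labels, i.e. with
#'   any planted swaps), `ledger` (truth: species tree and gene trees as
#'   newick, `indel_events`, `label_swaps`, `host_moves`, `true_species`),
#'   `outgroup_id`, and `params`.
#' @export
generate_dataset <- function(params) {
  set.seed(params$seed)
  st <- simulate_species_tree(params)
  species <- st$sections$species[st$sections$section != "outgroup"]

  counts <- if (!is.null(params$sample_counts)) {
    # permute so large-sample species are spread across sections
    stats::setNames(sample(rep_len(params$sample_counts,
                                   length(species))), species)
  } else {
    rng <- range(params$samples_per_species)
    stats::setNames(sample(rng[1L]:rng[2L], length(species),
                           replace = TRUE), species)
  }
  sample_species <- unlist(lapply(species, function(sp) {
    stats::setNames(rep(sp, counts[sp]),
                    sprintf("%s_%02d", sp, seq_len(counts[sp])))
  }))
  outgroup_id <- NULL
  if (isTRUE(params$outgroup)) {
    outgroup_id <- "outgrp_01"
    sample_species <- c(sample_species,
                        stats::setNames("outgrp", outgroup_id))
  }
  ids <- names(sample_species)

  # planted misidentifications: labels swapped across sections
  n_swap <- round(params$mislabel_rate * sum(counts))
  assigned <- sample_species
  swaps <- data.frame(sample_id = character(), true_species = character(),
                      assigned_species = character(),
                      stringsAsFactors = FALSE)
  if (n_swap > 0L) {
    sec_of <- stats::setNames(st$sections$section, st$sections$species)
    multi <- names(counts)[counts >= 2L]
    pool <- ids[sample_species %in% multi]
    victims <- sample(pool, min(n_swap, length(pool)))
    for (v in victims) {
      truth <- sample_species[v]
      elsewhere <- species[sec_of[species] != sec_of[truth]]
      if (length(elsewhere) == 0L) next
      assigned[v] <- if (length(elsewhere) == 1L) elsewhere else
        sample(elsewhere, 1L)
      swaps <- rbind(swaps, data.frame(
        sample_id = v, true_species = truth,
        assigned_species = unname(assigned[v]), stringsAsFactors = FALSE))
    }
  }

  metadata <- data.frame(
    sample_id = ids, species = unname(assigned),
    section = st$sections$section[match(assigned, st$sections$species)],
    source = "synthetic", stringsAsFactors = FALSE)

  # per-sample locus availability drawn jointly so nobody is absent from
  # every locus (the outgroup is always present)
  avail <- matrix(TRUE, length(ids), length(params$loci),
                  dimnames = list(ids, NULL))
  if (params$locus_missing_rate > 0) {
    avail[] <- stats::runif(length(avail)) >= params$locus_missing_rate
    avail[ids == outgroup_id, ] <- TRUE
    none <- rowSums(avail) == 0L
    for (i in which(none)) avail[i, sample.int(ncol(avail), 1L)] <- TRUE
  }

  alignments <- list()
  gene_trees <- character()
  indel_events <- list()
  host_moves <- list()
  for (k_locus in seq_along(params$loci)) {
    lc <- params$loci[[k_locus]]
    present <- ids[avail[, k_locus]]
    gt <- simulate_gene_tree(st$tree, st$sections,
                             sample_species[present],
                             params$theta, params$ils)
    ev <- evolve_sequences(gt$tree, lc, params$kappa)
    alignments[[lc$name]] <- ev$alignment
    gene_trees[lc$name] <- ape::write.tree(gt$tree)
    indel_events[[lc$name]] <- ev$indel_ledger
    host_moves[[lc$name]] <- gt$host_moves
  }

  # every sample survives in at least one locus
  seen <- unique(unlist(lapply(alignments, sample_ids)))
  stopifnot(setequal(seen, ids))

  structure(list(
    alignments = alignments, metadata = metadata,
    ledger = list(species_tree = ape::write.tree(st$tree),
                  sections = st$sections,
                  gene_trees = gene_trees,
                  indel_events = do.call(rbind, indel_events),
                  label_swaps = swaps,
                  host_moves = do.call(rbind, host_moves),
                  true_species = data.frame(sample_id = ids,
                                            species = unname(sample_species),
                                            stringsAsFactors = FALSE)),
    outgroup_id = outgroup_id, params = params),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", nrow(x$metadata), " samples, ",
      length(unique(x$metadata$species)), " species, ",
      length(x$alignments), " locus/loci (seed ", x$params$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the exact formats the readers consume: one aligned FASTA per
#' locus, a metadata TSV, and the truth ledger as JSON.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(ds$alignments))
    write_fasta_alignment(ds$alignments[[nm]],
                          file.path(dir, paste0(nm, ".fasta")))
  write_metadata(ds$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(ds$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
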