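# Double-gene-phylum testing and DFD classification.
#
# A duplication whose two daughter clades contain exactly the same species
# (all extant descendants of the duplication that are sampled in the family)
# is a "double-gene phylum": both copies were retained everywhere, the
# retention signature expected when the copies differentiated in function or
# expression (DFD). Recent duplications show the same signature simply
# because there has been no time for losses, so the verdict is qualified by
# the age of the event.

#' Configuration for double-gene-phylum testing and DFD classification
#'
#' @param tol Allowed missing fraction per daughter clade in `[0, 1)`.
#'   Default 0: strict identical species composition. Exposed because real
#'   assemblies contain gaps.
#' @param ancient_cutoff Age (Mya) above which a fully retained duplication
#'   is considered old enough to suggest functional differentiation rather
#'   than mere lack of time for loss. Default 100: separates the
#'   pre-angiosperm events (~200 Mya) from family-level WGDs (24-70 Mya).
#' @param required_phyla Named list mapping phylum name to a character vector
#'   of 6-letter taxon codes; clusters must cover every listed phylum.
#' @param root_age_ceiling Upper age bound for events mapped to the species
#'   root (Mya, default 350).
#' @param lossy_fraction A daughter clade missing at least this fraction of
#'   the expected species counts as "lost in many species" (default 0.5).
#' @param family_map Optional named character vector mapping taxon code to
#'   taxonomic family; enables the "whole family lost" rule (zero copies in
#'   a family with >= 2 sampled taxa).
#' @param hybrid_taxa Character vector of taxon codes flagged as hybrids /
#'   allopolyploids; they are excluded from completeness denominators and
#'   from duplication inference, and reported separately.
#' @return A list of class `dfd_config`.
#' @export
dfdConfig <- function(tol = 0, ancient_cutoff = 100,
                      required_phyla = list(), root_age_ceiling = 350,
                      lossy_fraction = 0.5, family_map = NULL,
                      hybrid_taxa = character(0)) {
  stopifnot(tol >= 0, tol < 1, ancient_cutoff > 0, root_age_ceiling > 0,
            lossy_fraction > 0, lossy_fraction <= 1)
  structure(list(tol = tol, ancient_cutoff = ancient_cutoff,
                 required_phyla = required_phyla,
                 root_age_ceiling = root_age_ceiling,
                 lossy_fraction = lossy_fraction,
                 family_map = family_map, hybrid_taxa = hybrid_taxa),
            class = "dfd_config")
}

#' Verdict levels for classified duplication events
#' @export
dfdVerdicts <- c("DFD_LIKELY", "RETAINED_RECENT", "NON_DFD_LOSSY",
                 "AMBIGUOUS")

# ---------------------------------------------------------------------------
# cluster detection
# ---------------------------------------------------------------------------

# node is a species-overlap duplication: two child clades share >= 1 taxon
overlapDupFlags <- function(tree) {
  spp <- cladeSpeciesSets(tree)
  kids <- childrenList(tree)
  n <- ape::Ntip(tree) + tree$Nnode
  flag <- logical(n)
  for (v in seq_len(n)) {
    ch <- kids[[v]]
    if (length(ch) < 2L) next
    for (a in seq_along(ch)[-length(ch)])
      for (b in seq((a + 1L), length(ch)))
        if (length(intersect(spp[[ch[a]]], spp[[ch[b]]]))) {
          flag[v] <- TRUE
        }
  }
  flag
}

#' Detect paralog clusters covering every required phylum
#'
#' Walks the rooted gene tree from the root. A clade whose species set
#' covers every required phylum and whose root is not a species-overlap
#' duplication is reported as a cluster; at species-overlap duplication
#' nodes the walk recurses into the children, so duplication-separated
#' copies of the family form separate clusters. Within each cluster the
#' shallowest species-overlap duplication (if any) splits it into
#' sub-lineages named `<cluster>.1`, `<cluster>.2`, ... in input order.
#'
#' @param gene_tree A rooted `gene_tree`; pass `outgroup` to drop outgroup
#'   leaves before detection.
#' @param config A `dfd_config`; `required_phyla` defines coverage.
#' @param outgroup Optional character vector of leaf labels to exclude.
#' @return A list of class `cluster_assignment`; each element has fields
#'   `name`, `node`, `members` (leaf labels), `species`, `coverage` (named
#'   logical over phyla) and `subclusters` (possibly empty list with fields
#'   `name`, `node`, `members`). Empty (with a warning) when no clade covers
#'   all phyla.
#' @export
detectClusters <- function(gene_tree, config, outgroup = NULL) {
  stopifnot(inherits(gene_tree, "gene_tree"), inherits(config, "dfd_config"))
  gt <- gene_tree
  if (!is.null(outgroup) && length(outgroup)) {
    keep <- setdiff(gt$tip.label, outgroup)
    phy <- gt; class(phy) <- "phylo"
    phy <- ape::keep.tip(phy, keep)
    gt <- geneTree(phy, family_tag = gene_tree$labels$family_tag[1L])
  }
  phyla <- config$required_phyla
  spp <- cladeSpeciesSets(gt)
  kids <- childrenList(gt)
  dupf <- overlapDupFlags(gt)
  coverage <- function(v)
    vapply(phyla, function(tax) length(intersect(spp[[v]], tax)) > 0L,
           logical(1L))
  coversAll <- function(v) length(phyla) == 0L || all(coverage(v))
  root <- if (gt$Nnode >= 1L) ape::Ntip(gt) + 1L else 1L
  clusters <- list()
  visit <- function(v) {
    if (!coversAll(v)) return(invisible(NULL))
    if (dupf[v]) {
      for (ch in kids[[v]]) visit(ch)
    } else {
      clusters[[length(clusters) + 1L]] <<- v
    }
    invisible(NULL)
  }
  visit(root)
  if (!length(clusters)) {
    warning("no clade covers all required phyla; empty cluster assignment",
            call. = FALSE)
    out <- list()
    attr(out, "gene_tree") <- gt
    class(out) <- "cluster_assignment"
    return(out)
  }
  leaf_sets <- cladeLeafSets(gt)
  # shallowest overlap-duplication node inside a clade (preorder tie-break)
  depths <- nodeDepths(gt)
  subSplit <- function(cnode, cname) {
    desc <- descendantNodes(gt, cnode)
    dups <- desc[dupf[desc] & desc > ape::Ntip(gt)]
    if (!length(dups)) return(list())
    d <- dups[order(depths[dups], dups)][1L]
    ch <- kids[[d]]
    lapply(seq_along(ch), function(i)
      list(name = paste0(cname, ".", i), node = ch[i],
           members = leaf_sets[[ch[i]]]))
  }
  out <- lapply(seq_along(clusters), function(i) {
    v <- clusters[[i]]
    nm <- as.character(i)
    list(name = nm, node = v, members = leaf_sets[[v]],
         species = spp[[v]],
         coverage = if (length(phyla)) coverage(v) else logical(0),
         subclusters = subSplit(v, nm))
  })
  attr(out, "gene_tree") <- gt
  class(out) <- "cluster_assignment"
  out
}

# all nodes (incl. tips and v itself) in the clade rooted at v
descendantNodes <- function(tree, v) {
  kids <- childrenList(tree)
  acc <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[[1L]]; stack <- stack[-1L]
    acc <- c(acc, x)
    stack <- c(stack, kids[[x]])
  }
  acc
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", length(x), "cluster(s)\n")
  for (cl in x) {
    cat("  cluster ", cl$name, ": ", length(cl$members), " leaves, ",
        length(cl$species), " taxa",
        if (length(cl$subclusters))
          paste0(" (", length(cl$subclusters), " sub-lineages)") else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Rename gene-tree leaves after their cluster placement
#'
#' Each leaf gets the label `<TaxonCode><family_tag><cluster>` where
#' `<cluster>` is its (sub)cluster name; when one species carries several
#' copies in the same (sub)cluster, ordinal letters `.a`, `.b`, ... are
#' appended in input order. Reference labels anchor cluster names: a
#' reference set wholly inside one detected cluster renames that cluster;
#' a reference set split across clusters is a naming conflict. Unanchored
#' clusters are numbered in root-to-tip, left-to-right order, skipping the
#' anchored names.
#'
#' @param assignment A `cluster_assignment` from [detectClusters()].
#' @param reference_labels Named list: cluster name -> character vector of
#'   leaf labels known to belong to it (may be empty).
#' @return A list with `tree` (the renamed `gene_tree`) and `mapping` (data
#'   frame with `old`, `new`, `cluster`).
#' @export
assignClusterNames <- function(assignment, reference_labels = list()) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  gt <- attr(assignment, "gene_tree")
  if (!length(assignment)) stop("empty cluster assignment", call. = FALSE)
  names_out <- rep(NA_character_, length(assignment))
  for (ref_name in names(reference_labels)) {
    labs <- reference_labels[[ref_name]]
    hits <- which(vapply(assignment, function(cl)
      any(labs %in% cl$members), logical(1L)))
    if (length(hits) > 1L)
      stop("naming conflict: reference labels for cluster '", ref_name,
           "' split across ", length(hits), " clusters", call. = FALSE)
    if (length(hits) == 1L) {
      if (!all(labs %in% assignment[[hits]]$members))
        stop("naming conflict: reference labels for cluster '", ref_name,
             "' only partially inside a cluster", call. = FALSE)
      names_out[hits] <- ref_name
    }
  }
  pool <- setdiff(as.character(seq_len(length(assignment) +
                                         length(reference_labels))),
                  names_out)
  names_out[is.na(names_out)] <- pool[seq_len(sum(is.na(names_out)))]
  # leaf -> (sub)cluster name
  leaf_cluster <- stats::setNames(rep(NA_character_, ape::Ntip(gt)),
                                  gt$tip.label)
  for (i in seq_along(assignment)) {
    cl <- assignment[[i]]
    leaf_cluster[cl$members] <- names_out[i]
    for (sc in cl$subclusters) {
      sc_name <- sub(paste0("^", cl$name), names_out[i], sc$name)
      leaf_cluster[sc$members] <- sc_name
    }
  }
  tag <- gt$labels$family_tag[1L]
  taxa <- gt$labels$taxon[match(names(leaf_cluster), gt$labels$raw)]
  new_lab <- rep(NA_character_, length(leaf_cluster))
  grp <- paste(taxa, leaf_cluster, sep = "|")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    base <- paste0(taxa[idx], tag, leaf_cluster[idx])
    if (length(idx) > 1L)
      base <- paste0(base, ".", letters[seq_along(idx)])
    new_lab[idx] <- base
  }
  mapping <- data.frame(old = names(leaf_cluster), new = new_lab,
                        cluster = unname(leaf_cluster),
                        stringsAsFactors = FALSE)
  phy <- gt; class(phy) <- "phylo"
  phy$tip.label <- mapping$new[match(phy$tip.label, mapping$old)]
  list(tree = geneTree(phy, family_tag = tag), mapping = mapping)
}

# ---------------------------------------------------------------------------
# retention completeness & classification
# ---------------------------------------------------------------------------

#' Retention completeness of a duplication event
#'
#' For each daughter clade, the fraction of the duplication's extant
#' descendant species (restricted to species sampled in the family, minus
#' hybrids) that carry a copy from that daughter.
#'
#' @param event One-row slice of the [inferDuplications()] table (or a list
#'   with `species_node`, `child_species_1`, `child_species_2`).
#' @param species_tree The `species_tree` used for reconciliation.
#' @param family_species Character vector of taxon codes with at least one
#'   copy anywhere in the family (the denominator basis); defaults to the
#'   union of the two child sets, but should normally be the full family
#'   species set.
#' @param hybrid_taxa Taxa excluded from the denominator (default none).
#' @return Numeric vector of two fractions in `[0, 1]`.
#' @export
retentionCompleteness <- function(event, species_tree,
                                  family_species = NULL,
                                  hybrid_taxa = character(0)) {
  ch1 <- unlist(event$child_species_1)
  ch2 <- unlist(event$child_species_2)
  s <- event$species_node[[1]]
  if (is.null(family_species)) family_species <- union(ch1, ch2)
  desc <- speciesDescendantTips(species_tree, s)
  D <- setdiff(intersect(desc, family_species), hybrid_taxa)
  if (!length(D))
    stop("inconsistent reconciliation: no sampled descendant species ",
         "under the mapped node", call. = FALSE)
  c(length(intersect(ch1, D)) / length(D),
    length(intersect(ch2, D)) / length(D))
}

speciesDescendantTips <- function(st, node) {
  sets <- cladeLeafSets(st)
  sets[[node]]
}

#' Is a duplication a double-gene phylum?
#'
#' `TRUE` iff both completeness values are at least `1 - tol`. At `tol = 0`
#' this is exactly the "identical species composition" criterion: both
#' daughter clades contain every sampled descendant species.
#'
#' @param completeness Numeric pair from [retentionCompleteness()].
#' @param tol Allowed missing fraction (default 0).
#' @return Logical scalar.
#' @export
isDoubleGenePhylum <- function(completeness, tol = 0) {
  stopifnot(length(completeness) == 2L, tol >= 0, tol < 1)
  all(completeness >= 1 - tol - 1e-12)
}

#' Classify a duplication event
#'
#' * `DFD_LIKELY`: double-gene phylum and `age_lower >= ancient_cutoff` —
#'   both copies retained everywhere for long enough that functional or
#'   expressional differentiation of the copies is the likely explanation.
#' * `RETAINED_RECENT`: double-gene phylum but younger than the cutoff —
#'   full retention is expected anyway, too recent to be informative.
#' * `NON_DFD_LOSSY`: a daughter clade is incomplete and the losses span at
#'   least one whole configured family (with >= 2 sampled taxa) or at least
#'   `lossy_fraction` of the expected species.
#' * `AMBIGUOUS`: anything else.
#'
#' @param event One-row event slice with `age_lower`.
#' @param completeness Pair from [retentionCompleteness()].
#' @param config A `dfd_config`.
#' @param species_tree The `species_tree` (used to recover the descendant
#'   species set for the loss rules).
#' @param family_species Denominator basis, as in [retentionCompleteness()].
#' @return One of [dfdVerdicts].
#' @export
classifyDfd <- function(event, completeness, config, species_tree = NULL,
                        family_species = NULL) {
  stopifnot(inherits(config, "dfd_config"))
  tol <- config$tol
  if (isDoubleGenePhylum(completeness, tol)) {
    if (event$age_lower[[1]] >= config$ancient_cutoff) return("DFD_LIKELY")
    return("RETAINED_RECENT")
  }
  # at least one daughter lost copies beyond tolerance; is it "lossy"?
  lossy <- FALSE
  if (min(completeness) < 1 - tol) {
    if (min(completeness) <= 1 - config$lossy_fraction) lossy <- TRUE
    if (!lossy && !is.null(config$family_map) && !is.null(species_tree)) {
      desc <- speciesDescendantTips(species_tree, event$species_node[[1]])
      D <- setdiff(desc, config$hybrid_taxa)
      if (!is.null(family_species)) D <- intersect(D, family_species)
      fam <- config$family_map[D]
      for (child in list(unlist(event$child_species_1),
                         unlist(event$child_species_2))) {
        missing <- setdiff(D, child)
        for (f in unique(fam[!is.na(fam)])) {
          fam_taxa <- D[!is.na(fam) & fam == f]
          if (length(fam_taxa) >= 2L && all(fam_taxa %in% missing))
            lossy <- TRUE
        }
      }
    }
  }
  if (lossy) "NON_DFD_LOSSY" else "AMBIGUOUS"
}

#' Fill completeness and verdicts for a table of duplication events
#'
#' Convenience wrapper applying [retentionCompleteness()] and
#' [classifyDfd()] to every row of an [inferDuplications()] table.
#'
#' @param events A `dfd_events` data frame.
#' @param species_tree The `species_tree`.
#' @param config A `dfd_config`.
#' @param family_species Taxa with >= 1 copy anywhere in the family;
#'   defaults to all taxa present in the events' child sets.
#' @return The events table with `completeness_1`, `completeness_2` and
#'   `verdict` filled.
#' @export
classifyEvents <- function(events, species_tree, config,
                           family_species = NULL) {
  if (is.null(family_species))
    family_species <- sort(unique(unlist(c(events$child_species_1,
                                           events$child_species_2))))
  family_species <- setdiff(family_species, config$hybrid_taxa)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, , drop = FALSE]
    comp <- retentionCompleteness(ev, species_tree, family_species,
                                  config$hybrid_taxa)
    events$completeness_1[i] <- comp[1L]
    events$completeness_2[i] <- comp[2L]
    events$verdict[i] <- classifyDfd(ev, comp, config, species_tree,
                                     family_species)
  }
  events
}

# ---------------------------------------------------------------------------
# WGD association
# ---------------------------------------------------------------------------

#' Read a WGD event table
#'
#' Tab-separated with header `name branch_node_label age_min age_max`
#' (and optionally `retention_prob` for simulation use). The branch is
#' identified by the label of the species-tree node (or tip) at its lower,
#' more recent end.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `wgd_table`.
#' @export
readWgdTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "branch_node_label", "age_min", "age_max")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("WGD table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$age_min > tab$age_max))
    stop("WGD table has age_min > age_max", call. = FALSE)
  class(tab) <- c("wgd_table", "data.frame")
  tab
}

wgdTable <- function(name, branch_node_label, age_min, age_max,
                     retention_prob = NULL) {
  tab <- data.frame(name = name, branch_node_label = branch_node_label,
                    age_min = age_min, age_max = age_max,
                    stringsAsFactors = FALSE)
  if (!is.null(retention_prob)) tab$retention_prob <- retention_prob
  if (any(tab$age_min > tab$age_max))
    stop("WGD table has age_min > age_max", call. = FALSE)
  class(tab) <- c("wgd_table", "data.frame")
  tab
}

# resolve a branch label (tip or internal node label) to a node id
resolveSpeciesNode <- function(st, label) {
  i <- match(label, st$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(st$node.label)) {
    j <- match(label, st$node.label)
    if (!is.na(j)) return(ape::Ntip(st) + j)
  }
  m <- regmatches(label, regexec("^node([0-9]+)$", label))[[1L]]
  if (length(m) == 2L) return(as.integer(m[2L]))
  NA_integer_
}

#' Associate a duplication event with known WGD events
#'
#' A WGD is consistent with a duplication when it sits on the species-tree
#' branch covered by the event's age interval — the branch ending at the
#' event's mapped node — and its age interval overlaps
#' `[age_lower, age_upper]`.
#'
#' @param event One-row event slice with `species_node`, `age_lower`,
#'   `age_upper`.
#' @param wgd_table A `wgd_table`.
#' @param species_tree The `species_tree`.
#' @return A data frame of matching WGDs with an `age_consistent` flag;
#'   zero rows when nothing matches.
#' @export
mapToWgd <- function(event, wgd_table, species_tree) {
  nodes <- vapply(wgd_table$branch_node_label,
                  function(l) resolveSpeciesNode(species_tree, l),
                  integer(1L))
  if (anyNA(nodes))
    stop("WGD table refers to unknown species-tree branch label(s): ",
         paste(wgd_table$branch_node_label[is.na(nodes)], collapse = ", "),
         call. = FALSE)
  on_branch <- nodes == event$species_node[[1]]
  hit <- wgd_table[on_branch, , drop = FALSE]
  if (!nrow(hit)) {
    hit$age_consistent <- logical(0)
    return(hit)
  }
  hit$age_consistent <- hit$age_min <= event$age_upper[[1]] &
    hit$age_max >= event$age_lower[[1]]
  hit <- hit[hit$age_consistent, , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

# ---------------------------------------------------------------------------
# recombination potential
# ---------------------------------------------------------------------------

#' Expected genetic distance from a physical distance
#'
#' Multiplies a physical distance (Mb) by an assumed genome-average
#' genetic-to-physical map ratio (cM/Mb, default 2) and flags free
#' recombination when the result reaches 50 cM.
#'
#' @param physical_mb Physical distance in Mb (>= 0).
#' @param ratio Map ratio in cM/Mb (>= 0, default 2).
#' @return A list with `cM` and logical `free_recombination`.
#' @examples
#' expectedGeneticDistance(10)   # 20 cM
#' @export
expectedGeneticDistance <- function(physical_mb, ratio = 2) {
  if (any(physical_mb < 0) || any(ratio < 0))
    stop("physical distance and map ratio must be non-negative",
         call. = FALSE)
  cm <- physical_mb * ratio
  list(cM = cm, free_recombination = cm >= 50)
}

#' Count species retaining at least one copy in each of two clusters
#'
#' The retention headline for a gene family: how many sampled species keep
#' at least one copy in each of two given clusters (for the GUS family, the
#' GUS1 and GUS3 clusters).
#'
#' @param assignment A `cluster_assignment`.
#' @param cluster_a,cluster_b Cluster names (matched against detected
#'   cluster names; sub-lineages of a cluster count toward it).
#' @return Integer count of taxa.
#' @export
countDoubleRetainers <- function(assignment, cluster_a, cluster_b) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  speciesOf <- function(nm) {
    hit <- Filter(function(cl) cl$name == nm, assignment)
    if (!length(hit)) return(character(0))
    hit[[1L]]$species
  }
  length(intersect(speciesOf(cluster_a), speciesOf(cluster_b)))
}
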