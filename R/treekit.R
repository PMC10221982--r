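#' @importFrom ape read.tree write.tree Ntip node.depth.edgelength is.rooted
NULL

# ---------------------------------------------------------------------------
# Newick syntax pre-check
# ---------------------------------------------------------------------------

#' Check Newick syntax and report the offending character offset
#'
#' Scans a Newick string for unbalanced parentheses and unterminated quotes
#' before handing it to the parser, so that malformed input fails with the
#' 1-based character offset of the problem rather than an opaque parser error.
#'
#' @param text A single Newick string.
#' @return Invisibly `TRUE`; errors on malformed input.
#' @keywords internal
checkNewickSyntax <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  been_open <- FALSE
  quote_open <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (!is.na(quote_open)) {
      if (ch == "'") quote_open <- NA_integer_
      next
    }
    if (ch == "'") {
      quote_open <- i
    } else if (ch == "(") {
      if (been_open && depth == 0L)
        stop("Newick parse error: '(' after the tree closed, at character ",
             "offset ", i, call. = FALSE)
      depth <- depth + 1L
      been_open <- TRUE
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character offset ", i,
             call. = FALSE)
    } else if (ch == ";" && depth > 0L) {
      stop("Newick parse error: ';' at character offset ", i,
           " inside ", depth, " unclosed '('", call. = FALSE)
    } else if (ch == "," && depth == 0L) {
      stop("Newick parse error: ',' outside parentheses at character ",
           "offset ", i, call. = FALSE)
    }
  }
  if (!is.na(quote_open))
    stop("Newick parse error: unterminated quote opened at character offset ",
         quote_open, call. = FALSE)
  if (depth > 0L)
    stop("Newick parse error: ", depth,
         " unclosed '(' at end of input (offset ", length(chars), ")",
         call. = FALSE)
  invisible(TRUE)
}

parseNewick <- function(text) {
  checkNewickSyntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("Newick parse error: input rejected by parser", call. = FALSE)
  phy
}

# ---------------------------------------------------------------------------
# Leaf labels
# ---------------------------------------------------------------------------

#' Parse a gene leaf label into taxon code, family tag and cluster suffix
#'
#' Leaf labels follow the convention `<TaxonCode><family_tag><suffix>`, where
#' the taxon code is a fixed 6-letter abbreviation (3-letter genus prefix +
#' 3-letter species prefix, e.g. `Nicsyl` for *Nicotiana sylvestris*) and the
#' suffix encodes the paralog cluster (e.g. `"3"`, `"3.1"`, `"1.a"`, or empty).
#'
#' @param raw Character vector of raw leaf labels.
#' @param family_tag Gene-family tag expected right after the taxon code
#'   (default `"GUS"`).
#' @return A data frame with columns `raw`, `taxon`, `family_tag`,
#'   `cluster_suffix`.
#' @examples
#' parseLeafLabel("NicsylGUS3.1")
#' parseLeafLabel("PhypatGUS1.a")
#' @export
parseLeafLabel <- function(raw, family_tag = "GUS") {
  stopifnot(is.character(raw), length(raw) >= 1L, nzchar(family_tag))
  bad_short <- nchar(raw) < 6L + nchar(family_tag)
  if (any(bad_short))
    stop("labeling error: label(s) too short for 6-char taxon code + '",
         family_tag, "' tag: ", paste(raw[bad_short], collapse = ", "),
         call. = FALSE)
  taxon <- substr(raw, 1L, 6L)
  bad_taxon <- !grepl("^[A-Za-z]{6}$", taxon)
  if (any(bad_taxon))
    stop("labeling error: non-alphabetic taxon code in: ",
         paste(raw[bad_taxon], collapse = ", "), call. = FALSE)
  tag_found <- substr(raw, 7L, 6L + nchar(family_tag))
  bad_tag <- tag_found != family_tag
  if (any(bad_tag))
    stop("labeling error: family tag '", family_tag,
         "' not found after taxon code in: ",
         paste(raw[bad_tag], collapse = ", "), call. = FALSE)
  suffix <- substr(raw, 7L + nchar(family_tag), nchar(raw))
  ok <- grepl("^$|^[0-9]+(\\.[A-Za-z0-9]+)*$", suffix)
  if (any(!ok))
    stop("labeling error: cluster suffix not of form digit[.alnum]: ",
         paste(raw[!ok], collapse = ", "), call. = FALSE)
  data.frame(raw = raw, taxon = taxon, family_tag = family_tag,
             cluster_suffix = suffix, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Species tree
# ---------------------------------------------------------------------------

#' Construct a dated species tree from a phylo object
#'
#' Node ages (in Mya) are recovered from branch lengths under the assumption
#' that the tree is ultrametric: the age of a node is its path length down to
#' any tip. Tips must sit at age 0 within `tol` (relative to tree depth);
#' non-ultrametric input is rejected. Polytomies are allowed.
#'
#' @param phy An `ape::phylo` object with branch lengths, or a Newick string.
#' @param tol Relative tolerance for the ultrametricity check (default 1e-6).
#' @return An object of class `species_tree` (subclassing `phylo`) with an
#'   `ages` element: a numeric vector of node ages indexed tips-first as in
#'   the `phylo` convention.
#' @seealso [readSpeciesTree()], [nodeAges()]
#' @export
speciesTree <- function(phy, tol = 1e-6) {
  if (is.character(phy)) phy <- parseNewick(phy)
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length))
    stop("species tree needs branch lengths to carry node ages", call. = FALSE)
  ntip <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  maxd <- max(depth)
  if (maxd <= 0) stop("species tree has zero depth", call. = FALSE)
  tip_age <- maxd - depth[seq_len(ntip)]
  if (any(abs(tip_age) > tol * max(maxd, 1)))
    stop("species tree is not ultrametric: tip age deviates by up to ",
         format(max(abs(tip_age))), " (tolerance ", tol * max(maxd, 1), ")",
         call. = FALSE)
  ages <- maxd - depth
  ages[seq_len(ntip)] <- 0
  # internal nodes must be strictly older than their children
  par <- phy$edge[, 1L]; chi <- phy$edge[, 2L]
  if (any(ages[par] <= ages[chi]))
    stop("species tree has a zero- or negative-length internal branch; ",
         "every internal node must be strictly older than its children",
         call. = FALSE)
  dup <- duplicated(phy$tip.label)
  if (any(dup))
    stop("duplicate species tip labels: ",
         paste(unique(phy$tip.label[dup]), collapse = ", "), call. = FALSE)
  phy$ages <- ages
  class(phy) <- c("species_tree", "phylo")
  phy
}

#' Node ages of a dated species tree
#'
#' @param x A `species_tree`.
#' @return Numeric vector of ages in Mya, tips first then internal nodes.
#' @export
nodeAges <- function(x) {
  stopifnot(inherits(x, "species_tree"))
  x$ages
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Dated species tree:", ape::Ntip(x), "tips, root age",
      format(max(x$ages)), "Mya\n")
  cat("  tips:", paste(utils::head(x$tip.label, 8L), collapse = ", "),
      if (ape::Ntip(x) > 8L) "..." else "", "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Gene tree
# ---------------------------------------------------------------------------

#' Construct a gene-family tree with parsed leaf labels
#'
#' @param phy An `ape::phylo` object or Newick string. Leaf labels must
#'   follow the `<TaxonCode><family_tag><suffix>` convention and be unique.
#' @param family_tag Family tag used to parse leaf labels (default `"GUS"`).
#' @param resolve_polytomies If `TRUE`, multifurcations are resolved
#'   deterministically in input order (via [ape::multi2di()] with
#'   `random = FALSE`); if `FALSE` (default) the tree is kept as is and
#'   binary-ness is enforced later, by the operations that require it.
#' @return An object of class `gene_tree` (subclassing `phylo`) with a
#'   `labels` element: the data frame returned by [parseLeafLabel()].
#' @export
geneTree <- function(phy, family_tag = "GUS", resolve_polytomies = FALSE) {
  if (is.character(phy)) phy <- parseNewick(phy)
  stopifnot(inherits(phy, "phylo"))
  dup <- duplicated(phy$tip.label)
  if (any(dup))
    stop("validation error: duplicate gene leaf labels: ",
         paste(unique(phy$tip.label[dup]), collapse = ", "), call. = FALSE)
  if (resolve_polytomies && any(tabulate(phy$edge[, 1L]) > 2L))
    phy <- ape::multi2di(phy, random = FALSE)
  labels <- parseLeafLabel(phy$tip.label, family_tag = family_tag)
  phy$labels <- labels
  class(phy) <- c("gene_tree", "phylo")
  phy
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene family tree ('", x$labels$family_tag[1L], "'): ",
      ape::Ntip(x), " leaves, ",
      length(unique(x$labels$taxon)), " taxa\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# IO
# ---------------------------------------------------------------------------

#' Read a Newick tree as a species or gene tree
#'
#' @param text Newick string (use `file` to read from disk instead).
#' @param kind `"species"` or `"gene"`.
#' @param file Optional path to a Newick file; overrides `text`.
#' @param ... Passed to [speciesTree()] or [geneTree()].
#' @return A `species_tree` or `gene_tree`.
#' @export
readNewick <- function(text = NULL, kind = c("species", "gene"), file = NULL,
                       ...) {
  kind <- match.arg(kind)
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE),
                                    collapse = "")
  if (is.null(text)) stop("either 'text' or 'file' must be given")
  phy <- parseNewick(text)
  switch(kind, species = speciesTree(phy, ...), gene = geneTree(phy, ...))
}

#' @rdname readNewick
#' @export
readSpeciesTree <- function(text = NULL, file = NULL, ...)
  readNewick(text, "species", file, ...)

#' @rdname readNewick
#' @export
readGeneTree <- function(text = NULL, file = NULL, ...)
  readNewick(text, "gene", file, ...)

#' Write a tree to a Newick string (or file)
#'
#' Round-trips topology, labels and branch lengths: reading the output back
#' reproduces the tree.
#'
#' @param tree A `phylo`, `species_tree` or `gene_tree`.
#' @param file Optional path; if given the string is also written to disk.
#' @return The Newick string, invisibly if `file` is given.
#' @export
writeNewick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  cls <- class(tree); class(tree) <- "phylo"
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# ---------------------------------------------------------------------------
# Rooting
# ---------------------------------------------------------------------------

#' Re-root a gene tree on an outgroup
#'
#' Roots the tree such that the outgroup clade is one child of the root.
#' Errors if any outgroup label is absent, if the outgroup is all leaves, or
#' if the outgroup cannot be made monophyletic. Idempotent: a tree already
#' rooted on the outgroup is returned unchanged.
#'
#' @param tree A `gene_tree`.
#' @param outgroup_labels Character vector of leaf labels forming the
#'   outgroup.
#' @return A re-rooted `gene_tree`.
#' @export
rootWithOutgroup <- function(tree, outgroup_labels) {
  stopifnot(inherits(tree, "gene_tree"))
  missing <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing))
    stop("outgroup labels absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(outgroup_labels) >= ape::Ntip(tree))
    stop("outgroup cannot be all leaves", call. = FALSE)
  if (isOutgroupRooted(tree, outgroup_labels)) return(tree)
  phy <- tree; class(phy) <- "phylo"
  rooted <- tryCatch(
    ape::root(phy, outgroup = outgroup_labels, resolve.root = TRUE),
    error = function(e) stop("cannot root on outgroup: ", conditionMessage(e),
                             call. = FALSE))
  out <- geneTree(rooted, family_tag = tree$labels$family_tag[1L])
  if (!isOutgroupRooted(out, outgroup_labels)) {
    sets <- cladeLeafSets(out)
    root <- ape::Ntip(out) + 1L
    kids <- out$edge[out$edge[, 1L] == root, 2L]
    best <- kids[which.max(vapply(kids, function(k)
      length(intersect(sets[[k]], outgroup_labels)), integer(1L)))]
    conflicting <- setdiff(sets[[best]], outgroup_labels)
    stop("outgroup is not monophyletic; conflicting leaves: ",
         paste(conflicting, collapse = ", "), call. = FALSE)
  }
  out
}

isOutgroupRooted <- function(tree, outgroup_labels) {
  sets <- cladeLeafSets(tree)
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  any(vapply(kids, function(k) setequal(sets[[k]], outgroup_labels),
             logical(1L)))
}

# ---------------------------------------------------------------------------
# Clade primitives
# ---------------------------------------------------------------------------

#' Leaf labels under every node
#'
#' One postorder pass accumulating, for each node, the labels of the leaves
#' descending from it (a leaf's own set is itself).
#'
#' @param tree A `phylo` (or subclass).
#' @return A list indexed by node number; element `i` is a character vector.
#' @keywords internal
cladeLeafSets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  sets[seq_len(ntip)] <- as.list(tree$tip.label)
  if (nnode > 0L && nrow(tree$edge) > 0L) {
    ord <- ape::reorder.phylo(tree, "postorder")
    for (i in seq_len(nrow(ord$edge))) {
      p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
      sets[[p]] <- c(sets[[p]], sets[[ch]])
    }
  }
  sets
}

#' Species composition of a clade
#'
#' The set of 6-letter taxon codes over the leaves descending from `node`.
#' For a leaf this is a singleton.
#'
#' @param tree A `gene_tree`.
#' @param node Node number (tips are `1..Ntip`, root is `Ntip + 1`). Defaults
#'   to the root.
#' @return Character vector of taxon codes (sorted, unique).
#' @export
leafSpeciesSet <- function(tree, node = ape::Ntip(tree) + 1L) {
  stopifnot(inherits(tree, "gene_tree"))
  if (ape::Ntip(tree) == 1L && node == 1L)
    return(tree$labels$taxon[1L])
  sets <- cladeLeafSets(tree)
  if (node < 1L || node > length(sets)) stop("node not in tree")
  labs <- sets[[node]]
  sort(unique(tree$labels$taxon[match(labs, tree$labels$raw)]))
}

# species set per node, for internal reuse
cladeSpeciesSets <- function(tree) {
  sets <- cladeLeafSets(tree)
  lapply(sets, function(l)
    sort(unique(tree$labels$taxon[match(l, tree$labels$raw)])))
}

# parent lookup vector: parentOf[node] = parent node id (0 for root)
parentVector <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# children lookup: list indexed by node
childrenList <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1L]]] <- c(kids[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  kids
}
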