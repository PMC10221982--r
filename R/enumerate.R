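# Systematic topology enumeration — validation utilities used to sweep the
# reconciliation code against the exhaustive oracle on small instances.

#' Enumerate all rooted binary leaf-labelled topologies
#'
#' Generates every rooted binary tree shape on the given labels (there are
#' `(2n-3)!!` of them) by recursive grafting, returned as Newick strings
#' without branch lengths.
#'
#' @param labels Character vector of leaf labels (1 to ~7; the count grows
#'   as the double factorial).
#' @return Character vector of Newick strings (terminated with `;`).
#' @examples
#' length(enumerateTopologies(c("A", "B", "C")))   # 3
#' @export
enumerateTopologies <- function(labels) {
  stopifnot(length(labels) >= 1L, !anyDuplicated(labels))
  build <- function(labs) {
    if (length(labs) == 1L) return(list(labs[[1L]]))
    prev <- build(labs[-length(labs)])
    x <- labs[[length(labs)]]
    out <- list()
    for (tr in prev) out <- c(out, graftAll(tr, x))
    out
  }
  graftAll <- function(tr, x) {
    res <- list(list(tr, x))                 # onto the edge above tr
    if (is.list(tr)) {
      for (i in 1:2) {
        for (sub in graftAll(tr[[i]], x)) {
          cp <- tr; cp[[i]] <- sub
          res <- c(res, list(cp))
        }
      }
    }
    res
  }
  toNewick <- function(tr) {
    if (!is.list(tr)) return(tr)
    paste0("(", toNewick(tr[[1L]]), ",", toNewick(tr[[2L]]), ")")
  }
  vapply(build(as.list(labels)),
         function(tr) paste0(toNewick(tr), ";"), character(1L))
}

#' Date a cladogram into an ultrametric species tree
#'
#' Assigns ages by node height: tips at 0, every internal node one
#' `age_step` above its tallest child, so that any topology becomes a valid
#' dated (ultrametric) species tree.
#'
#' @param topology Newick string or `phylo` (branch lengths ignored).
#' @param age_step Mya per level (default 50).
#' @return A `species_tree`.
#' @export
datedCladogram <- function(topology, age_step = 50) {
  phy <- if (is.character(topology)) parseNewick(topology) else topology
  stopifnot(inherits(phy, "phylo"))
  n <- ape::Ntip(phy) + phy$Nnode
  h <- numeric(n)
  if (nrow(phy$edge) > 0L) {
    ord <- ape::reorder.phylo(phy, "postorder")
    for (i in seq_len(nrow(ord$edge))) {
      p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
      h[p] <- max(h[p], h[ch] + 1)
    }
    phy$edge.length <- (h[phy$edge[, 1L]] - h[phy$edge[, 2L]]) * age_step
  }
  speciesTree(phy)
}
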