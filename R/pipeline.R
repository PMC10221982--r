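# End-to-end orchestration: root -> reconcile -> classify -> clusters ->
# WGD association, with a machine-readable JSON report.

#' Run the full duplication/DFD analysis on one gene family
#'
#' Convenience front end combining [rootWithOutgroup()], [lcaMap()],
#' [inferDuplications()], [classifyEvents()], [detectClusters()] and
#' [mapToWgd()] into a single call producing a structured report.
#'
#' @param gene_tree A `gene_tree` (rooted, or rootable with `outgroup`).
#' @param species_tree A `species_tree`.
#' @param config A `dfd_config`.
#' @param wgd_table Optional `wgd_table` for event/WGD association.
#' @param outgroup Optional character vector of outgroup leaf labels; used
#'   to root the tree and excluded from cluster detection and
#'   reconciliation.
#' @param reference_labels Optional anchors for cluster naming (see
#'   [assignClusterNames()]).
#' @param family_species Taxa with at least one copy in the family;
#'   defaults to the taxa present in the (ingroup) gene tree.
#' @return A list of class `dfd_report` with elements `events` (classified
#'   `dfd_events` with a `wgd_matches` list-column), `clusters`, `losses`,
#'   `n_leaves`, `taxa`, `hybrids_excluded` and `summary` (character
#'   narrative).
#' @export
dfdScan <- function(gene_tree, species_tree, config = dfdConfig(),
                    wgd_table = NULL, outgroup = NULL,
                    reference_labels = list(), family_species = NULL) {
  stopifnot(inherits(gene_tree, "gene_tree"),
            inherits(species_tree, "species_tree"),
            inherits(config, "dfd_config"))
  gt <- gene_tree
  if (!is.null(outgroup) && length(outgroup)) {
    gt <- rootWithOutgroup(gt, outgroup)
    keep <- setdiff(gt$tip.label, outgroup)
    phy <- gt; class(phy) <- "phylo"
    gt <- geneTree(ape::keep.tip(phy, keep),
                   family_tag = gene_tree$labels$family_tag[1L])
  }
  # hybrids are excluded from inference and reported separately
  hybrids_present <- intersect(config$hybrid_taxa, unique(gt$labels$taxon))
  if (length(hybrids_present)) {
    keep <- gt$tip.label[!gt$labels$taxon %in% hybrids_present]
    phy <- gt; class(phy) <- "phylo"
    gt <- geneTree(ape::keep.tip(phy, keep),
                   family_tag = gene_tree$labels$family_tag[1L])
  }
  if (is.null(family_species)) family_species <- unique(gt$labels$taxon)
  family_species <- setdiff(family_species, config$hybrid_taxa)
  recon <- lcaMap(gt, species_tree)
  events <- inferDuplications(gt, species_tree, recon,
                              root_age_ceiling = config$root_age_ceiling)
  events <- classifyEvents(events, species_tree, config, family_species)
  losses <- countLosses(gt, species_tree, recon)
  clusters <- detectClusters(gt, config)
  named <- NULL
  if (length(clusters) && length(reference_labels))
    named <- assignClusterNames(clusters, reference_labels)
  events$wgd_matches <- rep(list(NULL), nrow(events))
  if (!is.null(wgd_table) && nrow(events)) {
    for (i in seq_len(nrow(events)))
      events$wgd_matches[[i]] <-
        mapToWgd(events[i, , drop = FALSE], wgd_table, species_tree)
  }
  rep <- list(events = events, clusters = clusters, naming = named,
              losses = losses, n_leaves = ape::Ntip(gt),
              taxa = sort(unique(gt$labels$taxon)),
              hybrids_excluded = hybrids_present,
              summary = reportSummary(events, clusters, losses))
  class(rep) <- "dfd_report"
  rep
}

reportSummary <- function(events, clusters, losses) {
  lines <- c(
    sprintf("%d paralog cluster(s) covering every required phylum",
            length(clusters)),
    sprintf("%d duplication event(s) inferred; %d implied loss(es)",
            nrow(events), losses))
  if (nrow(events)) {
    tab <- table(factor(events$verdict, levels = dfdVerdicts))
    lines <- c(lines, sprintf("verdicts: %s",
                              paste(names(tab), tab, sep = "=",
                                    collapse = ", ")))
    for (i in seq_len(nrow(events))) {
      lines <- c(lines, sprintf(
        "event at %s [%g, %g] Mya: completeness (%.2f, %.2f) -> %s",
        events$species_label[i], events$age_lower[i], events$age_upper[i],
        events$completeness_1[i], events$completeness_2[i],
        events$verdict[i]))
    }
  }
  lines
}

#' @export
print.dfd_report <- function(x, ...) {
  cat("DFD scan report\n")
  for (l in x$summary) cat(" ", l, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# JSON serialisation & schema check
# ---------------------------------------------------------------------------

#' Convert a DFD report to a JSON-ready list
#'
#' @param report A `dfd_report`.
#' @return A nested list mirroring the shipped report schema
#'   (`inst/schema/dfd-report-schema.json`).
#' @export
reportToJson <- function(report) {
  stopifnot(inherits(report, "dfd_report"))
  ev <- report$events
  events <- lapply(seq_len(nrow(ev)), function(i) {
    wm <- ev$wgd_matches[[i]]
    list(gene_node = ev$gene_node[i],
         species_label = ev$species_label[i],
         age_lower = ev$age_lower[i],
         age_upper = ev$age_upper[i],
         child_species = list(ev$child_species_1[[i]],
                              ev$child_species_2[[i]]),
         completeness = c(ev$completeness_1[i], ev$completeness_2[i]),
         verdict = ev$verdict[i],
         wgd_matches = if (is.null(wm) || !nrow(wm)) list()
                       else lapply(seq_len(nrow(wm)), function(j)
                         list(name = wm$name[j],
                              age_min = wm$age_min[j],
                              age_max = wm$age_max[j])))
  })
  clusters <- lapply(report$clusters, function(cl)
    list(name = cl$name, members = cl$members, species = cl$species,
         coverage = as.list(cl$coverage),
         subclusters = lapply(cl$subclusters, function(sc)
           list(name = sc$name, members = sc$members))))
  list(n_leaves = report$n_leaves,
       taxa = report$taxa,
       hybrids_excluded = report$hybrids_excluded,
       losses = report$losses,
       events = events,
       clusters = clusters,
       summary = report$summary)
}

#' Validate the structure of a JSON-ready report
#'
#' Checks the presence and types of every field the shipped report schema
#' requires; errors on the first violation.
#'
#' @param x A list from [reportToJson()] (or parsed back from JSON).
#' @return Invisibly `TRUE`.
#' @export
validateReport <- function(x) {
  need <- c("n_leaves", "taxa", "losses", "events", "clusters", "summary")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("report missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(is.numeric(x$n_leaves), is.numeric(x$losses))
  for (ev in x$events) {
    need_ev <- c("gene_node", "species_label", "age_lower", "age_upper",
                 "child_species", "completeness", "verdict")
    miss <- setdiff(need_ev, names(ev))
    if (length(miss))
      stop("event missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (!ev$verdict %in% dfdVerdicts)
      stop("unknown verdict: ", ev$verdict, call. = FALSE)
    if (ev$age_lower > ev$age_upper)
      stop("event with age_lower > age_upper", call. = FALSE)
  }
  for (cl in x$clusters) {
    if (!all(c("name", "members", "species") %in% names(cl)))
      stop("cluster missing name/members/species", call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the pipeline from file inputs to file outputs
#'
#' Reads the gene tree, species tree and (optionally) WGD table from disk,
#' runs [dfdScan()], validates the report, and writes `report.json` plus a
#' plain-text `summary.txt` into `out_dir`. Deterministic given its inputs.
#'
#' @param gene_tree_file,species_tree_file Paths to Newick files.
#' @param out_dir Output directory (created if missing).
#' @param wgd_file Optional path to a WGD TSV.
#' @param config A `dfd_config`.
#' @param outgroup,reference_labels,family_species Passed to [dfdScan()].
#' @param family_tag Family tag for leaf-label parsing (default `"GUS"`).
#' @return The `dfd_report`, invisibly; side effect: files in `out_dir`.
#' @export
runPipeline <- function(gene_tree_file, species_tree_file, out_dir,
                        wgd_file = NULL, config = dfdConfig(),
                        outgroup = NULL, reference_labels = list(),
                        family_species = NULL, family_tag = "GUS") {
  for (f in c(gene_tree_file, species_tree_file, wgd_file))
    if (!is.null(f) && !file.exists(f))
      stop("input file not found: ", f, call. = FALSE)
  gt <- readGeneTree(file = gene_tree_file, family_tag = family_tag)
  st <- readSpeciesTree(file = species_tree_file)
  wgd <- if (!is.null(wgd_file)) readWgdTable(wgd_file) else NULL
  rep <- dfdScan(gt, st, config, wgd_table = wgd, outgroup = outgroup,
                 reference_labels = reference_labels,
                 family_species = family_species)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  js <- reportToJson(rep)
  validateReport(js)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(rep$summary, file.path(out_dir, "summary.txt"))
  invisible(rep)
}
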