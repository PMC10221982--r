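# CDS curation: the record filters applied before tree building.
#
# Rules, in fixed order: discard coding sequences shorter than 300 nt;
# discard those shorter than 800 nt whose annotation does not identify them
# as members of the family (keyword match); discard later records from the
# same species and locus; keep the rest.

filterRules <- c("LEN_LT_300", "LEN_LT_800_UNANNOTATED", "DUP_LOCUS", "KEPT")

#' Build a CDS record table from metadata (and optional sequences)
#'
#' @param meta Data frame with columns `id`, `taxon`, `locus`, `chromosome`,
#'   `length`, `annotation`.
#' @param sequences Optional named character vector of nucleotide sequences;
#'   names must match `meta$id` and lengths must equal `meta$length`.
#' @return A data frame of class `cds_records`.
#' @export
cdsRecords <- function(meta, sequences = NULL) {
  need <- c("id", "taxon", "locus", "chromosome", "length", "annotation")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(meta$length <= 0)) stop("record length must be > 0", call. = FALSE)
  if (anyDuplicated(meta$id))
    stop("duplicate record ids: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  bad <- !grepl("^[A-Za-z]{6}$", meta$taxon)
  if (any(bad))
    stop("invalid 6-letter taxon code(s): ",
         paste(unique(meta$taxon[bad]), collapse = ", "), call. = FALSE)
  rec <- meta[, need]
  if (!is.null(sequences)) {
    idx <- match(rec$id, names(sequences))
    rec$sequence <- unname(sequences[idx])
    have <- !is.na(rec$sequence)
    bad <- have & nchar(rec$sequence) != rec$length
    if (any(bad))
      stop("validation error: sequence length differs from metadata length ",
           "for: ", paste(rec$id[bad], collapse = ", "), call. = FALSE)
  } else {
    rec$sequence <- NA_character_
  }
  class(rec) <- c("cds_records", "data.frame")
  rec
}

#' Read CDS records from a FASTA file and a metadata TSV
#'
#' The metadata TSV must have header
#' `id taxon locus chromosome length annotation`; FASTA ids must match
#' metadata ids one-to-one, and sequence lengths must match the metadata
#' `length` column.
#'
#' @param fasta Path to an (uncompressed) FASTA file.
#' @param meta Path to the metadata TSV.
#' @return A `cds_records` data frame with sequences attached.
#' @export
readRecords <- function(fasta, meta) {
  tab <- utils::read.delim(meta, stringsAsFactors = FALSE,
                           colClasses = "character")
  tab$length <- as.integer(tab$length)
  dna <- ape::read.FASTA(fasta)
  seqs <- vapply(as.character(dna), function(x)
    paste(toupper(x), collapse = ""), character(1L))
  only_fa <- setdiff(names(seqs), tab$id)
  only_meta <- setdiff(tab$id, names(seqs))
  if (length(only_fa) || length(only_meta))
    stop("FASTA/metadata id mismatch; FASTA-only: [",
         paste(only_fa, collapse = ", "), "], metadata-only: [",
         paste(only_meta, collapse = ", "), "]", call. = FALSE)
  cdsRecords(tab, seqs)
}

#' Apply the curation filter rules
#'
#' Rules are applied in fixed order: `LEN_LT_300` (hard minimum length),
#' `LEN_LT_800_UNANNOTATED` (soft minimum length with rescue when the
#' annotation contains a family keyword, case-insensitively), `DUP_LOCUS`
#' (later records from the same taxon and locus are discarded; the
#' first-listed one is kept), else `KEPT`. Every record receives exactly
#' one rule.
#'
#' @param records A `cds_records` data frame.
#' @param annotation_keywords Keywords whose presence in the annotation
#'   rescues a short record (default `c("heparanase", "glucuronidase",
#'   "GUS")`).
#' @param min_len_hard Hard minimum length in nt (default 300).
#' @param min_len_soft Soft minimum length in nt (default 800); must be
#'   `>= min_len_hard`.
#' @return A data frame of class `filter_decisions` with columns `id`,
#'   `kept`, `rule`.
#' @export
applyFilters <- function(records,
                         annotation_keywords = c("heparanase",
                                                 "glucuronidase", "GUS"),
                         min_len_hard = 300L, min_len_soft = 800L) {
  stopifnot(min_len_hard <= min_len_soft)
  n <- nrow(records)
  rule <- rep("KEPT", n)
  rule[records$length < min_len_hard] <- "LEN_LT_300"
  pat <- paste(annotation_keywords, collapse = "|")
  annotated <- grepl(pat, records$annotation, ignore.case = TRUE)
  idx <- rule == "KEPT" & records$length < min_len_soft & !annotated
  rule[idx] <- "LEN_LT_800_UNANNOTATED"
  alive <- rule == "KEPT"
  key <- paste(records$taxon, records$locus, sep = "|")
  dup <- logical(n)
  dup[alive] <- duplicated(key[alive])
  rule[dup] <- "DUP_LOCUS"
  out <- data.frame(id = records$id, kept = rule == "KEPT", rule = rule,
                    stringsAsFactors = FALSE)
  class(out) <- c("filter_decisions", "data.frame")
  out
}

#' Summarise kept record lengths
#'
#' @param records A `cds_records` data frame (normally the kept subset).
#' @return A list with `n`, `median`, `min`, `max`. The median of an even
#'   count is the mean of the central pair.
#' @export
summarizeLengths <- function(records) {
  if (!nrow(records)) stop("no records to summarise", call. = FALSE)
  list(n = nrow(records),
       median = stats::median(records$length),
       min = min(records$length),
       max = max(records$length))
}

#' Collapse tightly clustered same-species paralogs
#'
#' Within each species, copies whose patristic distance on the guide tree is
#' below `threshold` (single-linkage grouping) are collapsed to one
#' representative: the longest CDS, ties broken by lexicographically
#' smallest id. Representatives carry `representative = TRUE` (the
#' "reported in bold" flag); collapsed copies `FALSE`.
#'
#' @param records A `cds_records` data frame whose ids label the guide tree.
#' @param guide_tree A `phylo`/`gene_tree` with branch lengths containing
#'   every record id as a leaf.
#' @param patristic_threshold Distance below which same-species copies are
#'   considered the same tight cluster (substitutions/site, default 0.05).
#' @return The records with added columns `representative` (logical) and
#'   `collapse_group` (integer id of the tight group within the species).
#' @export
collapseTightParalogs <- function(records, guide_tree,
                                  patristic_threshold = 0.05) {
  stopifnot(patristic_threshold > 0)
  phy <- guide_tree; class(phy) <- "phylo"
  absent <- setdiff(records$id, phy$tip.label)
  if (length(absent))
    stop("record(s) absent from guide tree: ",
         paste(absent, collapse = ", "), call. = FALSE)
  dmat <- ape::cophenetic.phylo(phy)
  records$representative <- TRUE
  records$collapse_group <- NA_integer_
  gid <- 0L
  for (tx in unique(records$taxon)) {
    idx <- which(records$taxon == tx)
    if (length(idx) < 2L) {
      gid <- gid + 1L
      records$collapse_group[idx] <- gid
      next
    }
    ids <- records$id[idx]
    sub <- dmat[ids, ids, drop = FALSE]
    # single-linkage components of the graph {d < threshold}
    comp <- seq_along(ids)
    repeat {
      changed <- FALSE
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        if (a != b && sub[a, b] < patristic_threshold &&
            comp[b] != comp[a]) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      gid <- gid + 1L
      members <- idx[comp == cc]
      records$collapse_group[members] <- gid
      if (length(members) > 1L) {
        ord <- order(-records$length[members], records$id[members])
        records$representative[members[ord[-1L]]] <- FALSE
      }
    }
  }
  records
}

#' Flag pseudogenization candidates
#'
#' Short copies (below the soft length threshold) falling in clusters known
#' to lose copies are flagged as possible pseudogenes. Advisory only: the
#' flag marks records for inspection, it removes nothing.
#'
#' @param records A `cds_records` data frame.
#' @param assignment A `cluster_assignment`; leaf labels are matched to
#'   record ids.
#' @param soft_len Length threshold in nt (default 800).
#' @param lossy_clusters Character vector of cluster names with documented
#'   losses.
#' @return Character vector of flagged record ids.
#' @export
flagPseudogenizationCandidates <- function(records, assignment,
                                           soft_len = 800L,
                                           lossy_clusters = character(0)) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cluster_of <- character(0)
  for (cl in assignment) {
    cluster_of[cl$members] <- cl$name
    for (sc in cl$subclusters) cluster_of[sc$members] <- sc$name
  }
  cl <- cluster_of[records$id]
  top <- sub("\\..*$", "", cl)
  flagged <- !is.na(cl) & records$length < soft_len &
    (cl %in% lossy_clusters | top %in% lossy_clusters)
  records$id[flagged]
}
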