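# A small worked dataset: one representative GUS copy set per major plant
# lineage, with a moss outgroup. Five taxa — Physcomitrella patens (moss
# outgroup), Amborella trichopoda (ancestral angiosperms), Ananas comosus
# (monocots), Aquilegia caerulea (basal eudicots), Nicotiana sylvestris
# (eudicots) — carrying 14 full-length GUS coding sequences across the
# three paralog clusters (1, 3, 4), with the two eudicot sub-lineages
# (3.1, 3.2) present as sister Nicotiana copies inside cluster 3.

demoSpeciesNewick <- function()
  paste0("(Phypat:470,(Ambtri:190,(Anacom:170,(Aqucae:130,Nicsyl:130)",
         "Eudicotyledoneae:40)Mesangiospermae:20)Angiospermae:280)",
         "Embryophyta;")

demoGeneNewick <- function()
  paste0("(PhypatGUS1.a:1.20,",
         "((AmbtriGUS3:0.45,(AnacomGUS3.a:0.40,(AqucaeGUS3:0.33,",
         "(NicsylGUS3.1:0.15,NicsylGUS3.2:0.17):0.18):0.07):0.05):0.25,",
         "((AmbtriGUS1:0.42,(AnacomGUS1.1:0.38,(AqucaeGUS1:0.30,",
         "NicsylGUS1.1:0.31):0.08):0.06):0.22,",
         "(AmbtriGUS4:0.48,(AnacomGUS4:0.44,(AqucaeGUS4:0.36,",
         "NicsylGUS4:0.37):0.09):0.07):0.28):0.12):0.30);")

demoMetadata <- function() {
  meta <- data.frame(
    id = c("PhypatGUS1.a",
           "AmbtriGUS1", "AmbtriGUS3", "AmbtriGUS4",
           "AnacomGUS1.1", "AnacomGUS3.a", "AnacomGUS4",
           "AqucaeGUS1", "AqucaeGUS3", "AqucaeGUS4",
           "NicsylGUS1.1", "NicsylGUS3.1", "NicsylGUS3.2", "NicsylGUS4"),
    taxon = c("Phypat",
              "Ambtri", "Ambtri", "Ambtri",
              "Anacom", "Anacom", "Anacom",
              "Aqucae", "Aqucae", "Aqucae",
              "Nicsyl", "Nicsyl", "Nicsyl", "Nicsyl"),
    locus = c("PP1G041200",
              "ATR0705G112", "ATR0512G033", "ATR1104G078",
              "ACO004G1410", "ACO011G0229", "ACO019G0871",
              "AQC002G2204", "AQC005G1133", "AQC007G0416",
              "NS0301G0054", "NS0808G1762", "NS1204G0917", "NS1605G0433"),
    chromosome = c("chr14",
                   "chr7", "chr5", "chr11",
                   "chr4", "chr11", "chr19",
                   "chr2", "chr5", "chr7",
                   "chr3", "chr8", "chr12", "chr16"),
    length = c(1620L,
               1590L, 1608L, 1570L,
               1600L, 1632L, 1545L,
               1612L, 1600L, 1500L,
               1641L, 1626L, 1588L, 750L),
    annotation = c("beta-glucuronidase (GH79)",
                   "heparanase-like protein", "beta-glucuronidase",
                   "heparanase-like protein",
                   "beta-glucuronidase", "heparanase", "heparanase-like",
                   "beta-glucuronidase", "heparanase",
                   "heparanase-like protein",
                   "beta-glucuronidase", "heparanase", "heparanase",
                   "heparanase-like protein, short"),
    stringsAsFactors = FALSE)
  meta
}

demoWgdTable <- function()
  wgdTable(
    name = c("seed_plant_wgd", "angiosperm_ancestor_wgd",
             "eudicot_gamma_hexaploidy", "solanaceae_wgd"),
    branch_node_label = c("Angiospermae", "Angiospermae",
                          "Nicsyl", "Nicsyl"),
    age_min = c(340, 190, 70, 24),
    age_max = c(360, 210, 133, 70))

demoRequiredPhyla <- function()
  list(ancestral_angiosperms = "Ambtri",
       monocots = "Anacom",
       basal_eudicots = "Aqucae",
       eudicots = "Nicsyl")

#' Build the worked demo dataset
#'
#' Returns a small, fully self-contained gene-family dataset: a dated
#' 5-taxon species tree (moss outgroup plus the four main angiosperm
#' phyla), a 14-leaf GUS gene tree with three paralog clusters and the two
#' eudicot sub-lineages inside cluster 3, CDS metadata for curation, a WGD
#' event table, and the phylum membership map used for cluster detection.
#'
#' @param dir Optional directory; if given, `species.nwk`, `gene.nwk`,
#'   `meta.tsv` and `wgd.tsv` are written there.
#' @return A list with `species_tree`, `gene_tree`, `metadata`
#'   (`cds_records`), `wgd_table`, `required_phyla`, `outgroup` (the moss
#'   leaf label) and `reference_labels` (cluster name anchors).
#' @examples
#' demo <- makeDemoFixture()
#' demo$gene_tree
#' @export
makeDemoFixture <- function(dir = NULL) {
  fx <- list(
    species_tree = readSpeciesTree(demoSpeciesNewick()),
    gene_tree = readGeneTree(demoGeneNewick()),
    metadata = cdsRecords(demoMetadata()),
    wgd_table = demoWgdTable(),
    required_phyla = demoRequiredPhyla(),
    outgroup = "PhypatGUS1.a",
    reference_labels = list("1" = "AmbtriGUS1",
                            "3" = "AmbtriGUS3",
                            "4" = "AmbtriGUS4"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeNewick(fx$species_tree, file.path(dir, "species.nwk"))
    writeNewick(fx$gene_tree, file.path(dir, "gene.nwk"))
    meta <- demoMetadata()
    utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(fx$wgd_table),
                       file.path(dir, "wgd.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  fx
}
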