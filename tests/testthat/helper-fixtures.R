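# Shared fixtures, all built in code.

# drop the outgroup from a rooted gene tree
ingroupOf <- function(gene_tree, outgroup) {
  phy <- gene_tree; class(phy) <- "phylo"
  geneTree(ape::keep.tip(phy, setdiff(gene_tree$tip.label, outgroup)),
           family_tag = gene_tree$labels$family_tag[1L])
}

demoIngroup <- function(fx = makeDemoFixture()) {
  gt <- rootWithOutgroup(fx$gene_tree, fx$outgroup)
  ingroupOf(gt, fx$outgroup)
}

# 12-record synthetic curation table exercising every rule
curationTable <- function() {
  data.frame(
    id = sprintf("r%02d", 1:12),
    taxon = c("Aaaaaa", "Aaaaaa", "Aaaaab", "Aaaaab", "Aaaaaa", "Aaaaaa",
              "Aaaaab", "Aaaaac", "Aaaaac", "Aaaaac", "Aaaaad", "Aaaaad"),
    locus = c("L9", "L8", "L7", "L6", "L1", "L1",
              "L1", "L5", "L2", "L2", "L4", "L3"),
    chromosome = paste0("chr", 1:12),
    length = c(250L, 290L, 500L, 750L, 500L, 1600L,
               1600L, 900L, 1700L, 1650L, 295L, 1600L),
    annotation = c("heparanase", "beta-glucuronidase",
                   "hypothetical protein", "unknown protein",
                   "heparanase", "heparanase",
                   "heparanase-like", "hypothetical protein",
                   "glucuronidase family", "heparanase",
                   "GUS", "beta-glucuronidase"),
    stringsAsFactors = FALSE)
}

# expected rules, aligned with curationTable() rows
curationExpectedRules <- function() {
  c(r01 = "LEN_LT_300", r02 = "LEN_LT_300", r03 = "LEN_LT_800_UNANNOTATED",
    r04 = "LEN_LT_800_UNANNOTATED", r05 = "KEPT", r06 = "DUP_LOCUS",
    r07 = "KEPT", r08 = "KEPT", r09 = "KEPT", r10 = "DUP_LOCUS",
    r11 = "LEN_LT_300", r12 = "KEPT")
}

# guide tree + records for paralog collapsing: K1/K2 tight same-species
# pair, K3 distant same-species copy, K4 another species
collapseFixture <- function() {
  tree <- geneTree(
    "((AaaaaaGUS1:0.01,AaaaaaGUS2:0.01):0.5,(AaaaaaGUS3:0.30,AaaaabGUS1:0.10):0.2);")
  rec <- cdsRecords(data.frame(
    id = c("AaaaaaGUS1", "AaaaaaGUS2", "AaaaaaGUS3", "AaaabGUS1x"),
    taxon = c("Aaaaaa", "Aaaaaa", "Aaaaaa", "Aaaaab"),
    locus = paste0("L", 1:4), chromosome = "chr1",
    length = c(1500L, 1550L, 1480L, 1520L),
    annotation = "heparanase", stringsAsFactors = FALSE))
  rec$id[4] <- "AaaabGUS1x"  # deliberately absent from the tree
  list(tree = tree, records = rec)
}

# gene labels with per-taxon ordinals
geneLabelsFor <- function(taxa, tag = "GUS") {
  labs <- character(length(taxa))
  for (tx in unique(taxa)) {
    idx <- which(taxa == tx)
    labs[idx] <- paste0(tx, tag, seq_along(idx))
  }
  labs
}

# a random reconciliation instance: dated species tree on 2..max_taxa taxa,
# gene tree with 2..max_leaves leaves assigned to random taxa
randReconInstance <- function(seed, max_taxa = 5, max_leaves = 7) {
  set.seed(seed)
  taxa <- c("Aaaaaa", "Aaaaab", "Aaaaac", "Aaaaad",
            "Aaaaae")[seq_len(sample(2:max_taxa, 1))]
  st <- datedCladogram(sample(enumerateTopologies(taxa), 1L))
  k <- sample(2:max_leaves, 1L)
  species <- sample(taxa, k, replace = TRUE)
  labs <- geneLabelsFor(species)
  top <- sample(enumerateTopologies(paste0("g", seq_len(k))), 1L)
  for (i in seq_len(k))
    top <- sub(paste0("\\bg", i, "\\b"), labs[i], top)
  list(species_tree = st, gene_tree = geneTree(top))
}
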