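test_that("congruent one-copy trees reconcile with no events", {
  st <- datedCladogram("((Aaaaaa,Aaaaab),Aaaaac);")
  gt <- readGeneTree("((AaaaaaGUS1,AaaaabGUS1),AaaaacGUS1);")
  recon <- lcaMap(gt, st)
  # gene root -> species root, inner node -> (A,B) ancestor
  expect_equal(as.integer(recon)[4L], 4L)
  expect_equal(as.integer(recon)[5L], 5L)
  expect_equal(nrow(inferDuplications(gt, st, recon)), 0L)
  expect_equal(countLosses(gt, st, recon), 0L)
  or <- oracleReconcile(gt, st)
  expect_equal(or$duplications, 0L)
  expect_equal(or$losses, 0L)
})

test_that("hand-mapped example: deep coalescing copies force duplications", {
  st <- datedCladogram("((Aaaaaa,Aaaaab),Aaaaac);")
  gt <- readGeneTree(
    "((AaaaaaGUS1,AaaaabGUS1),(AaaaaaGUS2,(AaaaabGUS2,AaaaacGUS1)));")
  recon <- lcaMap(gt, st)
  root_s <- 4L
  # gene root and its right child both map to the species root
  expect_equal(as.integer(recon)[6L], root_s)
  expect_equal(as.integer(recon)[8L], root_s)
  ev <- inferDuplications(gt, st, recon)
  or <- oracleReconcile(gt, st)
  expect_equal(nrow(ev), or$duplications)
  expect_equal(or$duplications, 2L)
  expect_equal(countLosses(gt, st, recon), or$losses)
  expect_equal(or$losses, 4L)
})

test_that("leaf and within-species cases map as expected", {
  st <- datedCladogram("((Aaaaaa,Aaaaab),Aaaaac);")
  one <- readGeneTree("(AaaaaaGUS1:1);")
  expect_equal(as.integer(lcaMap(one, st))[1L], 1L)
  pair <- readGeneTree("(AaaaaaGUS1,AaaaaaGUS2);")
  ev <- inferDuplications(pair, st)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$species_label, "Aaaaaa")
  expect_equal(ev$age_lower, 0)
  expect_error(lcaMap(readGeneTree("(AaaaaaGUS1,ZzzzzzGUS1);"), st),
               "Zzzzzz")
})

test_that("demo family shows two angiosperm-crown duplications, no losses", {
  fx <- makeDemoFixture()
  ing <- demoIngroup(fx)
  recon <- lcaMap(ing, fx$species_tree)
  ev <- inferDuplications(ing, fx$species_tree, recon)
  expect_equal(nrow(ev), 3L)
  expect_equal(sum(ev$species_label == "Angiospermae"), 2L)
  expect_equal(ev$age_lower, sort(ev$age_lower, decreasing = TRUE))
  expect_equal(ev$age_lower[1:2], c(190, 190))
  expect_equal(ev$age_upper[1:2], c(470, 470))
  losses <- countLosses(ing, fx$species_tree, recon)
  or <- oracleReconcile(ing, fx$species_tree)
  expect_equal(nrow(ev), or$duplications)
  expect_equal(losses, or$losses)
  expect_equal(losses, 0L)
})

test_that("events mapped to the species root get the configured ceiling", {
  st <- datedCladogram("((Aaaaaa,Aaaaab),Aaaaac);")  # root at 100 Mya
  gt <- readGeneTree(
    "((AaaaaaGUS1,AaaaacGUS1),(AaaaaaGUS2,AaaaacGUS2));")
  ev <- inferDuplications(gt, st, root_age_ceiling = 350)
  expect_equal(ev$age_lower[1L], 100)
  expect_equal(ev$age_upper[1L], 350)
  # a ceiling below the root age never inverts the interval
  ev2 <- inferDuplications(gt, st, root_age_ceiling = 50)
  expect_true(all(ev2$age_lower <= ev2$age_upper))
})

test_that("duplication and loss counts agree with the exhaustive oracle", {
  # full sweep over all topologies at the smallest sizes
  taxa3 <- c("Aaaaaa", "Aaaaab", "Aaaaac")
  for (stop in enumerateTopologies(taxa3)) {
    st <- datedCladogram(stop)
    for (k in 2:3) {
      for (gtop in enumerateTopologies(paste0("g", seq_len(k)))) {
        grid <- expand.grid(rep(list(taxa3), k), stringsAsFactors = FALSE)
        for (r in seq_len(nrow(grid))) {
          species <- as.character(grid[r, ])
          labs <- geneLabelsFor(species)
          top <- gtop
          for (i in seq_len(k))
            top <- sub(paste0("\\bg", i, "\\b"), labs[i], top)
          gt <- geneTree(top)
          recon <- lcaMap(gt, st)
          or <- oracleReconcile(gt, st)
          expect_equal(nrow(inferDuplications(gt, st, recon)),
                       or$duplications)
          expect_equal(countLosses(gt, st, recon), or$losses)
        }
      }
    }
  }
  # seeded random larger instances
  for (seed in 1:60) {
    inst <- randReconInstance(seed)
    recon <- lcaMap(inst$gene_tree, inst$species_tree)
    or <- oracleReconcile(inst$gene_tree, inst$species_tree)
    expect_equal(nrow(inferDuplications(inst$gene_tree, inst$species_tree,
                                        recon)), or$duplications)
    expect_equal(countLosses(inst$gene_tree, inst$species_tree, recon),
                 or$losses)
  }
})

test_that("duplication count is invariant under child-order rotation", {
  for (seed in 1:10) {
    inst <- randReconInstance(seed)
    gt <- inst$gene_tree
    base <- nrow(inferDuplications(gt, inst$species_tree))
    phy <- gt; class(phy) <- "phylo"
    for (v in ape::Ntip(phy) + seq_len(phy$Nnode)) {
      rot <- geneTree(ape::rotate(phy, v))
      expect_equal(nrow(inferDuplications(rot, inst$species_tree)), base)
    }
  }
})

test_that("removing a gene leaf can only drop the duplication count by <= 1", {
  for (seed in 1:10) {
    inst <- randReconInstance(seed)
    gt <- inst$gene_tree
    if (ape::Ntip(gt) < 3L) next
    base <- nrow(inferDuplications(gt, inst$species_tree))
    for (tip in gt$tip.label) {
      phy <- gt; class(phy) <- "phylo"
      sub <- geneTree(ape::drop.tip(phy, tip))
      d <- nrow(inferDuplications(sub, inst$species_tree))
      expect_lte(d, base)
      expect_gte(d, base - 1L)
    }
  }
})

test_that("the oracle refuses oversized input and non-binary trees fail", {
  st <- datedCladogram("(Aaaaaa,Aaaaab);")
  set.seed(1)
  x <- ape::rtree(17)
  x$tip.label <- geneLabelsFor(rep("Aaaaaa", 17))
  expect_error(oracleReconcile(geneTree(x), st), "refuses")
  poly <- readGeneTree("(AaaaaaGUS1,AaaaaaGUS2,AaaaabGUS1);")
  expect_error(inferDuplications(poly, st), "non-binary")
  resolved <- readGeneTree("(AaaaaaGUS1,AaaaaaGUS2,AaaaabGUS1);",
                           resolve_polytomies = TRUE)
  expect_equal(nrow(inferDuplications(resolved, st)), 1L)
})
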