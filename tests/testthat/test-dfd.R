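demoConfig <- function(fx) dfdConfig(required_phyla = fx$required_phyla)

test_that("the demo family splits into three phylum-complete clusters", {
  fx <- makeDemoFixture()
  cl <- detectClusters(fx$gene_tree, demoConfig(fx), outgroup = fx$outgroup)
  expect_length(cl, 3L)
  for (c in cl) expect_true(all(c$coverage))
  # the GUS3 cluster holds the two eudicot sub-lineages
  with3 <- Filter(function(c) "AmbtriGUS3" %in% c$members, cl)[[1L]]
  expect_length(with3$subclusters, 2L)
  expect_setequal(unlist(lapply(with3$subclusters, `[[`, "members")),
                  c("NicsylGUS3.1", "NicsylGUS3.2"))
})

test_that("cluster detection handles single-copy and uncovered families", {
  fx <- makeDemoFixture()
  cfg <- demoConfig(fx)
  single <- readGeneTree(
    "(AmbtriGUS1,(AnacomGUS1,(AqucaeGUS1,NicsylGUS1)));")
  cl <- detectClusters(single, cfg)
  expect_length(cl, 1L)
  expect_length(cl[[1L]]$subclusters, 0L)
  nomono <- readGeneTree("(AmbtriGUS1,(AqucaeGUS1,NicsylGUS1));")
  expect_warning(cl0 <- detectClusters(nomono, cfg), "no clade covers")
  expect_length(cl0, 0L)
})

test_that("cluster membership is invariant under child-order rotation", {
  fx <- makeDemoFixture()
  cfg <- demoConfig(fx)
  base <- detectClusters(fx$gene_tree, cfg, outgroup = fx$outgroup)
  keyOf <- function(cl) sort(vapply(cl, function(c)
    paste(sort(c$members), collapse = ","), character(1L)))
  subKey <- function(cl) sort(unlist(lapply(cl, function(c)
    lapply(c$subclusters, function(sc)
      paste(sort(sc$members), collapse = ",")))))
  phy <- fx$gene_tree; class(phy) <- "phylo"
  for (v in ape::Ntip(phy) + seq_len(phy$Nnode)) {
    rot <- geneTree(ape::rotate(phy, v))
    cl <- detectClusters(rot, cfg, outgroup = fx$outgroup)
    expect_equal(keyOf(cl), keyOf(base))
    expect_equal(subKey(cl), subKey(base))
  }
})

test_that("cluster naming follows anchors and flags conflicts", {
  fx <- makeDemoFixture()
  cl <- detectClusters(fx$gene_tree, demoConfig(fx), outgroup = fx$outgroup)
  nm <- assignClusterNames(cl, fx$reference_labels)
  map <- stats::setNames(nm$mapping$new, nm$mapping$old)
  expect_equal(unname(map["NicsylGUS3.1"]), "NicsylGUS3.1")
  expect_equal(unname(map["NicsylGUS3.2"]), "NicsylGUS3.2")
  expect_equal(unname(map["NicsylGUS4"]), "NicsylGUS4")
  expect_equal(unname(map["NicsylGUS1.1"]), "NicsylGUS1")
  expect_equal(unname(map["AnacomGUS3.a"]), "AnacomGUS3")
  expect_error(assignClusterNames(cl, list("1" = c("AmbtriGUS1",
                                                   "AmbtriGUS3"))),
               "naming conflict")
  # unanchored clusters get traversal-order numbers
  nm0 <- assignClusterNames(cl)
  expect_setequal(unique(nm0$mapping$cluster),
                  c("1", "1.1", "1.2", "2", "3"))
})

test_that("retention completeness counts daughter coverage over sampled taxa", {
  fx <- makeDemoFixture()
  ing <- demoIngroup(fx)
  ev <- inferDuplications(ing, fx$species_tree)
  fam <- unique(ing$labels$taxon)
  crown <- ev[ev$species_label == "Angiospermae", ]
  for (i in seq_len(nrow(crown)))
    expect_equal(retentionCompleteness(crown[i, , drop = FALSE],
                                       fx$species_tree, fam), c(1, 1))
  # synthetic: daughter missing 2 of 8 descendants
  st8 <- datedCladogram(enumerateTopologies(
    c("Aaaaaa", "Aaaaab", "Aaaaac", "Aaaaad"))[1L])
  taxa <- st8$tip.label
  fake <- list(species_node = ape::Ntip(st8) + 1L,
               child_species_1 = list(taxa),
               child_species_2 = list(taxa[1:3]))
  comp <- retentionCompleteness(fake, st8, taxa)
  expect_equal(comp, c(1, 0.75))
  empty <- list(species_node = 1L, child_species_1 = list("Aaaaab"),
                child_species_2 = list("Aaaaab"))
  expect_error(retentionCompleteness(empty, st8, "Aaaaab"),
               "inconsistent")
})

test_that("double-gene phylum test equals set equality at tol 0", {
  expect_true(isDoubleGenePhylum(c(1, 1), 0))
  expect_false(isDoubleGenePhylum(c(1, 0.4), 0))
  expect_true(isDoubleGenePhylum(c(0.95, 0.92), 0.1))
  # oracle: at tol 0 the flag is TRUE iff both child sets equal the
  # restricted descendant set
  st <- datedCladogram(enumerateTopologies(
    c("Aaaaaa", "Aaaaab", "Aaaaac", "Aaaaad"))[3L])
  D <- st$tip.label
  set.seed(7)
  for (i in 1:30) {
    c1 <- sample(D, sample(seq_along(D), 1L))
    c2 <- sample(D, sample(seq_along(D), 1L))
    ev <- list(species_node = ape::Ntip(st) + 1L,
               child_species_1 = list(c1), child_species_2 = list(c2))
    comp <- retentionCompleteness(ev, st, D)
    expect_equal(isDoubleGenePhylum(comp, 0),
                 setequal(c1, D) && setequal(c2, D))
  }
})

test_that("verdicts follow the age-qualified retention rules", {
  cfg <- dfdConfig(ancient_cutoff = 100)
  ancient <- list(age_lower = 200)
  recent <- list(age_lower = 40)
  expect_equal(classifyDfd(ancient, c(1, 1), cfg), "DFD_LIKELY")
  expect_equal(classifyDfd(recent, c(1, 1), cfg), "RETAINED_RECENT")
  # heavy loss -> lossy
  expect_equal(classifyDfd(ancient, c(1, 0.3), cfg), "NON_DFD_LOSSY")
  # mild loss, no family information -> ambiguous
  expect_equal(classifyDfd(ancient, c(1, 0.75), cfg), "AMBIGUOUS")
  # whole-family loss triggers the lossy verdict even when the overall
  # missing fraction is small
  st <- datedCladogram(
    "(((Aaaaaa,Aaaaab),(Aaaaac,Aaaaad)),(Aaaaae,Aaaaaf));")
  fams <- c(Aaaaaa = "F1", Aaaaab = "F1", Aaaaac = "F2", Aaaaad = "F2",
            Aaaaae = "F3", Aaaaaf = "F3")
  cfg2 <- dfdConfig(ancient_cutoff = 100, lossy_fraction = 0.9,
                    family_map = fams)
  taxa <- st$tip.label
  ev <- list(species_node = ape::Ntip(st) + 1L, age_lower = 200,
             child_species_1 = list(taxa),
             child_species_2 = list(setdiff(taxa, c("Aaaaac", "Aaaaad"))))
  comp <- retentionCompleteness(ev, st, taxa)
  expect_equal(classifyDfd(ev, comp, cfg2, st, taxa), "NON_DFD_LOSSY")
  # same fraction missing but scattered across families -> ambiguous
  ev2 <- list(species_node = ape::Ntip(st) + 1L, age_lower = 200,
              child_species_1 = list(taxa),
              child_species_2 = list(setdiff(taxa, c("Aaaaab", "Aaaaac"))))
  comp2 <- retentionCompleteness(ev2, st, taxa)
  expect_equal(classifyDfd(ev2, comp2, cfg2, st, taxa), "AMBIGUOUS")
})

test_that("every event receives exactly one known verdict", {
  st <- simulateSpeciesTree(10, 0.04, seed = 31, root_age = 250)
  cfg <- dfdConfig()
  for (seed in 1:5) {
    sim <- suppressWarnings(evolveGeneFamily(st, simParams(
      lambda_dup = 0.008, lambda_loss = 0.004, p_dfd = 0.3, seed = seed)))
    if (is.null(sim$gene_tree) || ape::Ntip(sim$gene_tree) < 2) next
    ev <- classifyEvents(inferDuplications(sim$gene_tree, st), st, cfg)
    expect_true(all(ev$verdict %in% dfdVerdicts))
    expect_false(anyNA(ev$verdict))
  }
})

test_that("WGD association respects both branch and age interval", {
  fx <- makeDemoFixture()
  ing <- demoIngroup(fx)
  ev <- inferDuplications(ing, fx$species_tree)
  crown <- ev[ev$species_label == "Angiospermae", ][1L, , drop = FALSE]
  hit <- mapToWgd(crown, fx$wgd_table, fx$species_tree)
  expect_setequal(hit$name, c("seed_plant_wgd", "angiosperm_ancestor_wgd"))
  # same ages, different branch -> no match
  wrong_branch <- list(species_node =
                         5L + match("Mesangiospermae",
                                    fx$species_tree$node.label),
                       age_lower = 190, age_upper = 470)
  expect_equal(nrow(mapToWgd(wrong_branch, fx$wgd_table,
                             fx$species_tree)), 0L)
  # right branch, too-young interval -> no match
  tip_event <- list(species_node = match("Nicsyl",
                                         fx$species_tree$tip.label),
                    age_lower = 0, age_upper = 5)
  expect_equal(nrow(mapToWgd(tip_event, fx$wgd_table, fx$species_tree)),
               0L)
  # the demo Nicotiana pair overlaps the Solanaceae WGD window
  nic <- ev[ev$species_label == "Nicsyl", , drop = FALSE]
  expect_true("solanaceae_wgd" %in%
                mapToWgd(nic, fx$wgd_table, fx$species_tree)$name)
  expect_error(mapToWgd(crown, wgdTable("x", "NoSuchNode", 1, 2),
                        fx$species_tree), "unknown")
})

test_that("recombination potential is the map-ratio product with a 50 cM flag", {
  r <- expectedGeneticDistance(10, 2)
  expect_equal(r$cM, 20)
  expect_false(r$free_recombination)
  expect_equal(expectedGeneticDistance(0, 5)$cM, 0)
  r2 <- expectedGeneticDistance(30, 2)
  expect_equal(r2$cM, 60)
  expect_true(r2$free_recombination)
  expect_error(expectedGeneticDistance(-1), "non-negative")
})

test_that("all demo angiosperms retain copies in both the 1 and 3 clusters", {
  fx <- makeDemoFixture()
  cl <- detectClusters(fx$gene_tree, demoConfig(fx), outgroup = fx$outgroup)
  with1 <- Filter(function(c) "AmbtriGUS1" %in% c$members, cl)[[1L]]
  with3 <- Filter(function(c) "AmbtriGUS3" %in% c$members, cl)[[1L]]
  expect_equal(countDoubleRetainers(cl, with1$name, with3$name), 4L)
})
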