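test_that("records round-trip through FASTA + metadata with id checks", {
  meta <- curationTable()[5:8, ]
  set.seed(2)
  seqs <- vapply(meta$length, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1L))
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeLines(as.vector(rbind(paste0(">", meta$id), seqs)), fa)
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rec <- readRecords(fa, tsv)
  expect_equal(nrow(rec), 4L)
  expect_equal(nchar(rec$sequence), rec$length)

  # orphan id in FASTA
  writeLines(c(paste0(">", meta$id[1]), seqs[1], ">ghost", "ACGT"), fa)
  expect_error(readRecords(fa, tsv), "mismatch")
  # length disagreement
  writeLines(as.vector(rbind(paste0(">", meta$id),
                             c(substr(seqs[1], 1, 10), seqs[-1]))), fa)
  expect_error(readRecords(fa, tsv), "length differs")
})

test_that("filter rules fire in the documented order", {
  rec <- cdsRecords(curationTable())
  dec <- applyFilters(rec)
  expect_equal(stats::setNames(dec$rule, dec$id), curationExpectedRules())
  expect_equal(sum(dec$kept), 5L)
  # a short annotated record dies on the hard rule, not the soft one
  expect_equal(dec$rule[dec$id == "r01"], "LEN_LT_300")
  # rescue by annotation keyword
  expect_equal(dec$rule[dec$id == "r05"], "KEPT")
  # same locus in a different taxon is no duplicate
  expect_equal(dec$rule[dec$id == "r07"], "KEPT")
  # every record gets exactly one decision
  expect_equal(nrow(dec), nrow(rec))
  expect_false(anyNA(dec$rule))
})

test_that("filtering is idempotent and order-invariant up to dedup choice", {
  rec <- cdsRecords(curationTable())
  dec <- applyFilters(rec)
  kept <- rec[rec$id %in% dec$id[dec$kept], , drop = FALSE]
  again <- applyFilters(kept)
  expect_true(all(again$kept))
  keptPairs <- function(records) {
    d <- applyFilters(records)
    k <- records[records$id %in% d$id[d$kept], ]
    sort(paste(k$taxon, k$locus, sep = "|"))
  }
  base <- keptPairs(rec)
  set.seed(9)
  for (i in 1:10)
    expect_equal(keptPairs(rec[sample(nrow(rec)), ]), base)
})

test_that("length summaries use the even-count median rule", {
  one <- cdsRecords(curationTable()[12, , drop = FALSE])
  expect_equal(summarizeLengths(one)$median, 1600)
  two <- curationTable()[c(6, 9), ]; two$length <- c(1500L, 1700L)
  expect_equal(summarizeLengths(cdsRecords(two))$median, 1600)
  fx <- makeDemoFixture()
  s <- summarizeLengths(fx$metadata)
  expect_equal(s$n, 14L)
  expect_equal(s$median, 1600)
  expect_true(s$min >= 300 && s$max <= 2000)
  expect_error(summarizeLengths(fx$metadata[0, ]), "no records")
})

test_that("tight same-species paralogs collapse to the longest copy", {
  cf <- collapseFixture()
  rec <- cf$records[1:3, ]
  out <- collapseTightParalogs(rec, cf$tree, 0.05)
  # the 0.02-apart pair collapses; the longer copy represents it
  expect_false(out$representative[out$id == "AaaaaaGUS1"])
  expect_true(out$representative[out$id == "AaaaaaGUS2"])
  # the distant third copy stays
  expect_true(out$representative[out$id == "AaaaaaGUS3"])
  expect_equal(sum(out$representative), 2L)
  # zero distance pair, tie on length -> lexicographically smaller id
  tie <- rec; tie$length <- rep(1500L, 3L)
  out2 <- collapseTightParalogs(tie, cf$tree, 0.05)
  expect_true(out2$representative[out2$id == "AaaaaaGUS1"])
  expect_false(out2$representative[out2$id == "AaaaaaGUS2"])
  # copies in different clusters are never collapsed
  far <- collapseTightParalogs(rec, cf$tree, 0.02)
  expect_equal(sum(far$representative), 3L)
  expect_error(collapseTightParalogs(cf$records, cf$tree), "absent")
})

test_that("short copies in lossy clusters get pseudogenization flags", {
  fx <- makeDemoFixture()
  cfg <- dfdConfig(required_phyla = fx$required_phyla)
  cl <- detectClusters(fx$gene_tree, cfg, outgroup = fx$outgroup)
  lossy <- Filter(function(c) "NicsylGUS4" %in% c$members, cl)[[1L]]$name
  flagged <- flagPseudogenizationCandidates(fx$metadata, cl,
                                            lossy_clusters = lossy)
  expect_equal(flagged, "NicsylGUS4")
  # full-length copies in the same cluster are not flagged
  expect_false("AmbtriGUS4" %in% flagged)
  # short copies outside lossy clusters are not flagged
  other <- Filter(function(c) "AmbtriGUS1" %in% c$members, cl)[[1L]]$name
  short1 <- fx$metadata
  short1$length[short1$id == "AqucaeGUS1"] <- 600L
  expect_equal(flagPseudogenizationCandidates(short1, cl,
                                              lossy_clusters = lossy),
               "NicsylGUS4")
  expect_setequal(flagPseudogenizationCandidates(
    short1, cl, lossy_clusters = c(lossy, other)),
    c("NicsylGUS4", "AqucaeGUS1"))
})
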