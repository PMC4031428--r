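test_that("the data summary counts sources, trees, taxa and characters", {
  empty <- dataSummary(PhyloDataset("void"))
  expect_match(empty, "Sources: 0")
  expect_match(empty, "Trees: 0")
  expect_match(empty, "Distinct taxa: 0")

  ds <- dsFromNewicks(c("(A,(B,C),D);"), c("((C,D),(E,A));", "((A,B),E);"),
                      years = c(1998, 2004))
  s <- dataSummary(ds)
  expect_match(s, "Sources: 2")
  expect_match(s, "Trees: 3")
  expect_match(s, "Distinct taxa: 5")
  expect_match(s, "1998: 1")
  expect_match(s, "2004: 1")
  # taxa list equals the independently recomputed union of leaf sets
  union <- sort(unique(unlist(lapply(sourceTrees(ds), function(st)
    ape::read.tree(text = st@treeString)$tip.label))))
  for (tx in union) expect_match(s, paste0("  ", tx))
})

test_that("cleaning removes uninformative trees and emptied sources, idempotently", {
  ds <- dsFromNewicks(c("(A,B,C);"), c("((A,B),(C,D));"))
  out <- cleanData(ds)
  expect_length(out$log, 2L)                 # tree + emptied source
  expect_equal(nSources(out$dataset), 1L)
  expect_equal(nTrees(out$dataset), 1L)

  ok <- dsFromNewicks(c("((A,B),(C,D));", "(A,(B,C),D);"))
  out2 <- cleanData(ok)
  expect_length(out2$log, 0L)
  expect_equal(nTrees(out2$dataset), 2L)

  again <- cleanData(out$dataset)
  expect_length(again$log, 0L)
  expect_equal(nTrees(again$dataset), nTrees(out$dataset))
})

test_that("independence check groups identical trees and flags taxon subsets", {
  ds <- dsFromNewicks(c("((A,B),(C,D));"), c("((A,B),C,D);"),
                      c("((A,B),D);"), c("((E,F),(G,H));"),
                      years = c(1995, 2001, 2003, 2000),
                      chars = list(list("cytb"), list("CYTB "),
                                   list("cytb"), list("cytb")))
  out <- checkIndependence(ds)
  rep <- out$report
  expect_length(rep@identicalGroups, 1L)
  expect_setequal(rep@identicalGroups[[1]], c("src01:1", "src02:1"))
  expect_true(all(c("src03:1") %in% rep@subsetPairs$smaller))
  # identical group keeps the earliest source; subset keeps the larger tree
  expect_setequal(rep@suggestedRemovals, c("src02:1", "src03:1"))
  removed <- checkIndependence(ds, autoRemove = TRUE)$dataset
  expect_equal(names(sourceTrees(removed)), c("src01:1", "src04:1"))

  # same taxa but different characters are independent
  ds2 <- dsFromNewicks(c("((A,B),(C,D));"), c("((A,B),(C,D));"),
                       chars = list(list("cytb"), list("nd2")))
  rep2 <- checkIndependence(ds2)$report
  expect_length(rep2@identicalGroups, 0L)
  expect_equal(nrow(rep2@subsetPairs), 0L)
})

test_that("independence requires character data and never flags the larger tree", {
  ds <- dsFromNewicks(c("((A,B),(C,D));"))
  expect_error(checkIndependence(ds), "src01:1")
  ds3 <- dsFromNewicks(c("((A,B),(C,D));"), c("((A,B),C);"), c("((A,B),D);"),
                       chars = list(list("c1"), list("c1"), list("c1")))
  rep <- checkIndependence(ds3)$report
  expect_false("src01:1" %in% rep@suggestedRemovals)
  expect_true(all(rep@subsetPairs$larger == "src01:1"))
})

test_that("overlap edges need k shared taxa and connectivity follows", {
  ds <- dsFromNewicks(c("((A,B),C);"), c("((B,C),D);"))
  ov <- checkOverlap(ds, 2)
  expect_equal(nrow(ov@edges), 1L)
  expect_equal(ov@edges$weight, 2L)
  expect_true(isConnected(ov))

  ds2 <- dsFromNewicks(c("((A,B),C);"), c("((B,C),D);"), c("((E,F),G);"))
  ov2 <- checkOverlap(ds2, 2)
  expect_false(isConnected(ov2))
  expect_length(ov2@components, 2L)

  ov3 <- checkOverlap(ds, 3)
  expect_equal(nrow(ov3@edges), 0L)
  expect_false(isConnected(ov3))
  expect_error(checkOverlap(ds, 1), ">= 2")
})

test_that("overlap connectivity agrees with brute-force reachability", {
  withr::local_seed(19)
  for (i in 1:40) {
    cfg <- synthConfig(seed = 1000L + i, nSources = sample(3:6, 1),
                       taxonPool = sample(c(15L, 30L, 60L), 1),
                       overlapBias = runif(1))
    ds <- generateDataset(cfg)
    leafSets <- lapply(sourceTrees(ds), function(st)
      unique(baseName(ape::read.tree(text = st@treeString)$tip.label)))
    for (k in 2:3) {
      ov <- checkOverlap(ds, k)
      comps <- bfsComponentsCount(leafSets, k)
      expect_equal(length(ov@components), comps)
      expect_equal(isConnected(ov), comps == 1L)
    }
  }
})

test_that("overlap graphs export as DOT and GraphML", {
  ds <- dsFromNewicks(c("((A,B),C);"), c("((B,C),D);"), c("((E,F),G);"))
  ov <- checkOverlap(ds, 2)
  dot <- withr::local_tempfile(fileext = ".dot")
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportOverlap(ov, dot, "dot")
  exportOverlap(ov, gml, "graphml")
  expect_match(paste(readLines(dot), collapse = " "), "src01")
  expect_match(paste(readLines(gml, warn = FALSE), collapse = " "),
               "graphml")
})

test_that("metadata subsets honour each filter and compose conjunctively", {
  ds <- dsFromNewicks(c("((A,B),(C,D));"), c("((A,C),(B,E));"),
                      c("((D,E),(A,F));"),
                      years = c(1999, 2005, 2010),
                      chars = list(list("cytb"), list("osteology"),
                                   list("cytb")))
  # mark tree 2's character as morphological
  ds@sources[[2]]@sourceTrees[[1]]@characterData$type <- "morphological"

  byYear <- createSubset(ds, years = c(2000, 2010))
  expect_equal(names(sources(byYear)), c("src02", "src03"))

  mol <- createSubset(ds, characterType = "molecular")
  expect_equal(names(sources(mol)), c("src01", "src03"))
  expect_equal(tail(history(mol)$operation, 1), "create_subset")
  expect_match(tail(history(mol)$parameters, 1), "molecular")

  all <- createSubset(ds, years = c(1900, 2100))
  expect_equal(nTrees(all), nTrees(ds))

  expect_warning(none <- createSubset(ds, years = c(1800, 1801)),
                 "no trees")
  expect_equal(nSources(none), 0L)

  # f1 then f2 equals the conjunction
  ab <- createSubset(createSubset(ds, years = c(2000, 2010)),
                     characterType = "molecular")
  both <- createSubset(ds, years = c(2000, 2010),
                       characterType = "molecular")
  expect_equal(names(sources(ab)), names(sources(both)))
  expect_equal(vapply(sourceTrees(ab), function(x) x@treeString,
                      character(1)),
               vapply(sourceTrees(both), function(x) x@treeString,
                      character(1)))
})
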