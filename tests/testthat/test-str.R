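test_that("row comparison follows the Wilkinson equivalence rules", {
  expect_equal(compareRows(c("1","1","0"), c("1","1","0")), "identical")
  expect_equal(compareRows(c("1","?","0"), c("1","1","0")), "a_subsumed_by_b")
  expect_equal(compareRows(c("1","1","0"), c("1","?","0")), "b_subsumed_by_a")
  expect_equal(compareRows(c("1","?","0"), c("1","0","0")), "a_subsumed_by_b")
  expect_equal(compareRows(c("1","1","0"), c("1","0","0")), "non_equivalent")
  expect_equal(compareRows(c("1","?"), c("?","0")), "symmetric_equivalent")
  expect_equal(compareRows(c("?","?"), c("?","?")), "identical")
  expect_error(compareRows("1", c("1","0")), "length")
})

test_that("vectorised classification matches the naive comparator exactly", {
  withr::local_seed(23)
  for (i in 1:40) {
    m <- randomValidMatrix(sample(4:9, 1), sample(3:10, 1),
                           pMissing = runif(1, 0.1, 0.6))
    got <- pairRelations(classifyMatrix(m))
    want <- naivePairTable(cells(m))
    expect_equal(got[order(got$taxonA, got$taxonB), ],
                 want[order(want$taxonA, want$taxonB), ],
                 ignore_attr = TRUE)
  }
})

test_that("identical rows keep the lexically smallest name", {
  cm <- rbind(B = c("1","0","1"), C = c("1","0","1"), A = c("0","1","0"),
              D = c("1","1","0"))
  rep <- classifyMatrix(MRPMatrix(cm))
  expect_equal(removals(rep)$taxon, "C")
  expect_equal(removals(rep)$representative, "B")
  expect_equal(unname(rep@categories[c("B","C")]), c("A", "C*"))
})

test_that("subsumption chains retain only the maximal row", {
  cm <- rbind(a = c("1","?","?","0"),
              b = c("1","1","?","0"),
              c = c("1","1","0","0"),
              z = c("0","0","1","1"))
  rep <- classifyMatrix(MRPMatrix(cm))
  expect_setequal(removals(rep)$taxon, c("a", "b"))
  expect_equal(unique(removals(rep)$representative), "c")
  # brute-force check: c is the only retain-one choice that subsumes both
  for (x in c("a", "b"))
    expect_equal(naiveCompareRows(cm[x, ], cm["c", ]), "a_subsumed_by_b")
})

test_that("conflicting matrices yield an empty plan; reduction is idempotent", {
  withr::local_seed(31)
  g0 <- generateStrMatrix(8, 10, nIdenticalGroups = 0, nSubsumed = 0,
                          seed = 77)
  expect_equal(nrow(removals(classifyMatrix(g0$matrix))), 0L)
  for (i in 1:15) {
    g <- generateStrMatrix(10, 8, nIdenticalGroups = sample(0:2, 1),
                           nSubsumed = sample(0:3, 1), seed = i)
    r1 <- applyStr(g$matrix)
    r2 <- applyStr(r1$reduced)
    expect_equal(nrow(removals(r2$equivalence)), 0L)
    expect_identical(cells(r2$reduced), cells(r1$reduced))
  }
})

test_that("planted structure is recovered exactly on conflict-free backgrounds", {
  for (seed in 1:20) {
    g <- generateStrMatrix(14, 12, nIdenticalGroups = 2, groupSize = 2,
                           nSubsumed = 3, seed = seed)
    plan <- removals(classifyMatrix(g$matrix))
    expect_equal(plan$taxon, g$groundTruth$removed)
    dups <- grepl("_dup", plan$taxon)
    expect_true(all(plan$category[dups] == "C*"))
  }
})

test_that("the reinsertion substitution file restores removed taxa", {
  cm <- rbind(B = c("1","0","1"), C = c("1","0","1"),
              A = c("0","1","0"), D = c("1","1","0"))
  out <- applyStr(MRPMatrix(cm))
  expect_equal(writeSubsFile(out$subs), "B = B,C\n")
  expect_false("C" %in% taxa(out$reduced))
  tr <- parseNewick("(A,(B,D));")
  back <- substituteTaxa(tr, out$subs)
  expect_setequal(leafLabels(back), c("A", "B", "C", "D"))
  expect_true(list(c("B", "C")) %in% cladeSets(back))
  # no removable taxa -> identity and empty rules
  out2 <- applyStr(out$reduced)
  expect_identical(cells(out2$reduced), cells(out$reduced))
  expect_length(out2$subs@old, 0L)
  expect_match(out$report, "C\\*")
})

test_that("reduction is safe: reinserted MP trees are MP trees of the full matrix", {
  skip_if_not_installed("phangorn")
  withr::local_seed(41)
  checked <- 0
  for (i in 1:20) {
    m <- randomValidMatrix(sample(5:7, 1), sample(4:8, 1),
                           pMissing = runif(1, 0.3, 0.6))
    out <- applyStr(m)
    if (nrow(removals(out$equivalence)) == 0) next
    checked <- checked + 1
    fullTrees <- allTopologies(taxa(m))
    minFull <- min(mpScores(fullTrees, m))
    redTrees <- allTopologies(taxa(out$reduced))
    scR <- mpScores(redTrees, out$reduced)
    for (j in which(scR == min(scR))) {
      back <- substituteTaxa(redTrees[[j]], out$subs)
      back <- withr::with_seed(1, ape::multi2di(back))
      expect_equal(mpScores(list(back), m), minFull)
    }
  }
  expect_gt(checked, 3)
})

test_that("the scan scales to thousands of taxa and stays exact", {
  g <- generateStrMatrix(400, 300, nIdenticalGroups = 5, nSubsumed = 10,
                         seed = 99)
  out <- applyStr(g$matrix)
  expect_equal(removals(out$equivalence)$taxon, g$groundTruth$removed)
  sub <- MRPMatrix(cells(g$matrix)[1:40, , drop = FALSE])
  got <- pairRelations(classifyMatrix(sub))
  want <- naivePairTable(cells(sub))
  expect_equal(got[order(got$taxonA, got$taxonB), ],
               want[order(want$taxonA, want$taxonB), ], ignore_attr = TRUE)
})
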