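test_that("deleting taxa collapses superfluous nodes", {
  t <- parseNewick("(A,(B,C));")
  expect_equal(writeNewick(deleteTaxa(t, "B")), "(A,C);")
  expect_equal(writeNewick(suppressWarnings(deleteTaxa(t, character(0)))),
               "(A,(B,C));")
  expect_true(isEmptyTree(deleteTaxa(t, c("A", "B", "C"))))
  expect_warning(deleteTaxa(t, "Z"), "not in tree")
  # deletion removes all %d instances of a base name
  t2 <- parseNewick("(A%1,(B,(A%2,C)));")
  expect_equal(sort(leafLabels(deleteTaxa(t2, "A"))), c("B", "C"))
})

test_that("delete leaf set equals input leaves minus the deleted set", {
  withr::local_seed(7)
  for (i in 1:50) {
    n <- sample(4:15, 1)
    t <- ape::rtree(n, br = NULL)
    t$tip.label <- sprintf("t%02d", sample(50, n))
    del <- sample(t$tip.label, sample(0:n, 1))
    out <- suppressWarnings(deleteTaxa(t, del))
    expect_equal(sort(leafLabels(out)), sort(setdiff(t$tip.label, del)))
    if (!isEmptyTree(out)) {
      # no single-child internal nodes survive
      tab <- tabulate(out$edge[, 1])
      expect_true(all(tab[tab > 0] >= 2))
    }
  }
})

test_that("substitution inserts polytomies, prunes duplicates, knows markers", {
  t <- parseNewick("(A,(B,C));")
  expect_equal(writeNewick(substituteTaxa(t, SubstitutionSet("B", list(c("X", "Y"))))),
               "(A,((X,Y),C));")
  expect_equal(writeNewick(substituteTaxa(t, SubstitutionSet("B", list("A")))),
               "(A,C);")
  t2 <- parseNewick("(A%1,(A%2,C));")
  expect_equal(writeNewick(substituteTaxa(t2, SubstitutionSet("A", list("Z")))),
               "(Z,C);")
  # empty replacement behaves as deletion
  expect_equal(writeNewick(substituteTaxa(t, SubstitutionSet("B", list(character(0))))),
               "(A,C);")
})

test_that("rename-only substitution is idempotent", {
  withr::local_seed(11)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    t <- ape::rtree(n, br = NULL)
    t$tip.label <- sprintf("t%02d", sample(30, n))
    from <- sample(t$tip.label, 2)
    subs <- SubstitutionSet(from, list("new_one", "new_two"))
    once <- substituteTaxa(t, subs)
    twice <- substituteTaxa(once, subs)
    expect_true(sameTopology(once, twice))
  }
})

test_that("substitution files parse and write with the documented grammar", {
  s <- parseSubsFile("Bos = Bos_taurus,Bos_indicus\n\nFelis = \n X=Y")
  expect_equal(s@old, c("Bos", "Felis", "X"))
  expect_equal(s@replacements[[1]], c("Bos_taurus", "Bos_indicus"))
  expect_equal(s@replacements[[2]], character(0))
  expect_error(parseSubsFile("A = B\nnot a rule"), "line 2")
  expect_error(parseSubsFile("A = B\nA = C"), "duplicate")
  rt <- parseSubsFile(writeSubsFile(s))
  expect_equal(rt@old, s@old)
  expect_equal(rt@replacements, s@replacements)
})

test_that("polyphyly permutation enumerates one instance per taxon", {
  ps <- permuteTree(parseNewick("(A%1,(B,(A%2,C)));"))
  expect_setequal(vapply(ps, writeNewick, character(1)),
                  c("(A,(B,C));", "(B,(A,C));"))
  one <- permuteTree(parseNewick("(A,(B,C));"))
  expect_length(one, 1L)
  expect_equal(writeNewick(one[[1]]), "(A,(B,C));")
  # product rule before de-duplication: 2 x 3 instances
  t <- parseNewick("((A%1,(D%1,x1)),((A%2,D%2),(D%3,(x2,x3))));")
  expect_length(permuteTree(t, deduplicate = FALSE), 6L)
  expect_error(permuteTree(t, maxPermutations = 5), "force")
})

test_that("permutations agree with the input on unmarked taxa", {
  withr::local_seed(13)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    t <- ape::rtree(n, br = NULL)
    t$tip.label <- sprintf("t%02d", sample(30, n))
    # mark one taxon as polyphyletic by grafting a second instance
    tgt <- sample(t$tip.label, 1)
    host <- sample(setdiff(t$tip.label, tgt), 1)
    marked <- substituteTaxa(t, SubstitutionSet(c(tgt, host),
                                                list(paste0(tgt, "%1"),
                                                     c(host, paste0(tgt, "%2")))))
    unmarked <- setdiff(baseName(leafLabels(marked)), tgt)
    ref <- suppressWarnings(deleteTaxa(t, tgt))
    for (p in permuteTree(marked)) {
      pruned <- suppressWarnings(deleteTaxa(p, tgt))
      expect_true(sameTopology(pruned, ref))
      expect_setequal(baseName(leafLabels(p)), c(unmarked, tgt))
    }
  }
})

test_that("genus leaves expand to polytomies of congeners in the dataset", {
  ds <- dsFromNewicks(c("(Bos_taurus,(Bos_indicus,Ovis_aries),Sus_scrofa);",
                        "((Bos,Ovis_aries),(Sus_scrofa,Capra_hircus));"))
  out <- replaceGenera(ds, timestamp = "2020-01-01T00:00:00")
  t2 <- parseNewick(sourceTrees(out)[["src01:2"]]@treeString)
  expect_setequal(leafLabels(t2),
                  c("Bos_taurus", "Bos_indicus", "Ovis_aries",
                    "Sus_scrofa", "Capra_hircus"))
  expect_true(list(c("Bos_indicus", "Bos_taurus")) %in% cladeSets(t2))
  expect_equal(tail(history(out)$operation, 1), "replace_genera")
})

test_that("genus replacement warns when no congeners exist and never duplicates", {
  ds <- dsFromNewicks(c("((Felis,Bos_taurus),(Bos,Ovis_aries));"))
  expect_warning(out <- replaceGenera(ds), "Felis")
  t <- parseNewick(sourceTrees(out)[[1]]@treeString)
  labs <- leafLabels(t)
  expect_equal(anyDuplicated(labs), 0L)
  expect_true("Felis" %in% labs)          # left unchanged
  expect_equal(sum(labs == "Bos_taurus"), 1L)
})

test_that("informativeness requires four leaves and a non-root clade", {
  expect_false(isInformative(parseNewick("(A,B,C);")))
  expect_true(isInformative(parseNewick("((A,B),(C,D));")))
  expect_false(isInformative(parseNewick("(A,B);")))
  expect_false(isInformative(parseNewick("(A,B,C,D,E);")))
  expect_true(isInformative(parseNewick("(A,(B,C),D);")))
})
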