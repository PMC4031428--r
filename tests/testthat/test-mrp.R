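test_that("informative clades enumerate non-root internal nodes", {
  expect_equal(informativeClades(parseNewick("(A,(B,C));")),
               list(c("B", "C")))
  expect_equal(informativeClades(parseNewick("((A,B),(C,D));")),
               list(c("A", "B"), c("C", "D")))
  expect_equal(informativeClades(parseNewick("(A,B,C,D);")), list())
})

test_that("Baum-Ragan coding scores members 1, others 0, absentees ?", {
  ds <- dsFromNewicks("(A,(B,C));", "((B,D),(C,E));")
  m <- buildMatrix(ds, withOutgroup = FALSE)
  cm <- cells(m)
  expect_equal(rownames(cm), sort(c("A", "B", "C", "D", "E")))
  # column 1 comes from (B,C) in tree 1; D and E are absent from that tree
  expect_equal(unname(cm[, 1]), c("0", "1", "1", "?", "?"))
  # tree 2 contributes clades (B,D) and (C,E); A is absent
  expect_equal(unname(cm["A", 2:3]), c("?", "?"))
  expect_equal(unname(cm[c("B", "D"), 2]), c("1", "1"))
  expect_equal(unname(cm[c("C", "E"), 2]), c("0", "0"))
  expect_equal(provenance(m)$source, c("src01", "src02", "src02"))
})

test_that("duplicated trees double the column count; outgroup row is all zero", {
  ds1 <- dsFromNewicks("((A,B),(C,D));")
  ds2 <- dsFromNewicks(c("((A,B),(C,D));", "((A,B),(C,D));"))
  m1 <- buildMatrix(ds1); m2 <- buildMatrix(ds2)
  expect_equal(ncol(cells(m2)), 2L * ncol(cells(m1)))
  expect_true(all(cells(m1)["MRP_Outgroup", ] == "0"))
  expect_equal(rownames(cells(m1))[1], "MRP_Outgroup")
  m3 <- buildMatrix(ds1, withOutgroup = FALSE)
  expect_false("MRP_Outgroup" %in% taxa(m3))
})

test_that("matrix construction rejects bad input with names", {
  expect_error(buildMatrix(PhyloDataset("none")), "no trees")
  ds <- dsFromNewicks(c("((A,B),(C,D));", "(A,B,C);"))
  expect_error(buildMatrix(ds), "src01:2")
  dsm <- dsFromNewicks("((A%1,B),(A%2,C),D);")
  expect_error(buildMatrix(dsm), "permuteTree")
})

test_that("NEXUS and TNT writers round-trip and are deterministic", {
  ds <- dsFromNewicks(c("(A,(B,C),D);", "((B,C),(D,E));"))
  m <- buildMatrix(ds)
  nx <- writeNexus(m)
  expect_identical(writeNexus(m), nx)
  m2 <- readNexus(nx)
  expect_identical(unname(cells(m2)), unname(cells(m)))
  expect_identical(taxa(m2), taxa(m))
  tnt <- writeTnt(m)
  expect_identical(writeTnt(m), tnt)
  m3 <- readTnt(tnt)
  expect_identical(unname(cells(m3)), unname(cells(m)))
  expect_identical(taxa(m3), taxa(m))
  # TNT rows appear in matrix taxa order
  lines <- strsplit(tnt, "\n")[[1]]
  rows <- lines[4:(3 + length(taxa(m)))]
  expect_equal(sub("\\s.*$", "", rows), taxa(m))
  # header carries NTAX/NCHAR
  expect_match(nx, sprintf("NTAX=%d NCHAR=%d", nrow(cells(m)), ncol(cells(m))))
})

test_that("NEXUS quoting protects odd names; TNT rejects them with guidance", {
  cm <- rbind("Weird name's" = c("1", "0"),
              B = c("0", "1"), C = c("1", "1"), D = c("0", "0"))
  m <- MRPMatrix(cm)
  nx <- writeNexus(m)
  expect_match(nx, "'Weird name''s'", fixed = TRUE)
  m2 <- readNexus(nx)
  expect_identical(taxa(m2), taxa(m))
  expect_error(writeTnt(m), "rename")
})

test_that("an independent NEXUS reader agrees with ours", {
  skip_if_not_installed("ape")
  ds <- dsFromNewicks(c("((A,B),(C,D),E);"))
  m <- buildMatrix(ds)
  path <- withr::local_tempfile(fileext = ".nex")
  writeLines(writeNexus(m), path)
  ind <- ape::read.nexus.data(path)
  expect_equal(names(ind), taxa(m))
  expect_equal(do.call(rbind, ind),
               unname(cells(m)), ignore_attr = TRUE)
})

test_that("a single source tree is the unique MP tree of its own matrix", {
  skip_if_not_installed("phangorn")
  withr::local_seed(5)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    t <- ape::rtree(n, br = NULL)
    t$tip.label <- sprintf("t%d", seq_len(n))
    ds <- dsFromNewicks(ape::write.tree(t))
    m <- buildMatrix(ds)                  # with outgroup
    cand <- allTopologies(taxa(m))
    sc <- mpScores(cand, m)
    best <- which(sc == min(sc))
    expect_length(best, 1L)
    mp <- ape::root(cand[[best]], "MRP_Outgroup", resolve.root = TRUE)
    mp <- suppressWarnings(deleteTaxa(mp, "MRP_Outgroup"))
    expect_true(sameTopology(mp, parseNewick(ape::write.tree(t))))
  }
})
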