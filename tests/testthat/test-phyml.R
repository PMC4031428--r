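minimalPhyml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<phylo_dataset format_version="1.0" name="mini">\n',
    '  <sources>\n',
    '    <source citation_key="smith2001">\n',
    '      <bibliographic entry_type="article">\n',
    '        <author>Smith, A.</author>\n',
    '        <title>A tree</title>\n',
    '        <year>2001</year>\n',
    '      </bibliographic>\n',
    '      <source_tree>\n',
    '        <tree_string>(A,(B,C));</tree_string>\n',
    '      </source_tree>\n',
    '    </source>\n',
    '  </sources>\n',
    '  <history/>\n',
    '</phylo_dataset>\n')
}

test_that("a minimal file parses into the expected dataset", {
  ds <- parsePhyml(minimalPhyml())
  expect_equal(datasetName(ds), "mini")
  expect_equal(nSources(ds), 1L)
  expect_equal(nTrees(ds), 1L)
  expect_equal(taxa(ds), c("A", "B", "C"))
  bib <- sources(ds)[["smith2001"]]@bibliographic
  expect_equal(bib@year, 2001L)
  expect_equal(bib@authors, "Smith, A.")
})

test_that("source and tree order are preserved", {
  ds <- dsFromNewicks(c("(A,(B,C),D);", "((A,B),(C,D));"),
                      c("((E,F),G,H);", "(E,(F,(G,H)));"))
  ds2 <- parsePhyml(writePhyml(ds))
  expect_equal(vapply(sources(ds2), function(s) length(sourceTrees(s)),
                      integer(1)),
               c(src01 = 2L, src02 = 2L))
  expect_equal(names(sourceTrees(ds2)),
               c("src01:1", "src01:2", "src02:1", "src02:2"))
  expect_equal(sourceTrees(ds2)[["src02:1"]]@treeString, "((E,F),G,H);")
})

test_that("write -> parse round trip is lossless and writing deterministic", {
  for (seed in c(3, 11, 27)) {
    ds <- generateDataset(synthConfig(seed = seed, nSources = 4L))
    x <- writePhyml(ds)
    ds2 <- parsePhyml(x)
    expect_true(datasetIdentical(ds, ds2))
    expect_identical(writePhyml(ds2), x)       # byte-identical re-write
  }
})

test_that("unknown extension elements survive the round trip", {
  txt <- sub("</source_tree>",
             "<conservation_status>LC</conservation_status>\n      </source_tree>",
             minimalPhyml())
  txt <- sub("</source>",
             "<accession db=\"gb\">AY123</accession>\n    </source>", txt)
  ds <- parsePhyml(txt)
  st <- sourceTrees(ds)[[1]]
  expect_match(st@extensions, "conservation_status")
  expect_match(sources(ds)[[1]]@extensions, "accession")
  ds2 <- parsePhyml(writePhyml(ds))
  expect_true(datasetIdentical(ds, ds2))
})

test_that("empty datasets and special characters are written validly", {
  ds <- PhyloDataset("empty & odd <name>")
  x <- writePhyml(ds)
  ds2 <- parsePhyml(x)
  expect_equal(datasetName(ds2), "empty & odd <name>")
  expect_equal(nSources(ds2), 0L)
})

test_that("parse errors name the offending structure", {
  expect_error(parsePhyml("<phylo_dataset><sources><source>"),
               regexp = ".")                 # malformed XML
  bad <- sub("\\(A,\\(B,C\\)\\);", "(A,(B,C);", minimalPhyml())
  expect_error(parsePhyml(bad), "smith2001")
  expect_error(parsePhyml(bad), "tree 1")
  expect_error(parsePhyml("<root/>"), "phylo_dataset")
})

test_that("history entries round-trip and processing ops append one each", {
  ds <- dsFromNewicks("(A,(B,C),D);")
  ds <- applySubstitutions(ds, SubstitutionSet("A", list("Aa")),
                           timestamp = "2020-01-01T00:00:00")
  cl <- cleanData(ds, timestamp = "2020-01-01T00:00:01")
  ds <- cl$dataset
  expect_equal(history(ds)$operation, c("substitute_taxa", "clean_data"))
  ds2 <- parsePhyml(writePhyml(ds))
  expect_identical(history(ds2), history(ds))
})

test_that("exportTrees writes one normalised Newick per line, in order", {
  ds <- dsFromNewicks(c("(A,(B,C),D);", "((A,B),(C,D));"), "((E,F),(G,H));")
  out <- exportTrees(ds)
  lines <- strsplit(out, "\n")[[1]]
  expect_length(lines, 3L)
  orig <- sourceTrees(ds)
  for (i in seq_along(lines))
    expect_true(sameTopology(parseNewick(lines[i]),
                             parseNewick(orig[[i]]@treeString)))
  expect_equal(exportTrees(PhyloDataset("none")), "")
})

test_that("file-level read/write helpers agree with the text API", {
  ds <- generateDataset(synthConfig(seed = 5, nSources = 3L))
  path <- withr::local_tempfile(fileext = ".phyml")
  savePhyml(ds, path)
  expect_true(datasetIdentical(readPhyml(path), ds))
})
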