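## Synthetic datasets and matrices with controllable structure, so every
## pipeline stage is testable without external downloads. All randomness
## is locally seeded (withSeed): no global RNG state leaks, and the same
## seed always yields byte-identical Phyml output.

#' Configuration for the synthetic dataset generator
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param nSources Number of sources (publications).
#' @param treesPerSource Length-2 integer range of trees per source.
#' @param taxonPool Size of the shared taxon pool (`Genus##_sp##` names).
#' @param treeTaxa Length-2 integer range of leaves per tree (min >= 4).
#' @param overlapBias Probability in `[0,1]` that a leaf is drawn from
#'   taxa already used by earlier trees; at `1`, each tree is forced to
#'   share at least two taxa with the previous tree, guaranteeing a
#'   connected overlap graph at `k = 2`.
#' @param polyphylyRate Per-leaf probability of splitting a taxon into
#'   `%1`/`%2` instances.
#' @param genusLeafRate Per-leaf probability of truncating a species to
#'   its genus.
#' @param years Length-2 publication-year range.
#' @param characterVocab data.frame with columns `type` and `name` to
#'   sample tree character data from.
#' @param speciesPerGenus Pool species per genus.
#' @return A validated list of class `synth_config`.
#' @export
synthConfig <- function(seed = 1L, nSources = 8L, treesPerSource = c(1L, 3L),
                        taxonPool = 40L, treeTaxa = c(5L, 12L),
                        overlapBias = 0.6, polyphylyRate = 0.05,
                        genusLeafRate = 0.05, years = c(1995L, 2013L),
                        characterVocab = defaultCharacterVocab(),
                        speciesPerGenus = 3L) {
  rates <- c(overlapBias = overlapBias, polyphylyRate = polyphylyRate,
             genusLeafRate = genusLeafRate)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0,1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (treeTaxa[1] < 4L) stop("treeTaxa minimum must be >= 4")
  if (taxonPool < treeTaxa[2])
    stop("taxonPool must be >= the maximum per-tree taxon count")
  if (!all(c("type", "name") %in% names(characterVocab)))
    stop("characterVocab needs columns 'type' and 'name'")
  structure(list(seed = as.integer(seed), nSources = as.integer(nSources),
                 treesPerSource = as.integer(treesPerSource),
                 taxonPool = as.integer(taxonPool),
                 treeTaxa = as.integer(treeTaxa),
                 overlapBias = overlapBias, polyphylyRate = polyphylyRate,
                 genusLeafRate = genusLeafRate, years = as.integer(years),
                 characterVocab = characterVocab,
                 speciesPerGenus = as.integer(speciesPerGenus)),
            class = "synth_config")
}

#' @rdname synthConfig
#' @export
defaultCharacterVocab <- function() {
  data.frame(
    type = c("molecular", "molecular", "molecular", "molecular",
             "morphological", "morphological", "behavioural"),
    name = c("cytb", "12S rRNA", "RAG1", "ND2",
             "osteology", "dentition", "vocalisation"),
    stringsAsFactors = FALSE)
}

.synthAnalyses <- c("parsimony", "Bayesian", "likelihood",
                    "neighbour joining")
.synthSurnames <- c("Adams", "Baker", "Clark", "Davis", "Evans", "Fischer",
                    "Garcia", "Hill", "Ivanov", "Jones")

#' Generate a synthetic dataset
#'
#' Trees are random binary topologies over taxa sampled from a shared
#' pool, with optional polyphyletic (`%d`) splits and genus-level leaves;
#' bibliographic metadata, character data and analyses are sampled from
#' fixed vocabularies. Deterministic under the config seed (including
#' history timestamps), so identical seeds give byte-identical Phyml
#' files.
#'
#' @param cfg A [synthConfig()] object.
#' @return A [PhyloDataset-class].
#' @export
generateDataset <- function(cfg = synthConfig()) {
  if (!inherits(cfg, "synth_config")) stop("cfg must come from synthConfig()")
  withSeed(cfg$seed, .generateDataset(cfg))
}

.generateDataset <- function(cfg) {
  nGenera <- ceiling(cfg$taxonPool / cfg$speciesPerGenus)
  pool <- character(cfg$taxonPool)
  for (i in seq_len(cfg$taxonPool)) {
    g <- (i - 1L) %/% cfg$speciesPerGenus + 1L
    s <- (i - 1L) %% cfg$speciesPerGenus + 1L
    pool[i] <- sprintf("Genus%02d_sp%02d", g, s)
  }
  used <- character(0)
  prevTaxa <- character(0)
  sources <- vector("list", cfg$nSources)
  for (si in seq_len(cfg$nSources)) {
    year <- sample(cfg$years[1]:cfg$years[2], 1L)
    surname <- sample(.synthSurnames, 1L)
    key <- sprintf("%s%d_%02d", tolower(surname), year, si)
    bib <- BibRecord(key = key, entryType = "article",
                     authors = c(paste0(surname, ", A."),
                                 paste0(sample(.synthSurnames, 1L), ", B.")),
                     title = sprintf("Phylogenetic relationships, study %d", si),
                     year = as.integer(year),
                     journal = "Journal of Synthetic Phylogenetics")
    nt <- sample(cfg$treesPerSource[1]:cfg$treesPerSource[2], 1L)
    trees <- vector("list", nt)
    for (ti in seq_len(nt)) {
      k <- sample(cfg$treeTaxa[1]:cfg$treeTaxa[2], 1L)
      sel <- .sampleTaxa(pool, used, prevTaxa, k, cfg$overlapBias)
      used <- union(used, sel)
      prevTaxa <- sel
      nl <- phyloToList(.randTopology(sel))
      nl <- .applyGenusLeaves(nl, cfg$genusLeafRate)
      nl <- .applyPolyphyly(nl, cfg$polyphylyRate)
      nChars <- sample(1:3, 1L)
      cd <- cfg$characterVocab[sort(sample(nrow(cfg$characterVocab), nChars)), ,
                               drop = FALSE]
      rownames(cd) <- NULL
      trees[[ti]] <- SourceTree(
        treeString = listToNewick(nl), characterData = cd,
        analysisUsed = sample(.synthAnalyses, 1L),
        fossilStatus = sample(c(.fossilLevels, NA_character_), 1L,
                              prob = c(0.7, 0.15, 0.05, 0.1)),
        pageRef = sprintf("%d", sample(1:500, 1L)))
    }
    sources[[si]] <- Source(bib, trees)
  }
  ds <- PhyloDataset(name = sprintf("synthetic_%d", cfg$seed),
                     sources = sources)
  appendHistory(ds, "generate",
                sprintf("seed=%d nSources=%d taxonPool=%d", cfg$seed,
                        cfg$nSources, cfg$taxonPool),
                timestamp = epochTimestamp())
}

.sampleTaxa <- function(pool, used, prevTaxa, k, bias) {
  sel <- character(0)
  if (bias >= 1 && length(prevTaxa) >= 2L)
    sel <- sample(prevTaxa, 2L)            # guarantee a k=2 overlap edge
  while (length(sel) < k) {
    fromUsed <- length(used) > length(sel) && stats::runif(1) < bias
    cand <- if (fromUsed) setdiff(used, sel) else setdiff(pool, sel)
    if (length(cand) == 0L) cand <- setdiff(pool, sel)
    sel <- c(sel, sample(cand, 1L))
  }
  sel
}

.randTopology <- function(labels) {
  t <- ape::rtree(length(labels), br = NULL)
  t$tip.label <- sample(labels)
  t
}

## Truncate random leaves to genus level; revert if the tree would fall
## below four leaves after duplicate-genus merging.
.applyGenusLeaves <- function(nl, rate) {
  if (rate <= 0) return(nl)
  walk <- function(node) {
    if (is.character(node)) {
      if (stats::runif(1) < rate) return(sub("_.*$", "", node))
      return(node)
    }
    lapply(node, walk)
  }
  out <- nlCollapse(.nlDeduplicate(walk(nl)))
  if (nlLeafCount(out) < 4L) nl else out
}

## Split random leaves L into two placements L%1 / L%2 (the second grafted
## as sister to another random leaf).
.applyPolyphyly <- function(nl, rate) {
  if (rate <= 0) return(nl)
  leaves <- nlLeaves(nl)
  toSplit <- leaves[stats::runif(length(leaves)) < rate]
  for (lab in toSplit) {
    others <- setdiff(nlLeaves(nl), c(lab, paste0(lab, "%1")))
    if (length(others) < 2L) next
    host <- sample(others, 1L)
    graft <- function(node) {
      if (is.character(node)) {
        if (node == lab) return(paste0(lab, "%1"))
        if (node == host) return(list(host, paste0(lab, "%2")))
        return(node)
      }
      lapply(node, graft)
    }
    nl <- graft(nl)
  }
  nl
}

#' Generate a binary matrix with planted STR structure
#'
#' Builds a conflict-free-by-construction background of distinct fully
#' known 0/1 rows (distinct full rows always conflict pairwise, so the
#' background itself admits no safe removal), then plants identical
#' groups (duplicated base rows) and subsumed rows (base rows with some
#' entries masked to `?`). The ground-truth removal plan is returned for
#' recovery testing.
#'
#' @param nTaxa Total rows, including planted ones.
#' @param nChars Number of characters.
#' @param nIdenticalGroups Number of identical groups to plant.
#' @param groupSize Rows per identical group (>= 2).
#' @param nSubsumed Number of subsumed rows to plant.
#' @param seed Integer seed.
#' @param maskRate Fraction of entries masked to `?` in subsumed rows
#'   (at least one entry is always masked).
#' @return A list with elements `matrix` ([MRPMatrix-class]) and
#'   `groundTruth` (list with `removed` and named `representatives`).
#' @export
generateStrMatrix <- function(nTaxa, nChars, nIdenticalGroups = 0L,
                              groupSize = 2L, nSubsumed = 0L, seed = 1L,
                              maskRate = 0.3) {
  nExtra <- nIdenticalGroups * (groupSize - 1L) + nSubsumed
  nBase <- nTaxa - nExtra
  if (groupSize < 2L) stop("groupSize must be >= 2")
  if (nBase < max(2L, nIdenticalGroups, 1L))
    stop("infeasible counts: only ", nBase, " background rows left for ",
         nIdenticalGroups, " identical groups")
  if (nChars < 2L) stop("need at least 2 characters")
  withSeed(seed, {
    base <- .distinctBinaryRows(nBase, nChars)
    rownames(base) <- sprintf("taxon_%04d", seq_len(nBase))
    rows <- base
    removed <- character(0)
    reps <- character(0)
    for (g in seq_len(nIdenticalGroups)) {
      for (d in seq_len(groupSize - 1L)) {
        nm <- sprintf("%s_dup%d", rownames(base)[g], d)
        rows <- rbind(rows, base[g, , drop = FALSE])
        rownames(rows)[nrow(rows)] <- nm
        removed <- c(removed, nm)
        reps[nm] <- rownames(base)[g]
      }
    }
    for (s in seq_len(nSubsumed)) {
      bi <- sample(nBase, 1L)
      r <- base[bi, ]
      nMask <- max(1L, stats::rbinom(1L, nChars, maskRate))
      r[sample(nChars, min(nMask, nChars - 1L))] <- "?"
      nm <- sprintf("%s_subs%d", rownames(base)[bi], s)
      rows <- rbind(rows, matrix(r, nrow = 1L))
      rownames(rows)[nrow(rows)] <- nm
      removed <- c(removed, nm)
      reps[nm] <- rownames(base)[bi]
    }
    colnames(rows) <- NULL
    list(matrix = MRPMatrix(rows),
         groundTruth = list(removed = sort(removed, method = "radix"),
                            representatives = reps))
  })
}

## Distinct random full 0/1 rows whose every column shows both states.
.distinctBinaryRows <- function(n, k) {
  m <- matrix(sample(c("0", "1"), n * k, replace = TRUE), nrow = n)
  repeat {
    dup <- duplicated(apply(m, 1, paste, collapse = ""))
    if (!any(dup)) break
    m[dup, ] <- sample(c("0", "1"), sum(dup) * k, replace = TRUE)
  }
  repeat {
    bad <- which(colSums(m == "0") == 0 | colSums(m == "1") == 0)
    if (length(bad) == 0L) break
    for (j in bad) {
      i <- sample(n, 1L)
      m[i, j] <- if (m[i, j] == "0") "1" else "0"
    }
    dup <- duplicated(apply(m, 1, paste, collapse = ""))
    while (any(dup)) {
      m[dup, ] <- sample(c("0", "1"), sum(dup) * k, replace = TRUE)
      dup <- duplicated(apply(m, 1, paste, collapse = ""))
    }
  }
  m
}
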