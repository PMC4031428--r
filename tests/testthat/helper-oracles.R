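# Independent oracles used across the suite. These are deliberately
# written as naive, direct implementations (position loops, BFS,
# exhaustive enumeration) so they share no code with the package paths
# they check.

# --- naive pairwise row comparison (Wilkinson equivalence) -------------
naiveCompareRows <- function(a, b) {
  aOnly <- FALSE; bOnly <- FALSE
  for (i in seq_along(a)) {
    if (a[i] != "?" && b[i] != "?") {
      if (a[i] != b[i]) return("non_equivalent")
    } else if (a[i] != "?") {
      aOnly <- TRUE
    } else if (b[i] != "?") {
      bOnly <- TRUE
    }
  }
  if (!aOnly && !bOnly) return("identical")
  if (!aOnly) return("a_subsumed_by_b")
  if (!bOnly) return("b_subsumed_by_a")
  "symmetric_equivalent"
}

naivePairTable <- function(cm) {
  n <- nrow(cm)
  out <- NULL
  if (n >= 2) for (a in 1:(n - 1)) for (b in (a + 1):n) {
    rel <- naiveCompareRows(cm[a, ], cm[b, ])
    if (rel != "non_equivalent")
      out <- rbind(out, data.frame(taxonA = rownames(cm)[a],
                                   taxonB = rownames(cm)[b],
                                   relation = rel,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(taxonA = character(0), taxonB = character(0),
                      relation = character(0), stringsAsFactors = FALSE)
  out
}

# --- brute-force graph reachability ------------------------------------
bfsComponentsCount <- function(leafSets, k) {
  n <- length(leafSets)
  if (n == 0) return(0L)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b && length(intersect(leafSets[[a]], leafSets[[b]])) >= k)
      adj[a, b] <- TRUE
  }
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  comps
}

# --- exhaustive parsimony on small matrices ----------------------------
toPhyDat <- function(m) {
  cm <- if (is(m, "MRPMatrix")) cells(m) else m
  phangorn::phyDat(cm, type = "USER", levels = c("0", "1"), ambiguity = "?")
}

# All unrooted binary topologies over the given labels (a single star for
# fewer than 4 labels, where topology is trivial).
allTopologies <- function(labels) {
  if (length(labels) < 4) {
    return(list(ape::read.tree(
      text = paste0("(", paste(labels, collapse = ","), ");"))))
  }
  phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
}

# Parsimony scores of trees on a {0,1,?} matrix. Indexing with [[ matters:
# multiPhylo objects may store tip labels compressed.
mpScores <- function(trees, m) {
  pd <- toPhyDat(m)
  if (inherits(trees, "phylo")) trees <- list(trees)
  vapply(seq_along(trees),
         function(j) phangorn::parsimony(trees[[j]], pd, method = "fitch"),
         numeric(1))
}

# --- quick dataset builders --------------------------------------------
dsFromNewicks <- function(..., name = "fixture", years = NULL,
                          chars = NULL) {
  groups <- list(...)   # one character vector of newicks per source
  sources <- lapply(seq_along(groups), function(i) {
    trees <- lapply(seq_along(groups[[i]]), function(j) {
      cd <- if (is.null(chars)) emptyCharacterData()
            else data.frame(type = "molecular", name = chars[[i]][[j]],
                            stringsAsFactors = FALSE)
      SourceTree(groups[[i]][j], characterData = cd)
    })
    year <- if (is.null(years)) 2000L + i else as.integer(years[i])
    Source(BibRecord(sprintf("src%02d", i), year = year,
                     authors = sprintf("Author%02d, A.", i)),
           trees)
  })
  PhyloDataset(name, sources)
}

# Random valid {0,1,?} matrix: every column has at least one 0 and one 1.
randomValidMatrix <- function(nTaxa, nChars, pMissing = 0.3) {
  m <- matrix("?", nTaxa, nChars)
  for (j in seq_len(nChars)) {
    repeat {
      col <- sample(c("0", "1", "?"), nTaxa, replace = TRUE,
                    prob = c((1 - pMissing) / 2, (1 - pMissing) / 2,
                             pMissing))
      if (any(col == "0") && any(col == "1")) break
    }
    m[, j] <- col
  }
  rownames(m) <- sprintf("t%02d", seq_len(nTaxa))
  MRPMatrix(m)
}
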