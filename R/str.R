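## Safe Taxonomic Reduction (STR) on binary MRP matrices. Two taxa are
## taxonomically equivalent (Wilkinson) when no character is known and
## different in both rows. A taxon whose known entries are a subset of
## another's (with agreement wherever both are known) contributes no
## grouping information of its own: removing it cannot change the set of
## most-parsimonious trees, and it can be reinserted next to its
## representative afterwards. Restricting states to {0, 1, ?} lets the
## whole pairwise scan be expressed as two matrix cross-products, which is
## what makes datasets of several thousand taxa tractable.

.relationLevels <- c("identical", "a_subsumed_by_b", "b_subsumed_by_a",
                     "symmetric_equivalent", "non_equivalent")

#' Compare two character rows for taxonomic equivalence
#'
#' @param rowA,rowB Character vectors over `{"0","1","?"}` of equal length.
#' @return One of `"identical"` (equal including the missing-data
#'   pattern), `"a_subsumed_by_b"` / `"b_subsumed_by_a"` (one row's known
#'   entries are a strict subset of the other's, agreeing where shared),
#'   `"symmetric_equivalent"` (no conflict, but each row has knowns the
#'   other lacks), or `"non_equivalent"` (some character known and unequal
#'   in both).
#' @export
#' @examples
#' compareRows(c("1", "?", "0"), c("1", "1", "0"))
compareRows <- function(rowA, rowB) {
  if (length(rowA) != length(rowB))
    stop("rows have different lengths: ", length(rowA), " vs ", length(rowB))
  if (length(rowA) == 0L) stop("rows must have length >= 1")
  ka <- rowA != "?"; kb <- rowB != "?"
  both <- ka & kb
  if (any(both & (rowA != rowB))) return("non_equivalent")
  aOnly <- any(ka & !kb); bOnly <- any(kb & !ka)
  if (!aOnly && !bOnly) return("identical")
  if (!aOnly) return("a_subsumed_by_b")
  if (!bOnly) return("b_subsumed_by_a")
  "symmetric_equivalent"
}

## Radix (C-locale) name ordering, for deterministic tie-breaks.
.lexOrder <- function(x) order(x, method = "radix")

## Pairwise relation codes for all taxa of a cells matrix, via BLAS
## cross-products on the 0/1/? indicator matrices.
## Codes: 0 non_equivalent, 1 identical, 2 a(row)_subsumed_by_b(col),
## 3 b(col)_subsumed_by_a(row), 4 symmetric_equivalent.
.relationMatrix <- function(cm) {
  n <- nrow(cm)
  kn <- t(cm != "?") * 1              # chars x taxa, known indicator
  vl <- t(cm == "1") * 1              # chars x taxa, known-one indicator
  conf1 <- crossprod(vl, kn - vl)     # [a,b] = #chars a=1 & b=0
  conf <- (conf1 + t(conf1)) > 0
  KK <- crossprod(kn)                 # [a,b] = #chars known in both
  kcounts <- colSums(kn)
  aOnly <- (kcounts - KK) > 0         # kcounts recycles down columns
  bOnly <- t(aOnly)
  rel <- matrix(0L, n, n)
  rel[!conf & !aOnly & !bOnly] <- 1L
  rel[!conf & !aOnly & bOnly] <- 2L
  rel[!conf & aOnly & !bOnly] <- 3L
  rel[!conf & aOnly & bOnly] <- 4L
  diag(rel) <- 0L
  dimnames(rel) <- list(rownames(cm), rownames(cm))
  rel
}

#' Classify pairwise taxonomic equivalence and plan safe removals
#'
#' Examines every pair of rows of the matrix and classifies it (see
#' [compareRows()]). The removal plan retains the maximal rows under
#' subsumption: a taxon is marked removable when its known entries are
#' subsumed by (or identical to) a retained representative's, so that its
#' removal is safe in Wilkinson's sense. Among mutually identical rows the
#' lexically smallest name is retained. Each removed taxon's
#' representative is the lexically smallest retained taxon that subsumes
#' it.
#'
#' Category letters reported per taxon: `A` member of an identical-rows
#' pair with no missing entries; `B` symmetric equivalence only (not
#' safe); `C` removed, strictly subsumed by its representative; `C*`
#' removed, identical to its representative (exactly reinsertable); `E`
#' no equivalence.
#'
#' @param m An [MRPMatrix-class].
#' @return An [EquivalenceReport-class].
#' @export
classifyMatrix <- function(m) {
  cm <- cells(m)
  n <- nrow(cm)
  taxaNames <- rownames(cm)
  rel <- .relationMatrix(cm)
  ut <- which(upper.tri(rel) & rel > 0L, arr.ind = TRUE)
  pairs <- data.frame(
    taxonA = taxaNames[ut[, 1]],
    taxonB = taxaNames[ut[, 2]],
    relation = .relationLevels[rel[ut]],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  ## Retained = maximal under subsumption; lexical tie-break within
  ## identical classes.
  lexRank <- integer(n)
  lexRank[.lexOrder(taxaNames)] <- seq_len(n)
  strictlySubsumed <- apply(rel == 2L, 1, any)
  removed <- logical(n)
  for (i in seq_len(n)) {
    if (strictlySubsumed[i]) { removed[i] <- TRUE; next }
    ident <- which(rel[i, ] == 1L)
    if (length(ident) && any(lexRank[ident] < lexRank[i]))
      removed[i] <- TRUE
  }
  retained <- which(!removed)
  repOf <- rep(NA_character_, n)
  for (i in which(removed)) {
    cand <- retained[rel[i, retained] %in% c(1L, 2L)]
    ## transitivity of subsumption guarantees a retained superior exists
    repOf[i] <- taxaNames[cand[which.min(lexRank[cand])]]
  }

  complete <- rowSums(cm == "?") == 0L
  categories <- rep("E", n)
  hasIdent <- apply(rel == 1L, 1, any)
  hasSym <- apply(rel == 4L, 1, any)
  for (i in seq_len(n)) {
    if (removed[i]) {
      repIdx <- match(repOf[i], taxaNames)
      categories[i] <- if (rel[i, repIdx] == 1L) "C*" else "C"
    } else if (hasIdent[i] && complete[i] &&
               any(rel[i, ] == 1L & complete)) {
      categories[i] <- "A"
    } else if (hasSym[i] && !hasIdent[i] && !any(rel[i, ] %in% 2:3)) {
      categories[i] <- "B"
    }
  }
  names(categories) <- taxaNames

  removals <- data.frame(taxon = taxaNames[removed],
                         representative = repOf[removed],
                         category = categories[removed],
                         stringsAsFactors = FALSE)
  removals <- removals[.lexOrder(removals$taxon), , drop = FALSE]
  rownames(removals) <- NULL
  new("EquivalenceReport", pairs = pairs, removals = removals,
      categories = categories)
}

#' Apply Safe Taxonomic Reduction to a matrix
#'
#' Drops the safely removable rows found by [classifyMatrix()] (and, as a
#' safety net, any column left without both a `0` and a `1`, although for
#' a valid matrix every removed row's known states are mirrored in its
#' representative, so no column can actually lose a state). Also emits a
#' plain-text category report and a [SubstitutionSet-class] mapping each
#' representative to itself plus its removed equivalents, so the removed
#' taxa can be reinserted into the final supertree as a polytomy at the
#' representative's position.
#'
#' @param m An [MRPMatrix-class].
#' @param restrictIdentical Reinsert (and remove) only members of
#'   identical-row groups (category `C*`); default `FALSE` removes all
#'   safely removable taxa.
#' @return A list with elements `reduced` ([MRPMatrix-class]), `report`
#'   (character scalar), `subs` ([SubstitutionSet-class]) and
#'   `equivalence` ([EquivalenceReport-class]).
#' @export
applyStr <- function(m, restrictIdentical = FALSE) {
  eq <- classifyMatrix(m)
  plan <- removals(eq)
  if (restrictIdentical) plan <- plan[plan$category == "C*", , drop = FALSE]
  cm <- cells(m)
  keep <- setdiff(rownames(cm), plan$taxon)
  red <- cm[keep, , drop = FALSE]
  colOk <- colSums(red == "0") > 0 & colSums(red == "1") > 0
  reduced <- MRPMatrix(red[, colOk, drop = FALSE],
                       provenance(m)[colOk, , drop = FALSE])
  subs <- if (nrow(plan)) {
    byRep <- split(plan$taxon, plan$representative)
    repNames <- names(byRep)[.lexOrder(names(byRep))]
    SubstitutionSet(repNames, lapply(repNames, function(r) {
      c(r, byRep[[r]][.lexOrder(byRep[[r]])])
    }))
  } else SubstitutionSet()
  list(reduced = reduced, report = .strReportText(m, eq, plan),
       subs = subs, equivalence = eq)
}

.strReportText <- function(m, eq, plan) {
  cats <- eq@categories
  lines <- c(
    "Safe Taxonomic Reduction report",
    "===============================",
    sprintf("Taxa: %d  Characters: %d", nrow(cells(m)), ncol(cells(m))),
    "",
    "Category convention:",
    "  A  - identical rows with no missing entries",
    "  B  - symmetric equivalence (complementary missing data; not safe)",
    "  C  - removed: known entries subsumed by the representative's",
    "  C* - removed: identical to the representative (exactly reinsertable)",
    "  E  - no equivalence",
    "",
    "Per-taxon categories:")
  ord <- .lexOrder(names(cats))
  lines <- c(lines, sprintf("  %-30s %s", names(cats)[ord], cats[ord]), "")
  if (nrow(plan)) {
    lines <- c(lines, "Safe removals (taxon -> retained representative):",
               sprintf("  %-30s -> %s", plan$taxon, plan$representative))
  } else {
    lines <- c(lines, "No taxa can be safely removed.")
  }
  eqp <- eq@pairs
  lines <- c(lines, "", sprintf("Non-trivial pairs: %d", nrow(eqp)))
  paste0(paste(lines, collapse = "\n"), "\n")
}
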