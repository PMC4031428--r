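## Newick parsing/writing sits on ape; this file adds the conventions the
## pipeline needs: topology-only trees, canonical taxon labels, a sentinel
## for trees pruned below two leaves, and clade-set utilities used for
## topology comparison and MRP coding.

#' Parse a Newick string into a topology-only tree
#'
#' Parses with [ape::read.tree()], then discards branch lengths, internal
#' node labels and root edges (supertree input is topological), collapses
#' any single-child nodes, and canonicalises leaf labels (whitespace
#' trimmed, internal spaces to underscores). Labels may carry a trailing
#' `%d` polyphyly marker, retained verbatim.
#'
#' @param s A single Newick string; the terminating semicolon is optional.
#' @return An [ape::phylo] object (or, for a single-leaf string such as
#'   `"(A);"`, a one-tip phylo).
#' @export
#' @examples
#' tr <- parseNewick("(A,(B,C));")
#' leafLabels(tr)
parseNewick <- function(s) {
  if (length(s) != 1L || !is.character(s))
    stop("expected a single Newick string")
  s <- trimws(s)
  if (!nzchar(s)) stop("empty Newick string")
  if (!grepl(";\\s*$", s)) s <- paste0(s, ";")
  nopen <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
  nclose <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
  if (nopen != nclose)
    stop("unbalanced parentheses in Newick string: ", nopen, " '(' vs ",
         nclose, " ')'")
  t <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                warning = function(w) NULL)
  if (is.null(t))
    stop("failed to parse Newick string: ", s)
  t$edge.length <- NULL
  t$node.label <- NULL
  t$root.edge <- NULL
  t$tip.label <- canonicalName(gsub("^'|'$", "", t$tip.label))
  if (any(!nzchar(baseName(t$tip.label))))
    stop("empty leaf label in Newick string")
  if (length(t$tip.label) > 1L) t <- ape::collapse.singles(t)
  t
}

#' Write a tree as a Newick string
#'
#' @param t An [ape::phylo] tree, a one-tip phylo, or the empty-tree
#'   sentinel (written as `";"`).
#' @return A single Newick string terminated by `;`.
#' @export
writeNewick <- function(t) {
  if (isEmptyTree(t)) {
    lv <- leafLabels(t)
    if (length(lv) == 1L) return(paste0("(", lv, ");"))
    return(";")
  }
  if (length(t$tip.label) == 1L) return(paste0("(", t$tip.label, ");"))
  ape::write.tree(t)
}

#' The empty-tree sentinel
#'
#' Pruning operations that leave fewer than two leaves return this sentinel
#' rather than a degenerate phylo object; [cleanData()] removes such trees
#' from a dataset.
#'
#' @param leaves Character vector of 0 or 1 remaining leaf labels.
#' @return An object of class `empty_tree`.
#' @export
emptyTree <- function(leaves = character(0)) {
  structure(list(leaves = leaves), class = "empty_tree")
}

#' @rdname emptyTree
#' @param t Any object.
#' @export
isEmptyTree <- function(t) inherits(t, "empty_tree")

#' Leaf labels of a tree
#'
#' @param t A phylo tree or empty-tree sentinel.
#' @return Character vector of leaf labels, in cladewise (pre-order) tip
#'   order.
#' @export
leafLabels <- function(t) {
  if (isEmptyTree(t)) return(t$leaves)
  t$tip.label
}

## ---- internal nested-list representation used for tree surgery ----
## A node is either a leaf (a character scalar) or an internal node
## (an unnamed list of >= 1 children). Surgery operations (deletion,
## substitution, permutation) are simple recursions on this form.

phyloToList <- function(t) {
  if (length(t$tip.label) == 1L) return(t$tip.label)
  t <- stats::reorder(t, "cladewise")
  nt <- length(t$tip.label)
  children <- split(t$edge[, 2], t$edge[, 1])
  build <- function(node) {
    if (node <= nt) return(t$tip.label[node])
    lapply(children[[as.character(node)]], build)
  }
  build(nt + 1L)
}

listToNewick <- function(nl) {
  render <- function(n) {
    if (is.character(n)) return(n)
    paste0("(", paste(vapply(n, render, character(1)), collapse = ","), ")")
  }
  if (is.character(nl)) return(paste0("(", nl, ");"))
  paste0(render(nl), ";")
}

## Count leaves of a nested-list node.
nlLeafCount <- function(nl) {
  if (is.null(nl)) return(0L)
  if (is.character(nl)) return(1L)
  sum(vapply(nl, nlLeafCount, integer(1)))
}

nlLeaves <- function(nl) {
  if (is.null(nl)) return(character(0))
  if (is.character(nl)) return(nl)
  unlist(lapply(nl, nlLeaves), use.names = FALSE)
}

## Collapse single-child internal nodes; drop empty subtrees (NULL).
## Returns a node, a leaf, or NULL if nothing remains.
nlCollapse <- function(nl) {
  if (is.null(nl) || is.character(nl)) return(nl)
  kids <- lapply(nl, nlCollapse)
  kids <- kids[!vapply(kids, is.null, logical(1))]
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1]])
  kids
}

## Convert a nested list back to a tree, returning the empty sentinel when
## fewer than two leaves remain.
nlToTree <- function(nl) {
  nl <- nlCollapse(nl)
  n <- nlLeafCount(nl)
  if (n < 2L) return(emptyTree(nlLeaves(nl)))
  parseNewick(listToNewick(nl))
}

#' Clade sets of a rooted tree
#'
#' Returns the leaf set subtended by each internal node except the root,
#' in pre-order. This is the basis of both MRP coding and topology
#' comparison.
#'
#' @param t A phylo tree or empty-tree sentinel.
#' @return A list of character vectors (each sorted).
#' @export
cladeSets <- function(t) {
  if (isEmptyTree(t) || length(leafLabels(t)) < 2L) return(list())
  nl <- phyloToList(t)
  out <- list()
  walk <- function(node, isRoot) {
    if (is.character(node)) return(invisible())
    if (!isRoot) out[[length(out) + 1L]] <<- sort(nlLeaves(node))
    for (k in node) walk(k, FALSE)
  }
  walk(nl, TRUE)
  out
}

#' Topology equality of two trees
#'
#' Two rooted trees are topologically equal when they have the same leaf
#' set and the same set of clades (child order is irrelevant).
#'
#' @param a,b phylo trees or empty-tree sentinels.
#' @return `TRUE` or `FALSE`.
#' @export
sameTopology <- function(a, b) {
  identical(topologyKey(a), topologyKey(b))
}

#' @rdname sameTopology
#' @param t A phylo tree or empty-tree sentinel.
#' @return For `topologyKey`, a canonical string identifying leaf set plus
#'   clade set.
#' @export
topologyKey <- function(t) {
  leaves <- sort(leafLabels(t))
  clades <- cladeSets(t)
  ck <- sort(vapply(clades, paste, character(1), collapse = ","))
  paste(paste(leaves, collapse = ","), paste(ck, collapse = ";"), sep = "|")
}
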