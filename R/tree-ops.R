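## Tree surgery: taxon deletion/substitution with node collapsing,
## polyphyly permutation, genus-to-species polytomy expansion, and the
## informativeness test. All operations maintain two invariants: no
## internal node with a single child, and no duplicated leaf label.

#' Delete taxa from a tree, collapsing superfluous nodes
#'
#' Removes every leaf whose base name (label without any `%d` marker) is
#' in `names`, then collapses internal nodes left with a single child.
#' Names absent from the tree are ignored with a warning.
#'
#' @param t A phylo tree (or empty-tree sentinel, returned unchanged).
#' @param names Character vector of taxon names to remove.
#' @return A phylo tree, or the [emptyTree()] sentinel if fewer than two
#'   leaves remain.
#' @export
#' @examples
#' writeNewick(deleteTaxa(parseNewick("(A,(B,C));"), "B"))
deleteTaxa <- function(t, names) {
  if (isEmptyTree(t)) return(t)
  names <- canonicalName(names)
  present <- baseName(leafLabels(t))
  missing <- setdiff(names, present)
  if (length(missing))
    warning("taxa not in tree, ignored: ", paste(missing, collapse = ", "))
  if (length(names) == 0L || !any(present %in% names)) return(t)
  nl <- phyloToList(t)
  prune <- function(node) {
    if (is.character(node)) {
      if (baseName(node) %in% names) return(NULL)
      return(node)
    }
    kids <- lapply(node, prune)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (length(kids) == 0L) return(NULL)
    kids
  }
  nlToTree(prune(nl))
}

#' Substitute or delete taxa in a tree
#'
#' Applies the rules of a [SubstitutionSet-class] to the tree: a leaf
#' matching a rule's old name is replaced by a single leaf (one
#' replacement), by a polytomy of new leaves (several replacements), or
#' deleted (no replacements). Matching is polyphyly-aware: an unmarked old
#' name matches every `%d`-marked instance of that taxon. If a
#' substitution would duplicate a leaf already in the tree, the first
#' occurrence in pre-order is kept and later duplicates are pruned.
#'
#' @param t A phylo tree (or empty-tree sentinel, returned unchanged).
#' @param subs A [SubstitutionSet-class].
#' @return A phylo tree or the [emptyTree()] sentinel.
#' @export
#' @examples
#' subs <- SubstitutionSet("B", list(c("X", "Y")))
#' writeNewick(substituteTaxa(parseNewick("(A,(B,C));"), subs))
substituteTaxa <- function(t, subs) {
  validObject(subs)
  if (isEmptyTree(t)) return(t)
  old <- canonicalName(subs@old)
  lookup <- function(label) {
    hit <- match(label, old)               # exact (marker-specific) rule
    if (is.na(hit)) hit <- match(baseName(label), old)
    hit
  }
  nl <- phyloToList(t)
  substitute1 <- function(node) {
    if (is.character(node)) {
      hit <- lookup(node)
      if (is.na(hit)) return(node)
      repl <- canonicalName(subs@replacements[[hit]])
      if (length(repl) == 0L) return(NULL)
      if (length(repl) == 1L) return(repl)
      return(as.list(repl))                # polytomy at the same position
    }
    kids <- lapply(node, substitute1)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (length(kids) == 0L) return(NULL)
    kids
  }
  nlToTree(.nlDeduplicate(substitute1(nl)))
}

## Prune duplicate leaves, keeping the first occurrence in pre-order.
.nlDeduplicate <- function(nl) {
  seen <- character(0)
  walk <- function(node) {
    if (is.null(node)) return(NULL)
    if (is.character(node)) {
      if (node %in% seen) return(NULL)
      seen <<- c(seen, node)
      return(node)
    }
    kids <- lapply(node, walk)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (length(kids) == 0L) return(NULL)
    kids
  }
  walk(nl)
}

#' Parse a substitution file
#'
#' Grammar: one rule per non-blank line, `old = new1, new2, ...`; an empty
#' right-hand side is a deletion. Whitespace around `=` and commas is
#' ignored. The same grammar is produced by [applyStr()] for post-analysis
#' reinsertion of safely removed taxa.
#'
#' @param text A single string or character vector of lines.
#' @return A [SubstitutionSet-class].
#' @export
#' @examples
#' parseSubsFile("Bos = Bos_taurus, Bos_indicus\nFelis =")
parseSubsFile <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  old <- character(0)
  repl <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (!grepl("=", line, fixed = TRUE))
      stop("line ", i, " has no '=': ", line)
    lhs <- canonicalName(sub("=.*$", "", line))
    rhs <- sub("^[^=]*=", "", line)
    if (!nzchar(lhs)) stop("line ", i, " has an empty old name")
    if (lhs %in% old) stop("duplicate old name '", lhs, "' at line ", i)
    parts <- trimws(strsplit(rhs, ",", fixed = TRUE)[[1]])
    parts <- canonicalName(parts[nzchar(parts)])
    old <- c(old, lhs)
    repl[[length(repl) + 1L]] <- parts
  }
  SubstitutionSet(old, repl)
}

#' @param subs A [SubstitutionSet-class].
#' @rdname parseSubsFile
#' @return For `writeSubsFile`, a single string in the same grammar.
#' @export
writeSubsFile <- function(subs) {
  if (length(subs@old) == 0L) return("")
  lines <- vapply(seq_along(subs@old), function(i) {
    paste0(subs@old[i], " = ", paste(subs@replacements[[i]], collapse = ","))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Enumerate polyphyly permutations of a tree
#'
#' Taxa marked with `%d` suffixes (e.g. `Bos%1`, `Bos%2`) record multiple
#' placements of one taxon. This generates every way of keeping exactly
#' one instance per polyphyletic taxon (marker stripped, other instances
#' deleted with node collapsing) so that a consensus can be built by
#' external software. Trees without markers yield a single-element list.
#'
#' @param t A phylo tree.
#' @param deduplicate Drop topologically identical permutations
#'   (default `TRUE`).
#' @param maxPermutations Refuse (with the required count in the error)
#'   when the product of instance counts exceeds this, unless
#'   `force = TRUE`.
#' @param force Override the `maxPermutations` guard.
#' @return A list of phylo trees.
#' @export
#' @examples
#' ps <- permuteTree(parseNewick("(A%1,(B,(A%2,C)));"))
#' vapply(ps, writeNewick, character(1))
permuteTree <- function(t, deduplicate = TRUE, maxPermutations = 1e6,
                        force = FALSE) {
  if (isEmptyTree(t)) return(list(t))
  labs <- leafLabels(t)
  marked <- labs[!is.na(polyphylyMarker(labs))]
  groups <- split(marked, baseName(marked))
  if (length(groups) == 0L) return(list(t))
  counts <- lengths(groups)
  total <- prod(counts)
  if (total > maxPermutations && !force)
    stop("tree has ", format(total, big.mark = ","),
         " polyphyly permutations (> ", maxPermutations,
         "); pass force = TRUE to enumerate them")
  choiceGrid <- expand.grid(groups, stringsAsFactors = FALSE)
  nl <- phyloToList(t)
  out <- vector("list", nrow(choiceGrid))
  for (i in seq_len(nrow(choiceGrid))) {
    keep <- unlist(choiceGrid[i, , drop = FALSE], use.names = FALSE)
    transform <- function(node) {
      if (is.character(node)) {
        if (node %in% marked) {
          if (node %in% keep) return(baseName(node))
          return(NULL)
        }
        return(node)
      }
      kids <- lapply(node, transform)
      kids <- kids[!vapply(kids, is.null, logical(1))]
      if (length(kids) == 0L) return(NULL)
      kids
    }
    out[[i]] <- nlToTree(.nlDeduplicate(transform(nl)))
  }
  if (deduplicate) {
    keys <- vapply(out, topologyKey, character(1))
    out <- out[!duplicated(keys)]
  }
  out
}

#' Replace genus-level leaves with polytomies of congeneric species
#'
#' A leaf whose name has no underscore is genus-level. For each such leaf,
#' all species `Genus_*` occurring anywhere in the dataset are collected;
#' if any exist, the leaf is replaced by a polytomy of those species
#' (species already present in that tree are not duplicated). Genus leaves
#' with no congeners in the dataset are left unchanged with a warning.
#' Intended as one of the final pipeline steps when building a
#' species-level supertree.
#'
#' @param ds A [PhyloDataset-class].
#' @param timestamp History timestamp (exposed for reproducible outputs).
#' @return The modified dataset, with one history entry appended.
#' @export
replaceGenera <- function(ds, timestamp = historyTimestamp()) {
  allTaxa <- taxa(ds, markers = FALSE)
  species <- allTaxa[grepl("_", allTaxa, fixed = TRUE)]
  genusOf <- sub("_.*$", "", species)
  for (si in seq_along(ds@sources)) {
    src <- ds@sources[[si]]
    drop <- integer(0)
    for (ti in seq_along(src@sourceTrees)) {
      st <- src@sourceTrees[[ti]]
      t <- parseNewick(st@treeString)
      genera <- unique(baseName(leafLabels(t)))
      genera <- genera[!grepl("_", genera, fixed = TRUE)]
      if (length(genera) == 0L) next
      old <- character(0); repl <- list()
      for (g in genera) {
        congeners <- sort(species[genusOf == g])
        if (length(congeners) == 0L) {
          warning("genus '", g, "' in ", src@citationKey, ":", ti,
                  " has no congeneric species in the dataset; left unchanged")
          next
        }
        old <- c(old, g)
        repl[[length(repl) + 1L]] <- congeners
      }
      if (length(old) == 0L) next
      t2 <- substituteTaxa(t, SubstitutionSet(old, repl))
      if (isEmptyTree(t2) && length(leafLabels(t2)) == 0L) {
        drop <- c(drop, ti)
        warning("tree ", src@citationKey, ":", ti,
                " lost all taxa during genus replacement; dropped")
        next
      }
      st@treeString <- writeNewick(t2)
      src@sourceTrees[[ti]] <- st
    }
    if (length(drop)) src@sourceTrees <- src@sourceTrees[-drop]
    ds@sources[[si]] <- src
  }
  appendHistory(ds, "replace_genera", "", timestamp)
}

#' Apply a substitution set to every tree of a dataset
#'
#' Trees reduced to a single leaf are kept (as `(X);`) for [cleanData()]
#' to remove; trees losing all leaves are dropped here with a warning.
#'
#' @param ds A [PhyloDataset-class].
#' @param subs A [SubstitutionSet-class].
#' @param timestamp History timestamp (exposed for reproducible outputs).
#' @return The modified dataset, with one history entry appended.
#' @export
applySubstitutions <- function(ds, subs, timestamp = historyTimestamp()) {
  for (si in seq_along(ds@sources)) {
    src <- ds@sources[[si]]
    drop <- integer(0)
    for (ti in seq_along(src@sourceTrees)) {
      st <- src@sourceTrees[[ti]]
      t2 <- suppressWarnings(
        substituteTaxa(parseNewick(st@treeString), subs))
      if (isEmptyTree(t2) && length(leafLabels(t2)) == 0L) {
        drop <- c(drop, ti)
        warning("tree ", src@citationKey, ":", ti,
                " lost all taxa during substitution; dropped")
        next
      }
      st@treeString <- writeNewick(t2)
      src@sourceTrees[[ti]] <- st
    }
    if (length(drop)) src@sourceTrees <- src@sourceTrees[-drop]
    ds@sources[[si]] <- src
  }
  params <- paste(vapply(seq_along(subs@old), function(i) {
    paste0(subs@old[i], "=", paste(subs@replacements[[i]], collapse = ","))
  }, character(1)), collapse = "; ")
  appendHistory(ds, "substitute_taxa", params, timestamp)
}

#' Is a tree informative for supertree construction?
#'
#' A tree contributes grouping information only when it has at least four
#' leaves and at least one clade (an internal node other than the root
#' subtending two or more, but not all, leaves). Star trees and very small
#' trees fail this and are removed by [cleanData()].
#'
#' @param t A phylo tree or empty-tree sentinel.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' isInformative(parseNewick("(A,B,C);"))
#' isInformative(parseNewick("((A,B),(C,D));"))
isInformative <- function(t) {
  if (isEmptyTree(t)) return(FALSE)
  n <- length(leafLabels(t))
  n >= 4L && length(cladeSets(t)) >= 1L
}
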