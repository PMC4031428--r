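# supertreeprep

Curation and matrix construction for supertree analyses.

Supertrees are large phylogenies assembled from tens to thousands of
smaller published source trees, most commonly by Matrix Representation
with Parsimony (MRP). Before any supertree algorithm can run, the source
trees have to be collected with their metadata, their taxonomy made
consistent, non-independent and uninformative trees removed, taxonomic
overlap verified, and the trees coded into one combined matrix. This
package implements that processing pipeline for R, for systematists
building species-level (or higher) supertrees:

* **A single-file XML dataset format** ("Phyml") coupling every source
  tree with its bibliographic record (BibTeX in/out), character data,
  analysis metadata and a history log of every processing step —
  `parsePhyml()`, `writePhyml()`, `importBibtex()`, `exportTrees()`.
* **Tree surgery** — `substituteTaxa()` / `deleteTaxa()` (synonym fixes
  and deletions that collapse superfluous nodes and never duplicate
  leaves), `permuteTree()` (enumeration of `%d`-marked polyphyletic
  placements), `replaceGenera()` (genus-level leaves expanded to
  polytomies of congeneric species present in the dataset).
* **Dataset checks** — `dataSummary()`, `cleanData()` (drops
  uninformative trees), `checkIndependence()` (identical / taxon-subset
  trees using the same characters), `checkOverlap()` (taxonomic-overlap
  graph with connectivity and DOT/GraphML export), `createSubset()`
  (metadata filters, e.g. molecular-only).
* **MRP coding** — `buildMatrix()` produces Baum–Ragan coding: for each
  informative clade *c* of each source tree *T*, a binary character with
  state 1 for members of *c*, 0 for the other taxa of *T*, and `?` for
  taxa absent from *T*, plus an optional all-zero `MRP_Outgroup` row for
  rooting. Writers for NEXUS (`writeNexus()`) and TNT xread
  (`writeTnt()`) are deterministic, byte for byte.
* **Safe Taxonomic Reduction (STR)** — `classifyMatrix()` classifies
  every taxon pair by Wilkinson's taxonomic equivalence on `{0,1,?}`
  rows (identical / subsumed / symmetric / non-equivalent) using a
  cross-product formulation that handles several thousand taxa in
  seconds; `applyStr()` removes the safely redundant taxa, writes a
  category report, and emits a substitution file that reinserts the
  removed taxa next to their representatives after the analysis.
  Removal is *safe*: every most-parsimonious tree of the reduced matrix,
  with the removed taxa reinserted, is most parsimonious for the full
  matrix.

A synthetic-data generator (`generateDataset()`, `generateStrMatrix()`)
produces seeded datasets and matrices with planted structure, and a CLI
(`inst/scripts/supertreeprep-cli.R`) exposes every step as a subcommand
over Phyml files.

## Worked example

```r
library(supertreeprep)

ds <- generateDataset(synthConfig(seed = 11, nSources = 4L))
ds
#> PhyloDataset 'synthetic_11'
#>   sources: 4  trees: 5  history entries: 1

cl <- cleanData(ds)                 # drop uninformative trees
checkOverlap(cl$dataset, k = 2)
#> OverlapResult (k >= 2): 5 trees, 8 edges, 1 component(s) -> connected

m <- buildMatrix(cl$dataset)
m
#> MRPMatrix: 21 taxa x 32 characters; 52.1% missing

out <- applyStr(m)
out$equivalence
#> EquivalenceReport: 70 non-trivial pair(s), 6 safely removable taxon/taxa

cat(substr(writeNexus(out$reduced), 1, 140))
#> #NEXUS
#>
#> BEGIN DATA;
#> 	DIMENSIONS NTAX=15 NCHAR=32;
#> 	FORMAT DATATYPE=STANDARD SYMBOLS="01" MISSING=?;
#> 	MATRIX
#> 	MRP_Outgroup 000000...
```

Read top to bottom: the overlap graph is connected (the dataset is fit
for a combined analysis); the 21 source taxa yield 32 MRP characters
with 52% missing data; STR finds 6 taxa whose rows carry no information
beyond another taxon's, so the matrix handed to PAUP\*/TNT shrinks to 15
rows (14 taxa + outgroup), and `out$subs` holds the rules that put the 6
taxa back into the finished supertree.

The same pipeline from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts","supertreeprep-cli.R",
                                  package="supertreeprep"))')
Rscript $CLI generate -o demo.phyml --seed 11 --sources 4
Rscript $CLI summary demo.phyml
Rscript $CLI overlap demo.phyml --min 2 --dot overlap.dot
Rscript $CLI matrix demo.phyml -o demo.nex --format nexus
Rscript $CLI str demo.nex -o reduced.nex --subs-out reinsert.txt
```

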