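---
title: "Inferring duplication-plus-functional-differentiation events from gene family trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring duplication-plus-functional-differentiation events from gene family trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfdscan)
```

## The question and the signature

After a gene duplicates, the most common fate of one copy is
pseudogenization and loss. When instead *both* copies persist in every
species descending from the duplication, something must have kept each of
them under selection — typically a differentiation of expression domains
or of function between the copies (sub- or neofunctionalization, or
escape from adaptive conflict). `dfdscan` calls such an event a
*duplication plus functional differentiation* (DFD) and looks for its
observable footprint in a gene-family tree: a **double-gene phylum**, two
sister clades descending from one duplication node whose species
compositions are identical.

The signature is necessary but not sufficient. A recent duplication also
shows full retention, simply because losses have not yet had time to
occur. The age of the duplication on a dated species tree is therefore
part of the verdict: only events older than a configurable cutoff are
reported as `DFD_LIKELY`; younger fully retained events are
`RETAINED_RECENT`. Conversely, duplications whose copies were lost in
many species, or in whole taxonomic families, are `NON_DFD_LOSSY`, and
everything in between is `AMBIGUOUS`. The verdicts partition the events:
every duplication receives exactly one.

## Reconciliation model

Duplications are inferred by last-common-ancestor (LCA) mapping. Each
gene leaf maps to its species-tree tip; each internal gene node `v` maps
to the MRCA of its children's images, computed in one postorder pass. A
binary node is a duplication iff its image equals a child's image. Losses
follow the standard parsimony embedding: for each gene-tree edge, one
loss per species-tree node skipped between the parent's and the child's
images (generalised to `k − 1` losses per skipped node with `k` children,
so polytomous *species* trees are allowed), plus the usual adjustment at
duplication nodes. Gene trees must be binary where duplications are
inferred; multifurcations are either rejected or, on request, resolved
deterministically in input order (`geneTree(resolve_polytomies = TRUE)`).

Each event's age interval is `[age(M(v)), age(parent(M(v)))]`: the
mapping tells us the duplication happened on the species-tree branch
above the mapped node. Events mapped to the species root have no parent;
they receive a configurable ceiling (`root_age_ceiling`, default 350 Mya,
about the age of the oldest WGD usually invoked for seed plants), never
below the root age itself, so intervals cannot invert.

The same accounting is implemented twice: once as the one-pass algorithm
used by the pipeline, and once as `oracleReconcile()`, an exhaustive
scorer that enumerates every valid reconciliation map (with memoisation)
and returns the minimum attainable duplication and loss counts. The two
must agree everywhere; the test suite and the acceptance script sweep
*all* species-tree topologies on 2–3 taxa crossed with *all* gene-tree
topologies on 2–4 leaves and all leaf-to-species assignments, plus
seeded random instances up to 5 taxa and 7 leaves. A literal exhaustion
at the largest sizes would be combinatorially idle (the instance count
grows as a product of double factorials and power sets); the stratified
sweep covers every small case completely and samples the larger strata
reproducibly.

## Clusters and naming

Paralog clusters are detected by walking the rooted, outgroup-free gene
tree from the root: a clade whose species set covers every *required
phylum* and whose root is not a species-overlap duplication (children
sharing at least one taxon) is a cluster; at overlap duplications the
walk descends, so duplication-separated copies of the family land in
separate clusters. Inside a cluster, the shallowest overlap duplication
(preorder tie-break) splits it into sub-lineages named `<cluster>.1`,
`<cluster>.2` in input order; one level of subdivision is reported, which
matches how such sub-lineages are named in practice. Cluster names are
anchored by user-supplied reference labels (e.g. which leaves are known
cluster-1 members); unanchored clusters are numbered in root-to-tip,
left-to-right order. When one species carries several copies in the same
(sub)cluster, ordinal letters `.a`, `.b` are appended in input order.

## Retention completeness and its denominator

For an event mapped to species node `s`, the denominator `D` is the set
of extant descendants of `s` **restricted to species with at least one
copy anywhere in the family**. Unsampled or unassembled genomes therefore
do not masquerade as losses; this mirrors the practice of counting
retention only over species for which family members could be retrieved
at all. Completeness per daughter is `|species(C_i) ∩ D| / |D|`.

Known hybrids and allopolyploids (e.g. allotetraploid tobacco or
rapeseed) carry homeologous copies that pair with different parental
lineages and distort both the tree and the retention counts; taxa flagged
in `dfdConfig(hybrid_taxa = ...)` are pruned before inference and listed
separately in the report.

## Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| `tol` | fraction | 0 | allowed missing fraction per daughter; 0 = strict identical composition, raise for gappy assemblies |
| `ancient_cutoff` | Mya | 100 | age above which full retention suggests differentiation; separates pre-angiosperm events (~200 Mya) from family-level WGDs (24–70 Mya) |
| `root_age_ceiling` | Mya | 350 | upper age bound for root-mapped events |
| `lossy_fraction` | fraction | 0.5 | a daughter missing at least this share of `D` counts as "lost in many species"; the field's sources do not quantify "many", so this is an explicit, configurable stand-in |
| `family_map` | — | none | taxon-to-family table enabling the "whole family lost" rule (zero copies in a family with ≥ 2 sampled taxa) |
| patristic threshold | subst/site | 0.05 | same-species copies closer than this on the guide tree collapse to one representative; "tightly clustered" is a visual notion in practice, so the default is an operational choice |

Curation thresholds (300 nt hard, 800 nt soft with keyword rescue) are
fixed by the workflow the package reproduces; the keyword list
(`heparanase`, `glucuronidase`, `GUS`) operationalises "recognised as a
family member by the source database" as a reproducible, case-insensitive
annotation match. The same-locus rule keeps the first-listed record — the
sources do not state their tie-break, and first-listed is deterministic.

## The simulator: what it emulates, and what it does not

`evolveGeneFamily()` generates families with known histories. One
ancestral gene enters the species root and, along every branch, each
lineage duplicates at `lambda_dup` and dies at `lambda_loss` (per Myr,
exponential waiting times; event order within a branch is strictly
decreasing in age, ties being almost surely impossible). WGDs are placed
on branches at fixed ages and double every live lineage, each copy
surviving with the event's `retention_prob`; a hexaploidization is
representable as two stacked doublings at the same age. Every duplication
(including a WGD doubling that keeps both copies) draws a
*differentiation lock* with probability `p_dfd`: both daughters and their
descendants have their loss rate multiplied by `lock_loss_factor`
(default 0, full protection) until a later duplication re-draws the lock
— protection is a property of the differentiated gene, not of one branch.
`lock_min_age` optionally restricts lock draws to events older than a
given age. With a fixed seed the output (tree, logs, tables) is
byte-identical across runs.

The generator reproduces the *retention geometry* the classifier relies
on: locked duplications leave double-gene phyla, unlocked ones decay.
It deliberately does not simulate sequences (no substitution model, so
no alignment or tree-estimation error), branch-length heterogeneity in
substitutions, gene conversion between paralogs, hybridization, or
incomplete genome sampling. Passing tests therefore show that the
inference chain is correct *given a correct gene tree*; they do not bound
errors introduced upstream by alignment and phylogeny estimation on real
data.

Scoring (`truthVsInferred()`) matches inferred duplication nodes to
logged events by their unordered pair of daughter leaf sets. A truth
event is detectable when both daughters left extant descendants. DFD
recall is computed over locked detectable events whose carrying branch
ends at or above `ancient_cutoff`: a locked duplication sitting on a
branch that ends below the cutoff maps to a node younger than the cutoff
under LCA reconciliation, so no age-qualified classifier could call it
ancient, and counting it would measure the species tree's node spacing
rather than the classifier.

## Study conditions used by the validation runs

The acceptance checks run at fixed, stated sizes chosen to be informative
at desk scale:

* **Demo family**: 14 sequences, 5 taxa — one representative copy set
  per major plant lineage with a moss outgroup; dated with round
  literature-scale ages (root 470 Mya, angiosperm crown 190 Mya, basal
  eudicot split 130 Mya).
* **Oracle sweep**: all topology pairs at 2–3 taxa × 2–4 gene leaves
  (4 183 instances) plus 200 seeded random instances up to 5 taxa and
  7 leaves; agreement must be 100%.
* **Calibration**: 2 000 replicates on a single 100-Myr branch at
  `lambda_dup = 0.01`, `lambda_loss = 0.005`; the mean extant copy number
  is compared with the analytic `e^{(λ−μ)t} = e^{0.5} ≈ 1.6487` within
  three standard errors.
* **Recovery**: 200 families on a 16-taxon tree with its root rescaled
  to 300 Mya — deep enough that several internal nodes are older than
  the 100-Mya cutoff, i.e. ancient duplications can exist at all. With
  `p_dfd = 1`, `lock_loss_factor = 0`, recall of `DFD_LIKELY` over
  locked ancient events must be exactly 1; with `p_dfd = 0` the
  `DFD_LIKELY` fraction must be non-increasing over the loss-rate grid
  {0.002, 0.01, 0.05}.

## Numerical and degenerate-input choices

* Species trees must be ultrametric within a relative tolerance of 1e-6;
  ages are recovered from branch lengths, the simplest unambiguous
  carrier of a time axis. Zero-length internal branches are rejected
  (node ages must strictly decrease toward the tips).
* Single-tip species trees are supported (they are the natural container
  for single-branch calibration runs).
* An empty gene family (all copies lost) is a *valid* simulation outcome:
  a warning, a `NULL` tree, and a complete loss log.
* Completeness with an empty denominator is an error — it indicates an
  inconsistent reconciliation, not a boundary case.
* The double-gene-phylum comparison uses a 1e-12 slack so that
  completeness values computed as ratios never fail `>= 1 - tol` by
  floating-point noise.
* Tight-paralog groups are single-linkage components of the
  "distance < threshold" graph; representatives are the longest CDS,
  ties broken by lexicographically smallest id.

## Known limitations

Reconciliation assumes the gene tree is correct and rooted; bootstrap
uncertainty is not propagated. Transfer events are out of scope, as are
statistical null models for retention (no p-values are attached to
verdicts) and any inference of expression differences — the signature
only *suggests* differentiation; confirming it requires expression data.
Whether an early-diverging single sequence (such as the *Scutellaria*
baicalinase inside cluster 3) reflects true early divergence or
long-branch attraction cannot be decided from placement alone; the
package only reports where it sits.
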