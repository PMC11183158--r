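---
title: "Methods: set partitions and their five views"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set partitions and their five views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setviews)
```

## The model: one partition, many views

Every analysis in this package starts from the same object: a collection of
$n$ named sets over a universe of elements (genes, differential metabolites,
OTUs/ASVs, enriched GO terms, ...). The collection induces a partition of
its elements into at most $2^n - 1$ *exclusive regions*: the region with
signature $S \subseteq \{1, \dots, n\}$, written `A&B&...` in the "&"
notation, holds the elements that belong to exactly the sets in $S$ and to
no others. These regions are the cells of a Venn diagram. The *inclusive*
intersection of $S$ is the full intersection cardinality,
$\mathrm{inc}(S) = \sum_{T \supseteq S} \mathrm{exc}(T)$.

All five diagram types are deterministic functions of this one partition:

* **Venn** (classic or Edwards, 2-6 sets) draws every region with its count;
* **Euler** (2-3 sets) draws circles whose region *areas* are proportional
  to the counts, omitting empty regions where geometry allows;
* **UpSet** (3-40 sets) lists the exclusive regions as sorted matrix
  columns;
* **flower** (3 to 70+ sets) reduces the partition to a shared core plus
  one per-set petal;
* **Venn network** renders the bipartite membership graph, where an
  element's degree is its membership multiplicity.

Because all views consume the same `RegionPartition`, their displayed
numbers are consistent by construction; the test suite checks this
cross-view agreement explicitly rather than assuming it.

## Input dialects and their normalization

Three dialects are read. The two-column TAB-separated long format (element,
set) is the canonical one; set order is the order of first appearance, and
duplicate (element, set) rows collapse. Pasted per-set element lists split
on newlines and commas. The "&"-signature count table gives (signature,
count) rows.

Tokens are trimmed of surrounding whitespace at both ends and compared
case-sensitively. Trimming removes the most common copy-paste artifact;
case sensitivity avoids silently merging distinct biological identifiers
(e.g. probe vs gene symbols differing only in case). Header handling is an
explicit flag, never inferred: silent header detection misreads inputs
whose first element legitimately looks like a title.

### Count-table semantics

A count table can mean two things: *exclusive* region sizes (the cells of
the drawn diagram) or *inclusive* intersection cardinalities. The package
defaults to **exclusive**, because that matches the region-by-region
reading of a drawn Euler diagram, and exposes `semantics = "inclusive"`
throughout. Inclusive tables are converted by Möbius inversion over the
subset lattice,

$$\mathrm{exc}(S) = \sum_{T \supseteq S} (-1)^{|T| - |S|}\, \mathrm{inc}(T),$$

with absent inclusive rows treated as zero. A consistent table inverts to
non-negative region counts; any negative recovered count aborts with the
offending signature named, since it certifies the input was not a valid
intersection table. Inversion then re-summation is the identity, which the
suite verifies on randomly generated consistent tables.

## Euler geometry

Radii are $r_i = \sqrt{|A_i| / \pi} \cdot s$ with $s$ chosen so the largest
circle has radius 1; one element therefore corresponds to a fixed drawn
area $\pi / \max_i |A_i|$ in every region. Two-circle overlaps use the
closed-form lens area

$$L(r_1, r_2, d) = r_1^2 \cos^{-1}\!\frac{d^2 + r_1^2 - r_2^2}{2 d r_1}
 + r_2^2 \cos^{-1}\!\frac{d^2 + r_2^2 - r_1^2}{2 d r_2}
 - \tfrac12\sqrt{(r_1 + r_2 - d)(d + r_1 - r_2)(d - r_1 + r_2)(d + r_1 + r_2)},$$

which is monotone non-increasing in $d$, so the center distance realizing a
target overlap is found by bisection on $[|r_1 - r_2|,\, r_1 + r_2]$
(default area tolerance $10^{-9}$). Two-set layouts are therefore exact up
to the bisection tolerance; disjoint sets are drawn with a gap of 20% of
the larger radius, and full containment at internal tangency.

Three circles have no exact solution in general. The layout initializes
the three pairwise distances from the exact two-circle inversions, places
the triangle by the law of cosines (clamped when the triangle inequality
fails), and then refines the three free coordinates (circle 1 pinned at
the origin, circle 2 on the positive x axis) with Nelder-Mead, minimizing
the stress

$$\sigma = \sum_{S} (\mathrm{area}_{\text{achieved}}(S) - \mathrm{area}_{\text{target}}(S))^2$$

over all seven signatures. Region areas have no convenient closed form, so
both the objective and the reported achieved areas use deterministic
quasi-random sampling: Halton points (bases 2 and 3) over the joint
bounding box, 20,000 per objective evaluation and 200,000 for the final
report (both configurable). Everything is deterministic -- Halton points
are a fixed sequence and Nelder-Mead from a fixed start is
deterministic -- so layouts are reproducible without any RNG. The
best-so-far objective trace is recorded and is non-increasing by
construction; it is exposed for inspection in the `stressTrace` slot.

Some target area vectors are not realizable by three disks (e.g. a triple
overlap larger than a pairwise one). These are drawn at the minimum stress
found, with a warning rather than an error, matching standard
Euler-diagram practice where an approximate diagram is more useful than a
refusal.

## Fixed Venn templates

Classic templates use overlapping circles (2-3 sets), two mirrored pairs
of congruent rotated ellipses (4 sets), five congruent ellipses in 5-fold
rotational symmetry (5 sets), and six triangles (6 sets). The Edwards
construction uses a vertical half-plane, a horizontal half-plane, a
circle, and closed serpentine curves that weave across the circle with 2,
4 and 8 lobes of decreasing amplitude.

None of these families has canonical published coordinates at the
precision the package needs, so the constants were fixed once by a seeded
numeric search within each family and frozen in the source
(`template-constants.R`). The search criterion: every one of the $2^n - 1$
interior cells must be present under grid sampling, with the smallest
cell's sampled area above 0.2% of the canvas so that a count label fits.
The six-set templates cannot reach that floor -- six-triangle Venn
diagrams and the 8-lobed Edwards curve intrinsically produce sliver cells
-- so their documented floors are 0.005% (classic, measured ~0.008%) and
0.05% (Edwards, measured ~0.1%), the best these families allow with a
margin. Grid verification at
500x500 runs in the test suite, so a regression in the frozen constants
cannot pass silently.

Count labels are placed at the centroid of each region's sampled cell;
when a non-convex cell's centroid falls outside it, the label snaps to a
deep interior point obtained by eroding the sampled mask, choosing the
deepest point nearest the centroid. Labels are therefore always inside
their regions, which the suite tests point by point.

## UpSet, flower, network

UpSet columns sort by count descending, then signature degree ascending,
then canonical signature lexicographically -- a total order, so shuffled
input reproduces identical output; a `sortBy = "degree"` override is
available. Keeping empty intersections enumerates all $2^n - 1$
signatures, which is capped at 12 sets (4095 columns) to bound the $2^n$
blowup; without empty intersections the column count is bounded by the
number of distinct elements, which is how 40-set inputs stay tractable.

Flower petals are congruent ellipses on a fixed orbit, petal $k$ rotated
by $2\pi k/n$; the tangential semi-axis and the label font scale as
$1/\sqrt{n}$ and $1/n$ respectively so that 70-set plots remain legible
(pairwise label separation is asserted geometrically in the tests). Petal
values are either the exclusive singleton counts ("unique") or set size
minus core ("residual"); residual + core = set size is an invariant.

The network view delegates its layout to a seeded Fruchterman-Reingold
force simulation (igraph), applied per connected component with
deterministic side-by-side packing; interactive physics from the
browser-based original reduces, in a library setting, to the contract that
layouts are deterministic for a seed, components do not overlap, and
elements sit nearer their member sets than others. The "flower-like"
display mode keeps exactly the degree-$n$ (core) and degree-1 (specific)
elements.

## Overlap significance

The platform-style "estimate" reports, for two sets of sizes $a$ and $b$
with overlap $k$ in a universe of size $N$, the one-sided hypergeometric
upper tail $P(X \ge k)$, $X \sim \mathrm{Hyper}(N, a, b)$ -- the standard
enrichment test for gene-list overlap (Fisher's exact test, one-sided). It
is computed through `phyper`, which is log-space stable for large counts;
the suite cross-checks a direct pmf enumeration up to $N = 200$ at
$10^{-12}$. The universe size is a required argument: inferring it from
the union of the two lists would systematically overstate significance,
and no default is safe across omics contexts (a genome's gene count, an
array's probe count, and a detected-metabolite panel differ by orders of
magnitude).

## Worked case reconstructions

The package ships generator functions (`caseMetaboliteCollection()`,
`caseRegulatorCollection()`, `caseOtuCollection()`, `caseGoCollection()`,
`caseEulerCountsText()`) that rebuild the published case studies'
membership structure from their printed summary counts: the five-part
metabolite comparison (119 shared by all five sets; unique counts 2, 5, 1,
0, 4; the stated pairwise-only counts), the seven-regulator ChIP target
comparison (3411 genes bound by all seven; 475 by the six excluding
H3K27ac; no single-regulator uniques), the 18-group OTU comparison (413
core ASVs; unique ASVs ASV_942, ASV_1022, ASV_1201 in WT3, OE1, KO3), and
the four-process GO network with its named genes. Element identifiers in
regions the source only reports as counts are synthetic (`Mcore0001`,
`g7x0001`, ...), and regions the source does not mention are left empty
(Cases I and III) or filled with fixed documented values between the
stated extremes (the Euler count table). These reconstructions exercise
the full pipeline end to end and reproduce the printed counts exactly;
they do not substitute for the original element-level supplementary
tables, and conclusions about those data should be drawn from the
originals.

## The synthetic collection generator

`generateCollection()` emulates the gross structure of multi-condition
comparisons: a core fraction present in every set, a unique fraction
spread one set at a time, and the remainder assigned to uniform random
non-empty subsets. Defaults (20% core, 20% unique) reflect the strongly
shared structure typical of replicate-style designs. What it does *not*
emulate: correlated set sizes, nested designs, abundance-driven detection,
or realistic identifier vocabularies. Passing tests on generated
collections therefore certify the combinatorics and geometry, not any
statistical property of real multi-omics data.

## Problem sizes and numerical choices

The test suite exercises 1000 random collections (up to 6 sets, up to 500
elements) against a brute-force region oracle, 100 random count tables for
the inversion round trip, 500x500 grid verification of all ten templates,
and 50 randomized hypergeometric checks; these sizes keep the full suite
comfortably within a few minutes on one CPU while covering every code
path. Ties in the UpSet sort break lexicographically; bisection runs at
most 200 halvings; Halton sampling replaces pseudo-random Monte Carlo
everywhere an area is estimated, trading a negligible bias for exact
reproducibility. Degenerate inputs are handled explicitly: empty
collections produce empty partitions and header-only CSVs, single-color
interpolation replicates the color, zero-overlap Euler targets draw
disjoint circles, and zero-count regions are omitted from partitions but
enumerable through the calculator.

## Known limitations

Euler layouts cover 2-3 sets only (by design; beyond three disks,
area-proportional circle diagrams are rarely faithful). Region areas in
Euler layouts are sampled, not exact, so reported achieved areas carry
Monte-Carlo error of order 0.2% at the default sample count. The 6-set
templates' sliver cells place labels correctly but can visually crowd at
small render sizes. GraphML export writes but does not re-read (JSON is
the round-trip format). SVG output targets correctness (one element per
primitive, exact label strings) rather than typographic polish.
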