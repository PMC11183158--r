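# setviews

Multi-view comparison of named sets for omics data: one region calculus,
five diagrams.

## The problem

Comparing lists of genes, differential metabolites, OTUs/ASVs or enriched
terms across conditions is one of the most common steps in multi-omics
analysis, and each comparison size calls for a different picture: Venn
diagrams up to 6 sets, area-proportional Euler diagrams for 2-3, UpSet
matrices for 3-40, flower plots beyond 10, and bipartite set-element
networks when the elements themselves matter. Tools for these views tend
to disagree on input formats and, worse, on the numbers they print.

`setviews` computes, once, the **exclusive-region partition** of an
n-set collection — every element assigned to the region of its full
membership signature `A&B&...`, giving the 2^n − 1 cells of a Venn
diagram — and derives every view from that single partition, so all
diagrams are mutually consistent by construction. Inclusive intersection
sizes are superset sums, inc(S) = Σ_{T ⊇ S} exc(T), and count-only inputs
in inclusive semantics are converted by Möbius inversion,
exc(S) = Σ_{T ⊇ S} (−1)^{|T|−|S|} inc(T), with inconsistent tables
rejected. Euler layouts solve circle distances from the closed-form lens
area by bisection (exact for 2 sets) and minimize the squared area stress
by deterministic Nelder-Mead over Halton-sampled region areas for 3 sets.
Pairwise overlap significance is the one-sided hypergeometric upper tail
P(X ≥ k), X ~ Hyper(N, a, b).

Inputs follow three standardized dialects: two-column TAB-separated
membership tables (element, set), pasted per-set element lists, and
"&"-signature count tables. Outputs are renderer-agnostic scene graphs
exported to SVG 1.1, per-region CSV element lists, and GraphML/JSON for
networks.

## Worked example

```r
library(setviews)

coll <- readTwoColumn("gene\tset
g1\tControl
g1\tTreated
g2\tControl
g3\tTreated
g3\tLate
g4\tControl
g4\tTreated
g4\tLate", hasHeader = TRUE)

vennCalculator(coll)
#>                 signature degree exclusive inclusive elements
#> 1                 Control      1         1         3       g2
#> 2                 Treated      1         0         3
#> 3                    Late      1         0         2
#> 4         Control&Treated      2         1         2       g1
#> 5            Control&Late      2         0         1
#> 6            Treated&Late      2         1         2       g3
#> 7    Control&Treated&Late      3         1         1       g4
```

Reading the table: `exclusive` counts are the Venn cells (g2 sits in
Control only; g4 in all three), and `inclusive` counts are full
intersections (|Control ∩ Treated| = 2 because g1 and g4 are in both).
The partition feeds any view:

```r
part <- exclusiveRegions(coll)
renderSVG(vennScene(part, mode = "edwards"), "venn.svg")
lay <- layoutEuler(part)
lay@stress
#> [1] 0.09737574
overlapSignificance(sizeA = 3, sizeB = 3, overlap = 2, universe = 20)
#> Hypergeometric overlap test
#>   |A| = 3, |B| = 3, overlap = 2, universe = 20
#>   expected overlap = 0.450, P(X >= 2) = 0.04561
```

The layout stress is the summed squared difference between achieved and
target region areas (in squared plot units, where the largest circle has
radius 1); this toy's seven tiny regions admit no exact three-disk
arrangement, so a residual stress remains. The p-value of 0.046 says the
two three-gene lists share more elements than independent draws from the
20-element universe would typically produce.

The same operations are scriptable through the bundled CLI
(`inst/scripts/setviews`), with subcommands `venn`, `euler`, `upset`,
`flower`, `network`, `calc` and `estimate`; every artifact embeds the tool
version, seed and input digest, and identical inputs produce byte-identical
outputs. A small demo membership table ships at
`inst/extdata/demo-two-column.tsv` (generated by `generateCollection()`
with a fixed seed):

```sh
setviews calc --input inst/extdata/demo-two-column.tsv --header --out-prefix demo
```

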