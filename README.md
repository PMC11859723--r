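# caulokit

High-resolution phylogenetics with minimally monophyletic groups: tools
for building and supporting ancestor–descendant trees (*caulograms*) from
morphological trait matrices, and for the distributional regularities —
the "rule of four" — that motivate them.

## Who this is for

Systematists and evolutionary biologists working with expressed
(morphological) traits who want descent-with-modification made explicit:
named ancestral species at tree nodes rather than anonymous cladogram
vertices. The unit of analysis is the **minimally monophyletic group**
(microgenus): one ancestral species plus its immediate descendants,
optimally at most four, each descendant inheriting the ancestor's newest
trait set (its **novon**) entire while adding a novon of its own.

## What it computes

* **Geometry of balanced peripatric speciation.** A regular *n*-gon
  inscribed in a circle splits the periphery of an ancestor's range into
  *n* equal descendant survival areas; the outside fraction
  `1 − n·sin(2π/n)/(2π)` falls steeply with *n*
  (`polygon_outside_fraction()`, `outside_fraction_series()`,
  `build_table1()`, with a Monte-Carlo cross-check).
* **Rank-law comparison.** Zipf's law `1/r^a`, the Zipf–Mandelbrot
  variant `1/(r+s)^a`, and the exponential meta-law `e^(−r/3)`; trendline
  fitting on linearised axes and RMSE-based curve comparison
  (`fit_trendline()`, `compare_to_laws()`).
* **Shannon-bit sequential-Bayes support.** One bit per new trait;
  bits add along ancestor chains and convert to posteriors via odds
  `2^b : 1` (`shannon_bits()`, `path_support()`, `bits_to_posterior()`);
  long edges flag extinct intermediates (`detect_extinction_gap()`).
* **The assembly protocol.** Outgroup polarisation, dual-criterion
  ancestor identification (most outgroup-similar + most generalist),
  novon extraction, microgenus assembly with secondary-descendant
  attribution, and caulogram construction with JSON + Newick output
  (`polarize()`, `identify_ancestor()`, `assemble_caulogram()`,
  `write_caulogram()`).
* **Hollow-curve diagnostics.** Species-per-genus histograms, the mass at
  ≤ 5 species, hollow-shape classification with power/exponential fits,
  the `log 5/log 4 = 1.16` fractal dimension, the rule-of-five bracketing
  probability 0.9375, and molecular paraphyly summary arithmetic
  (`size_histogram()`, `classify_hollow()`, `paraphyly_summary()`).
* **A seeded simulator.** Planted trait matrices with known ground truth
  and a peripatric-radiation simulator whose genus-size samples are
  hollow by mechanism, for method validation
  (`generate_planted_matrix()`, `simulate_peripatric()`).

## Worked example

A two-genus toy matrix ships with the package (synthetic, hand-wired so
every expected count is known): outgroup `OG`; genus g1 = ancestor `A1`
with descendants `X1`, `X2`; genus g2 = ancestor `A2` (derived from `A1`
by four traits) with `Y1`, `Y2`.

```r
library(caulokit)
tm <- read_trait_matrix(system.file("extdata", "toy_traits.csv", package = "caulokit"),
                        outgroup_id = "OG",
                        group_assignments = system.file("extdata", "toy_groups.csv",
                                                        package = "caulokit"))
cg <- assemble_caulogram(tm)
cg
#> caulogram: 6 species, 5 edges, 1 root(s) [A1]
#>   total support: 20 bits over the edges
cg$edges
#>   ancestor descendant bits
#> 1       A1         X1    4
#> 2       A1         X2    4
#> 3       A2         Y1    4
#> 4       A2         Y2    4
#> 5       A1         A2    4
```

Each edge carries the descendant's novon size: four new traits, four
bits. Support along a chain accumulates:

```r
path_support(cg, "A1", "Y2")
#> $bits
#> [1] 8
#> $posterior
#> [1] 0.9961089
```

Eight bits are odds of 256:1 that `Y2` descends through `A2` from `A1`
rather than the reverse reading. The Newick rendering keeps ancestors as
labelled internal nodes:

```r
caulogram_newick(cg)
#> (X1:4,X2:4,(Y1:4,Y2:4)A2:4)A1;
```

An 11-bit edge would flag an extinction gap — about one missing
intermediate species at the typical four-trait novon:

```r
detect_extinction_gap(11)
#> $flagged
#> [1] TRUE
#> $estimated_missing_intermediates
#> [1] 1
```

On the rank-law side, the published geometric rank column is matched
better by the exponential meta-law than by Zipf's law:

```r
geo <- rank_series(1:12, c(0.67, 0.50, 0.37, 0.27, 0.20, 0.15,
                           0.11, 0.09, 0.07, 0.06, 0.05, 0.04), "geometric")
compare_to_laws(geo)
#> curve_comparison for 'geometric'
#>   RMSE vs zipf     0.100028
#>   RMSE vs metalaw  0.021189 <- best
```

## Command line

A thin CLI wraps the same functions (installed at `exec/caulokit`, or run
`caulokit_main()` directly):

```sh
caulokit table1 --max-rank 12
caulokit build --matrix traits.csv --outgroup OG --groups groups.csv \
               --out tree.json --newick tree.nwk
caulokit support --caulogram tree.json --from A1 --to Y2
caulokit gaps --caulogram tree.json --threshold 9
caulokit simulate --seed 7 --founders 200 --epochs 20 --out sizes.csv
```

Exit codes: 0 success, 1 data/validation error, 2 usage error.

## File formats

* Trait matrices: CSV/TSV (first column species id, header of trait ids,
  `?` missing) or NEXUS standard characters blocks (via ape).
* Caulograms: schema-versioned JSON (authoritative; exact round trip)
  plus Newick with labelled ancestors and bit branch lengths.
* Genus sizes and paraphyly records: plain CSV.

The methods vignette (`vignettes/caulogram-methods.Rmd`) documents the
model, the protocol's decision rules and tie-breaks, the simulator's
assumptions and defaults, and known limitations.
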