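---
title: "Methods: diseasome construction, null models, homogeneity and candidate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diseasome construction, null models, homogeneity and candidate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseasome)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters, the numerical
conventions, the design choices made where the design was genuinely open,
and what the synthetic-data experiments do and do not demonstrate about
real data.

## The diseasome model

The root input is a disease–gene association table: rows of
`(disease_id, category, gene)`, with categories drawn from a closed
vocabulary of twelve organ-system labels plus `"multiple"`. The package
takes this table as given — merging synonymous diseases and resolving
gene-symbol synonyms are curation steps upstream of the analysis, and the
only normalization applied at the boundary is uppercasing of gene
symbols. A disease appearing with several category votes receives its
plurality category, or `"multiple"` on a tie (`resolve_category()`).

From the table, `build_bipartite()` makes a two-mode network (one edge
per distinct disease–gene pair), `restrict_to_anchor()` keeps exactly the
diseases whose gene sets intersect an anchor gene set — keeping *all*
their genes, not only the anchor genes — and `project()` collapses the
result onto disease nodes: diseases A and B are linked iff they share at
least one gene, with integer weight `|genes(A) ∩ genes(B)|`. One shared
gene suffices for a link; the weight is the exact intersection
cardinality. Diseases left without links remain as isolated nodes, so the
anchored disease count is preserved by projection. Internally the
projection is a sparse incidence cross-product, and its correctness is
tested against a brute-force double loop over all disease pairs.

## Network statistics

`centralities()` reports degree, betweenness and closeness on the
unweighted topology (the weighted diseasome is reported, but centralities
deliberately ignore weights — shared-gene counts are evidence of
association, not distances). Betweenness is the raw count of shortest
paths through a node, each unordered pair counted once. Because an
anchored diseasome may be disconnected, closeness uses the
within-component convention scaled by component size,
$C(v) = \frac{n_c-1}{\sum_u d(v,u)}\cdot\frac{n_c-1}{n-1}$, which stays
in $[0,1]$, never errors, and assigns 0 to isolated nodes.

`log_binned_distribution()` bins positive values into geometric bins
(`bins_per_decade` per factor of ten, default 5) starting at the minimum
value; each value is counted exactly once. Both the normalized frequency
(sums to 1) and the width-normalized density are emitted, because the
axis convention for heavy-tailed degree plots varies; the density is the
right quantity for slope reading, and a property test verifies that a
discrete power-law sample with exponent 2 yields a log–log density slope
within ±0.3 of −2.

## Permutation null models

The significance question is: does the observed anchored diseasome have
more links than expected if genes were assigned to diseases at random?
`shuffle_disease_genes()` redraws every disease's gene set — same size,
same category — uniformly without replacement (within the disease) from
the pooled set of all genes appearing in the map. `null_link_significance()`
recomputes the full statistic per trial (re-shuffle, re-restrict,
re-project, count links), then summarizes with the normal-theory z-score
$(real-\mu)/\sigma$, its one-sided upper-tail p-value, an empirical
permutation p-value $(1 + \#\{null \ge real\})/(trials+1)$, and the fold
change $real/\mu$. The default is 10,000 trials; the package's tests use
100–2,000. `intra_category_significance()` applies the same machinery to
the per-category counts of links joining two same-category diseases,
with category levels fixed from the full map so every trial reports the
same vector.

Two conventions are worth stating. First, whether the shuffle should
preserve each gene's disease-multiplicity is genuinely open; the default
does not (a gene may land in any number of diseases), and
`preserve_gene_degree = TRUE` provides the multiplicity-preserving
variant (a permutation of the gene column of the long table) for
sensitivity analysis. Second, a degenerate null ($\sigma = 0$) is
reported as a flag, never as an invented z-score.

## Pathway and GO homogeneity

For disease $i$, with $n_i$ the number of its genes annotated to at least
one gene set and $n_{ji}$ the number annotated to set $j$,

$$PH_i = \max_j \frac{n_{ji}}{n_i} \in (0, 1],$$

undefined (flagged, excluded) when $n_i = 0$. GO homogeneity is the same
statistic computed per aspect (BP, MF, CC) on flat term-membership
annotations; no propagation over the ontology graph is performed —
annotations are taken as retrieved. Note a property that looks intuitive
but is false in general: enlarging the set collection does *not*
monotonically increase $PH_i$, because extra sets can annotate previously
unannotated genes and grow the denominator. The max-over-sets monotonicity
holds exactly when $n_i$ is unchanged, and that is the form the property
test asserts.

`perfect_homogeneity_test()` counts the diseases with $PH = 1$ and
compares against a null in which each scorable disease's *annotated gene
count* $n_i$ is redrawn uniformly from the universe of annotated genes.
Holding $n_i$ (rather than the raw gene-set size) fixed is deliberate:
$PH$ is a statistic of the $n_i$ annotated genes only, and redrawing the
full set size from the all-annotated universe would systematically raise
the null's annotated counts and bias the z-score upward even under the
null. With the matched null, data generated with zero planted coherence
yield z-scores centred on 0 — a calibration the test suite checks over 50
replicates. The fold change is the ratio of the real $PH = 1$ count to
the null mean count; the z-score reduces to the plain
$(real - \mu)/\sigma$ of that count, verified against a brute-force
recomputation on frozen seeds. Single-gene diseases are always perfectly
homogeneous, in the data and in every trial; a map consisting only of
such diseases therefore produces a degenerate (flagged) null.

`degree_vs_homogeneity()` and `shared_genes_vs_mean_ph()` summarize how
functional coherence relates to connectivity: mean disease degree per
homogeneity bin, and mean endpoint homogeneity per shared-gene count.

## DIAMOnD expansion

`hypergeom_pmf()` and `connectivity_pvalue()` implement the
connectivity-significance model: in an $N$-node interactome whose current
disease module has $s_0$ members, a protein with $k$ links, $k_s$ of them
into the module, has

$$p(k, k_s) = \frac{\binom{s_0}{k_s}\binom{N-s_0}{k-k_s}}{\binom{N}{k}},
\qquad
p\text{-value}(k, k_s) = \sum_{k_i=k_s}^{\min(k, s_0)} p(k, k_i).$$

Both are evaluated in log space (`lchoose` + log-sum-exp); the upper
summation limit is capped at $\min(k, s_0)$, where the mass beyond is
identically zero. The pmf sums to one over its support to $10^{-10}$
across a thousand random argument tuples, and the tail matches
term-by-term brute-force sums in log-space comparison.

`diamond_rank()` iterates: score every non-module node with at least one
module link, move the smallest-p node into the module, repeat
(`n_iterations` default 1000). Module members added along the way count
toward $s_0$ in subsequent rounds; `fixed_s0 = TRUE` freezes $s_0$ at the
seed count and then scores links to the original seeds only (so
$k_s \le s_0$ always holds), as a sensitivity variant. Determinism
requires a complete tie policy: p-values are compared after rounding to
12 significant digits — mathematically equal tails reached through
different summation orders must compare equal — with ties broken by
higher $k_s$, then lexicographic gene id. The ranking is tested for exact
equality against an independent brute-force implementation that rescores
every node each round with `stats::phyper`. Nodes unreachable from the
seeds simply never acquire $k_s > 0$; no largest-connected-component
restriction is imposed.

## Boundary and screening

The expansion ranks as many genes as asked; the biologically meaningful
prefix is found by pathway enrichment. `seed_enrichment()` tests each
pathway for enrichment in the seed genes by one-sided Fisher's exact test
(enrichment is the only coherent direction here) over a background
defined as interactome genes ∩ annotated genes — the genes that *could*
have been ranked and annotated — with BH correction across pathways and
an adjusted-p cut-off of 0.05. `sliding_window_boundary()` slides a
window of `w` consecutive ranks (convention: `w` = seed count, stride 1,
both configurable) and Fisher-tests each window's overlap with the union
of seed-significant pathway genes against the background. The boundary is
the end rank of the last window in the *initial* contiguous run of
windows with $p < 0.05$ — the ranking is a quality-ordered sequence, so
the first failure marks where reliable biology stops; a `"last_pass"`
mode (last significant window anywhere) is available for comparison. If
the first window already fails, the boundary is 0 and nothing is
accepted.

Accepted candidates then pass three orthogonal screens: membership in a
seed-significant pathway (`flag_true_hits()`), an abnormal-heart mouse
ortholog (`mouse_phenotype_screen()`; candidates whose orthologs carry
only non-heart phenotypes are dropped), and expression in the tissue of
interest (`expression_screen()`, pTPM strictly greater than 2 — a gene at
exactly 2.0 is dropped, at 2.5 kept). All screens are set-monotone.
Finally `new_disease_links()` augments the anchor disease's gene set with
the surviving candidates and reports the diseases newly linked through
them, crediting every candidate shared on a new link (a link naming
several candidates credits each) with contribution percentages over the
total new-link count.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` holds every tunable. The generators share one gene
universe so pathway, interactome and screening tables join on the same
symbols, and all are byte-deterministic given the seed.

* `generate_disease_gene_data()`: each disease gets a home pathway
  (round-robin) and draws each gene from it with probability `coherence`
  (π), else uniformly from the universe; categories rotate through the
  twelve organ-system labels; disease sizes follow a truncated power law.
  GO-style annotations mirror the pathways (one term per aspect per
  pathway, 90% member coverage) so planted coherence carries to the GO
  aspects. Mean homogeneity rises monotonically with π; π = 1 with
  disease sizes below the smallest pathway gives all $PH = 1$, and π = 0
  reproduces the homogeneity test's null.
* `generate_interactome()`: Erdős–Rényi background (`p_bg`, default 0.02)
  over `n_nodes` (default 400) genes with a planted `module_size`-gene
  module densified to `p_mod` (default 0.3), plus a random seed subset of
  the module; `module_genes` lets callers align the module with a pathway
  so boundary detection sees real enrichment structure.
* `generate_screening_tables()`: mouse orthologs cover
  `ortholog_coverage` of the universe; abnormal-heart flags are planted
  at `heart_rate_true` (default 0.5) on designated true candidates and
  `heart_rate_background` (default 0.05) elsewhere; pTPM is log-normal
  per tissue (default meanlog 2, sdlog 1: median ≈ 7.4, comfortably
  above the 2.0 presence cut-off).

The corpus defaults — 400 diseases over a 500-gene universe, 40 pathways
of 12–25 genes, disease sizes 1–30 from a power law with exponent 1.8,
π = 0.8 — were chosen once to reproduce, at desk scale, the statistical
regime of a curated disease-gene corpus: small median gene counts with a
heavy tail, dense sharing inside same-pathway disease families, and a
corpus that nearly saturates its gene universe. That last property
matters for the permutation null: the shuffle draws from the pooled
*observed* genes, and when the corpus uses only a small fraction of its
universe the null operates on a much smaller pool than the data were
drawn from, mechanically inflating both anchor retention and chance
collisions — which would push the z-score negative for *any* clustered
structure.

What the generator does **not** emulate: strong hub-gene pleiotropy —
single genes implicated in dozens of diseases across families — which in
real corpora is a major driver of strongly positive link-count z-scores;
literature-curation noise; and realistic annotation content. Passing
tests on synthetic data therefore demonstrate correctness and calibration
of the machinery, not effect sizes to expect on real corpora: at these
defaults the anchored link-count z fluctuates around small positive
values across seeds, far below what a real hub-rich corpus shows.

## Numerical conventions and degenerate inputs

* All hypergeometric quantities in log space; p-values clipped into
  $(0, 1]$.
* Tie policy of the expansion: p rounded to 12 significant digits, then
  higher $k_s$, then lexicographic id (fully deterministic across
  platforms).
* Degenerate nulls ($\sigma = 0$) are flagged, never scored; undefined
  homogeneity ($n_i = 0$) is flagged and excluded from counts in both
  real and null runs.
* Empty tables, empty restrictions, exhausted candidate pools and absent
  expression rows warn or log and return empty objects rather than error;
  malformed files (missing columns, non-numeric weights, short GMT lines,
  duplicate set ids) error with the offending location.
* Every randomized routine takes an explicit integer seed and records it
  in its report; reruns reproduce results exactly.

## Problem sizes used by the test-suite and acceptance script

The suite exercises: exact projection against a brute-force oracle at
146 diseases × 1929 genes; 1,000 random tuples for the pmf; 50 random
graphs for oracle equivalence of the expansion; 100 replicates × 500
trials for null calibration; 50 replicates × 400 trials for homogeneity
calibration; 20 replicates of the 400-node planted-module recovery; and
the boundary/screening constructions described above. The acceptance
script runs the generator at its defaults with 2,000-trial nulls and a
200-iteration expansion. These sizes are the package's choices for
routine verification; all scale up through the exported parameters.

## Known limitations

* The input table is assumed pre-merged; no disease-name fuzzy matching
  or gene-synonym resolution is attempted.
* GO annotations are used flat; ancestor propagation would raise $n_i$
  and generally lower GH.
* The exact 2×2 table of the sliding-window test (window vs background,
  membership in the seed-enriched gene universe) is one defensible
  reading of the boundary construction; the window size, stride, mode
  and background are all exposed for sensitivity analysis.
* Contribution percentages multi-credit shared candidates, so they can
  sum to more than 100 across candidates by design.
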