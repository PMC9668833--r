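# diseasome

Disease–gene networks, diseasome projection and candidate-gene screening.

Complex diseases — cardiomyopathies are the motivating case — share
implicated genes with diseases in entirely different organ systems. A
*diseasome* makes that shared genetic architecture explicit: diseases are
nodes, and two diseases are linked whenever at least one gene is
implicated in both, with the link weighted by the shared-gene count.
`diseasome` implements the full analysis pipeline around that object for
researchers in network medicine and systems biology:

* **Bipartite construction and projection.** From a disease–gene
  association table, build the bipartite disease–gene network, restrict
  it to the diseases touching an *anchor* gene set (e.g. the known
  cardiomyopathy genes), and project onto disease nodes; edge weight
  `w(A, B) = |genes(A) ∩ genes(B)|`.
* **Permutation null models.** Re-draw every disease's gene set (same
  size, pooled genes), re-restrict, re-project, and summarize the observed
  link count against the randomized distribution with a normal-theory
  z-score, one-sided p-value and fold change; the same machinery covers
  per-category intra-category link counts.
* **Pathway / GO homogeneity.** Per disease, `PH_i = max_j (n_ji / n_i)`,
  the largest fraction of its annotated genes falling in a single pathway
  (or GO term, separately per BP/MF/CC aspect), with a permutation test of
  the count of perfectly homogeneous (PH = 1) diseases.
* **DIAMOnD candidate prediction.** Iterative seed-expansion over an
  interactome: a node with `k` links, `k_s` of them into the current
  `s0`-gene module, is scored by the hypergeometric tail
  `p(k, k_s) = Σ_{k_i ≥ k_s} C(s0, k_i) C(N−s0, k−k_i) / C(N, k)`,
  and the most significant node joins the module each round.
* **Boundary + screening.** A sliding window of ranked genes (window size
  = seed count) is tested by one-sided Fisher's exact test for enrichment
  in the seed-enriched pathway universe (BH-corrected seed enrichment,
  cut-off 0.05); the boundary ends the initial run of significant
  windows. Accepted candidates are screened against abnormal-heart mouse
  orthologs and tissue expression (pTPM strictly > 2), and the new
  diseasome links they create are attributed per candidate.
* **Synthetic data with planted structure.** Every input — corpus,
  pathways, GO annotations, interactome, screening tables — can be
  generated with tunable pathway coherence, a planted dense interactome
  module and planted phenotype signal, so each stage is testable and
  calibratable offline.

## Worked example

```r
library(diseasome)

tab <- validate_disease_gene_table(data.frame(
  disease_id = c("HCM", "HCM", "HCM", "DCM", "DCM", "Alzheimer disease"),
  category   = c("cardiovascular", "cardiovascular", "cardiovascular",
                 "cardiovascular", "cardiovascular", "nervous"),
  gene       = c("MYH7", "TNNT2", "NOS3", "MYH7", "LMNA", "NOS3")))

bn <- build_bipartite(tab)
bn
#> bipartite_network: 3 diseases, 4 genes, 6 edges

d <- project(restrict_to_anchor(bn, anchor_genes = c("MYH7", "TNNT2")))
igraph::as_data_frame(d)
#>   from  to weight
#> 1  DCM HCM      1
```

Only HCM and DCM contain an anchor gene, so the anchored diseasome keeps
those two diseases (with *all* their genes) and links them through their
one shared gene, MYH7. The connectivity p-value behind the DIAMOnD
ranking is exposed directly — a protein with 5 links, 3 into a 12-protein
module inside a 400-protein interactome, is a strong candidate:

```r
connectivity_pvalue(k = 5, k_s = 3, N = 400, s0 = 12)
#> [1] 0.0002007966
```

Candidate genes surviving the screens are credited with the new disease
links they create. Dropping the NOS3 row from HCM above and then asking
what the candidate NOS3 would add:

```r
dgm <- disease_gene_map(tab_without_nos3_in_hcm)
new_disease_links(dgm, "HCM", candidates = "NOS3")
#> $links
#>             disease shared_candidates
#> 1 Alzheimer disease              NOS3
#> $contribution
#> NOS3
#>  100
```

NOS3 alone creates the HCM–Alzheimer link, hence a 100% contribution —
the miniature version of how candidate genes fill in missing
cross-disease links at corpus scale.

The full pipeline (projection → nulls → homogeneity → DIAMOnD → boundary
→ screens → link attribution) runs from a directory of input files via
`run_pipeline()`; `simulate_inputs()` writes a complete synthetic bundle
to start from. See the methods vignette (`vignettes/diseasome-methods.Rmd`)
for the models, parameters and design choices.

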