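# gecn — enzyme correlation networks and co-expressed metabolic routes

Proteomic and metabolomic measurements of many tissues — fast-growing
pollen tubes and pollinated stigmas are the motivating case — are hard or
impossible to obtain, while transcriptomes are routine. `gecn` turns
transcript-level evidence into metabolic-route evidence by the
"guilt by association" principle: if the genes encoding the enzymes of
**consecutive** steps of a metabolic route are all differentially
expressed in the same process, the route is inferred active in that
process.

The package is for systems biologists working from pathway-genome-database
dumps (BioCyc/PlantCyc-style flat files or a plain TSV schema) plus
differential-expression tables. It provides:

* **Network construction** — a genome-scale enzyme correlation network
  (GECN): enzymes are nodes, and a directed edge E₁ → E₂ exists iff some
  product of a reaction of E₁ is a substrate of a reaction of E₂ and the
  shared compound is not a *currency metabolite*:

  E₁ → E₂  ⇔  ( P(E₁) ∩ S(E₂) ) \ C ≠ ∅

  with C defaulting to {H+, ADH/NADH, NADP, NADPH, NH3, ATP, ADP, AMP,
  NAD, CoA, O2, CO2, Glu, pyrophosphate}. Matching is exact-token, so
  `acetyl-CoA` is never excluded just because `CoA` is.
* **DEG overlay** — genes passing fold change ≥ 2 and FDR ≤ 1e-10 (both
  inclusive, in ≥ 1 contrast) are mapped to the enzymes they encode; the
  sub-interaction network is the GECN induced on those enzymes with
  isolated nodes dropped.
* **Route extraction** — all maximal simple reaction chains in which every
  consecutive pair shares a non-currency metabolite and every step has at
  least one DEG-encoded enzyme, plus per-step gene/EC expression reports.
* **Topology & comparison** — connected components, the connected-pairs
  statistic Σₖ nₖ(nₖ−1)/2, degree tables, and cross-species network
  overlap keyed on EC number.
* **I/O & fixtures** — BioCyc-style attribute-value parsing, a canonical
  TSV bundle schema, DEG/PPI/SIF readers and writers, a seeded synthetic
  database generator with plantable routes, and packaged worked-example
  fixtures transcribing published pollination routes.

## Worked example

The glycolysis-IV fixture shows the characteristic result of the method: a
7-step pathway chain whose longest DEG-covered route is only 5 steps,
because no differentially expressed gene encodes the aldolase step.

```r
library(gecn)

fx   <- paper_fixture("fig7_glycolysis_IV")
degs <- call_degs(fx$deg_table)          # fold change >= 2, FDR <= 1e-10
g    <- build_gecn(fx$db)                # currency metabolites excluded
g
#> <gecn> 7 enzyme node(s), 6 directed edge(s)

chain <- pathway_chain(fx$db, fx$pathway_id)
chain
#> <pathway_chain> pathway PWY-GLYCOLYSIS-IV: 1 chain(s); longest 7 reaction(s)

routes <- find_maximal_routes(chain, degs, fx$db)
routes
#> <route_set> 2 maximal route(s)
#>   [5] RXN-GLY-3 -> RXN-GLY-4 -> RXN-GLY-5 -> RXN-GLY-6 -> RXN-GLY-7
#>   [1] RXN-GLY-1
```

The 7-step chain breaks at step 2 (fructose-bisphosphate aldolase, EC
4.1.2.13, no DEGs), leaving a maximal covered route of 5 reactions
(GAPDH → phosphoglycerate kinase → phosphoglycerate mutase → enolase →
pyruvate kinase) and an isolated length-1 route at the
phosphofructokinase entry step. `route_report(longest_route(routes),
fx$deg_table)` expands this to one row per step gene (18 rows here) with
EC, contrast, log2 fold change, FDR and the linking metabolite, and
`plot_route_profile()` draws the per-step expression profile.

A thin command-line front end wraps the same functions
(`inst/cli/gecn.R`): `fixture`, `build`, `map-degs`, `routes`, `stats`,
`overlap`.

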