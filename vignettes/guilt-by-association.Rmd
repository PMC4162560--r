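---
title: "Enzyme correlation networks and co-expressed metabolic routes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme correlation networks and co-expressed metabolic routes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gecn)
library(dplyr)
```

## The model

Transcript-level evidence can stand in for hard-to-measure proteomic and
metabolomic data when it is read through the structure of the metabolic
network. The idea — "guilt by association" — is that if the genes encoding
the enzymes of *consecutive* steps of a metabolic route are all
differentially expressed in the same biological process, the route itself
is likely active in that process, even though no metabolite was measured.

The package operationalizes this in four stages.

**1. The enzyme correlation network (GECN).** From a pathway genome
database (compounds, reactions with substrate/product sets and EC numbers,
enzymes, a gene-to-enzyme map), enzymes become nodes, and a directed edge
runs from enzyme $E_1$ to enzyme $E_2$ whenever some product of a reaction
of $E_1$ is a substrate of a reaction of $E_2$:

$$E_1 \to E_2 \iff \big(P(E_1) \cap S(E_2)\big) \setminus C \neq \emptyset$$

where $P(\cdot)$ and $S(\cdot)$ are the unions of product and substrate
sets over the enzyme's reactions (reversible reactions contribute both
orientations) and $C$ is the currency-metabolite set. The linking
compounds are recorded on the edge. Without the exclusion $C$, cofactors
such as ATP or NAD would connect nearly every enzyme to every other and
the network would carry no pathway signal.

**2. DEG overlay.** A gene is a DEG when, in at least one contrast,
$|\log_2 \mathrm{FC}| \ge \log_2 2$ and $\mathrm{FDR} \le 10^{-10}$, both
inclusive. DEGs map to the enzymes they encode; the sub-interaction
network is the GECN induced on DEG-encoded enzymes with isolated nodes
removed. Dropping isolated nodes is what makes the sub-network's node
count smaller than the count of mapped enzymes: an enzyme whose neighbors
are all unresponsive carries no consecutive-step evidence.

**3. Route extraction.** A route is an ordered sequence of distinct
reactions in which every consecutive pair shares a non-currency metabolite
(product of one step, substrate of the next) and every step has at least
one DEG-encoded enzyme (any isozyme gene suffices, since published route
figures list several genes per EC). The package returns all *maximal*
routes — not extendable at either end — sorted by length. Declared
pathways are reconstructed as chains first (`pathway_chain()`), so a gap
such as the aldolase step of cytosolic glycolysis shows up as a shorter
covered route inside a longer chain.

**4. Topology and cross-species comparison.** Connected components, the
NetworkAnalyzer-style connected-pairs count $\sum_k \binom{n_k}{2}$, and
degree tables describe the sub-network's structure. Two species' networks
are compared on EC number — the only species-independent key in the data
model — by collapsing each network to one node per EC and keeping the
nodes and edges present in both.

## Worked example

```{r example}
fx <- paper_fixture("fig5_ethanol_degradation_II")
degs <- call_degs(fx$deg_table)
g <- build_gecn(fx$db)
routes <- find_maximal_routes(g, degs, fx$db)
route_report(longest_route(routes), fx$deg_table)
```

The three-step ethanol degradation route (alcohol dehydrogenase →
aldehyde dehydrogenase → acetyl-CoA synthetase) is recovered intact
because all three loci are DEGs; note that the final product acetyl-CoA
would *not* have been usable as a linking metabolite had the route
continued through a CoA-only coupling — currency matching is by exact
token, so `CoA` is excluded but `acetyl-CoA` and `succinyl-CoA` are
ordinary metabolites.

## Parameters that matter

* **Currency set** (`default_currency_set()`): H+, ADH, NADP, NADPH, NH3,
  ATP, ADP, AMP, NAD, CoA, O2, CO2, Glu, pyrophosphate, plus NADH. The
  token "ADH" in the standard cofactor list is read as a spelling variant
  of NADH — alcohol dehydrogenase is an enzyme (indeed one this package's
  fixtures analyze), not a metabolite — so both spellings are excluded by
  default; pass a custom `currency_set()` to change that. "Glu" carries
  the alias "L-glutamate" and is excluded only as a *linking* metabolite;
  the glutamate-degradation fixture still works because its internal links
  are 4-aminobutyrate and succinate semialdehyde. Matching is exact-token
  after trimming and case-folding, never substring.
* **DEG thresholds** (`fc_min = 2`, `fdr_max = 1e-10`): linear fold change
  and FDR, both boundaries inclusive. The table is expected to carry
  already-computed `log2fc`/`fdr`; the package does no expression modeling.
* **`max_paths` (default 10,000)**: cap on route enumeration. Below the
  cap behavior is exhaustive; at the cap the result is flagged
  `truncated`, never silently shortened. Enumeration order is
  deterministic (lexicographic successor order), so truncation is
  reproducible.
* **`directed`**: edges are built directed (the coupling rule is
  asymmetric); topology statistics and SIF export use the undirected
  collapse, with linking sets unioned.

## Numerical and design choices

* **Reaction–enzyme linkage is by exact EC string equality** (after
  trimming), including partial ECs like `2.4.1.-`; enzymes with no EC pair
  only with reactions with no EC. The canonical table schema carries EC on
  both reactions and enzymes and no explicit reaction–enzyme table, so EC
  is the join key. This is also why the EC-less NRS/ER step of the
  rhamnose fixture participates in routes but is excluded (and counted)
  in EC-keyed cross-species overlap.
* **One node per enzyme entity**, not per EC: isozymes at different loci
  stay distinct nodes. Cross-species overlap performs the EC collapse
  explicitly where a shared key is required.
* **Stoichiometry is ignored**; substrate/product membership is all the
  coupling rule uses. Self-edges are excluded — an interaction is between
  two enzymes.
* **Ties break lexicographically everywhere** (radix order, locale
  independent): chain covers and route sets sort by length then first
  reaction id; inferred pathway order is a topological order with
  lexicographic tie-break; cyclic pathway graphs are cut at the
  lexicographically smallest edge inside a strongly connected component,
  with a warning.
* **Dirty inputs degrade, never crash**: compounds cited but not declared
  are auto-registered with empty names; gene links to unknown enzymes are
  dropped; both warn with counts.
* **Partial ECs in overlap** match only under exact string equality;
  wildcard expansion would inflate overlaps irreproducibly and is not
  performed.

## What the synthetic generator emulates

`make_random_pgdb()` produces databases whose reactions draw 1–3
substrates and products from a compound pool, chained so the set is
connected by construction, with currency metabolites attached at a
configurable rate (default 0.2; the oracle-equivalence tests use 0.35 to
exercise the exclusion logic). `plant_linear_route()` appends a linear
chain with one fresh enzyme, gene and linking compound per step and
builds the matching DEG table: covered steps get log2FC 2.0 and FDR
1e-12; filler rows draw log2FC uniformly on (−0.5, 0.5) and FDR on
(0.1, 1), so they can never pass the thresholds. Default problem sizes
(20 reactions, 15 enzymes, 30 genes; oracle suites run 200 seeds at ~18
reactions and route enumeration at ≤ 12 nodes) keep exhaustive reference
checks exact while covering branching, reversibility and currency usage.

What the generator does **not** emulate: realistic EC distributions,
shared metabolites between unrelated pathways at genome scale, noise in
fold-change estimates, or the size of real organism databases (thousands
of enzymes). Passing tests therefore demonstrate correctness of the
algorithms under the stated rules, not that a particular organism's
network will have any given shape.

The packaged worked-example fixtures transcribe published
consecutive-step routes (ethanol degradation II, a TCA-cycle variation,
glycolysis IV, kaempferol and rhamnose/kaempferol-glucoside biosynthesis,
phosphatidic-acid production, glutamate degradation IV) with their gene
ids, EC numbers and metabolite names as printed. Two caveats are encoded
deliberately: the lily superpathway fixture is a *synthetic* planted
9-step chain (only the step count is published, not the per-step enzyme
list), and the glutamate-degradation fixture keeps the published step 3
("succinate semialdehyde to GABA") verbatim even though the canonical
GABA shunt runs that conversion the other way — the transcription is
faithful rather than corrected. The kaempferol fixture's intermediate
metabolite names use the canonical pathway intermediates, as the source
lists only the enzymes.

## Known limitations

* Genome-scale published node/edge counts depend on specific versioned
  AraCyc/CornCyc dumps and the original expression datasets; they are not
  reproducible from packaged fixtures and are out of scope here.
* "Co-expressed" is operationalized as joint DEG status in the same
  dataset; no correlation over expression profiles is computed.
* No flux-balance analysis, thermodynamics, or gap-filling: a step with
  no DEG-encoded enzyme simply interrupts a route.
* Community structure beyond connected components (centrality, layout,
  modularity) is out of scope; export to SIF feeds external viewers.
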