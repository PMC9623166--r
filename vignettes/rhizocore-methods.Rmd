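---
title: "rhizocore: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rhizocore: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizocore)
```

# The problem

Soil microbial communities are commonly profiled as OTU count tables
(16S rRNA amplicons clustered at 97% similarity, samples in rows), and a
recurring question is which *group* of taxa, rather than which single
taxon, underpins soil nutrient-cycling function. A widely used answer
is: build a co-occurrence network from strong, significant pairwise
abundance correlations; partition it into modules; call the module whose
abundance tracks soil functional potential the **core module**; and call
the nodes with high degree, high closeness and low betweenness the
**keystone taxa**. rhizocore implements that inference chain end to end,
together with the measurements it consumes — functional-gene qPCR,
RubisCO activity, potential nitrification (PNR) and denitrification
(DEA) rates — and a synthetic-community generator with planted structure
so every stage can be tested without field data.

# The pipeline, stage by stage

## Community table

Counts are rarefied to an even depth (default 28,795 reads/sample, a
typical MiSeq depth for an 18-sample design) by subsampling without
replacement; all-zero OTU columns are retained so ids remain stable.
Alpha diversity uses the Shannon index in natural-log units (the vegan
default; the base is a convention, not a result). The network is built
over the *dominant* OTUs: OTUs ranked by mean relative abundance across
samples, keeping the shortest prefix covering 80% of total abundance.
We interpret "relative abundance in the total community" as the mean
per-OTU relative abundance because per-sample selection would give
non-comparable node sets; ties break by OTU id and the cumulative
threshold is inclusive.

## Correlation network

All pairwise Spearman correlations are computed by rank transform
(average ranks for ties) followed by the product-moment correlation on
ranks. P-values are exact by full permutation enumeration for n ≤ 9
samples and use the t approximation with n − 2 df otherwise; constant
columns have no defined correlation and are recorded as rho = 0, p = 1
and barred from edges at any threshold. An edge survives iff
|rho| ≥ 0.8 **and** p ≤ 0.01; the magnitude reading (absolute value)
keeps negative associations as blue-edge analogues, stored as a sign
attribute. The p ≤ 0.01 default is configurable; a stricter 0.001 is
equally defensible and supported.

Correlations are computed on relative abundances of the rarefied table.
Spearman is rank-based, so per-sample normalisation is harmless once
depths are equal — which is why rarefaction comes first.

## Modules and keystones

Modules are found on the unweighted graph of non-isolated nodes with the
seeded Louvain multilevel modularity heuristic (igraph's
`cluster_louvain`), the same family of algorithm behind the usual
Gephi workflow. Partitions are relabelled deterministically by
decreasing size; modules below 5 nodes are excluded from the
"main module" ranking (the cutoff is invented and configurable — field
studies report a handful of main modules and a tail of fragments). We
test module detection by planted-structure recovery (adjusted Rand
index against the generator's truth), not by exact partition equality,
because modularity heuristics are only defined up to their tie-breaking.

Keystones use an unweighted rank-sum composite —
rank(degree, desc) + rank(closeness, desc) + rank(betweenness, asc),
average ranks on ties, node-id tie-break — because the criteria are
cited qualitatively in the literature without a formula; the top 20
nodes are returned by default. Closeness is the Wasserman–Faust
component-scaled form so disconnected networks do not inflate small
components; betweenness is normalised by (n−1)(n−2)/2. Correlation
magnitude is deliberately *not* used as an edge weight: no weighting
rule is established for this analysis, and unweighted centralities are
what the cited tools compute by default.

## Module abundance, core designation, function linkage

Per-sample module abundance is the mean of members' z-scored relative
abundances (z-scores use the n − 1 denominator; zero-variance vectors
z-score to zeros with a warning so constant OTUs cannot crash the
pipeline). Modules are correlated (Spearman) against the 11 functional
variables — 8 gene abundances (cbbL, β-glu, ChiA, nifH, AOB-amoA, narG,
nirK, cnorB), RubisCO activity, PNR and DEA — and displayed as the
familiar starred matrix (p < 0.05/0.01/0.001, uncorrected, mirroring how
such matrices are reported).

The **core module** is designated by a rule we had to invent (the
concept is narrative in the literature): the module with the most
*significant positive* correlations, ties broken by larger mean rho over
its significant positives, then by module size. One design choice
matters here: the designation decision (not the displayed matrix)
applies Benjamini–Hochberg correction across the module × variable
matrix by default. With 3 modules × 11 variables and uncorrected
per-cell tests at α = 0.05, the probability that a *null* dataset shows
zero significant positives is about 0.975³³ ≈ 0.43 — the none-marker
would be nearly a coin flip, and the multiplicity-driven false
positives would defeat the point of a null calibration. Under BH the
probability of any discovery under the global null is ≈ α, so the
none-rate calibrates near 95%, while a genuine core module (many tiny
p-values) is unaffected. Set `p_adjust = "none"` to reproduce the raw
behaviour.

Richness–function regressions are ordinary least squares of the
functional-potential z-score on per-sample module richness, matching
the usual presentation of richness on the x-axis.

## Process rates and qPCR

PNR and DEA are slopes of OLS fits of concentration on time; DEA uses
the four latest time points when more are supplied, honouring the
four-point convention of the acetylene-block assay (the 24–154 h grid
is the default in the simulator). The qPCR standard curve is an OLS fit
of Cq on log10 copies with efficiency 10^(−1/slope) − 1 and QC gates at
R² > 0.98 and efficiency ≥ 85%; quantification from a failed curve
requires an explicit override. RubisCO activity is reconstructed from
the coupled spectrophotometric assay: the blank-corrected A340 slope
divided by ε_NADH = 6.22 mM⁻¹cm⁻¹ × path, scaled by reaction volume and
divided by 2 NADH per CO₂ and the dry soil mass. Only the wavelength
and the output units are fixed by the assay description; the extinction
coefficient and stoichiometry are the standard constants of the coupled
reaction and every constant is an argument.

## Genome mapping

OTU representatives are compared to the 16S copies of reference genomes
with a free-end-gap global alignment (match +1, mismatch −1, gap −2);
identity is matches over aligned columns excluding end overhangs, with
N never counting as a match. Two non-obvious choices: (1) an alignment
covering less than half of the shorter sequence scores identity 0,
because the best-scoring overlap of two *unrelated* sequences is
typically a short chance-match segment with spurious identity ≈ 1 — the
coverage filter is the desk-scale analogue of a BLAST coverage cutoff;
(2) a genome maps to an OTU when *any* of its 16S copies reaches the
97% threshold, recording the best copy. Mapped genomes inherit the
module of their best-identity OTU (a stand-in for phylogenetic
clustering, which is out of scope), and per-genome functional-gene
content — percentage of genes per genome, by gene or by C-/N-cycling
category — is compared between modules with two-sided Mann–Whitney U
tests. The category gene lists ship with the eight assayed genes plus
canonical reference symbols and are user-replaceable.

## Treatment statistics

One-way ANOVA with Tukey HSD produces a compact letter display via the
insert–absorb procedure (letters assigned alphabetically). Bray–Curtis
dissimilarity feeds a distance-based PERMANOVA (Anderson's pseudo-F on
the squared-distance partition) with seeded label permutations and the
add-one p estimator, so p is never exactly 0; an exact enumeration mode
is available for n ≤ 8.

# The synthetic generator: a stated world

No generative model for such community data is published, so the
generator is an explicit stand-in and all of its choices are labelled as
such. Each of 3 modules has a per-sample latent factor
f\_m(s) ~ N(0, 1); a member OTU's log-intensity is
0.9·f\_m(s) + 0.3·ε, a background OTU's is pure noise; intensities are
exponentiated, closed to proportions and counts drawn multinomially at
28,795 reads. The defaults emulate an 18-sample, 3-treatment,
6-replicate design with 3 × 25 planted OTUs + 25 background OTUs. One
module (the planted core) drives the 11 functional variables on the log
scale with unit slope; gene baselines are 10⁶ copies g⁻¹ and rate
baselines 10 units — arbitrary positive scales, since only the
association structure matters downstream. Recovery experiments use 60
samples rather than 18 because |rho| ≥ 0.8 at n = 18 sits near the
significance boundary; 18 remains the stress-test preset. One master
seed expands to per-stage child seeds by fixed offsets (community +0,
functions +1, rates +2, sequences +3).

What the generator does *not* emulate: compositional effects beyond
closure (no taxon-specific totals), over-dispersion beyond the
log-normal, treatment effects on the community (treatment labels are
balanced but exchangeable), PCR/chimera artefacts, and phylogenetic
signal in the 16S fixtures. A green recovery test therefore establishes
that the pipeline recovers *this* kind of planted block structure — not
that it is robust to every failure mode of real amplicon data. One
real-data feature the generator *does* reproduce, and tests must
tolerate: closing to proportions induces mild negative between-module
correlation, which stays far below the 0.8 edge threshold.

# Numerical conventions

Exact Spearman p-values enumerate all n! rank permutations (n ≤ 9);
above that, the t approximation. Ties always use average ranks.
Degenerate inputs: zero-variance vectors z-score to zeros (warning);
constant columns never form edges; an edgeless graph is an error for
module detection but a reported zero-module outcome for the pipeline;
blank-exceeds-sample RubisCO rates clamp to 0 (warning); k larger than
the node count returns all nodes (warning). All randomised components —
rarefaction, Louvain, permutations, the generator — take explicit seeds
and restore the caller's RNG state.

# Known limitations

Compositionality-aware network inference (SparCC/SPIEC-EASI) is out of
scope by design; Spearman-threshold networks over proportions are the
method being implemented, with their known closure bias. The core
module designation rule and the < 5-node main-module cutoff are
package conventions, configurable but invented. The genome→module
assignment by best 16S identity ignores phylogenetic uncertainty. The
exact Spearman path is O(n! · pairs) and is intended for n ≤ 9 only.
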