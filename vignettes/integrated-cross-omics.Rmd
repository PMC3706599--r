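---
title: "Gene-set based integration of transcriptomics and proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set based integration of transcriptomics and proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgsea)
```

## The problem

Paired-phenotype designs with very few samples — here, matched invasive and
angiogenic tumor samples from a serially transplanted glioblastoma xenograft
model — leave single-entity differential-expression statistics underpowered.
When two omics layers (a microarray transcript matrix and an iTRAQ
protein-profile matrix) measure the same biology through partially
overlapping entities, each layer can instead be used to corroborate the
other *as a set*: the top differentially expressed entities of one layer,
mapped across platforms, are tested for coordinated enrichment in the
complementary layer. That is the procedure this package implements, together
with its companions (GO over-representation, Rank Product meta-analysis) and
a synthetic dual-omics generator that makes the whole pipeline testable
without any external downloads.

## The model and its pieces

**Per-pair log ratios.** Each invasive/angiogenic sample pair is collapsed
to one column of `log2(invasive) - log2(angiogenic)`. Positive values mean
up in the invasive phenotype; this orientation is not derivable from the
data themselves, so the package fixes it once and propagates it everywhere
(flipping it only flips result signs). Raw microarray intensities are
quantile normalized (Bolstad's mean-of-sorted-quantiles reference, ties
receiving the mean of the quantiles they span) before log transformation;
the normalization is delegated to `limma::normalizeQuantiles` behind
`quantile_normalize()`.

**Rank Product.** Within each ratio column, entities are ranked from most
extreme in the requested direction (ties averaged). The Rank Product of an
entity is the geometric mean of its available ranks,
`RP_g = (prod_i r_{g,i})^{1/k_g}`. The exponent `1/k_g` over the *available*
columns makes values comparable across entities with different missingness —
the iTRAQ layer observes each protein profile only in its own experiment
block. Significance is the permutation-based *percentage of false
prediction*: ranks are redrawn uniformly within each column (tie-free,
preserving the missingness pattern), and
`pfp(g) = E[#\{RP_perm <= RP_g\}] / rank(g)`. Raw pfp is not monotone along
the RP ranking, so a monotonized companion (running minimum from the bottom,
clipped at 1) is reported and used for thresholding; both columns are kept
so either convention can be matched. Observed ties get average ranks but
permutations draw integer ranks: the null should be exchangeable and
tie-free.

**GSEA with a log-fold metric.** Entities of the target layer are ranked by
the arithmetic mean of their non-missing log ratios (a median alternative is
available). The enrichment score is the signed maximum deviation of the
usual weighted running sum: hits add `|r_j|^p / N_R`, misses subtract
`1/(N - N_H)`, with `p = 1` by default. The null is *gene permutation*:
random member sets of the same effective size. With only 3–4 ratio columns,
sample-label permutation would be degenerate, which is exactly why gene
permutation is the right null in this design. `NES = ES / mean(|null ES|)`
over same-signed nulls, the nominal p is the same-signed tail fraction, and
the FDR q follows the standard ratio of permuted-to-observed tail fractions
over same-signed NES (clipped to [0, 1]; a single tested set falls back to
its nominal p). The *leading edge* — members at or before the running-sum
peak for positive ES, strictly after it for negative ES — is the
interpretable output.

**GO over-representation.** Fisher's exact (hypergeometric upper-tail) test
of each term in a top list against the reference universe, which is the
dataset the Rank Product analysis ran on, not the whole annotation file.
P-values are reported nominal by design. True-path propagation of
annotations over `is_a` and `part_of` is on by default but can be disabled,
since over-representation tools differ on this and the convention of the
original analysis suite is not documented.

**Identifier mapping.** All mapping is table-driven from local files
(columns `source_id, source_ns, target_id, target_ns, link_path,
species_origin`); chains of `link_path` labels express multi-hop routes such
as SwissProt → rat Entrez → human Entrez homolog. Unmapped identifiers are
flagged, never dropped. Protein *profiles* are entities distinct from
proteins: several profiles (different iTRAQ experiments or species origins)
may map to the same gene, and gene-set membership in the proteomics ranked
list is evaluated per profile through its mapped gene. "Uniquely mapping"
for the matched subsets used by the meta-analysis means a strict 1:1
correspondence after chain resolution; every exclusion is logged so that a
different ambiguity policy can be compared.

**The integrated run.** For one direction, `integrated_enrichment()` chains:
Rank Product on the mapped subset of the source layer → top list at the
configured q → identifier mapping → gene set → GSEA against the *full*
target matrix → leading edge with provenance. `run_reciprocal_analysis()`
does this in all four direction/layer combinations; `rp_meta_comparator()`
runs the two-step Rank Product meta-analysis (`sqrt(rank_a * rank_b)` on
re-densified matched ranks, same permutation scheme) as the standard
comparator.

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `q_threshold` | 0.5 | published analyses report both q = 30% and q = 50% cut-offs without stating which fed the gene sets; 0.5 keeps proteomics-side sets above GSEA's minimum size. |
| `n_permutations` | 1000 | for both pfp and the GSEA null; the source analyses do not state a count. Standard error of a tail probability near 0.05 is then about 0.007. |
| `min_size`, `max_size` | 10, 500 | the cited GSEA defaults. |
| `weight_p` | 1 | the cited weighted scheme; `p = 0` reduces the ES to the two-sample Kolmogorov–Smirnov statistic (a tested identity). |
| ORA `p_threshold` | 0.02 | flagging convention of the accompanying over-representation analyses; purely cosmetic, no adjustment applied. |

## What the generator emulates — and what it does not

`synthetic_config()` encodes the emulated study conditions: 2000 transcripts
in 4 ratio columns; 2000 protein profiles in 3 columns with each profile
observed in one two-column experiment block (three iTRAQ experiments, two
sample pairs); roughly 1.5 profiles per gene; 60% of protein-layer genes
shared with the transcript layer; per direction and layer, 100 planted DE
genes shifted by `effect_size_mu = 1.0` against noise `sd = 0.5` (an
effect of two noise SDs); 50 of the invasive-direction genes concordant
across layers and none in the angiogenic direction, mirroring the
direction-specific concordance the method is designed to detect. Mixed
human/rat profile origins exercise the two-hop homolog mapping, and a 5%
decoy rate of many-to-many mapping records exercises the 1:1 exclusion
logic. Non-concordant planted genes are drawn from each layer's whole gene
universe (excluding anything planted elsewhere), so overlap genes can be
*discordantly* DE — present in both layers but shifted in only one — as in
real paired-platform data.

Log-ratio noise is iid Gaussian with equal variance across entities
(a heavier-tailed `t3` option exists for stress-testing); real data have
correlated columns, intensity-dependent variance and annotation errors, none
of which the generator models. Passing tests therefore demonstrate
*statistical correctness of the machinery under its stated model*, not
performance guarantees on any particular real dataset.

## Numerical and degenerate-input choices

* Rank Product permutation counts compare `RP_perm <= RP_obs` with a
  relative tolerance of 1e-9, absorbing float noise between equal geometric
  means computed along different paths.
* The running-sum profile telescopes to 0 by construction; tests assert the
  final value to 1e-9 and the ES against a brute-force recomputation to
  1e-12.
* Ties in ranked lists keep input order (stable sorts throughout); permuted
  member sets sample positions and are unaffected.
* A zero-variance same-signed GSEA null yields `NES = NA` and inference
  falls back to the nominal p.
* Columns with fewer than two observed values, all-missing rows, empty top
  lists, gene sets outside the size bounds, and empty mapping results all
  raise located errors rather than propagating silently.
* Every random step (generator, pfp, GSEA null) takes an explicit seed and
  restores the caller's RNG state, so fixed seeds plus fixed inputs give
  byte-identical reports.

## Problem sizes used by the test suite

The oracle tests enumerate exhaustively where that is feasible: all
`(3!)^2` and `(4!)^2` rank permutations for the pfp oracle, all
`(M, K, n, k)` hypergeometric configurations up to `M = 50` for the ORA
closed form, and 1000 random instances for the enrichment-score brute
force. Calibration and recovery use 200 seeded null replicates (GSEA and
ORA p uniformity), 20 seeds of the full 2000-entity pipeline at the default
operating point, and 3 discordant instances for the meta-analysis negative
control. These sizes were chosen to keep the Monte-Carlo standard errors
well inside the asserted margins.

## Known limitations

* The package consumes mapping tables; it does not build them. A BioMart
  export with the expected six columns is the intended source for real data.
* OBO parsing covers the 1.2 stanza subset needed for GO (`is_a`,
  `part_of`, obsolete flags); other relationship types are deliberately
  ignored.
* Sample-label permutation GSEA and parametric DE alternatives (limma,
  SAM) are out of scope: the design point of the method is exactly the
  regime where those are unavailable or degenerate.
* Raw proteomics spectra and array-native file formats are not parsed;
  inputs are the tab-delimited matrices exported by upstream tools.

## A minimal run

```{r example, eval = FALSE}
sim <- generate_cross_omics(synthetic_config(seed = 17))
cfg <- pipeline_config(seed = 17)
report <- integrated_enrichment(sim$tr, sim$pr, sim$table,
                                direction = "up_in_invasive", cfg)
report
recovery_report(sim, report)
plot(report$gsea)   # enrichment plot of the mapped set
```
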