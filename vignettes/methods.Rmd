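---
title: "Codon optimization, growth, and niche: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon optimization, growth, and niche: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galcodon)
```

This vignette is the package's account of its own methods: the models,
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## From tRNA pools to codon optimization

**Relative adaptiveness (wi).** Each sense codon receives a raw weight
summing, over every tRNA anticodon that can decode it, the product of the
tRNA gene copy number (tGCN) and one minus the pairing penalty of the
codon:anticodon class. Anticodons decoding a codon share the reverse
complement of its first two bases; the third-position pairing is scored by
a wobble table with Watson–Crick classes at `s = 0` and four wobble
classes (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68 — the standard tAI
literature defaults, stored as data in `default_wobble_rules()` so they
can be replaced wholesale). Weights are normalized so the best codon has
`wi = 1`. Codons no tRNA decodes are imputed with the geometric mean of
the non-zero values and flagged, so users can exclude genes dominated by
imputed codons. `wi` is invariant to rescaling the whole tRNA pool; only
relative copy numbers matter.

**stAI and estAI.** A gene's stAI is the geometric mean of `wi` over its
codons, excluding the start codon (which is constrained) and stop codons,
computed in log space for numerical stability. Genome-wide stAI levels
differ between species, so cross-species comparison uses estAI: the
fraction of genes in the same genome with *strictly* lower stAI. The
strictly-lower convention means ties share the estAI of the lowest tied
member, values live on the exact grid `{0, 1/N, …, (N−1)/N}`, and the
transform is invariant to any strictly monotone rescaling of stAI. The
estAI background is every gene passing sequence validation for that
species; no length re-filter is applied at this stage.

**CUG clades.** Two yeast clades translate CTG as Ser or Ala. The
`genetic_code()` variants affect translation and validation only; wi/stAI
deliberately ignore the reassignment, because the CUG codon is rare in the
affected genes (fractions near 0.005), and `cug_frequency()` is provided
as the materiality check for any particular gene.

**The s-value.** Genomes under translational selection rank their highly
expressed genes near the top of the stAI distribution. The package scores
this with a reference set of highly expressed genes (ribosomal-protein
genes in practice; the generator labels its top-proxy decile) and computes
the rank correlation between stAI and set membership. For a binary
reference set we use the rank-biserial correlation `2·AUC − 1`, the
Mann–Whitney probability that a reference gene out-ranks a background gene,
rescaled to [−1, 1]. A Spearman correlation against a 0/1 indicator is
capped far below 1 (near 0.5 for a 10% reference set even under perfect
ranking), which would make the conventional pass threshold of 0.5
unattainable by construction; rank-biserial puts genuinely selected
genomes near 1 and unselected ones near 0, the scale the threshold
presumes. Continuous proxies fall back to Spearman.
`optimize_wobble_weights()` additionally maximizes this correlation over
the four wobble penalties by coordinate-wise grid search (step 0.01, at
most 50 sweeps, fixed order, ties keep the current value — deterministic
without a seed); non-convergence returns the best point with a warning.

## Pathway profiles

Multi-copy families are represented by the copy with the highest estAI
(exact ties broken by lexicographically smallest gene id), with the
max−min estAI gap reported. A pathway is complete when all required
families are present (default *GAL1*, *GAL10*, *GAL7*), partial or absent
otherwise. A complete pathway is clustered when *some* combination of one
copy per family shares a contig — equivalently, when one contig appears in
every family's contig set; this generalizes the single-copy rule to
multi-copy genomes without extra assumptions. Contig ends can truncate
real clusters; the package reports the boolean as computed and leaves any
"unknown at contig end" interpretation to the user.

## Growth quantification

Growth rate is the maximum over sliding windows (default 5 consecutive
points) of the least-squares slope of OD against time, clipped at 0. The
window method is deterministic, dependency-free, and matches the operative
definition "maximum slope of the growth curve"; a spline smoother would
differ mainly in noise response, and window width is configurable. The
endpoint is final minus initial OD. A replicate "grew" when its endpoint
reaches 0.2 OD — an explicit stand-in for by-eye growth calls, and
configurable. A species grows if at least 2 of 3 replicates grew;
otherwise rate and endpoint are set to 0. Normalization divides the test
(galactose) mean rate by the glucose control mean rate, so 1 means equal
growth; replicate means are rounded to 3 decimals before the ratio and the
reported ratio to 2 decimals, matching how such tables are conventionally
printed (the worked example: 0.070 / 0.072 → 0.97), while full-precision
values are retained for downstream analysis.

## Comparative inference

`pic_contrasts()` implements Felsenstein's post-order algorithm: at each
node `(x1 − x2)/√(b1 + b2)` with branch-weighted ancestral values and the
parent branch extended by `b1·b2/(b1 + b2)`. Trees are pruned to trait
coverage; polytomies are resolved deterministically into zero-length
branches, and zero-length branches receive a configurable jitter (default
1e−8). Contrast regressions run through the origin — contrasts have
arbitrary sign — with a two-sided t-test at tips − 2 degrees of freedom.
`pgls_fit()` solves the same Brownian model by explicit generalized least
squares through the Cholesky factor of the tip covariance matrix; its
slope equals the through-origin contrast slope to numerical precision,
which the tests assert on random fixtures along with agreement with the
independent `ape::pic` implementation and a brute-force whitening oracle.
Prediction for a species outside the tree uses fixed effects only: with no
phylogenetic placement there is no covariance to condition on.

**Outlier screening.** Contrasts assume all tip variation is Brownian.
Measured traits carry white noise (codon-sampling error in estAI,
rate-estimation error in growth), and between very close relatives that
noise is amplified by `1/√b` into single contrasts that can dominate — and
flip — the regression. `residual_outliers()` flags species by whitened
PGLS residuals but never removes them. `contrast_outliers()` flags
contrasts exceeding 4 robust SDs (MAD scale) in either trait and suggests
dropping the flagged clade's shortest-terminal-branch tip, which is
deterministic and targets near-duplicate taxa; the pipeline applies this
screen as an explicit, logged action (`screen_outliers = TRUE`) and
reports exactly which species were excluded. On clean Brownian data the
screen fires rarely; on the default synthetic conditions it removes a few
species per dataset and is the difference between a stable positive slope
and occasional confidently wrong ones.

## Random-codon nulls

`randomize_codons()` resamples each codon uniformly among its synonyms
(start codon preserved, protein identical). Uniform sampling is the
maximal-entropy reading of "randomly assigned codon usage";
genome-frequency weighting would test a different null (optimization
beyond the genome's average bias) and can be layered on via the statistic
function. `null_test()` draws the per-position synonymous log-wi directly
— exactly equivalent in distribution to generating the sequences, but
vectorized — and reports the observed statistic's percentile, its side,
and central-interval (2.5/97.5 and 0.5/99.5) as well as one-sided 95th/99th
verdicts, since "outside the 95%" is used in both senses in practice. The
statistic defaults to stAI; any monotone function of it (e.g. a PGLS
growth prediction through the genome's stAI ECDF) leaves percentiles
unchanged, which is tested.

## Ecology

Niche contrasts use the two-sided Wilcoxon rank-sum test: exact
enumeration when both groups have ≤ 10 observations without ties, normal
approximation with tie correction otherwise. Species in neither group are
excluded. The KO scan regresses each KO's estAI contrasts on the pathway's,
Bonferroni-adjusting over the KOs actually tested (those present in at
least `min_species` species; 100 at subphylum scale, scaled to half the
species count on small datasets, with skipped KOs reported). When several
genes share a KO the maximum estAI represents it, mirroring the pathway
multi-copy rule.

## The synthetic-data generator

The generator defines the study conditions for every stochastic test:

| Parameter | Default | Why |
|---|---|---|
| species | 60 | large enough for comparative power, small enough for fast suites |
| tree | Yule (birth 1, death 0), depth rescaled to 1 | simplest branching model giving realistic Brownian structure |
| genes/genome | 200 (+3 pathway) | estAI granularity of 0.005 with desk-scale runtimes |
| gene length | log-normal, median 150 codons, sd(log) 0.3 | typical CDS scale |
| coupling | 2 (logistic slope, proxy → P(top-wi codon)) | gives Spearman(stAI, proxy) > 0.8, i.e. genomes clearly under selection |
| trait model | rate = 0.3 + 0.5·opt + BM(σ = 0.1) | slope and noise of the focal association |
| growth curves | logistic, 0–48 h at 0.5 h, 3 replicates, OD noise sd 0.01 | plate-reader-like sampling at reduced duration |
| glucose rate | 0.07 OD/h (log-normal spread 10%) | matches observed baseline rates |
| niches | π = 0.8 for top-quartile optimization, 0.2 otherwise | clear but not deterministic enrichment |
| KOs | 40, of which 8 share the pathway signal | small scan with known positives |

tRNA pools draw Poisson(3) copies at each Watson–Crick anticodon (every
synonymous family guaranteed one decoder); true wi follows from the
default wobble table. Background genes choose the top-wi synonymous codon
with probability increasing in a log-normal expression proxy; pathway
genes use the species-level optimization trait (a Brownian latent squashed
to (0, 1)) as that probability, which ties pathway estAI to the trait.
Null KOs are independent Brownian traits rather than white noise — real
KO optimization is phylogenetically structured, and white-noise tips would
manufacture short-branch contrast artifacts that say nothing about the
scan.

What the generator does *not* emulate: substitution processes and
phylogenetic signal in sequence content, GC covariates, amino-acid
composition bias, expression measurement, horizontal transfer, partial or
absent pathways, and assembly artifacts. Passing tests therefore
demonstrate that the pipeline recovers known signals through its own
transformations — not that real genomes satisfy the model.

## Numerical choices and degenerate inputs

Geometric means in log space; empty tRNA pools, all-zero weight tables,
genes with no scorable codons, sub-minimum gene sets, and empty niche
groups are errors, not silent results. Ambiguity codes and internal stops
exclude a sequence with a named warning (configurable to a hard error).
Sequence-length violations are always errors. Ties: representative copies
break by gene id; grid search keeps the current penalty; estAI shares the
lowest tied rank. All simulation randomness flows from a single config
seed; the wobble optimization is deterministic without one.

Problem sizes used by the test and acceptance suites — 1,000 random genes
for the stAI oracle, 100 ten-tip trees for the contrast oracles, 200
repeats × 500 nulls for percentile calibration, 500 regressions at 200
tips for test size, 50 generator seeds for end-to-end power, 20 seeds ×
500 KOs for scan error control — were chosen to make sampling error small
relative to the margins being asserted while keeping the default run in
the minutes range.

## Known limitations

The s-value here is a declared reimplementation on a reference-set proxy,
not a reproduction of any particular published optimizer's objective; its
0.5 gate is conventional. PIC/PGLS assume Brownian covariance — no
Pagel's λ or OU transforms are provided. Predictions for unplaced species
ignore phylogenetic covariance and are correspondingly conservative. The
cluster rule cannot distinguish "not clustered" from "truncated at a
contig end". Growth quantification targets long plate-reader series; lag
and carrying-capacity parameters are out of scope.
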