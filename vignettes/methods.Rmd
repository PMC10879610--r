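---
title: "Co-occurrence of gut-microbiota ASVs, genetic distance, and environment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence of gut-microbiota ASVs, genetic distance, and environment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcooc)
library(dplyr)
```

## The scientific question

Two classical hypotheses make opposite predictions about which microbes
share a gut. Environmental filtering says that close relatives, having
similar resource and habitat requirements, respond alike to their
environment and therefore co-occur; competitive exclusion says that close
relatives overlap too much in niche space to coexist. `microcooc`
implements a pipeline for testing these predictions on amplicon (16S) data
from a multi-treatment animal experiment: gut communities of group-housed
voles whose diet (natural grass vs. chow), physical-contact regime, and
group size were manipulated across dozens of treatment groups.

The unit of analysis is the **ASV pair within a treatment group**. For
each pair we compute a *co-occurrence index* — Spearman's rank correlation
of the two ASVs' relative abundances across the samples of that group — and
relate it to:

* `gd` — the pairwise genetic distance between the two ASVs' aligned 16S
  sequences (p-distance by default, Jukes–Cantor optionally);
* `shannon` — the treatment's alpha diversity (mean per-sample Shannon
  entropy, nats);
* `n_voles` — the number of cohabitating animals (crowding);
* `diet` — grass vs. chow (reference: chow);
* `contact` — physical contact allowed vs. not (reference: no).

The regression stage fits the Gaussian-identity GLM

```
minmax(rho) ~ minmax(gd) + minmax(shannon) + minmax(n_voles) + diet_grass + contact_yes
```

after min–max rescaling of the response and the continuous predictors,
followed by exhaustive all-subsets AIC selection. Environmental filtering
predicts a negative `gd` coefficient; favourable conditions (high
diversity, natural diet, low stress) are expected to raise co-occurrence.

## Pipeline stages and their parameters

| stage | operation | default | why |
|---|---|---|---|
| preprocess | rarefaction depth | 50,000 reads | equalises sequencing effort; the conventional depth for this assay |
| preprocess | rare-ASV cut | 0.01% pooled relative abundance, strict `<` | rare ASVs contribute mostly zeros, which distort rank correlations |
| cooccur | pair zero filter | pooled zeros / 2n > 50% removes the pair | same motivation at the pair level |
| cooccur | p-value | two-sided t approximation on `n − 2` df | groups have 20–48 samples; the exact permutation null is available for n ≤ 8 |
| cooccur | FDR | Benjamini–Hochberg step-up within each group's pair family | pairs, not ASVs, are the tested family |
| network | prevalence filter | ≥ 20 non-zero samples | sparse taxa cannot support stable edges |
| network | edge test | 100 bootstrap resamples, retain `p_boot ≤ 0.05` | sign-crossing fraction of the resampled rho |
| network | hubs | degree > 1% of edges **and** betweenness > 0.1 (both strict) | "total volume" is read as the edge count: a node-count base would make the degree cut vacuous |
| glm | collinearity screen | Spearman \|rho\| > 0.5, transitive closure, Shannon kept first | mirrors retaining one variable per correlated cluster of diversity indices |
| glm | model selection | all subsets, minimum AIC, ties to fewer terms | with ≤ 5 candidate terms the 2^k enumeration is exact |
| glm | robustness | 10 refits on 1% row subsamples | pair rows share ASVs; the subsample check probes sensitivity to that dependence |

Decisions the data formats left open: the abundance TSV orientation is an
explicit flag (`samples_as_rows` default); IDs are opaque strings; the
0.01% filter is interpreted against the pooled table (a per-sample-mean
mode is provided); rarefaction *drops* under-depth samples rather than
failing, with each sample drawing from its own RNG stream derived from
`(seed, sample_id)` so that row order can never change results; `N` in a
sequence is treated as missing (like a gap), not as a mismatch; Shannon
uses natural logs; Chao1 is the bias-corrected form, which is defined even
when no doubletons are observed; treatment-level diversity is the mean
over the treatment's samples (a pooled-counts mode is provided); the
bootstrap edge p-value is a plain sample-bootstrap sign-crossing fraction,
not the full permutation-renormalisation scheme of network tools built on
ensembles of measures.

## What the synthetic-data generator emulates

Real data for this design are a samples × ASVs count table, aligned 16S
sequences for the ASVs, and per-sample housing covariates. The generator
(`synth_config()`, `generate_study()`) produces all three with known
ground truth:

1. **Sequences.** A pure-birth tree on `n_asvs = 40` tips
   (`birth_rate = 1`), a uniform random root sequence of
   `seq_length = 250` sites, Jukes–Cantor substitutions at
   `subst_rate = 0.05` per site per unit branch length. Realised pairwise
   p-distances span roughly 0–0.4, similar to within-gut 16S V3–V4
   divergence.
2. **Latent abundances.** Per treatment, a Gaussian copula draws latent
   log-abundances with target correlation
   `clip(shift_g + beta_gd * (1 − d_ij/d_max))`, where
   `shift_g = baseline_cor + beta_shannon * e_g + beta_n * n_g/n_max +
   beta_diet * [grass] + beta_contact * [contact]` collects the
   treatment-level effects and `e_g` is the treatment's diversity level.
   The matrix is clipped to ±0.95 and repaired to the nearest valid
   correlation matrix by eigenvalue clipping at 1e-6.
3. **Counts.** Latents are exponentiated, normalised to proportions, and
   sampled multinomially at `depth = 5000` reads per sample.

### Compositional closure and the shared-response channel

Fixed-depth counts are compositional: dividing by the sample total
removes any variation that is common to all taxa. In correlation terms,
closure approximately double-centres the latent correlation structure, so
the *uniform* part of the target matrix — exactly the treatment-level
`shift_g` — is unobservable in relative abundances. (The two-taxon case
makes this vivid: whatever the latent correlation, the two proportions
sum to 1 and their Spearman correlation is −1.) The pair-specific
`beta_gd` structure survives, attenuated.

The generator therefore carries treatment-level effects through a second,
biologically motivated channel: a **shared environmental response**. A
block of 20 dominant "responder" taxa (4 independent factors × 5 taxa,
drawn at random so the block is unrelated to phylogeny, with a small
abundance bonus of 0.3 log-units) moves jointly along a per-sample
environmental axis. Samples sit at fixed symmetric quantile positions on
that axis, randomly assigned, with spread
`stress_scale * sqrt(max(shift_g, 0))`. When the responder block swells
or shrinks, every other taxon's relative abundance moves oppositely
through the shared denominator — a real, observable source of
co-occurrence whose strength is set by the treatment covariates. The
bounded, mean-preserving axis moves the responder share without shifting
its expectation, so coupling strength barely perturbs mean diversity,
and because the realised spread is exact (a quantile grid, not a random
draw), group-level coupling carries no extra Monte-Carlo noise.

### The diversity channel

A treatment's diversity level `e_g` acts on community structure, not on
the copula: the lowest `0.5 * (1 − e_g)` quantile of taxa is absent from
that treatment outright (nested richness loss, as along a stress
gradient), and the dominance hierarchy of the remaining taxa sharpens in
proportion to `(1 − e_g)`. Absent taxa are constant zeros and drop out of
the treatment's pair set, so they add no tied-rank noise. Realised
Shannon, Simpson, and Chao1 then covary as they do in real communities,
which matters because the pipeline's collinearity screen must see them as
one cluster and retain Shannon.

### The treatment layout

The default layout has **24 treatments × 20 samples**. Diet and contact
are balanced and mutually orthogonal, group sizes (2/4/8) are balanced
within diet, and diversity levels are assigned so no treatment-level
covariate is strongly confounded with another. Identifying four
treatment-level coefficients *from group means* requires ample residual
degrees of freedom at the group level: with only six treatments a
five-parameter treatment-level model is nearly saturated and sign
recovery is a coin flip, which is why the emulated study is sized closer
to the 37 treatment groups of the real design. Forty ASVs, depth 5,000,
and 250-site alignments keep a full study to about a second of
simulation.

Effect-size defaults (`beta_gd = 0.6`, `beta_shannon = 0.35`,
`beta_n = −0.2`, `beta_diet = 0.12`, `beta_contact = −0.12`,
`baseline_cor = 0.2`) give every term a clearly detectable but far from
overwhelming signal at this scale; the expected GLM signs are
(gd −, shannon +, n −, grass +, contact −).

### What the generator does *not* emulate

Sequencing error and chimeras; strain-level dynamics; overdispersion
beyond the lognormal-multinomial; thousands of ASVs (desk scale is 40);
longitudinal sampling; and any taxonomic structure (taxonomy is an
optional input throughout). Passing the recovery tests therefore shows
that the *pipeline* is correct and well calibrated on data with the
assumed generating structure — not that the biological conclusions of any
particular real dataset are right.

## Simulation properties the package maintains

* **Sign recovery.** Across 50 independent synthetic studies at default
  settings, the AIC-selected GLM reproduces all five coefficient signs in
  well over 90% of replicates, and the per-experiment least-squares slope
  of co-occurrence on genetic distance is negative in every experiment in
  at least 95% of replicates (`replicate_sign_recovery()`).
* **Type-I control.** With all five effect sizes and the ambient coupling
  set to zero the community is exchangeable, and the full-model `gd` term
  is significant at 0.05 in about 5% of replicates
  (`replicate_null_gd()`). Calibration of the naive pairs-as-independent
  GLM is *not* automatic: communities with strong dominance structure
  induce correlated pair records through the compositional denominator
  and inflate the rate — one more reason the subsample robustness check
  exists.
* **Edge-wise type-I.** On independent-noise communities the bootstrap
  retains about `alpha` of candidate edges (`null_edge_retention()`).

## Numerical choices

Spearman p-values use the t approximation `t = rho * sqrt((n−2)/(1−rho²))`
(exact permutation available for n ≤ 8); `|rho| = 1` maps to p = 0.
BH adjustment is the standard step-up with a cumulative minimum from the
largest rank; the raw printed quotients `p·N/rank` are also exposed
(`fdr_quotient()`) with average ranks for ties. The bootstrap edge
p-value is `2·min(#{rho_b ≤ 0}, #{rho_b ≥ 0})/n_valid`, capped at 1, with
resamples where a pair member is constant excluded from the denominator.
Correlation-matrix repair clips eigenvalues at 1e-6 and re-unitises the
diagonal. Betweenness is computed on the unweighted graph and normalised
by `(n−1)(n−2)/2`. AIC ties break toward fewer terms, then
lexicographically. All randomness flows from one root seed, split per
stage and per sample by stable string-hash labels, so results are
invariant to row order and bit-reproducible.

## Known limitations

Pair records are treated as independent observations in the GLM although
pairs share ASVs and group-level structure; the subsample robustness
procedure reports, but does not correct, that dependence. Compositional
effects mean the co-occurrence index measures association of *relative*
abundances; absolute-abundance interactions are not identified. The
bootstrap edge test is liberal for small sample sizes. The distance stage
requires pre-aligned sequences and offers only p and JC69 distances —
downstream conclusions depend only on the monotone ordering of distances,
which both share with more elaborate models.
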