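---
title: "Distinguishing pleiotropy from linkage in mixed-model GWAS: models and design choices"
author: "pleiolink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing pleiotropy from linkage in mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

A genome-wide association study that finds the same genomic region associated
with two traits cannot, by itself, say whether one causal variant influences
both traits (pleiotropy) or whether two distinct causal variants sit close
enough together that their signals merge (linkage, producing *spurious
pleiotropy*). `pleiolink` is a simulation framework for quantifying how often
univariate and two-trait multivariate linear mixed models (MLMs) confuse the
two situations, as a function of the linkage disequilibrium (LD) between the
causal loci, their allele frequencies, trait heritabilities, sample size, and
the LD landscape of the species.

The design crosses six genetic-architecture variants — independent QTNs on
different chromosomes; linked QTN pairs with LD controlled directly or
indirectly at an upper bound of 0.01 or 0.98; and a single pleiotropic QTN —
with two target minor allele frequencies (0.05, 0.40), three heritability
pairs ((0.30, 0.30), (0.30, 0.80), (0.80, 0.80)), three sample sizes (500,
1,000, 2,815) and two species LD profiles, giving 216 scenarios, each
replicated (100 times at full scale) with freshly drawn QTNs.

## Synthetic genotype panels

Real diversity panels are replaced by a generator whose presets emulate the
contrasting LD decay of a maize diversity panel (mean pairwise
r² falls to about 0.10 within roughly 10 kb) and a soybean panel (the same
decay takes about 1 Mb). The generator works per chromosome:

1. **Marker positions.** Inter-marker gaps are exponential with the preset's
   mean spacing. The maize-like preset mixes in a short-gap "cluster"
   component (35% of gaps, mean 1 kb) because genotyping-by-sequencing
   markers cluster near restriction sites; the soybean-like preset uses even,
   array-like spacing.
2. **Founder haplotypes.** A pool of 512 founder haplotypes is drawn from a
   distance-decaying AR(1) Gaussian latent process thresholded at each site's
   allele-frequency quantile. The AR(1) correlation length is the preset's
   main decay knob (16 kb maize-like, 1.6 Mb soybean-like). Founders *must*
   carry internal LD: if founder alleles were independent across sites, the
   attainable r² between nearby markers would be capped near the reciprocal
   of the founder-pool size, and no calibration could produce the high-LD
   marker pairs the linked architectures need.
3. **Allele-frequency spectrum.** Site frequencies are marginally uniform on
   [0.025, 0.5] but spatially autocorrelated on the same length scale, so
   neighbouring sites have similar frequencies. Without this, frequency
   mismatch between tightly linked sites strongly attenuates their r²
   (a rare and a common allele cannot be highly correlated), again capping
   short-range LD well below what real panels show.
4. **Mosaic copying.** Each gamete copies along the chromosome from a
   randomly chosen founder, switching templates between adjacent markers
   with probability `1 − exp(−rate × gap)`. The switch rate (1/200 kb
   maize-like, 1/20 Mb soybean-like) erases founder sharing at long range so
   that distant markers decorrelate to the sampling floor.
5. **Individuals.** An individual is two gametes; with probability
   `inbreeding` (default 1, as in inbred diversity panels) the two gametes
   are identical, so default panels are fully homozygous and the kinship
   diagonal averages 1 + f = 2.

The founder-pool size matters beyond LD. An early 48-founder version gave
panels whose kinship structure was so strong that any single marker vector
was almost perfectly "heritable" under the genomic relationship matrix: the
mixed model attributed a single-QTN trait entirely to the polygenic term
(variance ratio at the search boundary, residual covariance estimated
singular), collapsing detection power in a way real panels do not show. With
512 founders the kinship matrix has realistic, moderate structure and the
pathology disappears; the LD presets were recalibrated after this change.

Calibration of the two presets was done once, by simulating decay curves
over many seeds (`analysis/02_ld_calibration.R` reruns the experiment):
mean r² in the bin around the target distance is 0.09–0.11 for both presets,
and the first bin at or below 0.10 brackets the target distance, which ties
the detection windows (10 kb maize-like, 1 Mb soybean-like) to the decay
scale. The synthetic panels contain no missing genotypes; the missingness
filter exists for imported real-format files.

What the generator does **not** emulate: subpopulation structure and
admixture (no trait in the study has a structured genetic background, and
the GWAS models deliberately omit structure covariates), allele-frequency
ascertainment of array design, multi-allelic sites, and genome-scale marker
counts (desk-scale panels use ~2,000 markers, not 45,000). Detection rates
here are therefore comparable across architectures — the quantity of
interest — but not numerically transferable to any real panel.

## Marker quality control

`filter_markers()` mirrors standard panel QC: markers with more than 5%
missing data are dropped, then markers with minor allele count below 5
(recomputed on the current panel, so nested subsamples re-apply it), then LD
pruning with plink's windowed greedy semantics (`--indep-pairwise 100 10
0.9`): within each 100-marker window, while any pair has r² ≥ 0.9, the
member of the worst pair with the smaller MAF is removed (later index on
ties), and the window advances by 10 markers. Windows never span
chromosomes. The implementation is checked against a brute-force
re-implementation of the verbal rule on small panels.

All LD in the package is composite LD: the squared Pearson correlation of
unphased dosage vectors, as plink computes on genotypes. Haplotype-phase r²
is never used — every downstream consumer (QTN selection, detection windows,
regional LD) operates on dosages.

## QTN selection and trait simulation

QTNs are drawn from the markers whose MAF lies within ±0.02 of the target
(the band doubles, with a message, if empty). The architectures differ in
how the second QTN is tied to the first:

- **independent** — both QTNs drawn by MAF, redrawn until their chromosomes
  differ. Their incidental interchromosomal r² is recorded; its occasional
  outliers exceed what direct control at 0.01 allows, a feature of real
  panels the study reproduces.
- **ld_direct** — QTN2 is the marker on QTN1's chromosome (within ±100
  marker indices) with the *highest* r² to QTN1 subject to r² ≤ bound, ties
  broken by physical proximity then index. The argmax-under-bound reading is
  a deliberate design choice: only it makes the 0.98 scenario a genuinely
  high-LD scenario; "any marker under the bound" would make 0.98
  indistinguishable from 0.01. The ±100-index window keeps the search
  tractable.
- **ld_indirect** — a *middle* marker is drawn by MAF; each QTN is the
  argmax-under-bound marker strictly upstream/downstream of it. The QTN-pair
  r² itself is only indirectly constrained (it is recorded). The middle
  marker is **retained** in the scanned marker set: it is not a causal
  variant, and removing it would delete exactly the best proxy and make the
  indirect scenarios artificially undetectable.
- **pleiotropic** — one marker controls both traits, with effect +0.10 on
  each (sign-concordant; exposed as a parameter).

Traits are single-QTN additive: `g = 0.10 × dosage`, and the residual
standard deviation is chosen so that `Var(g) / (Var(g) + sd²)` equals the
inputted h² *exactly* (sample variances). The two traits' residuals are
independent — a residual correlation is a hook left at 0, since the study
design never specifies one. Under pleiotropy this construction implies a
genetic correlation of 1 and a phenotypic correlation of √(h²₁h²₂), both
verified by simulation in the tests. QTN markers are removed from the
scanned marker set in every replicate (the causal variant is typically not
genotyped), and a fresh QTN assignment is drawn per replicate.

Seeding is hierarchical — master seed → scenario identity hash → replicate
index — so any replicate is reproducible in isolation and results cannot
depend on execution order or worker count.

## Mixed-model scans

The kinship matrix is VanRaden's genomic relationship matrix,
`K = WW′ / (2Σp(1−p))` with dosages centered by twice the allele frequency.
It is computed once per scenario panel from all filtered markers, including
the soon-to-be-removed QTNs — removing ≤2 of ~2,000 markers perturbs K
negligibly, and recomputing per replicate would dominate runtime.

**Univariate.** `y = μ1 + xα + u + e` with `u ~ N(0, σ²g K)`. After one
eigendecomposition of K, the profile log-likelihood over δ = σ²g/σ²e costs
O(n) per evaluation; δ is optimized on log δ ∈ [−10, 10] by Brent search,
with the endpoints checked explicitly and boundary solutions reported
honestly. Marker tests use maximum likelihood (not REML) and a χ²₁
likelihood ratio against the no-marker null, re-optimizing δ per marker in
the default `per_snp_ml` mode. The `null_based` mode (the EMMAX/P3D idea)
fixes δ at the null estimate and uses a generalized-least-squares Wald test;
the two agree to high accuracy on test panels and `null_based` is what the
scenario pipeline uses at scale.

**Multivariate.** After the same rotation, phenotype row *i* is bivariate
normal with covariance `d_i Vg + Ve`. The six free parameters are optimized
through a log-Cholesky parameterization (Ve positive definite, Vg
semidefinite allowed) by Nelder–Mead followed by BFGS from three fixed
starting points, best likelihood winning. The per-marker test of the 2-df
null "no effect on either trait" defaults to fixing (Vg, Ve) at the null
estimates (GLS Wald, χ²₂) — a deliberate P3D-style deviation from per-marker
optimization, chosen for desk-scale runtime; `per_snp_ml` exists to quantify
the difference and is validated against a dense 2n × 2n Kronecker-form
likelihood oracle and, in the kinship-free limit, against the closed-form
two-response regression LRT.

Numerical safeguards: kinship eigenvalues are clamped at zero; underflowed
p-values are floored at 10⁻³⁰⁰ so BH adjustment stays defined; and if the
estimated residual covariance is nearly singular (possible when the
polygenic term absorbs almost all variance), it is ridged by 10⁻⁴ of its
trace before inversion. Constant markers yield NA p-values, flagged and
excluded from FDR adjustment.

## Detection statistics

Within each scan, p-values are Benjamini–Hochberg adjusted genome-wide (the
two univariate traits separately, never pooled), significant means adjusted
p < the FDR level (0.10 primary, 0.05 secondary). A QTN counts as identified
if a significant marker lies on its chromosome within the detection window
(10 kb maize-like / 1 Mb soybean-like; alternates 1 kb / 10 kb). The window
boundary is inclusive — the study never specifies open vs closed, and the
choice is covered by an explicit boundary test. Per replicate and model the
four recorded outcomes are: trait-1 detected, trait-2 detected, both
detected, and the error flag — any significant marker outside *both* QTN
windows, applied literally even to a univariate scan for which only one QTN
is causal. Multivariate detection rates under the independent and linked
architectures are labelled *spurious pleiotropy detection rates*: the model
has identified a signal it cannot attribute to a single causal locus.

The headline diagnostic is the univariate simultaneous detection rate: under
pleiotropy (and under linked QTNs in very high LD) it tracks
min(rate T1, rate T2), because one shared local signal drives both traits;
under independent QTNs it falls toward the product rate T1 × rate T2 / 100.
The multivariate model, by contrast, detects linked non-pleiotropic pairs at
rates comparable to genuinely pleiotropic QTNs even when the QTN-pair r² is
bounded at 0.01 — which is exactly why it cannot distinguish the two.

## Problem sizes and what the tests show

The shipped tests and the acceptance checks run at desk scale, the package's
own choice of problem size: panels of ~2,000 filtered markers over 10
chromosomes, samples of 150–1,000 individuals, 20 replicates per scenario
for the signature checks and 100 draws for the selection-contract checks.
At these sizes the detection-rate *contrasts* between architectures are
stable, but individual rates carry binomial noise of several points per 20
replicates; the signature tests therefore compare gaps and aggregates with
a one-to-two-replicate slack rather than asserting bar heights. Full-scale
runs (216 scenarios × 100 replicates) use the same code path via
`run_study(study_design())`.

## Known limitations

- Two traits only; no epistasis, dominance, multi-QTN architectures, or
  polygenic background beyond the single causal locus per trait.
- No population-structure confounding is simulated, and none is corrected
  for — faithful to the study design, but it means the kinship term is
  essentially a no-op safeguard on these panels.
- The generator's LD is stationary along chromosomes apart from marker
  clustering; real genomes have recombination hot/cold spots that create
  heavier-tailed proxy-strength distributions.
- GEMMA-style semantics are reproduced (ML, LRT, genome-wide BH), not
  GEMMA's bit-exact numerics.
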