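---
title: "Methods: low-coverage ancient-genome imputation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-coverage ancient-genome imputation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoimpute)
```

## Scope and assumptions

`paleoimpute` analyses a low-coverage diploid genome against a phased
reference panel of biallelic SNPs (minor allele count > 1, one
chromosome, strictly increasing positions). The analysis assumes
independent reads, per-read Phred-calibrated base error, and post-mortem
deamination acting as C→T substitutions decaying exponentially from the
5′ read end (with the complementary G→A signal at the 3′ end). Indels,
multi-allelic sites and mapping artefacts are out of scope.

## Genotype likelihoods and the flat-likelihood rules

For a read stack at a site with alleles ref/alt, a read whose base is
neither allele is discarded. With error probability $e_r = 10^{-Q_r/10}$,
the allele likelihood is $1-e_r$ on a match and $e_r/3$ otherwise, and a
genotype's likelihood is the product over reads of the mean of its two
allele likelihoods, accumulated in log space and normalised once at the
end (the contract is the normalised triple; the representation is free).
Two flat-likelihood rules follow:

* a site with no usable reads gets the flat triple (0.3333 per genotype)
  and an `uncovered` flag;
* a site whose allele pair is C/T or G/A is reset to the flat triple
  (`site-flat` masking) because deamination can manufacture the alternate
  allele from the reference one.

The masking question — reset the whole site or only the genotypes that
could contain a deamination product — is genuinely open; resetting
individual genotypes breaks normalisation and retains damage-driven
information, so the conservative site-flat reading is the default and the
per-genotype variant (`genotype-flat`, with renormalisation) is kept as
an explicit mode. Masking is idempotent in both modes.

## The diploid copying model

Imputation treats the target's two chromosomes as imperfect mosaics of
the K panel haplotypes. The hidden state is the ordered haplotype pair
(K² states, uniform start). Per haplotype and per inter-site step the
chain stays with probability $e^{-\rho}$ and otherwise jumps to a
uniformly drawn haplotype; the factorised structure lets the K²-state
transition be applied with row/column sums in O(K²). The emission at a
site convolves the genotype-likelihood triple with two independent
miscopy draws of rate $\varepsilon$, so it takes at most four distinct
values per site (one per allele pair). A scaled forward–backward pass
(C++, O(M·K²) time, O(M·K²) memory for the stored forward matrix)
returns per-site genotype probabilities (GP) and the data log-likelihood.
An exhaustive path-sum implementation (`brute_force_posterior`) is
exported purely as a test oracle and is guarded to tiny instances.

Parameter defaults, exposed in `hmm_params()`:

* `switch_rate` ρ = 0.001 per site (≈10 expected template switches per
  10⁴ sites) or per Mb when `use_map = TRUE`;
* `copy_error` ε = 0.002. This value matters structurally: a perfectly
  copied allele pair can reach GP at most $(1-\varepsilon)^2$, so with
  ε = 0.01 no uncovered or masked site could ever pass the genome-wide
  0.99 calling threshold and the call rate would collapse to the covered,
  unmasked minority of sites. ε = 0.002 gives a ceiling of 0.996,
  restoring the regime in which confidently imputed flat-likelihood sites
  are callable while genuinely ambiguous ones are not.

Calls use the argmax genotype when its GP reaches the threshold (0.99
genome-wide, 0.85 single-locus); exact ties are treated as missing.
Sites at the extreme chromosome ends are flanked from one side only and
occasionally fall just below 0.99 even under perfect data — the usual
edge behaviour of un-chunked HMM smoothing.

## What the generator emulates, and what it does not

`sim_config()` defaults define the synthetic study conditions:

* K = 100 phased haplotypes, M = 5,000 sites on a 10 Mb chromosome;
  per-site derived-allele frequency uniform on (0.05, 0.95), with sites
  redrawn (frequency and alleles jointly) until minor allele count > 1,
  i.e. sites are ascertained the way a polymorphism panel is.
* `transition_fraction = 0.66` of sites are C/T or G/A — the approximate
  transition share among human SNPs — and are therefore subject to
  deamination masking.
* The target diploid is a founder mosaic with
  `mosaic_switch_rate = 1e-6` per bp (≈10 switches per 10 Mb haplotype).
  This keeps the target an *imperfect* mosaic of the panel, emulating the
  fact that an ancient individual's haplotypes are only approximately
  represented in a modern reference panel. In the perfect-copy limit
  (rate 0) imputation from high coverage recovers every genotype; at the
  default rate, sites near template switches are genuinely ambiguous and
  stay uncalled at the 0.99 threshold, which is what places the 1×
  call-rate in the published operating regime of this analysis (~3/4 of
  loci called, ≥98–99% of calls concordant) rather than at an
  unrealistically perfect 100%.
* Reads: Poisson(coverage) per site; fragment length a discretised
  normal (mean 60, sd 15, truncated to 30–150 bp, matching a ≥30 bp
  post-trim filter; real fragment-length spectra vary by library and are
  not modelled further); the site placed uniformly in the fragment gives
  the distances from both read ends; deamination applies on the read
  strand with probability $\delta\,e^{-(i-1)/\lambda}$ (defaults
  δ5 = δ3 = 0.2, λ = 3 positions); Phred errors substitute a uniform
  other base; contaminant reads (default rate 0.005, matching sub-1%
  contamination in well-preserved ancient samples) carry alleles drawn
  from panel frequencies (a modern-like contaminant).
* mtDNA reads cover configurable diagnostic positions where endogenous
  and contaminant haplotypes differ (half the pairs C/T by default, to
  exercise the damage confound); X/Y counts are binomial with male Y
  fraction 0.09.

Not emulated: linkage-disequilibrium decay within the panel (haplotypes
are exchangeable Bernoulli draws), demography/coalescent structure,
sequence context of deamination, mapping bias, and reference bias.
Passing tests therefore demonstrate the *mechanics* of the pipeline —
likelihood construction, masking, HMM inference, estimator calibration —
not performance on real ancient libraries, where panel representation
and damage chemistry are less favourable.

## QC and contamination estimators

The damage profile counts observed C→T by distance from the 5′ end (and
G→A from the 3′ end) against the reference allele, complement-normalising
minus-strand reads; only reference-C (resp. -G) sites enter the
denominators, and callers should restrict the site table to sites where
the sample is not genuinely polymorphic (the end-to-end pipeline uses
homozygous-reference sites for exactly this reason). The decay summary
fits $A e^{-(i-1)/\lambda}$ by nonlinear least squares seeded from a
log-linear fit, with a direct optimiser fallback; fits with λ > 10³
positions (or degenerate solutions) are flagged "no decay detected". At
very low coverage the per-position denominators are small and the decay
fit is honest but noisy.

Sex calling uses Ry = nY/(nX+nY) with a normal-approximation binomial
95% CI and the conventional shotgun bounds (XX if the interval lies
below 0.016, XY if above 0.075, otherwise indeterminate). The bounds are
exposed because they are a convention, not a fitted quantity.

mtDNA contamination is the fraction of reads carrying the contaminant
allele at diagnostic positions (exact binomial CI). Positions whose
endogenous→contaminant difference is C→T or G→A are excluded by default
so deaminated endogenous reads are not mistaken for contamination; the
exclusion is toggleable.

X contamination in males uses the fact that a male X is haploid: at
panel-polymorphic X sites with depth ≥ 2, the mismatch fraction against
the site majority allele, minus the supplied allele-crossing error rate,
scaled by the mean panel heterozygosity $\overline{2p(1-p)}$, estimates
the contaminant fraction (clipped to [0, 1]; site-level bootstrap CI).
When site alleles are supplied the estimator restricts itself to
transversion sites and to reads carrying one of the two alleles, which
makes it immune to deamination by construction. The autosomal error rate
is an input — estimated elsewhere, never re-fitted inside the estimator.
This moment estimator is the package's own design; likelihood-based
mixture estimators over the full mtDNA are out of scope.

## Validation design

`coverage_sweep()` reproduces the downsampling experiment: simulate (or
thin) reads at each coverage in 0.1–5×, rebuild masked likelihoods,
re-impute, and report call rate, overall concordance, heterozygote
concordance and non-reference discordance against the generator's truth
at each GP threshold. Heterozygote concordance is conditioned on
truth-heterozygous called loci; the alternate conditioning on called-het
loci is reported alongside (`het_callhet`), since the published summaries
do not disambiguate the two. Evaluable loci are the truth-called loci.

## PCA, Procrustes and ROH choices

PCA drops monomorphic sites, mean-imputes missing modern genotypes per
site, centres by the mean dosage and scales by
$\sqrt{(\mu/2)(1-\mu/2)}$. Ancient samples are never imputed here:
each is placed by a per-sample PCA of the moderns restricted to the
sample's covered sites, onto which the sample is projected, and the
restricted modern configuration is Procrustes-fitted (scale, orthogonal
rotation *including reflections* — PCA axes have arbitrary sign — and
translation, by SVD of the cross-covariance) back onto the canonical
frame. Projecting rather than co-decomposing keeps the placement
independent of the ancient sample and makes the identity check exact (a
copy of a modern individual lands on its twin); with near-degenerate
trailing eigenvalues a co-decomposition would not even preserve the
retained subspace. Two axes are retained by default. Disparity is the
residual sum of squares over the centred target variance.

ROH detection follows the PLINK sliding-window tradition: 50-SNP
windows, ≤1 heterozygote and ≤5 missing per homozygous window, a SNP is
in-run when ≥5% of its spanning windows are homozygous, segments split
at gaps > 1 Mb and filtered at ≥500 kb and ≥50 SNPs (the SNP minimum is
set to desk-scale densities; all values sit in `roh_config()`). Segments
are classed short/long at 1.6 Mb; the boundary length exactly 1.6 Mb is
owned by "long", a choice the strict inequalities of the usual plots
leave open. The age regression is ordinary least squares of total ROH
(Mb) on median calibrated age with a two-sided slope p-value; a constant
response is defined to have r² = 0.

## Trait loci

`extract_trait_genotypes()` reads single loci off the imputed posterior
at the 0.85 threshold and orients dosage by the effect allele (the
bundled default panel covers the pigmentation sweeps rs1426654/SLC24A5,
rs16891982/SLC45A2, rs2733831/TYRP1 and the lactase-persistence allele
rs4988235-T; in the synthetic pipeline these names label designated panel
sites, and the coordinates are synthetic stand-ins). Loci absent from
the panel are reported `absent`, not errored. Phenotype *prediction*
(HirisPlex-style systems) is deliberately only a pluggable interface:
the published coefficient sets are external and are not re-derived or
bundled.

## Orchestration, determinism and problem sizes

The pipeline is a set of exported R functions; `run_pipeline()` wires
simulate → damage → sex/contamination → likelihoods → imputation →
evaluation → PCA → ROH → traits, writes every report as plain text
(VCF/TSV/BED/JSON) plus a manifest echoing version, seed and parameters,
and names the failing stage on error while retaining partial outputs.
One global seed derives per-stage seeds, so a stage can be re-run in
isolation with identical randomness and a rerun of the whole pipeline is
byte-identical. The R interface *is* the command surface: each pipeline
stage corresponds to one exported function, so no separate shell CLI is
shipped.

Test problem sizes are chosen so the full suite runs comfortably on one
CPU: oracle equivalences use K ≤ 3, M ≤ 4 (exhaustive path sums),
recovery studies use K = 20–100 and M = 500–5,000 with 10–100
replicates, and the study-scale imputation checks use K = 100,
M = 5,000 over the 0.1–5× grid with 10 replicates per coverage.

## Known limitations

* The copying HMM is O(M·K²); K in the hundreds is the intended scale,
  not thousands (no chunking/ligation is implemented).
* The panel lacks LD structure, so imputation here is easier per
  informative site than on real data; conversely the mosaic switch rate
  is the single knob that makes it harder. Absolute call rates should be
  read as regime checks, not forecasts.
* Damage fitting at < 1× coverage is noisy; profile fits there are
  reported but weakly determined.
* No genetic map support beyond a per-Mb switch-rate scaling.
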