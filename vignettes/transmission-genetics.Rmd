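---
title: "Transmission genetics under gamete lethality: model, estimators, simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission genetics under gamete lethality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seglethal)
```

## The genetic system

The package models the three-locus system that arises when the large-grain
allele *GW2* (incompletely dominant, from the Japonica variety Inochinoichi)
and the semidwarfing allele *d60* are combined in the Koshihikari background.
*d60* comes with a complementary gametic lethal: gametes — male and female
alike — carrying both *d60* and *gal* are inviable. Koshihikari is
*D60D60 galgal*, the semidwarf donor line is *d60d60 GalGal*, so the F1
(*D60d60 Galgal*, heterozygous at both loci) sheds a quarter of its gametes
and its pollen and seed fertility drop to 75%. Selfing that F1 yields the
characteristic 6 fertile long-culm : 2 partially sterile long-culm :
1 semidwarf ratio instead of a Mendelian 3:1 at the semidwarfing locus.

*GW2* and *D60* lie on chromosome 2 at recombination fraction r (default
0.176, the study system's point estimate); *Gal* assorts independently of
both by default. The independence of *Gal* is required by the observed 6:2:1
culm segregation; whether it is truly unlinked is not established, so
`study_map(gal_linked = TRUE, r_d60_gal = ...)` allows a linked
configuration.

## Transmission model

`gamete_frequencies()` enumerates a parent's gamete haplotypes under
independent assortment between linkage groups and, within a group, crossover
events in each adjacent interval with probability r, assumed independent
across intervals (no interference — the package only ever makes two-point
statements, for which interference is irrelevant). Lethal haplotypes are
removed, the remainder renormalised, and the pre-lethality surviving
fraction is kept as the parent's *fertility*. Keeping fertility separate
from the renormalised frequencies means both expected population
compositions and the "partially sterile" phenotype (fertility < 1) are
derivable from one object.

```{r}
gd <- gamete_frequencies(study_f1_d60(), rule = study_rule())
gd
attr(gd, "fertility")
```

`zygote_distribution()` is the outer product of two gamete pools, pooled
into unordered genotypes: the model never distinguishes reciprocal
heterozygotes, because no downstream quantity depends on parental origin
once phase within a haplotype is fixed.

Three phenotype classifiers translate genotypes into the field-scored
classes: the culm rule (semidwarf iff *d60d60*; partially sterile iff
*D60d60 Galgal*, i.e. heterozygous at both loci — the F1 type; long culm
otherwise), the grain rule (large/medium/small for 2/1/0 copies of *GW2*
under incomplete dominance), and their joint interaction. Deriving the
culm expectations from the model rather than hard-coding 1:2:6 keeps every
reported statistic reproducible from first principles:

```{r}
expected_class_probabilities(resolve_design(design_d60_f2()),
                             culm_classifier())
```

Two headline consequences of the model, both recomputed (not stored) by
`model_derivations()`: under complete *GW2*–*D60* linkage the selfed
coupling-phase F1 gives 5/9 *GW2* carriers vs 4/9 *gw2gw2* (the "5:4"
argument), while under independence *GW2*-homozygous long-culm and
partially sterile plants appear at 6/36 and 2/36 — classes whose observed
absence is what indicates linkage.

## Segregation testing

`chi_square_gof()` is the uncorrected Pearson statistic; the study's
printed values match the uncorrected form, so no Yates correction is
offered. The exact p-value from the chi-square survival function is
reported together with a 0.05-grid bracket ("0.85 < P < 0.90") mirroring
the classical table-lookup presentation. Degrees of freedom default to
classes − 1; an explicit override covers tests where parameters were
estimated or where a reported df is being reproduced.

`reproduce_reported()` re-runs every embedded segregation test of the
source field study. Two of the ten reported statistics do not recompute
from their own printed counts (8:18:10 against 1:2:1 gives 0.22, not the
reported 0.20; 17:36:104 against 1:2:6 gives 0.05, not 0.01); these rows
are flagged, never corrected or asserted. Likewise the reported "df = 1"
beside the three-class 10:32:8 test is presentation we reproduce only via
the explicit df override, since its printed P range matches df = 2.

## Recombination estimation

Selection on the recessive semidwarf class removes the lethality
distortion: every surviving *d60*-bearing gamete carries *Gal*, and among
them the probability of carrying *gw2* is exactly r. A semidwarf individual
is therefore two independent Bernoulli(r) gametes, the class segregates
$(1-r)^2 : 2r(1-r) : r^2$, and the counting formula

$$\hat r = \frac{n_{het} + 2\,n_{rec}}{2N}$$

is the conditional maximum-likelihood estimate. This is the model's
justification for the study's counting calculation (11:6:0 gives
17.6%). `ml_estimator()` generalises to any class system whose
probabilities are a function of r: it maximises the multinomial
log-likelihood on a coarse 0.005 grid, refines on a 1e-4 grid in the
bracketing interval, polishes with `optimize()`, breaks ties toward
smaller r, and reports a 1-unit support interval; the procedure is
deterministic. Estimates outside [0, 0.5] are never silently clamped —
the counting estimator returns them flagged with a phase warning, since an
all-recombinant class usually means the assumed coupling phase is wrong.
Phase is otherwise taken as known from the pedigree (donor alleles in
coupling).

`marker_trait_recombination()` applies the same recessive-class counting
marker by marker to a genotype table of trait-homozygous segregants,
reducing N per marker for missing codes. `haldane_r()`/`haldane_d()`
convert between map distance and recombination fraction under the
no-interference model.

## The breeding simulator

`simulate_population()` samples finite populations through a cross design:
each offspring receives one surviving gamete drawn from each parent's exact
gamete distribution. Selection steps filter on genotype predicates even
though the field programme selected on phenotype: the simulator's purpose
is reproducing the scheme's genetic state, and a phenotype route (thresholds
on noisy traits via `sample_phenotypes()` + `classify_counts()`) is
available when misclassification is the object of study. Each step draws
from its own RNG stream derived deterministically from the run seed, so
appending steps to a design never perturbs earlier generations.

Default population sizes mirror the study's printed totals where available
(186 F2, 112 BC1F2, 157 BC4F2); property tests use sizes from 200 to
10,000 chosen so that sampling error, not runtime, is the binding
constraint.

`attach_markers()` adds SSR/SNP-style marker genotypes by walking a
no-interference crossover chain outward from an anchor trait locus,
converting physical spacing to genetic distance at 4 cM/Mb — an explicitly
arbitrary rice-scale order of magnitude, configurable — and then to per
interval recombination fractions via Haldane. Conditioning the chain on the
anchor allele makes marker genotypes jointly consistent with the sampled
trait haplotype; the construction assumes each haplotype is an intact
F1-meiosis gamete, true for F2 material like the mapping population, an
approximation for advanced backcross generations.

The phenotype model is Gaussian noise around class means: grain areas
20.0/22.0/24.6 mm² (sd 0.8) anchored by the marker-diagnosed class means
of the mapping material, culm lengths 49/64 cm (sd 3) from the BC4F2 class
ranges. With the default midpoint thresholds (21.0, 23.3 mm²) the expected
classification accuracy has a closed Gaussian-overlap form of about 0.88,
and the tests assert the simulation against that closed form rather than
against a nominal figure.

## What the simulator does and does not emulate

It reproduces the transmission genetics: distorted segregation, fertility
classes, marker co-inheritance, and the sampling noise of finite
populations. It does not model field environmental variance, genotype-by-
environment interaction, misscoring of markers, segregation of background
loci, or quality traits. Passing calibration tests therefore shows the
estimators are correct under the stated model, not that field data will be
this clean; in particular the marker panel's real recombination values
depend on the local Mb-to-cM relationship, which the flat 4 cM/Mb default
deliberately does not claim to capture.

## Numerical choices and degenerate inputs

Frequencies are exact rational arithmetic in floating point; distributions
are checked to sum to 1 within 1e-12. Zero-probability haplotypes (r = 0)
are dropped rather than reported as zeros. A lethality rule that removes
all gametes, an empty count class, a zero expected count, unordered
threshold cuts, and selection predicates that match nothing all raise typed
errors rather than propagating NaN. Threshold intervals are half-open
[low, high), with the cut point belonging to the upper class.

## Known limitations

Two-point analysis only: no multipoint likelihood or interval mapping, and
no crossover interference. The analytic design resolver weights a
mixed-genotype parent population's gametes by genotype frequency, not by
fertility-weighted gamete output; in the study's designs every crossing
parent is a single selected genotype, so the simplification is inert there.
Physical-to-genetic calibration from sequence data is out of scope.
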