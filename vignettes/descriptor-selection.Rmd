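---
title: "Measurement descriptors for keratin biopolymers: generation, selection and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement descriptors for keratin biopolymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Hair fibres are keratin composites: a crystalline alpha-helical cortex
wrapped in a disulfide-rich amorphous cuticle, with lipids and water
distributed through both. No single measurement sees all of this. Solid-state
NMR (static wide-line and magic-angle-spinning ^1^H, CP-MAS ^13^C) reads
molecular composition and mobility; low-field time-domain NMR reads the
rigid/mobile proton partition from solid-echo decays; ATR FT-IR reads
secondary structure at the fibre surface; derivative thermogravimetry (DTG)
reads the thermal decomposition of the different histological compartments.
The question `mdselect` addresses is how to convert such heterogeneous curves
into a common currency — scalar *measurement descriptors* — and how to find,
among hundreds of them, the small subset that predicts a mechanical property
(breaking force, elastic modulus, extension, yield strength) of the fibres.

The pipeline is: pre-treat each modality; deconvolve the curve families that
have physically meaningful component models; convert everything into a
descriptor table (bins, PCA scores, fit parameters and their transforms);
get an overview by canonical correlation analysis; and then select
descriptors by importance-guided recursive elimination under two different
regression algorithms, keeping the descriptors both algorithms agree on.

# Pre-treatment

Each modality has a fixed recipe, recorded in every spectrum's lineage:

* **NMR spectra** (wide-line, MAS, CP-MAS): optional cubic-spline alignment
  to a common axis, Savitzky–Golay second-order differentiation (cubic
  polynomial), truncation to the informative windows (−102…102 ppm,
  −8.0…14.2 ppm, 2.8…185.2 ppm respectively), then normalisation to unit
  total area. Both the nonderivative and second-derivative branches are kept.
* **FT-IR**: second derivative, excision of the ATR-crystal interference
  windows 1711–2669 and 3400–4000 cm^−1^, area normalisation, replicate
  averaging. Only the derivative branch is used downstream.
* **DTG**: rebinning to 1 °C bins over 44–497 °C (454 bins, left-closed
  intervals so integer boundaries are assigned deterministically), division
  by the sample mass, and a second-derivative branch to sharpen overlapping
  mass-loss events.
* **TD-NMR**: each replicate decay is fitted as three components and divided
  by the fitted t = 0 intensity, so the model evaluates to one at the origin;
  the five replicate decays and their fitted curves are averaged per pool.

Two numerical choices deserve comment. The Savitzky–Golay **window length**
is 11 points by default (configurable per modality): long enough to suppress
point noise, short enough that the narrowest template bands (two to three
bins wide) survive differentiation. Windows are dropped at the edges
((w−1)/2 points each side) rather than padded, so no polynomial edge
artifact reaches the outermost bins. Second, "total area" of a
second-derivative profile is defined as the **absolute-value** trapezoidal
integral: the signed integral of a derivative is near zero by construction
and would make the normalisation ill-conditioned (`signed = TRUE` preserves
the alternative).

# Deconvolution

The wide-line ^1^H spectra are decomposed into **three Voigt profiles**
(broad rigid envelope, intermediate, narrow mobile peak). The Voigt function
is evaluated through the Faddeeva function w(z) via Weideman's 36-term
rational approximation, which is accurate to near machine precision over the
upper half-plane and cheap enough to sit inside least-squares iterations.
FWHMs are obtained by bracketed root finding on the profile itself (the
Olivero–Longbothum approximation only seeds the bracket), so the pure
Gaussian and Lorentzian limits are exact. Fitting uses bounded
Levenberg–Marquardt with a deterministic start set: a peak-stripping start
(fit the broad envelope alone, seed the remaining peaks from the residual)
plus a fixed grid of width combinations; the best residual wins, and the
search stops early once a candidate reaches the numerical noise floor
(relative RSS below 10^−6^). Amplitudes are floored at a trace level
(10^−6^ of the total area) so that reported area proportions stay positive —
their logarithms and inverses are later used as descriptors.

The TD-NMR decays are fitted as **one Abragam component plus two
exponentials** — the standard rigid/intermediate/mobile proton partition:
exp(−t²/2T²)·sin(bt)/(bt) for the rigid lattice and exp(−t/T) for the mobile
fractions, all normalised to one at t = 0. The reported "relaxation time" of
the Abragam component is its Gaussian time constant T. Eight starts with
log-spaced relaxation times in [5 µs, 1 ms] make the optimisation
deterministic; components are reported sorted by ascending relaxation time
and intensity proportions sum to one exactly. The component shapes are
configurable because vendor implementations of the three-component model
differ; the default is the conventional choice.

# Descriptor generation

Four descriptor families are produced per sample pool:

* **Even-step bins** per modality and derivative order; the bin value is the
  mean intensity in the interval. Ids follow the `<modality>.<n>` /
  `<modality>.2der.<n>` convention, numbering consecutively across a block's
  regions (so the FT-IR gap keeps a single running index). Default counts —
  51 wide-line, 74/142 MAS (nonderivative/derivative), 100 CP-MAS, 91 FT-IR,
  45/72 DTG — keep the template bands resolved: roughly two bins per band
  FWHM at the narrowest.
* **40 logarithmic bins** of the decay curves up to 1.0 ms, edges log-spaced
  from the first positive sample time; an empty early bin (coarse sampling)
  is merged rightward and recorded.
* **PCA scores**: each profile family (including the pre-fitted and fitted
  decay curves) is mean-centred and every principal component with a
  variance proportion above 1% is retained.
* **Deconvolution parameters**: Voigt area proportions and FWHMs; decay
  intensity proportions and relaxation times — each family expanded into
  inverses, exponentials, logarithms, and ordered mutual ratios within its
  own family (3k + k(k−1) derived columns for k parameters, plus the k raw
  values).

On the default synthetic dataset the full configuration yields **902
descriptor columns**. Because the PCA rule is data-dependent, the count can
move by two or three columns for other generator seeds; the bin and
deconvolution counts are exact config arithmetic
(`predicted_descriptor_count()`).

# Association and selection

The canonical-correlation overview first reduces the descriptors to a
pairwise |r| < 0.3 subset (0.4 within a single modality). The construction
is a greedy forward pass in stored column order — deterministic, and any
order satisfies the advertised guarantee (every surviving pair is below the
bound); a variance-ordered walk is available. CCorA itself is computed from
the SVD of the whitened cross-correlation matrix after standardising both
blocks; axis signs are fixed so the property with the largest score is
positive.

Selection is the core. For a property y and descriptor matrix X:

1. Evaluate the current set by **repeats × 10-fold CV** (100 repeats in the
   reference protocol). RMSE and R² are computed on the pooled held-out
   predictions of each repeat — R² = 1 − SSE/SST about the overall mean —
   then averaged (± sd) over repeats. Adjusted R² is deliberately not used.
2. Average descriptor **importance** over all fits: the forest's out-of-bag
   permutation importance for random forest (held-out-fold permutation
   importance is available as an option), and the explained-variance-weighted
   squared loading weights for PLSR.
3. Keep the top ⌈0.9 p⌉ descriptors (always at least one fewer; stop before
   the count falls below two) and repeat.
4. The **best set** is the step with the highest mean R², ties resolved
   toward the smaller set; importance ties break lexicographically by id.

PLSR is a univariate NIPALS implementation with predictors standardised and
the response mean-centred; the component count is chosen per training fold
by minimum PRESS under an inner 10-fold CV nested in the training data. By
default all standardisation statistics come from training folds only; a
`standardize_scope = "global"` flag reproduces the conventional
whole-dataset workflow. Forests default to 1000 trees with mtry = p/3.

Finally, the top-20 descriptors by importance at each algorithm's best step
are intersected: descriptors that two structurally different learners agree
on are the ones worth interpreting.

# The synthetic benchmark

No public dataset accompanies this problem domain, so the generator *is* the
study design. It emulates a 63-pool panel (9 cat, 12 cow, 21 human, 21 pig;
two pools per donor) with latent compositional variables — alpha-helix
fraction, lipid content, bound water, thermal resistance, cross-section
area — drawn around species means with donor and pool jitter. Species means
follow the qualitative contrasts of real panels: pig bristle thick and
crystalline, cat hair fine and lipid-rich, cow hair stiff and
heat-resistant, human hair water-rich.

Templates are sums of Voigt/Gaussian bands, skewed-Gaussian mass-loss
events, and Abragam/exponential decay mixtures — line-shape realism, not
spectral physics. Three kinds of structured nuisance make the benchmark
honest rather than trivially separable:

* **Background factors**: the large constant bands (aliphatic carbons,
  amide A, cortex pyrolysis, …) carry per-pool amplitude factors unrelated
  to any property.
* **Nuisance and crowding lines**: 28 narrow minor bands with independent
  per-pool intensities. Narrow features survive second-order
  differentiation, so these dominate the derivative blocks' PCA components
  and crowd the bins adjacent to the informative bands — the reason binning
  must "keep the peaks resolved" in the first place.
* **Band-shape jitter**: every informative band has per-pool amplitude,
  width and centre jitter.

Twelve bands respond to the three latents that drive yield strength (the
benchmark property); their strongest carrier bins — located by propagating a
unit amplitude bump through the actual pre-treatment chain
(`band_bin_sensitivity()`) — are the **20 planted informative descriptors**.
Yield strength depends on the latents *and* on the band-level jitters
themselves (amplitude = trace-constituent variation; width = structural
disorder, readable only by combining a band's nonderivative and derivative
bins; centre = conformational shift, readable only from a flank-bin pair),
so each listed bin carries a share of signal that no other descriptor
duplicates. Bound water deliberately drives no part of yield strength and
its species means are orthogonalised against the yield-strength species
pattern: the decay-fit parameters and their many transforms, which all track
bound water, therefore stay distractors for the benchmark property while
remaining genuinely informative for extension and elastic modulus.

Property values are linear in the latents (breaking force additionally
proportional to cross-section area, in MPa × mm² = N), with replicate noise
of 0.6 N / 0.8 GPa / 12% / 25 MPa — deliberately about half the experimental
standard deviations reported for real fibre panels, because those include
fibre-to-fibre morphology variation that the pool-level latent model does
not simulate. Spectral point noise defaults to SNR 2000 (modern averaged
spectra): at that level the >1% PCA rule responds to structured variance,
not to noise.

## What passing tests do and do not show

The synthetic benchmark demonstrates that the pipeline's machinery is
correct (every pre-treatment step, both deconvolutions, the binning/PCA/
transform bookkeeping, both CV engines, the elimination schedule) and that
selection finds planted signal: the elimination curve rises and peaks as in
the reference workflow, and the RF∩PLSR consensus is strongly enriched for
the planted descriptors (hypergeometric p ≈ 10^−6^). It does **not**
demonstrate recovery of *all* planted descriptors by the random-forest best
set. With 63 pools, a forest's cross-validated R² plateaus once a minimal
sufficient subset of eight to thirty descriptors covers the latent
directions, and the highest-R²-with-ties-to-smaller rule then returns a
small set; twenty specific ids can never all be members. This is a property
of best-subset semantics under redundancy, not a defect of the importance
ranking: the PLSR arm, which can combine many weak correlated carriers,
selects best sets of 100–250 descriptors that do contain 80–90% of the
planted ids, and real studies meet the same phenomenon when two algorithms
select different-sized best sets — which is exactly why the consensus step
exists. The corresponding acceptance check reports the RF recovery rate
honestly and fails its 80% clause by design of the statistics, not of the
code.

## Study sizes

Desk runs scale the reference protocol down and state it openly: the
acceptance study uses 10 CV repeats (reference: 100), forests of 40 trees
with mtry 30 (reference: 1000 trees, mtry p/3), ten selection master seeds
for the RF arm and one for the PLSR arm, all on the one default 63 × 902
dataset. The analysis scripts use 5 repeats. Scaling affects the variance of
the estimates, not the structure of the pipeline; every number the package
reports is computed, never assumed.

# Known limitations

* Axis calibration errors, phase errors and baseline curvature are not
  simulated (an optional polynomial baseline hook exists but the synthetic
  data are baseline-clean by construction).
* The generator's bin placement and the descriptor config were co-designed;
  with real data the bin boundaries are a user decision and the 902-column
  count has no special status.
* The Abragam-component form and the vendor's three-component conventions
  differ between instruments; the shape set is configurable but no claim is
  made that the default matches any particular analyzer.
* CCorA is reported without a permutation significance test, as an overview
  only.
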