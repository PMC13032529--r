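---
title: "Tracking carbon flux with isotope-resolved vibrational spectroscopy: models and methods"
author: "isoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoflux methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoflux)
```

## The problem

When a microorganism builds its metabolites from a ¹³C-labelled carbon
source, the heavier nuclei lower the frequencies of the molecular
vibrations: the corresponding infrared and Raman bands shift to lower
wavenumbers ("red shift"), typically by a few tens of cm⁻¹. Feeding an
oleaginous, carotenogenic fungus a mixture of ¹³C glucose and unlabelled
glycerol therefore leaves an isotopic fingerprint in every storage
metabolite: a triacylglycerol (TAG) ester C=O band at ~1745 cm⁻¹ signals
lipid built from ¹²C (glycerol or yeast extract), while the partner band at
~1701 cm⁻¹ signals lipid built from ¹³C glucose. `isoflux` implements this
measurement chain end to end: a forward simulator with known ground truth,
the preprocessing recipes used for each of the four acquisition modes
(bulk FTIR and FT-Raman; FTIR and Raman microspectroscopy), isotope-resolved
band metrics, multiblock consensus PCA, PLS regression with reliability
flags, and hyperspectral-image unmixing.

Because the corresponding experimental raw data are not freely
redistributable, the package ships a synthetic-data generator as a
first-class, tested module: every analysis stage can be exercised against
a dataset whose composition, isotope fractions and spatial structure are
known exactly.

## The forward model

A bulk spectrum is synthesised as

$$ s(\nu) \;=\; \ell \sum_m w_m\, c_m(\nu; f^{13}_m) \;+\; b(\nu) \;+\; \varepsilon(\nu), $$

where \(w_m \ge 0\) are metabolite weights (unitless, relative to protein
= 1), \(\ell\) is a multiplicative effective-path-length factor
(log-normal across technical replicates, \(\sigma_{\log} = 0.15\)),
\(b(\nu)\) is an additive baseline and \(\varepsilon\) is i.i.d. Gaussian
noise calibrated to a signal-to-noise ratio of ~200 at the strongest band.
The baseline family matches the artefact each preprocessing recipe is
designed to remove: a random degree-3 polynomial for Raman (fluorescence
and heating offsets) and an offset plus broad sigmoid for FTIR (scatter).

Component spectra \(c_m\) are sums of area-normalised pseudo-Voigt lines
(Lorentzian fraction η = 0.7 — a typical condensed-phase compromise; band
widths 10–25 cm⁻¹ by band class; both are conventions, not published
values). The isotope model has two modes:

* **two_bands** (default): each band contributes
  \((1-f^{13})\,L(\nu_{12}) + f^{13} L(\nu_{13})\). Area normalisation
  makes the integrated component intensity independent of \(f^{13}\)
  (exactly so for Gaussian lines; Lorentzian tails truncated at the axis
  edges leak ~10⁻³ relative area between isotope positions, which is why
  the conservation test uses Gaussian lines at the 10⁻⁶ level).
* **interpolate_position** (carotenoids only): a single line at
  \(\nu_{12} - f^{13}(\nu_{12}-\nu_{13})\). β-carotene's 40 carbons admit
  many isotopologue mixtures, and the observed C=C band slides
  continuously between the pure-isotope positions (1523 → 1490 cm⁻¹)
  rather than splitting into two lines.

Bands without a ¹³C partner — all polyphosphate P–O vibrations, which
contain no carbon — are isotope-insensitive.

Default axes follow the instrument grids: FT-Raman 3785–50 cm⁻¹ and
HTS-FTIR 4000–400 cm⁻¹ at 1.928 cm⁻¹ spacing; FTIR microspectroscopy
3850–900 cm⁻¹ at 3.851 cm⁻¹. The Raman-microscope CCD grid is not uniform
in reality; it is approximated by a uniform 1.928 cm⁻¹ grid over
2920–0 cm⁻¹.

## The fermentation timeline as a parametric model

`composition_trajectory()` encodes the qualitative carbon-utilisation
narrative as smooth parametric rules; every rate constant lives in
`trajectory_params()` and can be overridden. The defaults express:

* protein and carbohydrate (from the ¹²C yeast extract) dominate the first
  8 h; storage metabolites are zero at inoculation;
* carotenoids pulse at 8–14 h and decline as lipogenesis redirects
  acetyl-CoA; under ¹³C glucose with a large glycerol surplus their ¹³C
  fraction is drawn per sample from a uniform continuum (0.15–0.85),
  reproducing the observed 1525–1490 cm⁻¹ peak-position spread;
* TAG capacity saturates in glucose concentration
  (\(A\,G/(G+K)\), K = 10 g/L); scarce glucose (≤ 10 g/L) is exhausted at
  ~24 h, after which that lipid pool decays; glycerol-driven lipogenesis
  starts at ~36 h and only under a large glycerol surplus (≥ 30 g/L)
  alongside some glucose; glycerol-only cultures accumulate a negligible
  TAG amount;
* polyphosphates rise and then decline, peaking at 24 h on glycerol-only
  medium and at 60 h under a glycerol surplus; glucose-rich cultures
  accumulate polyphosphate to the end of the run. (The latter choice
  follows the observed band trajectories for the glucose controls; the
  peak times are parameters.)

The ¹²C/¹³C TAG pools are tracked separately, so the generator's isotope
fraction is available as ground truth for the estimator-recovery tests. A
small residual ¹²C lipid pool (0.005 relative weight) represents yeast
extract carbon; it keeps the ¹³C fraction of glucose-only ¹³C cultures
just below 1, as observed for protein signals.

What the generator does **not** emulate: Mie-type resonant scattering
(no physically modelled scatter artefacts beyond the sigmoid surrogate),
resonance-Raman cross sections (the 785 vs 1064 nm carotenoid enhancement
is a flat ×5 intensity multiplier), detector nonlinearity, wavenumber
miscalibration, and biological replicate variance. Passing tests therefore
demonstrate the correctness of the *computational chain*, not robustness
to every instrumental artefact of real measurements.

## Preprocessing

All primitives are deterministic; the seven packaged recipes apply them in
their printed order (see `packaged_recipes()`). Numerical choices:

* **Savitzky–Golay**: local least-squares polynomial filtering.
  Differentiation is with respect to the *point index* (the convention of
  vendor chemometrics software); per-cm⁻¹ units would require an extra
  \((1/\Delta\nu)^d\) factor, which cancels out of every downstream
  relative quantity. Edge points evaluate the first/last full-window fit
  at the edge offsets, so output length equals input length. On
  second-derivative spectra band maxima appear as *negative* minima; all
  band metrics follow that sign convention.
* **Rubberband**: the baseline is the lower convex hull of
  \((\nu, y)\) (monotone-chain construction), linearly interpolated
  between hull vertices. The corrected spectrum is nonnegative up to
  round-off and invariant to adding any affine function.
* **Polynomial baseline** (Raman imaging): iterative re-fitting that
  excludes points above the current fit (≤ 20 passes, until the retained
  set stabilises), so peaks do not drag the baseline upward. The degree
  (default 3) is a parameter; the procedure name alone was published.
* **MSC / EMSC**: least-squares against a reference spectrum (dataset mean
  unless stated). The EMSC polynomial part uses monomials of the axis
  mapped affinely to \([-1, 1]\); degree 2 for the FTIR-microscopy
  variant (reference = mean of all block spectra), degree 3 for the
  FT-Raman PLSR recipe.
* **Cosmic-ray removal**: spikes are flagged on the second-difference
  signal by a median/MAD modified z-score (threshold 8) *and* a relative
  height floor (1% of the intensity range), then replaced by linear
  interpolation of the nearest unflagged neighbours, at most two passes.
  The criterion assumes a visible noise floor; in strictly noiseless
  synthetic spectra the MAD collapses and sharp band curvature could be
  flagged without the floor. Both parameters are exposed.
* Recipes demand raw input (derivative order 0); re-applying a derivative
  recipe raises rather than silently double-differentiating.

## Band metrics

Marker intensities are window extrema (minimum of the second derivative
within ±4 cm⁻¹ of the target), not point reads — robust to grid offsets
and to the few-cm⁻¹ discrepancies between assignment-table and
figure-convention positions (1745/1746, 1701/1700, 1268/1263, 1523/1525).
Peak positions are refined by a three-point parabolic fit, giving
sub-0.1 cm⁻¹ accuracy on the 1.928 cm⁻¹ grid for isolated bands. The
isotope fraction estimator \(|i_{13}|/(|i_{12}|+|i_{13}|)\) is exact at
the endpoints for two-band components and recovers the generator's
\(f^{13}\) with bias well below 0.1 at the default noise level.
Trajectories are *relative* intensities; no absolute concentrations are
claimed without a calibration model.

## Multivariate models

* **PCA**: column-mean-centred SVD (no variable scaling — standard for
  derivative spectra). Signs are fixed by making each component's
  largest-magnitude loading positive, so plots reproduce across
  platforms.
* **Consensus PCA**: each centred block is divided by its Frobenius norm
  and the global solution is the PCA of the concatenated scaled
  super-matrix — the deterministic member of the consensus/hierarchical
  PCA family, chosen over NIPALS iteration for exact reproducibility and
  an explicit SVD oracle. Block scores project each scaled block onto its
  renormalised loading sub-vectors; per-block explained variance of
  component k is \(100\, d_k^2 \lVert v_{bk}\rVert^2 / \lVert X_b
  \rVert_F^2\). With one block the model reduces exactly to PCA; global
  scores are invariant to rescaling any block.
* **Correlation loadings**: per-variable Pearson correlation with the
  global scores. The inner circle is drawn at \(r = \sqrt{0.5}\) (50%
  *explained variance*), the outer at 1; "50% correlation" is ambiguous
  and the radius is configurable.
* **PLSR**: NIPALS PLS1. The Q residual of a projected sample is the
  squared norm of its spectrum after deflation through the model
  loadings; samples above the 99th percentile of the training residuals
  are flagged as outside the calibration space. The synthetic calibration
  test checks prediction RMSE against an oracle given the generative
  model (ordinary least squares of the response on the spectra's
  projections onto the true component spectra, on a held-out split).

## Imaging

* **Pixel quality control**: a pixel is kept when its integrated absolute
  signal over a reference region (default 1700–1500 cm⁻¹) exceeds the
  integral of (channel median + 3 × channel MAD), with the channel
  statistics estimated from the lowest-decile pixels. Computing the
  threshold per channel rather than on the integrated-signal distribution
  makes the screen sharp: background pixels integrate |noise| ≈ 0.8σ per
  channel while the threshold sits at ≈ 1.25σ per channel, so background
  is removed near-completely, while any pixel with genuine biomass signal
  clears the threshold by an order of magnitude. A uniform noise-free
  image keeps all pixels (signal equals threshold); an all-zero image
  keeps none.
* **Binning**: full blocks (default 10×10 pixels) tile from the top-left
  corner; the remainder strip per axis forms the edge blocks, giving the
  10×8 / 8×10 / 8×8 inventory and 13 × 13 = 169 blocks for a fully valid
  128×128 image. Blocks with fewer than 5 valid pixels are dropped. The
  pixel-count-weighted mean of the block spectra equals the mean of all
  valid pixels exactly.
* **Basis analysis**: per-pixel least squares against up to four basis
  spectra, nonnegative by default (concentrations cannot be negative; the
  unconstrained vendor-style variant is selectable, as is an optional
  constant-offset column, off by default). The NNLS solver takes a
  vectorised fast path (unconstrained solutions that are already feasible
  are accepted) and falls back to an active-set solver per remaining
  pixel; it matches a subset-enumeration oracle to 10⁻⁸ on small
  instances. Basis spectra come from k-means centroids of area-normalised
  pixel spectra (seeded, deterministic) or from caller-picked pixels.

## Problem sizes and reproducibility

The packaged tests and the acceptance script run the full 7-media ×
6-timepoint × 3-replicate bulk design (126 spectra per modality on the
native ~1900-point grids) and one 128×128 imaging scene on a 900–1900 cm⁻¹
sub-grid (260 channels; the full 767-channel cube is supported and simply
larger). Estimator-recovery studies use 20 replicates × 9 isotope levels
and a 60-sample PLSR calibration. A single run seed deterministically
derives all per-sample substreams; re-running any pipeline with the same
configuration and seed reproduces every output bit for bit.

## Known limitations

* The band table encodes only the isotope pairs that could be assigned
  unambiguously; the heavily overlapped C–H stretching/deformation
  multiplets are represented by a reduced set of pairs, and sub-10 cm⁻¹
  deformation shifts are omitted.
* Electromagnetic scatter correction for infrared microspectroscopy is
  performed by EMSC; no deep-learning scatter model is included.
* The carotenoid resonance enhancement is a scalar multiplier; no
  excitation-wavelength physics is modelled.
* Trajectory defaults are plausible parameterisations of qualitative
  dynamics, not fitted kinetics; conclusions about real fermentations
  require real spectra.
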