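# isoflux

Isotope-resolved vibrational spectroscopy chemometrics for tracking
carbon flux into microbial metabolites.

## What it is for

Fermentations on mixed carbon substrates (e.g. glucose plus waste
glycerol) raise a question chromatography answers only slowly and
destructively: *which* substrate ends up in *which* metabolite, and
*when*? Stable-isotope labelling plus vibrational spectroscopy answers it
spectrally. When biomass is built from ¹³C-labelled glucose, the heavier
carbon lowers vibrational frequencies and the infrared/Raman marker bands
shift red by tens of cm⁻¹. For an oleaginous, carotenogenic fungus the key
pairs (¹²C/¹³C, cm⁻¹) are:

| metabolite | modality | vibration | ¹²C | ¹³C |
|---|---|---|---|---|
| TAG lipid | FTIR | ester C=O stretch | 1745 | 1701 |
| TAG lipid | Raman | ester C=O stretch | 1747 | 1705 |
| carotenoid | Raman | −C=C− stretch | 1523 | 1490 |
| polyphosphate | FTIR | P=O stretch | 1268 | — (no carbon) |

Reading the paired band intensities over a fermentation time course gives
the carbon-source → metabolite timeline: lipid built from ¹³C glucose
appears at 1701 cm⁻¹, lipid built from unlabelled glycerol at 1745 cm⁻¹,
and a mixed-isotope carotenoid population slides continuously between
1523 and 1490 cm⁻¹.

`isoflux` is an R package for this whole measurement chain, aimed at
spectroscopists and bioprocess researchers:

* **synthetic data** — a forward simulator of bulk FTIR/FT-Raman spectra
  and 128×128 hyperspectral images with known composition, isotope
  fractions and spatial masks, emulating a 7-media × 6-timepoint ×
  3-replicate design (42 samples, 126 spectra per bulk modality, 16,384
  pixel spectra per image);
* **preprocessing** — Savitzky–Golay derivatives, rubberband / linear /
  iterative-polynomial baselines, MSC and EMSC, vector / area / band-area
  normalisation, cosmic-ray removal, packaged as the seven named
  per-modality recipes with their exact published parameters;
* **band metrics** — windowed second-derivative band intensities,
  parabola-refined peak positions, an isotope-fraction estimator
  |i₁₃|/(|i₁₂|+|i₁₃|), and tidy marker-band trajectory tables;
* **chemometrics** — PCA, multiblock consensus PCA (Frobenius-scaled
  super-matrix SVD with global and block scores, per-block explained
  variance, correlation loadings), and NIPALS PLS1 with Q-residual
  reliability flags;
* **imaging** — pixel quality control, 10×10 binning with edge blocks,
  nonnegative least-squares basis unmixing (k-means or manual basis),
  and single-wavenumber absorbance maps.

## Worked example

Simulate the full design, preprocess the infrared block with the
band-ratio recipe (truncate 1800–800 cm⁻¹, linear baseline, amide-I area
normalisation, 2nd-derivative Savitzky–Golay), and read the lipid and
polyphosphate markers for the medium with ¹³C glucose and a large
glycerol surplus:

```r
library(isoflux)

sim   <- simulate_design_dataset(default_design(), seed = 1)
ftir2 <- apply_recipe(sim$HTSFTIR, "htsftir_bandratio")
traj  <- aggregate_trajectories(metabolite_trajectories(ftir2))
wide  <- xtabs(intensity ~ timepoint_h + label,
               data = subset(traj, medium == "iGlu1:Gly7"))
round(wide * 1e4, 2)
#>            label
#> timepoint_h polyP TAG12 TAG13
#>         8   -0.10 -1.19 -0.06
#>         14  -4.14 -0.91 -2.94
#>         24  -6.75 -0.86 -6.07
#>         36  -8.75 -0.82 -3.14
#>         60  -8.90 -5.03 -0.85
#>         120 -1.26 -8.27 -0.53
```

Intensities are second-derivative minima: **more negative = stronger
band**. The table reads as a carbon-flux timeline: ¹³C lipid (TAG13, from
the scarce ¹³C glucose) rises by 14 h and collapses after the glucose is
exhausted; ¹²C lipid (TAG12, from glycerol) takes over after 36 h;
polyphosphate accumulates to ~60 h and is then spent. The isotope
fraction of the TAG pool at 60 h,

```r
isotope_fraction(wide["60", "TAG12"], wide["60", "TAG13"])
#> [1] 0.1445749
```

confirms the lipid is by then predominantly glycerol-derived.

Consensus PCA of the two (replicate-averaged) bulk blocks:

```r
blocks <- list(
  HTSFTIR = average_replicates(apply_recipe(sim$HTSFTIR, "htsftir_mva"))$intensity,
  FTRaman = average_replicates(apply_recipe(sim$FTRaman, "ftraman_mva"))$intensity)
cm <- cpca_fit(blocks, ncomp = 5)
round(cm$pct_variance_global, 2)
#> [1] 57.53 25.72 11.53  1.41  0.62
```

The global scores separate timepoints along one direction and ¹²C- vs
¹³C-glucose media along another; `correlation_loadings(cm, blocks)` maps
each wavenumber's correlation with those components (inner circle √0.5,
outer 1).

The whole chain — simulation, preprocessing, trajectories, CPCA, imaging
QC/binning/unmixing — runs from one seeded configuration:

```r
report <- run_pipeline(run_config(seed = 1, out_dir = "isoflux_run"))
```

A thin command-line wrapper is installed at
`inst/scripts/isoflux-pipeline.R`.

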