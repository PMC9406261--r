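# eosinQuant

Quantification of intravascular blood in H&E-stained tissue sections from
the red-shift of eosin Y fluorescence.

## The problem

Eosin Y, the counterstain in every H&E section, is fluorescent. Bound to
bulk tissue it emits green with a peak near **550 nm**; bound to
erythrocytes the emission red-shifts to a peak near **570 nm** and becomes
brighter, with individual red blood cells appearing as ~5 µm donut-shaped
objects. This spectral difference makes blood separable from tissue in any
standard fluorescence microscope with FITC (emission 520–540 nm) and TRITC
(emission 570–610 nm) filter sets — no extra staining required. The package
is aimed at histopathology image-analysis workflows that need an objective
blood-to-tissue area fraction from such two-channel images (for example to
score pulmonary haemorrhage), plus the lambda-stack spectral analysis that
underpins the approach.

## The method

Given co-registered FITC and TRITC images *F* and *T*:

1. min–max normalise each channel: *F′ = (F − min F)/(max F − min F)*,
   likewise *T′*;
2. mean image *M = (F′ + T′)/2*;
3. tissue mask = automatic threshold of *M* (Huang's fuzzy-entropy
   method);
4. blood-enhanced image *B = max(M − F′, 0) = max((T′ − F′)/2, 0)* — high
   exactly where the emission is red-shifted;
5. rolling-ball background subtraction of *B* (grey-scale opening with a
   disc, default radius 50 px);
6. blood mask = Huang threshold of the corrected image;
7. report **blood % = 100 · |blood mask| / |tissue mask|**.

The Huang threshold minimises the fuzzy entropy
*E(t) = (1/N) Σ<sub>g</sub> h(g) S(u<sub>t</sub>(g))* with membership
*u<sub>t</sub>(g) = 1/(1 + |g − μ<sub>class</sub>|/C)* and
*S(u) = −u ln u − (1−u) ln(1−u)*; it is implemented from that definition
and verified against an exhaustive brute-force minimiser.

Because no public reference images exist for this assay, the package ships
a first-class synthetic phantom generator: seeded fields with textured
tissue (peak 550 nm), donut-shaped erythrocytes (peak 570 nm, 2×
amplitude, 5 µm at 0.32 µm/px) inside vessel ellipses, a 480–690 nm lambda
stack at 10-nm steps, channels integrated through the FITC/TRITC
passbands, and exact ground-truth masks — so the whole pipeline can be
validated against known truth.

## Worked example

```r
library(eosinQuant)

# a synthetic field with known ground truth
ph <- renderPhantom(PhantomSpec(seed = 1, noise = noNoise()))
trueBloodPercent(ph)
#> [1] 11.5952

# spectral analysis: per-pixel peak wavelength
pm <- peakWavelengthMap(lambdaStack(ph))
table(pm@peak[bloodMask(ph)])        # blood pixels peak at 570 nm
#>  570
#> 5754

# the two-channel quantification pipeline
res <- quantifyBlood(channels(ph))
res
#> QuantResult
#>   tissue: threshold 0, area 49624 px (5081.50 um^2)
#>   blood:  threshold 0, area 5754 px (589.21 um^2)
#>   blood-to-tissue: 11.60%
```

The estimated 11.60% equals this phantom's ground truth exactly: on
noise-free phantoms the pipeline recovers the blood fraction essentially
exactly, and within ~1 percentage point under realistic shot and read
noise.

## Command line

```sh
inst/scripts/eosinquant simulate  --config spec.yaml --out sim/
inst/scripts/eosinquant spectra   --stack sim/stack.tif --out spectra/
inst/scripts/eosinquant quantify  --fitc f.tif --tritc t.tif \
    --pixel-size 0.32 --out quant/
inst/scripts/eosinquant threshold --input img.tif --out thr/
```

Every run writes a `manifest.json` (flags, package version, input MD5
checksums). `quantify --batch pairs.csv` processes many image pairs into
one `results.csv`; per-file failures are logged, not fatal.

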