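# octseg

Fully automated retinal segmentation and thickness quantification for
rodent spectral-domain OCT volumes, with a synthetic phantom generator that
makes the whole pipeline verifiable without animal imaging.

## Who this is for

Preclinical vision researchers measuring total retinal thickness
longitudinally in small rodents (for example in oxygen-induced retinopathy
studies), who export OCT volumes as image stacks and want an objective,
reproducible alternative to manual boundary tracing.

## The algorithm

Two boundaries are segmented sequentially in every A-scan of every B-scan,
with depth *z* in µm measured from the vitreous side of the frame:

1. **Sclera anchor** — the B-scan is blurred with a Gaussian filter
   (σ = 20 µm); the sclera, the brightest object in rodent B-scans, is
   localized as the absolute intensity maximum of each smoothed A-scan.
2. **Outer retinal boundary (ORL)** — on the axial intensity slope
   dI/dz (computed after σ = 2 µm smoothing), the first valley above the
   sclera centre marks the retina→choroid descent.
3. **Inner retinal boundary (IRL)** — the highest slope peak strictly more
   than 120 µm above the ORL marks the vitreoretinal interface.

Retinal thickness per A-scan is RT = z(ORL) − z(IRL). Per B-scan, the mean
and sample SD over A-scans give a percentage error 100·SD/mean; B-scans
above 25 % are discarded. The volume mean is the inverse-SD weighted
average of retained B-scan means,

    RT_volume = Σ (mean_i / SD_i) / Σ (1 / SD_i),

with the standard error among B-scans as its uncertainty. Group comparisons
use one-way ANOVA (α = 0.05) with Bonferroni post hoc pairwise tests.

All constants are physical (µm) and converted to pixels through mandatory
spacing metadata, so the method is resolution-independent. See the methods
vignette (`vignettes/segmentation-methods.Rmd`) for design choices, the
phantom noise model and known limitations.

## Worked example

```r
library(octseg)

spec <- phantom_spec(seed = 42)    # 7 B-scans x 768 A-scans, 240 um apart,
                                   # true thickness 200 um, 14% speckle
gen <- generate_volume(spec)
ana <- analyze_volume(gen$volume)

ana$volume
#> Volume thickness: 199.63 um (SE 0.05 um, 7 B-scans retained)

head(ana$bscans[, c("index", "n_valid", "mean_um", "sd_um", "pct_error", "retained")], 3)
#>   index n_valid  mean_um    sd_um pct_error retained
#> 1     1     768 199.4411 2.039646 1.0226812     TRUE
#> 2     2     768 199.8240 1.967207 0.9844695     TRUE
#> 3     3     768 199.6477 1.915879 0.9596302     TRUE
```

The weighted volume mean recovers the 200 µm ground truth to a fraction of
an axial pixel (3.87 µm) despite the speckle; every B-scan's coefficient of
variation (~1 %) is far below the 25 % discard threshold, so all seven are
retained.

Real volumes load from multi-page TIFF (or PNG-stack directories) plus a
JSON sidecar with `axial_um_per_px`, `lateral_um_per_px` and
`bscan_spacing_um`:

```r
vol <- load_volume("rat01_P30.tif", sidecar = "rat01_P30.json")
ana <- analyze_volume(vol)
write_results(vol, ana$traces, ana$bscans, ana$volume, "out/rat01_P30")
```

which writes per-A-scan boundary CSVs, per-B-scan summaries, a volume
summary JSON and overlay PNGs with the IRL/ORL/sclera curves drawn on each
B-scan.

## Command line

A thin CLI over the same functions lives at `inst/cli/octseg`:

```sh
octseg=$(Rscript -e 'cat(system.file("cli", "octseg", package = "octseg"))')
Rscript "$octseg" simulate --outdir data/phantom --seed 1
Rscript "$octseg" segment --input data/phantom/phantom.tif --outdir out \
        --pct-error-threshold 25
Rscript "$octseg" compare --table thickness_by_group.csv --outdir stats
```

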