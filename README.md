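# mpmquant

Automated quantification of label-free multiphoton microscopy images of
tissue sections, for imaging groups and computational pathologists assessing
treatment response. Two co-registered channels are analyzed:

* **TPAF** (two-photon autofluorescence): cells are bright, nuclei are
  signal-void dark ellipses. `mpmquant` segments nuclei with a **spatially
  constrained watershed superpixel (SWS)** algorithm — a marker watershed on
  the relief `g(p) + λ·(2/s)·d(p, nearest seed)`, where `g` is the Sobel
  gradient magnitude of the preprocessed image (histogram equalization,
  Gaussian smoothing, opening-by-reconstruction), `d` the distance to the
  nearest seed of a square grid with spacing `s`, and `λ` a compactness
  weight. Superpixels are classified dark/bright by Otsu's criterion on
  their mean intensities; adjacent dark superpixels merge into nuclei and
  **nuclear area** is the pixel count (px²).
* **SHG** (second-harmonic generation): only fibrillar collagen produces
  signal. `mpmquant` binarizes the channel with **robust automatic threshold
  selection (RATS)**: per quadtree leaf, the threshold is the
  gradient-weighted mean intensity `T = Σ w·I / Σ w` with
  `w = max(g − λσ̂, 0)²`, interpolated into a per-pixel threshold map.
  **Collagen content** is the percentage of foreground pixels in the region
  of interest.

Groups (pre- vs post-treatment) are compared per metric with a two-sample
*t*-test (pooled by default, Welch available) at α = 0.05, from either raw
per-sample values or published summary statistics (mean ± SD, n).

A seeded phantom generator produces TPAF/SHG image pairs and whole two-arm
cohorts with exact ground truth (nucleus label masks, collagen masks), so
the entire pipeline is testable without any real data.

## Worked example

```r
library(mpmquant)

# a synthetic TPAF field: 8 dark nuclei of ~700 px^2 in bright cytoplasm
ph  <- generate_tpaf(n_nuclei = 8, nucleus_area_mean_px2 = 700, seed = 42)
seg <- segment_nuclei(ph$image)
seg
#> <nucleus_segmentation> 256 x 256 px, 484 superpixels, 8 nuclei, mean area 736.9 px^2
glance(seg)
#> # A tibble: 1 × 4
#>   n_superpixels n_nuclei mean_area_px2 sd_area_px2
#>           <int>    <int>         <dbl>       <dbl>
#> 1           484        8          737.        67.8

head(tidy(seg), 3)   # one row per nucleus
#>   nucleus_id area_px2 centroid_row centroid_col mean_intensity
#>        <int>    <int>        <dbl>        <dbl>          <dbl>
#> 1          1      841        166.          58.5           18.0
#> 2          2      726         19.6         64             18.6
#> 3          3      730        102.         115.            18.2

# a synthetic SHG field at 30% collagen, quantified by RATS
sh  <- generate_shg(target_collagen_fraction_pct = 30, seed = 42)
quantify_collagen(sh$image)
#> <collagen_result> 30.00% collagen over 65536 ROI pixels
```

The mean measured area (736.9 px²) tracks the generator's per-nucleus truth
(the phantom drew nuclei around 700 px²; the label-mask truth for this seed
averages 740 px²), and the measured collagen content reproduces the
ground-truth mask fraction to a hundredth of a percentage point.

Group statistics work directly from summary statistics, e.g. for nuclear
area in a 30 + 30 cohort reported as 596.56 ± 208.69 px² before and
856.22 ± 255.74 px² after therapy:

```r
pre  <- tibble::tibble(group = "pre",  metric = "nuclear_area_px2",
                       n = 30L, mean = 596.56, sd = 208.69)
post <- tibble::tibble(group = "post", metric = "nuclear_area_px2",
                       n = 30L, mean = 856.22, sd = 255.74)
t_test_from_summary(pre, post)
#> Two-sample t-test (pooled): t = 4.3087, df = 58, p = 6.43e-05 (significant at alpha = 0.05)
```

An entire study is one call: `run_pipeline()` simulates (or reads) a cohort,
runs both branches per sample, and writes per-nucleus, per-sample, per-group
and comparison tables plus a JSON run report:

```r
run <- run_pipeline(list(output_dir = "outputs/demo", seed = 1))
run$comparison
```

A thin command-line front end with `simulate` / `analyze` / `stats`
subcommands is installed at `inst/cli/mpmquant.R`.

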