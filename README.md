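# mrordenoise

Removal of impulse noise from 8-bit grayscale mammograms (and similar
images) by a switching pipeline: a robust statistical detector decides
*which* pixels are corrupted, and restoration touches *only* those pixels,
so clean pixels — including the microcalcification-like specks that
computer-aided detection depends on — pass through bit-identical. The
package is aimed at mammography preprocessing work, but nothing in it is
specific to breasts: any 8-bit image corrupted by salt-and-pepper or
random-valued impulses is fair game.

## Method

For each pixel $x_{ij}$, over its $5\times5$ window $y$:

$$\mathrm{AMED} = \operatorname{med}(y), \qquad
  \mathrm{AMAD} = \operatorname{med}\left(|y - \mathrm{AMED}|\right), \qquad
  \mathrm{NAMAD} = \mathrm{AMAD} / 0.6457,$$

$$\mathrm{mROR}_{ij} = \frac{|x_{ij} - \mathrm{AMED}_{ij}|}
                            {\max(\mathrm{NAMAD}_{ij},\ \epsilon)}.$$

The modified robust outlyingness ratio mROR grades how impulse-like each
pixel is; pixels are partitioned into four clusters (mROR $>3$, $2$–$3$,
$1$–$2$, $\le 1$), each with its own decision threshold on
$|x - \mathrm{AMED}|$. Detection iterates in a coarse stage (larger
thresholds, up to 4 passes) then a fine stage (smaller thresholds, up to 2
passes); after every pass, newly flagged pixels are restored by an adaptive
fuzzy median filter (growing-window median with triangular fuzzy weighting
of clean neighbours) and the statistics are recomputed on the restored
image. Finally, a mask-restricted non-local means filter re-restores the
flagged pixels of the original image, using the cascade's restored image as
its reference: weights $e^{-d(p,q)/h^2}$ with mask-aware patch distances
$d$, so the result is a convex combination of clean reference intensities.
Quality is scored by $\mathrm{MSE}$ and
$\mathrm{PSNR} = 10\log_{10}(255^2/\mathrm{MSE})$ dB.

The package also provides the impulse-noise simulator (with ground-truth
masks), a seeded mammogram-like phantom generator so everything runs
offline, standard/adaptive median baselines, and a benchmark harness that
returns tidy tibbles and ggplot figures.

## Worked example

```r
library(mrordenoise)

clean <- make_phantom(phantom_spec(seed = 8))            # 256 x 256 phantom
noisy <- corrupt(clean, noise_spec("random_valued", p = 0.2, seed = 3))

det <- denoise(noisy$image, return_details = TRUE)
glance(det$detection)
#> # A tibble: 1 × 4
#>   n_flagged fraction_flagged n_flagged_coarse iterations_run
#>       <int>            <dbl>            <int>          <int>
#> 1     10777            0.164             8588              5

psnr(clean, noisy$image)   # 17.34 dB
psnr(clean, det$image)     # 38.33 dB
```

At 20% random-valued noise the cascade flags 16.4% of pixels (recall 0.81
against the ground-truth mask, false-positive rate 0.0004 — the impulses it
misses are those whose replacement landed too close to the true value to
matter), and restoration lifts PSNR from 17.3 to 38.3 dB. The
per-iteration trace shows the design working as intended — the first
coarse pass does the heavy lifting, later passes converge quickly:

```r
tidy(det$detection)
#> # A tibble: 5 × 4
#>   stage  iteration new_flags total_flags
#>   <chr>      <int>     <int>       <int>
#> 1 coarse         1      8580        8580
#> 2 coarse         2         8        8588
#> 3 coarse         3         0        8588
#> 4 fine           1      2188       10776
#> 5 fine           2         1       10777
```

Benchmarking against the baselines:

```r
res <- run_benchmark(phantom_spec(height = 128, width = 128, seed = 1),
                     ratios = c(0.1, 0.3, 0.5), seeds = 1:5)
summarize_benchmark(res)$psnr_table
plot_benchmark(res)
```

A command-line front end over the same functions lives in
`inst/cli/mrordenoise.R` (subcommands `simulate`, `stats`, `detect`, `afm`,
`denoise`, `baseline`, `benchmark`; YAML configuration per `?read_config`).

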