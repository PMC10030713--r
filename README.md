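# ecgtda — topological quality assessment of ambulatory ECG signals

Wearable ECG monitors produce 10-second segments that are frequently
contaminated by baseline wander, electrode motion, muscle artifact or
broadband noise. Before any rhythm analysis, each segment has to be sorted
into **acceptable** vs **unacceptable**. `ecgtda` makes that decision with
topological data analysis: it summarises each segment by its persistent
homology, renders the summary as a deterministic image, and classifies the
images under stratified 10-fold cross-validation.

The package is aimed at biomedical-signal researchers who want a fully
reproducible, dependency-light reference implementation of the
TDA-for-signal-quality pipeline, including a synthetic data factory that
replaces the usual PhysioNet downloads.

## The method in brief

* **Delay embedding.** A segment $x_1,\dots,x_n$ becomes a point cloud of
  $t$ points in $\mathbb{R}^d$, $d = \lfloor n/t\rfloor$, with point
  $p_j = (x_j, x_{j+t}, \dots, x_{j+(d-1)t})$ and $t$ the sliding-window
  length in samples. For 10-s, 500-Hz records: $d$ = 100/50/33/25/20 for
  0.1–0.5-s windows; 12-lead clouds concatenate per-lead coordinates
  ($12 \times 10 = 120$ at 1 s).
* **Vietoris–Rips persistence** of the cloud (H0 via minimum spanning
  tree, H1 via boundary-matrix reduction over $\mathbb{F}_2$), in
  distance (ball-diameter) units.
* **Sublevel-set persistence** of the raw waveform: components born at
  local minima, merged at local maxima under the elder rule; exactly one
  infinite bar per segment (the global minimum).
* **Rendering**: 224 × 224 × 3 barcode or diagram rasters, H0 blue,
  H1 red, byte-deterministic PNG output.
* **Classification**: a CPU-scale convolutional baseline (fixed random
  filters + trained ridge-logistic head) or a linear pixel baseline;
  metrics Se, Sp, F1, Acc and mAcc = (Se + Sp)/2, the headline score for
  imbalanced corpora.
* **Synthetic data**: sum-of-Gaussians P-QRS-T beats with jittered RR
  intervals, plus four contaminant classes (`bw`, `em`, `ma`,
  `gaussian`) mixed at an exact segment-level SNR (default −10 dB), with
  corpus assembly (empty-lead screening, 2:2:2:1 noise allocation by
  largest remainder) mirroring the published construction counts.

## Worked example

```r
library(ecgtda)
cfg <- run_config(mode = "single_lead", filtration = "sls",
                  n_clean = 100, k = 10, seed = 1)
report <- run_pipeline(cfg)
print(report$metrics)
#> <cv_result: 10-fold, backend baseline_cnn>
#>   Se   100.00 +/- 0.00
#>   Sp   100.00 +/- 0.00
#>   F1   100.00 +/- 0.00
#>   Acc  100.00 +/- 0.00
#>   mAcc 100.00 +/- 0.00
```

This simulates 100 clean 10-s segments plus 100 copies corrupted at
−10 dB, computes sublevel-set diagrams, renders them, and cross-validates
the baseline classifier (about 17 s on one CPU). At −10 dB the corruption
is drastic — noise carries ten times the signal power — so clean vs
corrupted separates perfectly; the interesting science is in how the
margin shrinks as the SNR rises.

Smaller building blocks:

```r
sls_persistence(c(2, 0, 1, -1, 3))
#>   dimension birth death
#> 1         0    -1   Inf
#> 2         0     0     1

sq <- matrix(c(0,0, 1,0, 1,1, 0,1), ncol = 2, byrow = TRUE)
vr_persistence(sq)          # unit square: the loop is born at 1,
#>   dimension birth    death     dies at sqrt(2)
#> 1         0     0 1.000000
#> 2         0     0 1.000000
#> 3         0     0 1.000000
#> 4         0     0      Inf
#> 5         1     1 1.414214

embedding_dimension(10, 500, 0.3, 1)   # 33
embedding_dimension(10, 500, 1, 12)    # 120
```

## Command line

```sh
inst/cli/ecgtda simulate --out-dir work/sim --n-clean 50 --seed 1
inst/cli/ecgtda persist  --in work/sim/synth0001.csv --filtration sls \
                         --out work/synth0001_sls.csv
inst/cli/ecgtda render   --in work/synth0001_sls.csv --kind diagram \
                         --out work/synth0001_sls.png
inst/cli/ecgtda run-all  --config cfg.json --out-dir work/run
```

Exit codes: 0 success, 2 configuration error, 3 data error.

## Documentation

The methods vignette (`vignettes/ecg-quality-tda.Rmd`) documents the
model, every numerical convention (tie-breaks, plateau handling, scale
caps), what the synthetic generator does and does not emulate, and the
package's known limitations.
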