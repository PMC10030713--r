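---
title: "Topological quality assessment of ambulatory ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological quality assessment of ambulatory ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgtda)
```

## The problem

Wearable ECG monitors record continuously under everyday conditions, so a
large share of 10-second segments is contaminated — by baseline wander
(respiration, electrode drift), electrode-motion artifact, muscle (EMG)
noise, or broadband interference — to the point of being useless for
downstream rhythm analysis. Automated quality assessment sorts segments
into *acceptable* and *unacceptable* before any diagnostic algorithm sees
them.

`ecgtda` implements a topological approach to this binary decision. Rather
than engineering waveform or spectral quality indices, each segment is
summarised by its persistent homology — a multiscale census of connected
components and loops — rendered as a fixed-size image, and handed to an
image classifier under 10-fold cross-validation.

## The model

### Sliding-window point cloud

A single-lead segment $x_1,\dots,x_n$ (here $n = 5000$: 10 s at 500 Hz) is
folded into a point cloud by the sliding-window (delay) map with window
length $t$ samples and ambient dimension $d = \lfloor n/t \rfloor$: point
$j \in \{1,\dots,t\}$ is

$$p_j = (x_j,\, x_{j+t},\, \dots,\, x_{j+(d-1)t}) \in \mathbb{R}^d ,$$

i.e. the segment is cut into $d$ consecutive windows and window $i$
supplies coordinate $i$. Trailing samples beyond $d\,t$ are discarded, and
a segment shorter than one window is rejected. A quasi-periodic clean ECG
traces a tight loop-like structure in $\mathbb{R}^d$; noise disperses it.
For 10-s, 500-Hz records this yields per-lead dimensions 100/50/33/25/20
for 0.1–0.5 s windows, and 12-lead clouds are formed by coordinate-wise
concatenation of the per-lead clouds (1-s window: $12 \times 10 = 120$).

The matrix of lagged samples can be read in two orientations; we take the
one under which all printed dimension grids and a 3-s/1-s example living in
$\mathbb{R}^3$ are simultaneously consistent: $t$ points in $\mathbb{R}^d$
with lag $t$. No Takens-style lag or dimension optimisation is attempted —
the window length is the single tunable, swept over a fixed grid.

### Vietoris–Rips persistence

On the cloud we build the Vietoris–Rips filtration: every vertex at scale
0, an edge when its endpoint distance is at most the scale, a triangle when
its three edges are present (entering at its longest edge). Filtration
values are kept in *distance* (ball-diameter) units throughout; a
ball-radius reading is distance/2. Homology is computed over
$\mathbb{F}_2$ by the standard left-to-right column reduction of the
boundary matrix, with two fast paths:

* H0 deaths are exactly the minimum-spanning-tree edge weights (Prim), and
* H1 reduces triangle columns against the edge basis only.

Both paths are cross-checked in the test suite against an independent
brute-force reduction of the full, unoptimised boundary matrix on hundreds
of small random clouds, and H0 against an external MST (igraph/Kruskal).
Ties in the filtration order are broken by (value, dimension, lexicographic
vertex tuple), so diagrams are deterministic. Homology above dimension 1,
and Čech/alpha/witness complexes, are out of scope.

The default scale cap is the cloud diameter for clouds of at most 200
points and the 90th percentile of pairwise distances for larger clouds:
triangle enumeration is cubic, and an uncapped 500-point cloud (12-lead,
1-s window) enumerates millions of triangles. Full-scale 12-lead VR runs
are therefore minutes-per-record; the grids that matter for single-lead
work (≤ 150 points) run in fractions of a second.

### Sublevel-set persistence

The second summary skips the embedding entirely: the segment's graph is
filtered by amplitude, $f_\alpha = \{ i : x_i \le \alpha \}$ on the path
graph. Sweeping $\alpha$ upward, a component is born at each local
minimum and two components merge at a local maximum, where the *elder
rule* kills the younger (higher-birth) component; the global minimum's
component never dies, so every series has exactly one infinite bar.
Numerical conventions, fixed once:

* plateaus (equal consecutive values) are collapsed to a single node
  before the sweep;
* ties between distinct minima at equal level are broken by position —
  the leftmost is the elder;
* a boundary sample counts as a minimum iff it is smaller than its single
  neighbour;
* zero-persistence pairs are dropped from diagrams (they are retained,
  flagged, inside the raw reduction output).

The implementation is a sorted union-find sweep (C++); the tests compare
it against an independent oracle that recomputes path-graph components
from scratch at every threshold on hundreds of random series.

### Images and classification

Diagrams become deterministic 224 × 224 × 3 rasters: barcodes (one
horizontal bar per pair, H0 blue, H1 red, white background) for the VR
path, birth–death scatters with a diagonal and a top gutter for infinite
deaths for the sublevel path. Classifier-bound images carry no axes or
text, so pixel content is a pure function of diagram geometry; the
abscissa range is fixed *per dataset* (the global range across all
diagrams of a run) so that bar positions are comparable between records —
per-image autoscaling would leak amplitude information inconsistently.
PNG output is byte-deterministic (fixed filter, fixed zlib settings,
hand-rolled writer with no timestamps).

The reference classifier in the original design is a fine-tuned GoogLeNet;
its value there is transfer-learned image recognition, not topology. This
package's default backend, `baseline_cnn`, is deliberately lighter: one
convolution layer of eight fixed, seed-determined random 5×5×3 filters
(ReLU, mean-pooled) on 64×64 downsampled images, with a trained
ridge-penalised logistic head (IRLS; the dual/Woodbury update when
features outnumber observations). Random convolutional features with a
trained linear head are a standard CPU-scale baseline; the choice keeps
training deterministic and in seconds on one core, which a backpropagated
deep network in plain R would not be. `linear_pixels` (ridge logistic on
raw downsampled pixels) is the sanity baseline, and `googlenet_transfer`
is an adapter stub that errors with guidance, since pretrained weights are
not shipped. Evaluation uses stratified 10-fold cross-validation and
reports sensitivity, specificity, F1, accuracy and the balanced accuracy
mAcc = (Se + Sp)/2 — the headline metric because the corpora are
class-imbalanced. The positive class is *acceptable* throughout.

## The synthetic data factory

Real corpora behind this problem (the PhysioNet/CinC 2011 challenge set,
the MIT-BIH noise stress test recordings) are downloads; the package ships
a generator instead, and the tests state explicitly what it does and does
not emulate.

* **Clean ECG**: sum-of-Gaussians P-QRS-T morphology per beat (amplitudes
  0.12/−0.12/1.1/−0.25/0.35 mV), RR intervals jittered at 3% relative SD
  around the nominal heart rate, random phase. This reproduces
  quasi-periodicity, realistic peak geometry and rate variability — not
  ECGSYN-grade dynamics, patient variability, or lead-field physics.
* **Contaminants**: `bw` — random-phase sinusoids below 0.5 Hz plus a slow
  random walk; `ma` — white noise FFT-masked to 5–100 Hz; `em` — a bw
  component plus an ma component plus sparse electrode steps/spikes;
  `gaussian` — white noise. Spectrally these match the nominal character
  of the real noise records, not their measured spectra.
* **Mixing**: `mix_at_snr()` scales the noise so that the segment-level
  power ratio `10 log10(P_clean / P_noise_added)` equals the requested SNR
  exactly; the default −10 dB puts ten times the signal's power into the
  noise. "SNR of the noise" is read as this segment-level mixing SNR.
* **Corpus assembly**: `build_dataset()` screens unacceptable inputs for
  empty leads, then corrupts a planned subset of the clean pool — one
  noise kind per record, apportioned 2:2:2:1 (bw:em:ma:gaussian) by
  largest-remainder — and relabels the corrupted *copies* unacceptable.
  Copies (rather than replacement) are the only reading under which the
  reference corpus's final class sizes (9,941 acceptable and 8,870 = 988 +
  7,882 unacceptable) are simultaneously attainable, so that is the
  behaviour implemented; the conservation law is
  `n_in + n_corrupted = n_manifest + n_removed`. The default number of
  corrupted copies is `n_clean − n_unacceptable_in`, which reproduces the
  reference 7,882 from 9,941/2,059; the true selection rule behind that
  count is not documented anywhere, so the parameter stays explicit.

A green end-to-end test on this stated world (200 clean + 200 corrupted at
−10 dB, sublevel path, baseline backend, 10-fold CV, mean mAcc ≥ 90%)
establishes that the pipeline separates drastically corrupted from clean
synthetic segments — it does **not** establish the published real-data
accuracies, which depend on the real corpora, human relabelling, and
transfer-learned networks, and are explicitly out of scope.

## Empty-lead detection

The reference corpus screens out 1,071 "empty" single-lead segments
without stating the criterion, so exact reproduction is impossible. The
rule here: a lead is empty when its longest run of consecutive samples
lying within `eps` of some constant covers ≥ 95% of the lead, with
`eps = 1e-4 ×` the lead's amplitude range (absolute 1e-6 mV for degenerate
leads). A monotone-deque two-pointer sweep finds the run in O(n). The
range-relative tolerance makes the detector invariant to DC offset and
catches saturated (railed) leads as well as flat lines.

## Normalization

Per lead, `mapminmax_normalize()` applies the affine map onto [−1, 1]:
$y = (y_{max}-y_{min})(x - x_{min})/(x_{max}-x_{min}) + y_{min}$.
Constant input raises an error (zero denominator) rather than returning a
convention value. Normalization happens after segmentation and before
embedding, so clouds of $x$ and $a x + b$ ($a > 0$) are identical — a
property the tests check both with and without normalization.

## Numerical and design choices

* **Coefficient field**: $\mathbb{F}_2$ (standard for persistence).
* **Seeds**: one run seed; every stage derives child seeds through a fixed
  affine map into `[0, 2^31)`, and all generation restores the caller's
  RNG state. Rerunning a config reproduces metrics and manifests bit for
  bit.
* **Window arithmetic**: `t = round(window_seconds × fs)`,
  `d = floor(n/t)`. A published per-lead value inconsistent with this
  formula (120 for a 0.1-s 12-lead window, against 1,200/12 = 100) is
  treated as the typo it appears to be, as is a "0 s" window in a
  published grid.
* **CLI**: subcommands `simulate`, `embed`, `persist`, `render`,
  `evaluate`, `run-all` over a file protocol (CSV records, CSV diagrams
  with JSON sidecars, PNG images, JSON metrics); exit codes 0/2/3 for
  success/config error/data error. A standalone `train` subcommand was
  deliberately not exposed: serialising model handles to files added a
  format without adding capability at this scale — training is reachable
  through `run-all` and the R API.

## Known limitations

* Full-scale 12-lead VR (1-s windows, 500-point clouds) is minutes per
  record under the exact reduction; use shorter segments, longer windows,
  or a lower `max_scale` cap.
* The clean-ECG generator does not model pathology; "acceptable" here
  means clean morphology, not clinical normality.
* `googlenet_transfer` requires weights and a runtime not shipped here.
* Real-data headline accuracies are not reproduced by design; see the
  scaled-down end-to-end bar above for what the tests do establish.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- run_config(mode = "single_lead", filtration = "sls",
                  n_clean = 100, k = 10, seed = 1)
report <- run_pipeline(cfg)
print(report$metrics)
```

See the README for the output of this exact run.
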