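# nvcouple

Data-driven modeling of **neurovascular coupling** — the relationship
between electrical cortical activity and the local hemodynamic response —
from simultaneously acquired EEG and NIRS recordings, aimed at
neuroimaging researchers working with multimodal EEG–fNIRS systems.

The electrical input is the EEG *spectral envelope* g(t): the Hilbert
amplitude of the first intrinsic mode function (EMD) of mu-band (8–13 Hz)
EEG, which desynchronizes during median nerve stimulation. The vascular
output is the oxy-hemoglobin concentration change ΔHbO f(t) computed from
four-wavelength NIRS intensities by the modified Beer–Lambert law. The two
are linked per stimulus epoch through a gamma transfer function

    f(t) = a (g ∗ h)(t; τ, n, d) + b,
    h(t) = ((t−d)/τ)^(n−1) exp(−(t−d)/τ) / (τ (n−1)!)   for t ≥ d,

with peak-time constant τ, integer shape n, pure delay d, gain a and
offset b. Parameters are estimated per epoch in two steps — a brute-force
grid search (τ 0.1–0.6 s, n 1–4, d 0.5–3 s) with least-squares gain/offset,
then joint Nelder–Mead refinement of (τ, n, d, a, b) on the residual sum of
squares. The recovered 5-dimensional parameter vectors are standardized,
clustered with Ward linkage, and each cluster is tested for predictive
significance via Fisher-Z statistics, z\* = √n·z̄, against
Bonferroni-corrected two-sided normal thresholds across dendrogram
divisions C_N = 2…12. The division with the most significant clusters
(largest on ties) is reported with per-cluster representative kernels.

A complete synthetic EEG-NIRS generator (9 Hz amplitude-modulated mu
carrier, eight 20 s desynchronization blocks, Kaiser-smoothed envelopes,
known gamma kernels, white and 0.5 Hz-modulated Gaussian noise titrated by
an amplitude ratio in dB) makes every stage testable without recorded
data.

## Worked example

```r
library(nvcouple)

# simulate the default validation dataset (known ground truth)
ds  <- simulate_dataset(sim_config(seed = 1))

# epochs for ground-truth kernel 1 (tau = 0.3 s, n = 2, d = 2 s), no noise
eps <- simulated_epochs(ds, set_idx = 1, ar_db = -Inf)
fit_epoch(eps[[1]])
#> <fit_result refined> tau=0.3000 n=2 d=2.0000 a=1.07 b=0 sse=0 r=1.0000

# the same epoch with noise at amplitude ratio 2.2 dB on both channels
fit_epoch(simulated_epochs(ds, 1, ar_db = 2.2)[[1]])
#> <fit_result refined> tau=0.5650 n=5 d=0.0000 a=1.281 b=-0.138 sse=1626 r=0.6149
```

The noise-free fit recovers the generating kernel exactly (r = 1, SSE at
machine precision; the gain absorbs the per-epoch standard-deviation
normalization). At 2.2 dB the correlation drops to ~0.6 — the noise
standard deviation is 10^(2.2/20) ~ 1.29 times the signal's, so even a
perfect predictor of the clean response would score r ~ 0.61 against the
noisy trace — and the kernel parameters of this single noisy epoch drift
(distinct kernels predict almost equally well under noise), which is
exactly why the method aggregates parameter vectors by clustering.

Clustering fitted parameter vectors (here: the noise-free fits of all five
ground-truth kernels):

```r
fits <- unlist(lapply(1:5, function(k)
  lapply(simulated_epochs(ds, k, -Inf), fit_epoch, grid = fit_grid())),
  recursive = FALSE)
tree   <- ward_linkage(build_features(fits))
report <- significance_scan(tree, sapply(fits, `[[`, "r"), n_range = 2:12)
report
#> <cluster_report>
#>  divisions scanned: 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12 
#>  significant clusters per division:
#>  2  3  4  5  6  7  8  9 10 11 12 
#>  2  3  4  5  6  7  8  9 10 11 12 
#>  optimal division: 12 
#>  note: P values are approximate
```

With noise-free fits every correlation is 1, so every cluster at every
division is significant and the profile saturates (the scan warns that
r = 1 is clamped before the Fisher transform). Recorded or noisy data
produce the interesting profiles, where C_S peaks at a few clusters and
decays as divisions outrun the structure; see the noise titration in
`run_simulation_study()`. P-values are approximate by construction and
flagged as such.

The full simulation recovery study (every kernel × amplitude ratio ×
epoch) is one call:

```r
study <- run_simulation_study(validate_config(list(seed = 1)))
head(study$r_vs_ar)   # mean r per kernel set and amplitude ratio
```

File-based inputs (delimited EEG table, four-wavelength NIRS intensity
table, events TSV) run through the full preprocessing stream with
`run_experimental_pipeline()`, or from the shell:

```sh
inst/cli/nvcouple simulate  --out sim_dir --seed 1
inst/cli/nvcouple study-exp --eeg eeg.csv --nirs nirs.csv \
    --events events.tsv --out results/
```

## Package layout

- `R/simulator.R` — synthetic EEG-NIRS generator with ground truth
- `R/filters.R`, `R/emd.R` — Butterworth/zero-phase filtering, EMD,
  Hilbert envelopes, resampling
- `R/preprocess.R` — Chauvenet rejection, Beer–Lambert oximetry,
  epoching, normalization, channel selection
- `R/nvc_model.R` — gamma kernels, forward model, two-step estimator
- `R/cluster_stats.R` — feature standardization, Ward clustering,
  Fisher-Z significance scan, representative kernels
- `R/pipeline.R`, `R/io.R`, `R/cli.R` — orchestration, file formats, CLI
- `vignettes/neurovascular-coupling.Rmd` — the methods notes: model,
  assumptions, synthetic world, numerical choices, limitations
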