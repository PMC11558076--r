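# traceimpute

Chromatin tracing (multiplexed DNA FISH) measures the 3D positions of many
genomic loci in single cells, but 50–90% of probes routinely go undetected,
which cripples downstream analyses such as cell-type clustering, compartment
calling and loop detection. `traceimpute` completes these traces by borrowing
information from three sources of increasing availability:

* **mode 1** — structurally similar traces within RNA-defined cell
  neighborhoods *plus* single-cell Hi-C contacts joined through an externally
  computed FISH↔Hi-C cell pairing;
* **mode 2** — structurally similar traces within RNA-defined neighborhoods;
* **mode 3** — structurally similar traces alone.

## Method

For one chromosome copy the trace is an *N* × 3 coordinate matrix *X*.
Spatial distances *D<sub>ij</sub>* are transformed into proximity scores with
a Gaussian kernel, *K<sub>ij</sub>* = exp(−*D<sub>ij</sub>*²/σ²), where σ is
the median observed distance. Structure similarity between copies is the RMSD
after orthogonal Procrustes superposition of the loci detected in both.

Missing entries of *K* are imputed per genomic-distance stratum *v*: the
observed entries, the *m*-neighbor average of similar traces (*K*<sub>nF</sub>)
and, in mode 1, the neighbor-averaged Hi-C contacts (*H*<sub>nH</sub>) are
each normalized to unit sum within the stratum, and weights (*a*, *b*) are
fitted by constrained least squares

> min<sub>a,b</sub> Σ<sub>observed</sub> (a·P<sub>nH</sub> + b·P<sub>nF</sub> − P<sub>FISH</sub>)²  s.t.  a ≥ w<sub>bound</sub>, b ≥ 0, a + b = 1,

with w<sub>bound</sub> = 0.4 inside the genomic range where Hi-C and FISH
rank-agree (selected by Spearman correlation) and 0 beyond; modes 2–3 fix
a = 0. The imputed normalized profile is rescaled by the estimated missing
stratum total and clipped to [0, 1]; observed entries are never changed.

Finally, coordinates of undetected loci are recovered by maximizing a Poisson
log-likelihood in which the scaled, rounded proximity scores act as contact
counts with rate λ<sub>ij</sub> = c·exp(−‖X<sub>i</sub>−X<sub>j</sub>‖²/σ²),
optimized by bounded L-BFGS-B with an analytic gradient, starting from the
linear-interpolation baseline and moving only the undetected loci.

## Worked example

Everything runs on synthetic multimodal bundles, so no downloads are needed:

```r
library(traceimpute)

cfg <- synth_config(cells_per_type = 6, hic_cells_per_type = 6,
                    n_loci = 20, seed = 9)
b   <- generate_multimodal(cfg)                   # traces + RNA + Hi-C + pairing
mk  <- mask_traces(b$traces, rates = 0.5, seed = 10)

fit <- trace_impute(mk$masked$rate_0.5, mode = 3, m_fish = 5, min_overlap = 4)
fit
#> Chromatin trace imputation, mode 3
#>   12 traces, sigma = 1.276 um
#>   mean missing pair fraction before imputation: 0.76

head(coef(fit), 3)
#>           trace v a         b n_obs n_miss  flag
#> 1 F1_001|chr1|0 1 0 1.0073084     6     13 FALSE
#> 2 F1_001|chr1|0 2 0 1.0001946     6     12 FALSE
#> 3 F1_001|chr1|0 3 0 0.9442978     4     13 FALSE

evaluate_imputation(b$truth[names(fit$traces)], fit$traces,
                    fit$scores, fit$sigma)
#>   mean_rmsd   mean_mse n_traces
#> 1  0.645371 0.07789895       12
```

`coef()` shows the per-stratum mixing weights (here `a = 0`: mode 3 uses no
Hi-C; `b ≈ 1`: the neighbor average is taken nearly at face value, with
`n_obs` observed pairs anchoring each stratum). The evaluation reports the
mean Procrustes RMSD (µm) between completed and ground-truth structures and
the mean squared error of the proximity matrices. The imputed matrices feed
the downstream analytics directly, e.g. `insulation_profile(fit$scores[[1]],
window = 5)` or `compartments(fit$scores[[1]])`.

At 50% missing loci, a masked benchmark on the default bundle (2 cell types ×
100 cells, 60 loci) gives mean RMSD ≈ 0.39 µm for imputation against ≈ 0.65 µm
for linear interpolation, with the gap widening to 80% missing.

A thin command-line wrapper with `synth`, `mask` and `run` subcommands lives
in `inst/cli/traceimpute.R`.

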