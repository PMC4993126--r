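# megscan

Estimation of head position — a non-linear forward-model parameter — from
non-stationary resting-state MEG data.

## The problem

MEG sensor data are a linear mixture of cortical dipole currents,
`Y = L(h) J + Ξ`, but the anatomical parameters `h` (here the three
head-position coordinates) enter the lead field `L` non-linearly.  If the
head position assumed during source reconstruction is wrong, every
downstream estimate inherits the error.  megscan recovers the position
from the data alone: it inverts the same recording under a grid of rigid
head displacements with a parametric empirical-Bayes (multiple sparse
priors) scheme and lets the variational free energy — a lower bound on the
log model evidence `ln p(Y | h)` — vote for the forward model that
generated the data.

Resting-state data are non-stationary, so a single data covariance mixes
source regimes.  The package segments the record before inversion, three
ways:

| scheme   | segmentation                                   | evidences per position |
|----------|------------------------------------------------|------------------------|
| `hmm_gs` | K-state Gaussian-emission HMM, Viterbi-decoded | K                      |
| `st_gs`  | K uniform consecutive time windows             | K                      |
| `gs`     | single pooled (stationary) covariance          | 1                      |

Per-segment free energies

`F = -T/2 tr(Δ⁻¹C) - T/2 ln|Δ| - CT/2 ln 2π - ½(μ-η)ᵀΩ⁻¹(μ-η) + ½ ln|ϒΩ⁻¹|`,

with model covariance `Δ = L Q Lᵀ + exp(λ_Ξ) I` and patch-based source
covariance `Q = Σ_p exp(λ_p) Q_p`, are summed per position (fixed
effects) and turned into a posterior probability map over displacements by
family-wise Bayesian model comparison.  The map's peak is the estimated
head position.

The package is self-contained: an analytic spherical-conductor MEG
forward model, a surrogate-cortex simulator of gated non-stationary
activity, Baum–Welch/Viterbi segmentation, covariance-component ReML with
greedy patch selection, and the displacement scan, all with plain-text
serialisation.  See the methods vignette
(`vignettes/megscan-methods.Rmd`) for the model details and design
rationale.

## Worked example

Simulate the study at desk scale (64 sensors, 162-vertex surrogate
cortex, 200 Hz × 75 s at 0 dB SNR), segment, and scan the x axis:

```r
library(megscan)

sim <- simulate_nonstationary_meg(seed = 1, n_channels = 64, n_vertices = 200)
K <- select_num_states(sim$data)        # singular-value elbow, capped at 10
hmm <- fit_hmm(sim$data, K, seed = 1, n_restarts = 2, n_pca = 20)
match_states(sim$truth_states, viterbi(hmm, sim$data))

fit <- headscan(sim$data, sim$space, sim$sensors,
                grid = build_grid("x", -30, 30, 5),
                hmm = hmm, seed = 1, n_patches = 64,
                control = greedy_control(top_m = 6, max_patches = 8))
summary(fit)
```

Output:

```
selected K: 5
  truth decoded correlation
1     1       3   0.9208885
2     2       4   0.9189021
3     3       5   0.8906262
4     4       2   0.8983323
5     5       1   0.9271077

Head-position scan over 13 positions, K = 5 segments
Peak displacement (mm):
       x y z
hmm_gs 0 0 0
st_gs  0 0 0
gs     0 0 0
95% probability-mass region size (positions):
hmm_gs  st_gs     gs
     1      1      1
```

The elbow of the covariance spectrum recovers the five gated confound
sources; the decoded state time courses correlate ~0.9 with the simulated
ones (≈0.95 at the full 274-channel scale); and all three segmentation
schemes place the head at the true position (0 mm offset), with the
posterior mass concentrated on a single grid node.  `coef(fit)` returns
the peak displacements, `plot(fit)` draws the posterior curves, and
`map_estimate()` reconstructs source amplitudes at any fitted position.

A thin command-line front end ships in `inst/cli/megscan`
(`simulate`, `segment`, `invert`, `scan`, `run` subcommands over key=value
configs and TSV outputs), and `run_pipeline()` is the same entry point in
R.

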