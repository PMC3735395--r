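# clockns

Nested sampling for Bayesian evidence computation and parameter inference
in stochastic kinetic models, demonstrated end-to-end on a minimal model
of the *Neurospora crassa* circadian clock.

## What problem this solves, and for whom

Systems biologists fitting kinetic models to sparse molecular time series
usually get a point estimate and a goodness-of-fit.  This package computes
instead the **Bayesian evidence**

$$Z = \int L(\theta)\,\pi(\theta)\,d\theta,$$

together with full posterior moments for every parameter.  That buys two
things a point fit cannot give: a principled currency for choosing between
model variants (log Bayes factors), and a per-parameter measure of how
tightly the data constrain the model — the posterior coefficient of
variation, cv = sd/mean, which separates identifiable parameters from
poorly constrained ones and thereby tells the experimenter which kinetic
constants are worth measuring directly.

Three pieces make this practical for stochastic kinetic models:

* **Nested sampling** with a small population (25 active points suffices
  up to 30 dimensions), converting the evidence integral into a 1-D sum
  over enclosed prior mass, which shrinks per iteration by Beta(n, 1)
  ratios; the logZ uncertainty is estimated as sqrt(H/n).
* **Slice-sampling exploration** with per-point, per-dimension
  self-tuning step sizes: a single stepping-out pass per dimension draws
  each replacement point under the hard constraint L > L*, at roughly 80%
  of the fixed-step likelihood-evaluation cost.
* A **transitional (bridging) likelihood** for sparse counts: over short
  steps the increment of a birth–death process is normal with mean
  (β−δ)ΔT and variance (β+δ)ΔT; sparse 2 h observation intervals are
  bridged by 20 drift-generated, end-corrected intermediate points, and
  each increment's windowed density is normalised by its maximum so that
  variance minimisation cannot bias the fit.

The circadian application ships complete: the three-species clock ODEs
(FRQ mRNA, cytoplasmic and nuclear protein; Hill-repressed transcription;
light–dark forcing), an exact Gillespie simulator at system size Ω = 500
for generating synthetic experimental data, parameter inference with nine
free kinetic constants, and Hill-coefficient model selection (N = 2…5).
Gaussian benchmarks with closed-form evidence and a simulated-annealing
bridge oracle validate every layer.

## Worked example

```r
library(clockns)

params <- circadian_parameters()      # published free-running parameter set
tr <- simulate_deterministic(params, t_end = 240)
estimate_period(tr)
#> [1] 21.5125

# one stochastic realisation, sparsely sampled every 2 h for 2 cycles
ts <- sparse_sample(ssa_simulate(params, t_end = 48, seed = 5), 2)

fit <- clock_infer(ts, seed = 99)     # ~25 s: nested sampling, n = 25
summary(fit)
#> log Z = -80.1754 +/- 1.1404   H = 32.515   n = 25 active points
#> 1570 posterior points; 69890 likelihood evaluations; stopped by logWt width test
#> Posterior moments (most to least constrained):
#>   parameter   mean       sd      cv
#> 1        vs 1.6260 0.021640 0.01331
#> 2        kI 0.9998 0.015210 0.01521
#> 3        ks 0.4913 0.008644 0.01759
#> 4        k1 0.5006 0.009617 0.01921
#> 5        k2 0.6147 0.012030 0.01957
#> 6        vm 0.5201 0.010960 0.02107
#> 7        vd 1.3580 0.032440 0.02389
#> 8        km 0.5520 0.042360 0.07673
#> 9        kd 0.1273 0.015460 0.12140
```

Reading the output: `log Z` is the log marginal likelihood of the model
given this realisation, with its sqrt(H/n) uncertainty.  The moments table
is ordered by cv: the transcription rate and repression threshold
(`vs`, `kI`) are constrained to ~2%, and every posterior mean sits close
to its generating value (e.g. `kI` = 0.9998 against a true 1.0), while the
degradation thresholds `km` and `kd` are an order of magnitude less
constrained — these are the constants an experimenter should measure
directly rather than infer.

Model selection treats the Hill coefficient as the model index:

```r
ds3 <- generate_dataset(params, cycles_list = 3, replicates = 1, base_seed = 20)
clock_select(ds3[[1]], base_seed = 77)
#> Model comparison by log marginal likelihood:
#>   label     logZ logZ_error logZ_rezeroed
#> 1   N=2 -155.410      1.230       -51.740
#> 2   N=3 -115.251      1.229       -11.581
#> 3   N=4 -103.670      1.217         0.000
#> 4   N=5 -116.631      1.237       -12.961
#> Best: N=4 (margin 11.581 over second best)
```

Three cycles of 2-hourly data recover the generating coefficient (N = 4)
decisively.

A thin command-line front end covers the same ground
(`exec/clockns simulate|infer|select|benchmark`, configured by
YAML/JSON; see `inst/extdata/example-config.yaml`).

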