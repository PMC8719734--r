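# clockfield

Bayesian inference for single-cell molecular clocks observed through
bioluminescence time-lapse imaging.

Circadian gene expression in tissues such as the suprachiasmatic nucleus
(SCN) arises from a delayed negative transcriptional–translational
feedback loop (TTFL) running noisily in every cell. Two questions define
a cell's oscillator phenotype: is its rhythm a self-sustained **limit
cycle** or a damped oscillation excited by molecular noise, and is its
transcriptional inhibition delivered as a sharp switch or spread over the
cycle? `clockfield` answers both from imaging data, for every location of
a recording at once.

## The model

mRNA copy number at location *i* follows a chemical Langevin equation
with a gamma-distributed transcriptional delay:

dX = [ R / (1 + (Z(t)/K)^n) − μX ] dt + √( R / (1 + (Z(t)/K)^n) + μX ) dW,

where Z(t) = ∫ X(t−s) g_{p,a}(s) ds is mRNA history weighted by a gamma
density truncated at τ_max = 24 h. The camera integrates light per
exposure: Y_t′ = κ ∫ X ds + η, with Gaussian read noise η. Parameters
R, K, n and the delay mean/SD carry multiplicative spatial random effects
θ_i = θ·exp(ε_i) with an intrinsic 8-neighbour CAR (conditional
autoregressive) prior on the imaging lattice, ε_i | ε_−i ~
N(Σ w_ij ε_j / w_i+, τ/w_i+), pooling strength across locations.

Fitting is by blocked adaptive random-walk Metropolis whose likelihood is
an extended Kalman–Bucy style filter of the augmented (current + lagged)
state. Two phenotype statistics come out of the posterior:

* **Robustness** V̂ — the posterior probability that a location's
  parameters imply limit-cycle dynamics of the macroscopic rate
  equation, computed by averaging a characteristic-root stability
  classifier over MCMC draws (V̂ > 0.05 separates limit-cycle from
  noise-driven phenotypes).
* **Inhibition Profile** IP(k) = −H′(x\*) g(k)/x\* — the lag-resolved
  relative inhibition of transcription by past mRNA; its entropy
  distinguishes switch-like from distributed regulation, and ensemble
  perturbation studies turn that into differential entrainability.

## Worked example

Simulate a synthetic 4×4 lattice recording (250 frames at 0.5 h exposure,
equilibrium 100 and peaks at 150–200 molecules), fit it, and read off the
phenotype:

```r
library(clockfield)

mu <- exp(-0.55)                      # reporter half-life prior mean
truth <- oscillator_params(R = 2 * mu * 100, K = 100, n = 5.57, mu = mu,
                           kernel = delay_kernel_from_moments(9.4, 4.2))
syn <- generate_synthetic_dataset(4, 4, truth, seed = 1, dt = 0.5)
chain <- run_mcmc(syn$record, n_iter = 5000, seed = 2)
print(chain)
#> Posterior chain: 5000 iterations, 16 location(s) (4 x 4)
#>   post-burn-in acceptance rates:
#>     tau          0.238
#>     theta        0.259
#>     eps_R        0.202
#>     eps_K        0.218
#>     eps_n        0.147
#>     eps_dmean    0.206
#>     eps_dsd      0.080
#>     mu           0.468
#>     kappa        0.455
#>     sigma_eta    0.446

head(posterior_summary(chain), 5)
#>   location parameter       mean       lower      upper
#> 1        1         R 28.1119785 17.41038640 35.5933684
#> 2        1         K 46.6275320 30.43069963 59.9456964
#> 3        1         n  6.4633622  4.62178181  9.9811791
#> 4        1     dmean  7.2643282  7.07643569  7.4860789
#> 5        1       dsd  0.2424095  0.05172708  0.4074545

robustness_estimate(chain, location = 1)$V     # limit-cycle probability
#> [1] 1
ip_entropy(compute_ip(truth))                  # regulation dispersion, nats
#> [1] 2.7594
```

The adapted blocks sit near their target acceptance rates (0.234
multivariate, 0.45 scalar). The posterior summary illustrates a finding
the package documents rather than hides: at this signal-to-noise (read
noise ≈ 0.07 light units against an oscillation amplitude ≈ 0.09), five
observed cycles cannot pin down all nine kinetic parameters — the
posterior concentrates on a lower-copy-number, shorter-delay oscillator
(here R ≈ 28, delay mean ≈ 7.3 h against a generating R ≈ 108, delay
mean 9.6 h at this location) that is nearly observationally equivalent
to the truth; a particle-filter check shows the exact likelihood is just
as undecided. What *is* identified is the oscillator phenotype: the
robustness estimate is 1, meaning every retained posterior draw implies
self-sustained limit-cycle dynamics, and the same experiment run on
damped ground truth gives 0 at every location, cleanly separated by the
V̂ > 0.05 cut-off.

The prototype oscillator types from the entrainment study are built in:

```r
perturbation_study(reference_params("I"), perturbation(0, 4, 130),
                   n_paths = 500, horizon = 144, seed = 3)
#> Phase distribution: 500 paths x 5 cycles, period 23.76 h
#>   circular mean shift -1.284 rad, synchrony 0.557
perturbation_study(reference_params("II"), perturbation(0, 4, 130),
                   n_paths = 500, horizon = 144, seed = 3)
#> Phase distribution: 500 paths x 5 cycles, period 23.28 h
#>   circular mean shift -1.118 rad, synchrony 0.570
```

A 4-hour, 130 molecules/hour shock at the trough delays the switch-like
Type I oscillator more than the distributed-delay Type II oscillator and
disperses both ensembles — the robustness/entrainability trade-off the
package quantifies. The methods vignette discusses how strongly such
contrasts depend on the shock-anchoring convention.

## Command line

A thin CLI over the package functions lives at `inst/cli/clockfield.R`:

```sh
Rscript inst/cli/clockfield.R synth --rows 5 --cols 5 --seed 1 --out-dir demo
Rscript inst/cli/clockfield.R fit --input demo/record.csv --iterations 5000 --out-dir demo
Rscript inst/cli/clockfield.R robustness --input demo/record.csv --out-dir demo
```
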