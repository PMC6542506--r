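# alphamass

Fitting a 22-parameter neural population model of the EEG alpha rhythm to
power spectra, and asking the question that matters afterwards: *which of
those parameters did the data actually teach us anything about?*

Mean-field models describe the interaction of excitatory and inhibitory
cortical populations through mean soma potentials $h_e, h_i$ and synaptic
activities $I_{jk}$ with alpha-function dynamics (rate constants
$\gamma_e, \gamma_i$, amplitudes $\Gamma_e, \Gamma_i$), sigmoidal
firing-rate coupling and external drives.  Linearized about a stable
resting state and driven by white noise on the external excitatory input,
the model predicts an EEG power spectrum

$$\langle S(\omega)\rangle = \alpha\,\hat S(\omega\mid\theta)
  = \alpha\,\bigl|C\,(i\omega I - A)^{-1}B\bigr|^2,$$

with $A$ the $10\times10$ Jacobian at the equilibrium and $\theta$ the 22
free physiological parameters, each bounded by a physiological range and
mapped affinely to $[-1,1]$.  A Welch spectral estimate with $K$ averaged
segments makes each spectral bin an independent gamma variate with shape
$K$ and mean $\alpha\hat S_n(\theta)$; the amplitude $\alpha$ is profiled
out analytically (least squares or maximum likelihood).  The package fits
this likelihood with two independent schemes — ensembles of particle swarms
on the least-squares cost, and Metropolis–Hastings sampling of the
posterior under the uniform box prior — and then quantifies identifiability
with per-parameter Kullback–Leibler divergences (posterior vs prior) and
the eigen-structure of the Fisher information matrix

$$I_{\mu\nu} = K \sum_n
  \frac{\partial \ln\hat S_n}{\partial\theta_\mu}
  \frac{\partial \ln\hat S_n}{\partial\theta_\nu},$$

whose eigenvalue spectrum spread over many decades is the signature of a
*sloppy* model, and whose leading eigenvectors name the few parameter
combinations the spectrum actually constrains.  A synthetic-data module
generates ground-truth parameter sets, gamma-sampled spectra and
noise-driven simulated EEG so the entire pipeline is validated by parameter
recovery, without any external data.

## A worked example

```r
library(alphamass)

gt   <- sample_ground_truth(seed = 7)   # stable, alpha-peaked truth
spec <- synth_spectrum(gt, seed = 11)   # one synthetic "measurement"
spec
#> Spectral estimate: 73 bins, 2-20 Hz, K = 29 (synthetic-gamma)

fit <- ml_refine(spec, gt$theta)        # local ML polish
round(fit$alpha, 3)
#> [1] 0.703

fim <- fisher_information(fit$theta, spec$freqs, spec$K)
e   <- fim_eigen(fim)
e$n_zero
#> [1] 16
round(log10(e$raw_values[1:6] / e$raw_values[1]), 1)
#> [1]  0.0 -1.8 -2.1 -2.6 -4.6 -8.3
```

The truth's model spectrum peaks at 9.5 Hz, inside the alpha band.  Of 22
FIM eigenvalues, 16 are numerically zero (below $10^{-10}$ of the largest):
the spectrum's shape depends on only seven independent parameter
combinations (two membrane decay rates, the two PSP rate constants, three
loop gains — a structural result of the transfer-function algebra), and of
those, roughly five sit above practical identifiability cutoffs.  The
remaining eigenvalues spread over eight decades — the sloppy-model
signature.

The full recovery experiment reproduces the headline result at scaled-down
chain length: fit a gamma-sampled spectrum from a synthetic subject
(`sample_subject_truth()`, the model's own ML fit to a realistic
1/f-plus-alpha-peak spectrum) with $10^5$ MCMC samples and compare
posterior to truth:

```r
rep <- recover(seed = 2, sampler = "mcmc",
               control = mcmc_control(n_samples = 1e5, burn_in = 4e4,
                                      store_every = 10))
data.frame(rep)[rep$parameter == "gamma_i", ]
#>    parameter   truth estimate  error     sd
#> 14   gamma_i -0.7723  -0.7899 0.0176 0.0309
```

The inhibitory PSP rate constant γ_i is recovered to 0.018 normalized units
with the smallest posterior SD of all 22 parameters — most other
parameters keep near-prior uncertainty.  That asymmetry, stable across
synthetic subjects, is the scientific point: the alpha peak pins down the
inhibitory synaptic timescale and very little else.

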