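# awflow

Pixel-super-resolution phase retrieval for lensless on-chip microscopy by
accelerated Wirtinger flow.

A lensless on-chip microscope records only low-resolution intensity images:
the sensor is blind to the phase of the diffracted wavefield, and its
physical pixels average away sub-pixel detail. Given K intensity images
acquired under known phase-only modulations (e.g. displayed by an SLM
conjugate to the sample plane), this package recovers the complex sample
transmittance `x` on a grid finer than the sensor pixels by solving

    x_hat = argmin_x  (1/2K) sum_k || sqrt(S |A_k x|^2) - y_k ||^2  +  lambda ||D x||_1

with `A_k = C H M_k` (phase modulation, angular-spectrum free-space
propagation, sensor crop) and `S` the sub-pixel binning of the sensor. The
solver is a proximal-gradient method on the amplitude-based fidelity with
Wirtinger gradients, Nesterov momentum `beta_t = t/(t+3)`, an anisotropic
complex total-variation proximal step, and an automatic step size
`gamma <= 2K / sum_k rho(A_k^H diag(s) A_k)` estimated by power iteration
(= 2 for the standard system). It is aimed at computational-imaging
practitioners: the forward model, its exact adjoints, a synthetic
acquisition simulator and ambiguity-aware metrics are all exported, so the
package runs end to end with no external data.

## Worked example

Simulate a modulation-diversity acquisition (64 x 64 grid, 2 x 2 binning,
K = 8, noiseless) and reconstruct it:

```r
library(awflow)

cfg   <- simulationConfig(gridSize = 64, sigma = 2, K = 8, seed = 42)
truth <- makeSample(cfg)                  # procedural complex sample
sys   <- makeSystem(cfg)                  # A_k = C H M_k + binning model
stack <- simulateStack(truth, sys, seed = 42)
stack
#> MeasurementStack: 8 intensity images of 32 x 32 sensor pixels
#>   simulated (truth digest 4333df095e4d984f2b9a1226d1a4f6c6)
#> SystemOperator: A_k = C H M_k, K = 8 measurements
#>   grid 64 x 64, pitch 0.95 um, wavelength 0.532 um, z = 500 um
#> SamplingOperator: grid 64 x 64 -> crop 64 x 64 (offset 0, 0) -> sensor 32 x 32
#>   binning sigma = 2 x 2 = 4, weights in [1, 1]

res <- awfReconstruct(stack, iterations = 100, seed = 42, truth = truth)
tail(convergenceHistory(res), 3)
#>     iter     fidelity    objective    rmseAmp  rmsePhase rmseComplex
#> 98    98 0.0002429277 0.0002429277 0.01545205 0.04504111  0.02179164
#> 99    99 0.0002354966 0.0002354966 0.01534888 0.04477947  0.02165855
#> 100  100 0.0002284285 0.0002284285 0.01524722 0.04452169  0.02152744

alignedRMSE(finalField(res), truth, border = 2)$relError
#> [1] 0.04804
```

The `fidelity` column is the amplitude-domain data misfit `F(x_t)`; it
falls by four orders of magnitude in 100 accelerated iterations. The RMSE
columns compare against the ground truth after removing the global phase
ambiguity (`alignedRMSE`): here the complex field is recovered to ~5%
relative error from 8 images with 4x fewer sensor pixels than unknowns.
Setting `schedule = "none"` runs plain (non-accelerated) Wirtinger flow —
on the 256 x 256, 4 x 4-binning benchmark it needs more than ten times as
many iterations to reach the same fidelity. With measurement noise, adding
the TV regularizer (`lambda = 2e-3`) lets K = 8–16 regularized images match
or beat a K = 32 non-regularized reconstruction.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/psr-awf.R` (subcommands `simulate`, `reconstruct`,
`evaluate`, `curves`).

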