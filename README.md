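# srtriplex

Simulation and precision-analysis framework for **triple-energy
photon-counting x-ray quantification of strontium in bone**.

Strontium (Z = 38) substitutes for calcium in bone mineral; monitoring its
concentration matters both for strontium-based osteoporosis therapies and
for correcting DXA bone-density readings, which strontium inflates. The
strontium K-edge at 16.105 keV gives the element a spectral fingerprint: a
photon-counting detector with three energy thresholds can, in a single
low-dose finger radiograph, separate strontium, bone and soft tissue by
basis-material decomposition. This package is for medical-physics
researchers who want to ask *how precisely* such a system could work: what
limit of quantification (LOQ) a given detector noise floor permits, what
absorbed dose a target LOQ costs, and where in (tube voltage, threshold)
space the optimum lies.

## Model

Expected counts in energy bin *i* for one detector pixel:

$$ c_i = A \int \phi_0(E)\, G_i(E)\,
   e^{-\mu_{Sr} a_{Sr} - \mu_B a_B - \mu_{ST} a_{ST}}\, dE $$

with $\phi_0$ the incident fluence, $G_i$ the large-area bin gain of a
750 µm CdTe sensor with analog charge summing, Gaussian electronic noise
and K-escape, and $a_j$ the areal densities (g/cm²) along the ray.
Linearization about the local background gives the sensitivity matrix
$M_{ij}$ (effective attenuation coefficient of material *j* in bin *i*);
normalized Poisson counts have covariance $\mathrm{diag}(1/c_i)$, and the
generalized least-squares (GLS) bound on the areal-density covariance is

$$ \Sigma_a = \left(M^T \Sigma_{\Delta c}^{-1} M\right)^{-1}. $$

The strontium-to-bone concentration $C = a_{Sr}/a_B$ is averaged over all
bone-traversing pixels of a three-phalanx finger phantom; delta-method
propagation gives $\sigma_C^2$, the blank-sample deviation defines
$LOQ = 10\,\sigma_{C_b}$, and the dose-independent product
$\tilde\sigma^2_{C_b} = \sigma^2_{C_b} D_b$ yields the minimum dose
$D_{min} = 100\,\tilde\sigma^2_{C_b}/LOQ^2$. An exhaustive grid search
maximizes the dose-normalized SNR over tube voltage (20–50 kVp) and
thresholds (0.5 keV steps), and a per-bin projected Fisher decomposition
attributes the precision to the three energy bins.

All inputs — filtered W/Ag, Rh/Rh and Mo/Mo spectra, K-edge attenuation
curves, the phantom, Poisson samplers — are generated parametrically by
the package, so the entire pipeline runs with no external data. Loaders
for two-column spectrum/attenuation text files accept reference-grade
tables when absolute fidelity is wanted. See the methods vignette
(`vignettes/triple-energy-strontium.Rmd`) for the model, defaults and
numerical choices in detail.

## Worked example

```r
library(srtriplex)

# precision of a W/Ag acquisition at 24 kVp, thresholds 12.5/15.5/20.5 keV,
# 5 keV electronic noise floor, 150 ppm Sr in trabecular bone
cfg <- acquisition_config(24, c(12.5, 15.5, 20.5), 5, "W/Ag")
rep <- precision_report(cfg, finger_phantom(C_trab = 150e-6))
rep
#> <precision_report> W/Ag, 24 kVp, thresholds 12.5/15.5/20.5 keV, 5 keV noise floor
#>   C_hat = 52.432 ppm over N = 361100 pixels, sigma_C = 828.888 ppm
#>   LOQ = 8291.07 ppm at D = 202 uGy; D_min(100 ppm) = 1.39e+06 uGy
#>   SNR at 20 uGy = 0.020; D/K_air = 291 uGy/mGy
#>   Fisher fractions (bins 1-3): 0.051 / 0.520 / 0.429

# optimize tube voltage and thresholds for Mo/Mo at a 5 keV noise floor
grid_search("Mo/Mo", 5)
#> <optimal_config> Mo/Mo, 5 keV noise floor
#>   kVp 23, thresholds 12.5 / 14.5 / 21.5 keV
#>   SNR/sqrt(D) = 0.008876, SNR = 0.0001999, D = 0.0005074 Gy, D/K_air = 205 uGy/mGy
```

Reading the first report: the projected concentration (52 ppm) is lower
than the trabecular 150 ppm because cortical bone carries one quarter of
the trabecular concentration and dominates the projected bone mass. The
mid-energy bin — the one straddling the strontium K-edge — carries half
of the Fisher information. The optimizer places the second threshold just
below the 16.105 keV K-edge, the mechanism that makes triple-energy
strontium imaging work. Absolute LOQ and dose figures depend on the
parametric fixture spectra and cross sections and on the
noise-floor-to-sigma mapping (see the vignette); within the model they
obey the exact inverse dose-scaling laws the tests assert.

The same computations are available from a shell:

```sh
Rscript inst/cli/srtriplex.R optimize --config inst/extdata/default_config.yaml --out out/
```

Subcommands: `precision`, `optimize`, `dose`, `loq-curve`, `snr-curve`,
`fisher`, `fixtures`.

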