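# qsmme — multi-echo combination strategies for QSM

Quantitative susceptibility mapping (QSM) recovers the tissue magnetic
susceptibility distribution χ (ppm) from the phase of multi-echo
gradient-recalled-echo (GRE) MRI. The phase φ(r, TE) = γ·ΔB_tot(r)·TE +
φ₀(r) must be unwrapped, freed of the harmonic background field, and
deconvolved with the unit dipole kernel D(k) = 1/3 − (k·b̂)²/|k|² — and
with several echoes there is a genuine methodological choice of *where*
in that chain to combine them. `qsmme` is for researchers comparing those
choices. It implements four complete pipelines over one shared numerical
backbone:

| pipeline | combination stage | rule |
|---|---|---|
| `nlfit` | before any Laplacian processing | complex-domain nonlinear fit of (ΔB_tot, φ₀) |
| `te-wavg` | after per-echo Laplacian unwrapping | w_i = TE_i / ΣTE_j on φ_i/TE_i |
| `snr-wavg` | after per-echo SHARP | w_i(r) ∝ TE_i·exp(−TE_i·R₂*(r)) |
| `susc-wavg` | after per-echo inversion | w_i(r) ∝ M²(r,TE_i)·TE_i² on χ_i |

The backbone comprises FFT Laplacian phase unwrapping, SHARP background
removal (3-voxel kernel, truncated deconvolution, 5-voxel mask erosion),
closed-form Tikhonov dipole inversion with L-curve selection of α and a
sphere-calibrated correction for susceptibility underestimation. Around
it sit a synthetic multi-echo GRE head-phantom generator with exact
ground-truth field decompositions, an analytic phase-noise propagation
layer for every pipeline (validated by a built-in Monte-Carlo oracle),
and evaluation statistics: RMSE, regional means/SDs, line profiles,
Bland–Altman fixed-bias analysis, normality-gated sign/t tests, and
subject pooling.

## Worked example

Simulate the default 96³ digital head phantom (5 echoes at
3/8.4/13.8/19.2/24.6 ms, 3 T, complex channel noise SD 0.07), run two
pipelines, and compare them against the known ground truth:

```r
library(qsmme)

spec <- phantom_spec(seed = 20220629)      # 96^3, defaults above
ph   <- build_phantom(spec)
fld  <- simulate_fields(ph$chi_true, ph$brain_mask)
gre  <- simulate_gre(c(ph, fld["db_total"]), spec, n_repeats = 1)[[1]]

res_nl <- run_pipeline(gre, ph$brain_mask, pipeline_config("nlfit"))
res_te <- run_pipeline(gre, ph$brain_mask, pipeline_config("te-wavg"))

m    <- res_nl$chi$mask                    # shared SHARP-eroded support
vein <- ph$labels %in% which(ph$name_map == "vein")

cat(sprintf("alpha* = %.3g, correction = %.2f\n",
            res_nl$intermediates$alpha,
            res_nl$intermediates$correction_factor))
cat(sprintf("chi RMSE:  nlfit %.1f %%   te-wavg %.1f %%\n",
            rmse_percent(res_nl$chi$chi, ph$chi_true, m),
            rmse_percent(res_te$chi$chi, ph$chi_true, m)))
cat(sprintf("vein chi:  nlfit %.3f   te-wavg %.3f   truth %.3f ppm\n",
            mean(res_nl$chi$chi[vein & m]),
            mean(res_te$chi$chi[vein & m]),
            mean(ph$chi_true[vein])))
```

```
alpha* = 0.0788, correction = 2.56
chi RMSE:  nlfit 89.7 %   te-wavg 69.8 %
vein chi:  nlfit 0.444   te-wavg 0.305   truth 0.450 ppm
```

Read: the nonlinear-fit pipeline has the *larger* whole-brain RMSE (its
combined field is intrinsically noisier — a two-parameter fit against an
offset-blind average), yet its venous mean is far closer to truth,
because averaging pipelines push wrapped, rapidly-varying vein phase
through per-echo Laplacian processing and lose contrast there. RMSE above
50% is normal for truncation-regularised QSM: the metric mixes noise,
streaking and regularisation shrinkage. The noise side of the comparison
is available analytically via `pipeline_sigma_chi()` and empirically via
`monte_carlo_sigma()`.

A thin command-line wrapper for simulate / run / evaluate lives at
`inst/cli/qsmme.R` (after installation:
`Rscript $(Rscript -e 'cat(system.file("cli/qsmme.R", package="qsmme"))') simulate --out-dir sim/`).

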