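# msotr

Reconstruction and multispectral analysis of optoacoustic (photoacoustic)
tomography data in R.

Multispectral optoacoustic tomography (MSOT) records, for each laser
shot, the ultrasound field generated by optical absorption in tissue.
Recovering images — and, across wavelengths, maps of oxy- and
deoxy-hemoglobin and oxygen saturation — requires a chain of signal
conditioning, tomographic inversion, temporal state filtering, and
spectral unmixing whose choices materially change the biology one infers.
`msotr` implements that chain end to end for 2D circular-array geometries,
together with the synthetic-data machinery needed to validate every link
of it, for researchers who want a transparent, testable alternative to
opaque vendor processing.

## What is inside

* **Forward models.** The discrete imaging operator
  `M = 1/(2 pi v_s) * D_t W`, with the arc-integral matrix `W` built
  either by curve sampling with bilinear interpolation (dIMMI) or by
  exact circle–pixel arc lengths (CDMMI), as sparse `Matrix` operators
  with exact adjoints.
* **Solvers.** LSQR (Golub–Kahan recurrence, optional Tikhonov damping),
  a non-negative accelerated projected-gradient solver whose output is
  element-wise `>= 0` by construction, and 2D universal backprojection
  `2 p(t) - 2 t dp/dt` along time-of-flight circles.
* **Analytical phantoms.** Random non-overlapping paraboloid absorbers
  `A (1 - r^2/R^2)` with closed-form circular line integrals and exact
  point-detector signals — the oracle every model is validated against.
* **Preconditioning.** Energy calibration, per-transducer mean
  subtraction, Wiener deconvolution, zero-phase band-pass
  (50 kHz–7 MHz default), Beer's-law water-absorption compensation,
  time regridding; fixed order, every stage linear and toggleable.
* **Spectral estimation.** Sliding-window stack assembly and Kalata
  alpha / alpha-beta tracking filters with gains from the tracking
  index; pseudoinverse and non-negative unmixing of HbO2/Hb with SO2
  maps (`SO2 = HbO2 / (HbO2 + Hb)`).
* **Metrics & statistics.** Pixel-scaled bias/L1/L2 error norms, SSIM,
  relative residual `||M I - d|| / ||d||`, negative-pixel indicator
  maps, binned Bland–Altman, Welch t-score maps, relative Cohen's d,
  correlation maps against a stimulus waveform, Fisher-Z comparison,
  and a 7-parameter piecewise-exponential gas-response fit.
* **Pipeline.** A YAML-configured, provenance-recording, worker-count
  invariant end-to-end runner over a simple chunked on-disk dataset
  store, plus a thin CLI at `inst/cli/msot-pipeline`.

## Worked example

Simulate a random phantom, compare both forward models against the exact
analytical signal, and reconstruct with the constrained solver:

```r
library(msotr)

geom   <- arc_detector_geometry(64, radius = 0.040)   # 270 deg, 40 mm
coords <- make_image_coords(50, fov = 0.025)          # 50 x 50, 2.5 cm
tax    <- default_time_axis(geom, 0.025, n = 512)

spec  <- sample_phantom(fov = 0.025, seed = 42)
truth <- rasterize(spec, coords)
data  <- analytical_signal(spec, geom, tax)           # exact oracle

for (kind in c("dimmi", "cdmmi")) {
  M <- assemble_model(kind, coords, geom, tax)
  pred <- model_apply(M, truth)
  cat(sprintf("%s forward rel. L2 error: %.3f\n", kind,
              sqrt(sum((pred - data$samples)^2) / sum(data$samples^2))))
}

M   <- assemble_model("cdmmi", coords, geom, tax)
rec <- nnapcg_solve(M, data, solver_options(max_iterations = 100))
cat(sprintf("min pixel: %g, SSIM vs truth: %.3f, r_rel: %.3f\n",
            min(rec$image$pixels), ssim(truth, rec$image),
            tail(rec$relative_residual, 1)))
```

```
dimmi forward rel. L2 error: 0.078
cdmmi forward rel. L2 error: 0.313
min pixel: 0, SSIM vs truth: 0.816, r_rel: 0.292
```

At this coarse 50-pixel grid the curve-sampling model (dIMMI) predicts
the true signal four times more accurately than the exact-arc-length
model (CDMMI) — its dense sampling along each integration circle acts as
an anti-aliasing filter — while the constrained reconstruction recovers
the phantom with no negative pixels (the projection guarantees it) and a
residual dominated by the model's own discretization error. Both models
converge to the analytical signal as the grid refines;
`benchmark_forward_models()` quantifies that convergence.

An end-to-end synthetic gas challenge (36 frames, 6 wavelengths,
rectangular inhaled-O2 waveform, sinogram SNR 10) is available as

```r
study <- run_gas_challenge_study(seed = 1)
study$constrained$median_correlation    # SO2 vs waveform, tissue median
study$unconstrained$median_correlation  # lower: noise + unphysical pixels
```

The methods vignette (`vignettes/msotr-methods.Rmd`) documents the model
conventions, solver contracts, filter gain derivations, generator
defaults, and known limitations.

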