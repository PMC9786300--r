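# nmrlcm — deconvolution of solid-state NMR mixture spectra

`nmrlcm` quantifies the solid-state forms present in a mixture sample from
its solid-state NMR (ssNMR) spectrum. It is aimed at pharmaceutical
development and quality control, where an unwanted crystalline fraction of
an active ingredient in an otherwise amorphous dispersion must be detected
and quantified, and where ssNMR's broad overlapping lines, magic-angle
spinning (MAS) sidebands and large phase errors defeat generic peak-fitting
tools.

## The model

The complex mixture spectrum is modelled as a constrained linear
combination of two experimentally acquired template spectra of the pure
forms — `form1` (amorphous) and `form2` (crystalline) — with the spectral
processing of the mixture estimated *jointly* with the composition. After
linear interpolation of all spectra onto the `form2` ppm grid, the residual
at point *n* is

    e_n = Δ_dmix[ Re( exp(i φ_n) · y_mix,n ) ]
          − α1 · Δ_dform1[ Re y_form1,n ]
          − α2 · Re y_form2,n,            α1 + α2 = 1,  0 ≤ α1, α2 ≤ 1,

where Δ_δ[·] shifts a trace horizontally by δ ppm (linear interpolation)
and φ_n = (φ0 − φ1·n*/N) + φ1·n/N is a zero- plus first-order phase ramp
anchored at a pivot point n*. The fit minimises Σ e_n² (RSS; default) or
Σ|e_n| (L1, robust to spike artefacts) by derivative-free, bound-constrained
optimisation, in one of three modes: `fixed` (apply given values),
`proportion_only` (estimate α2 alone) or `full` (α2, φ0, φ1 and both
shifts). The estimated α2 is the crystalline proportion.

A synthetic-spectrum module generates physically phaseable complex
pseudo-Voigt templates with MAS sidebands and mixtures with known
composition, phase error, misalignment and noise, so the whole pipeline is
testable against ground truth. A session log records every fit for
traceable, replayable analyses.

## Worked example

Simulate a spiked sample — 3% crystalline in 97% amorphous — with a large
phase error (φ0 = 1.05 rad ≈ 60°, φ1 = 0.3 rad), a 0.08 ppm misalignment
and 1% complex noise, then deconvolute it fully automatically:

```r
library(nmrlcm)

specs   <- demo_simspecs()            # 0 .. -150 ppm, 4096 points
form1   <- make_template(specs$form1) # amorphous: broad lines
form2   <- make_template(specs$form2) # crystalline: sharp lines + sidebands
mixture <- make_mixture(form1, form2, alpha2 = 0.03, phi0 = 1.05, phi1 = 0.3,
                        delta_mix = 0.08, noise_sigma = 0.01, seed = 4)

fit <- deconv_fit(mixture, form1, form2,
                  fit_config(mode = "full", normalize = FALSE))
fit
```

```
<deconv_result: mode=full, L2 loss=0.00441424, form2 = 3.04%, converged>
<deconv_params: alpha2=0.030417 (form2 3.04%), phi0=1.0437 rad, phi1=0.2940 rad,
  delta_mix=0.0916 ppm, delta_form1=-0.0111 ppm, pivot=3053>
```

The fit recovers the crystalline proportion as 3.04% (truth: 3%), the
zero-order phase to 0.006 rad and the first-order phase to 0.006 rad; the
remaining loss is the noise floor. `write_results()` exports the parameter
table and the processed/fitted/residual traces as CSV.

The same analysis from the shell (the launcher script is installed under
`inst/cli/`):

```sh
nmrlcm simulate --out fx --seed 4 --alpha2 3% --ph0 60 --ph1 17 --noise 0.01
nmrlcm fit --mix fx/mixture.jdx --form1 fx/form1.jdx --form2 fx/form2.jdx \
           --mode full --no-normalize --out results
nmrlcm replay --log results/session_log.csv \
           --mix fx/mixture.jdx --form1 fx/form1.jdx --form2 fx/form2.jdx
```

`fit` prints a one-line summary (`alpha2 = 3.04% | L2 loss = 0.00441186 |
converged`), writes `parameters.csv`, `processed_spectra.csv` and an
append-only `session_log.csv`; `replay` re-applies the last logged state
and verifies the logged loss, exiting non-zero on any mismatch.

Spectra are read from JCAMP-DX (`.jdx`/`.dx`; NTUPLES real/imaginary pages
or paired XYDATA blocks, AFFN and basic SQZ/DIF/DUP ordinates) or from CSV
(a `ppm,real` + `ppm,imag` pair, or one three-column `ppm,real,imag` file).
An imaginary channel is required — phasing needs complex data.

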