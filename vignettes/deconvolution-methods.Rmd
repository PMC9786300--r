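---
title: "Linear combination modelling of ssNMR mixture spectra: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear combination modelling of ssNMR mixture spectra: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrlcm)
```

## The problem

Solid-state NMR is the standard tool for quantifying the solid-state forms
(polymorphs) of an active pharmaceutical ingredient: an unwanted crystalline
fraction in an amorphous dispersion changes bioavailability and stability,
and its spectrum changes with the packing arrangement. Because signal
intensity is linear in concentration, the spectrum of a solid–solid mixture
is, to excellent approximation, a linear combination of the spectra of its
pure components — provided all spectra were acquired under the same
conditions. Deconvolution is nonetheless hard in practice: ssNMR lines are
broad and overlap severely, magic-angle spinning (MAS) splits each signal
into sidebands, lineshapes are irregular, and mixture spectra routinely
carry large phase errors that are slow and subjective to correct by hand.

`nmrlcm` therefore models a complex mixture spectrum directly as a
constrained linear combination of two experimentally acquired, carefully
phased *template* spectra — `form1` (the dominant, typically amorphous form)
and `form2` (the minority, typically crystalline form of QC interest) —
while *jointly* estimating the spectral-processing parameters that a
spectroscopist would otherwise set manually.

## The model

All three spectra are first placed on a common chemical-shift grid; the
`form2` ppm axis is the reference and the other two spectra are linearly
interpolated onto it. With point index $n = 1,\dots,N$, the model residual
is

$$
e_n \;=\; \Delta_{\delta_\text{mix}}\!\left[\operatorname{Re}\!\left(
   e^{i\varphi_n}\, y_{\text{mix},n}\right)\right]
 \;-\; \alpha_1\, \Delta_{\delta_\text{form1}}\!\left[
   \operatorname{Re}\, y_{\text{form1},n}\right]
 \;-\; \alpha_2\, \operatorname{Re}\, y_{\text{form2},n},
$$

subject to $\alpha_1 + \alpha_2 = 1$ and $0 \le \alpha_1, \alpha_2 \le 1$;
$\alpha_1$ is never a free parameter ($\alpha_1 \equiv 1 - \alpha_2$).
Here $\Delta_\delta[\cdot]$ is the linear-interpolation shift operator that
moves a trace horizontally by $\delta$ ppm, and the phase ramp

$$
\varphi_n \;=\; \left(\varphi_0 - \varphi_1 \tfrac{n^\ast}{N}\right)
             + \varphi_1 \tfrac{n}{N}
$$

applies a zero-order (constant) plus first-order (linear-in-frequency)
phase correction to the complex mixture, anchored so that the correction at
the pivot point $n^\ast$ equals $\varphi_0$ exactly. Only the mixture is
phased: the templates are assumed carefully phased once and then frozen for
the quantification project. Since only relative alignment matters, `form2`
fixes the ppm frame and carries no shift of its own.

The fit minimises either the residual sum of squares $\sum_n e_n^2$ (L2,
default) or the least absolute deviation $\sum_n |e_n|$ (L1, robust against
sparse artefacts such as spikes). Three estimation modes are provided:
`fixed` (apply supplied values, no optimisation — for manual work and for
replaying logged sessions), `proportion_only` (optimise $\alpha_2$ alone),
and `full` (optimise $\alpha_2, \varphi_0, \varphi_1, \delta_\text{mix},
\delta_\text{form1}$ jointly).

## Parameters, units and defaults

| parameter | meaning | unit | default start | default bounds |
|---|---|---|---|---|
| `alpha2` | proportion of form2 | – | 0 | $[0, 1]$ (fixed by the model) |
| `phi0` | zero-order phase at the pivot | rad | auto (see below) | $[-\pi, \pi]$ |
| `phi1` | first-order phase span across the spectrum | rad | 0 | $[-2\pi, 2\pi]$ |
| `delta_mix` | mixture shift | ppm | 0 | $[-1, 1]$ |
| `delta_form1` | form1 shift | ppm | 0 | $[-1, 1]$ |
| `pivot_index` | first-order anchor point | index | magnitude maximum of the mixture | – |

The starting policy encodes the expected use case: spectra arrive
referenced (shifts start at 0), `form2` is the minority form ($\alpha_2$
starts at 0), and the zero-order phase is auto-initialised. The phase
bounds exclude the $\varphi_0 \leftrightarrow \varphi_0 + 2\pi$ wrap-around
degeneracy. Angles are radians inside the package and degrees at the CLI
and in session logs, where spectroscopists expect them. If the fitted
`alpha2` finishes within tolerance of 0 or 1 the result is flagged
`at_bound`: a 0% estimate is a substantive QC finding and must not be
confused with non-convergence.

**Automatic PH0.** `auto_ph0()` grid-searches $\varphi_0 \in [-180°, 179°]$
in 1° steps and scores the "positiveness" of the rotated real part:
$\sum_n r_n - \lambda \sum_n \max(-r_n, 0)$ with $r = \operatorname{Re}(e^{i
\varphi_0} y)$ and $\lambda = 5$. For an absorption spectrum (nonnegative
real part, zero imaginary part) rotated by a known angle, the maximiser
recovers that angle to within one grid step — a property the tests assert
over 50 random rotations. On fully complex data the dispersion tails bias
the score by up to a few degrees; that is acceptable for a starting value,
which is all this heuristic is meant to provide (the optimiser refines
$\varphi_0$ afterwards).

## Normalisation

With the sum-to-one constraint, $\alpha_2$ is only interpretable as a
physical proportion when the three spectra share an intensity scale. Under
matched acquisition conditions they do, and `normalize = FALSE` preserves
the raw scales. By default, however, `deconv_fit()` area-normalises the
set: each template is scaled so the trapezoidal integral of its real part
is 1 (templates are phased, so their real part is the absorption signal);
the mixture's scale is estimated phase-robustly as the real-part integral
after a PH0-only `auto_ph0()` pre-rotation. Only the scale is taken from
that rotation — the mixture handed to the optimiser is not pre-phased, so
normalisation never depends on the final fit. A template with nonpositive
area is rejected as unphased. On dispersive complex data the PH0-estimated
mixture scale inherits the few-degree heuristic bias described above, which
propagates into a proportion bias of order $10^{-3}$; the package's own
synthetic fixtures are generated on a common area-1 scale, so the recovery
tests run with `normalize = FALSE` and exercise the matched-acquisition
path, while normalisation itself is verified separately against
absorption-only constructions where it is exact.

## Optimisation

The loss is minimised by derivative-free bound-constrained local
optimisation. `proportion_only` uses Brent's method on $\alpha_2 \in
[0,1]$; for the L2 loss the objective is *exactly* quadratic in
$\alpha_2$, so the result can be checked against the closed-form parabola
vertex, which the tests do to $10^{-6}$. `full` mode uses Nelder–Mead on
$\sin^2$-transformed coordinates (each bounded parameter $x \in [l, u]$ is
represented as $x = l + (u - l)\sin^2 t$ with $t$ unbounded), restarted
from the incumbent with a fresh simplex until an entire cycle improves the
loss by less than the relative f-tolerance ($10^{-10}$ by default; at most
20,000 evaluations). Restarting matters: a single simplex collapse is a
well-known failure mode, and the restart loop is what carries the noiseless
demo fixture from a starting loss of order $10^{-2}$ down to $10^{-13}$.
The shift parameters are expressed internally in units of the grid spacing
so that all five coordinates have comparable magnitudes — simplex methods
are scale-sensitive. Both modes are deterministic given the starting point,
and the returned loss is never above the loss at the start (enforced by
construction, asserted across a fixture battery). An optional seeded
multistart jitters the $\varphi_1$ start, the one parameter the default
policy leaves at zero without data-driven initialisation.

## The synthetic generator

The simulator exists so that every operation is testable against known
ground truth without any experimental download. `make_template()` builds
complex pseudo-Voigt lines: the real part is the absorption profile, the
imaginary part the matching dispersion — analytic for the Lorentzian
component, and via the Dawson-function Hilbert pair for the Gaussian
component ($\operatorname{disp}(u) \propto 2F(u)/\sqrt{\pi}$, with the
Dawson function computed through `pracma::erfi` below $|u| = 10$ and an
asymptotic series beyond). A real-only simulator could not be phased
physically; this one satisfies unitarity and inversion identities to
machine precision. MAS sidebands are scaled copies at $\pm k \times$
spacing with amplitude $\text{decay}^k$ — a visual and structural emulation,
not a physically rigorous sideband-intensity calculation. Templates are
area-normalised on their real part.

`make_mixture()` is the exact inverse of the model: it builds the clean
combination $(1-\alpha_2)\Delta_{\delta_\text{form1}}[f_1] + \alpha_2 f_2$,
inverts the mixture shift, and removes the phase ramp with the conjugate
factor. The shift inversion deserves a note: applying `shift(-delta)` would
*not* invert `shift(delta)` (two linear interpolations smooth the sharp
crystalline lines by $\mathcal{O}(h^2 f'')$, enough to leave a visible
residual floor), so the generator instead solves the interpolation
operator's banded linear system exactly, running the two-term recursion in
whichever direction is numerically stable (contraction ratio
$\min(f, 1-f)/\max(f, 1-f)$ for fractional shift part $f$). Consequently
the residual at the generating parameters vanishes except for a few points
at one grid edge, where the shift operator's constant edge-fill meets the
true baseline; the demonstration peak geometry keeps all lines — including
every sideband — at least 10 ppm inside the grid so those edge terms are at
the $10^{-13}$ loss level. Noise is i.i.d. circular complex Gaussian with
standard deviation expressed as a fraction of the maximum template
magnitude; a sparse-spike contaminator (`add_spikes()`) exists solely to
study L1-vs-L2 robustness.

The default demonstration conditions mirror the intended application: a
0 to −150 ppm window with $N = 4096$ points; an amorphous template of three
broad pseudo-Voigt peaks (half-widths 6–9 ppm); a crystalline template of
four sharp peaks (0.35–0.6 ppm) with two orders of sidebands spaced 27 ppm
and decaying by 0.45 per order; mixture parameters $\alpha_2 = 0.10$ (or
0.03 for the low-spike regime), $\varphi_0 = 0.5$ rad, $\varphi_1 = 0.3$
rad, $\delta_\text{mix} = 0.1$ ppm, $\delta_\text{form1} = -0.05$ ppm, and
1% complex noise for noisy runs.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: baseline roll and correlated (coloured) noise,
lineshape distortions that differ between mixture and template
acquisitions, temperature- or packing-induced peak-position changes beyond
a rigid shift, and rigorous sideband intensities. On real spectra these
appear as model misfit in the residual line, and the estimate quality must
be judged from it.

## Numerical choices and degenerate inputs

* **Out-of-range rule.** Both interpolation to the reference grid and the
  shift operator fill points sampled outside the source range with the
  nearest edge value, never extrapolating linearly: real ssNMR baselines
  are flat at the spectrum edges, and constant fill avoids fabricated
  slopes. Edge fill also keeps $N$ constant across shift values, which the
  optimiser requires for comparable losses.
* **Indexing.** Internally 0-based point indices with an ascending ppm
  axis; the 1-based convention of the phase-ramp formula is applied at
  evaluation ($n = \text{index} + 1$). Descending (display-convention)
  axes are canonicalised on read and restored on write.
* **I/O quantisation.** JCAMP-DX and CSV writers format with 17 significant
  digits, so write/read round trips reproduce doubles exactly; JCAMP
  tabular output requires a uniform grid (non-uniform grids go to CSV).
  The JCAMP reader accepts AFFN and the basic compressed ordinate forms
  SQZ/DIF/DUP, and rejects anything else by name; a file without an
  imaginary channel is rejected with a message explaining that phasing
  needs complex data.
* **Degenerate inputs.** All-zero spectra make `auto_ph0()` warn and return
  0; out-of-bounds starting values are clipped into bounds with a warning;
  an optimiser that fails to improve within its evaluation budget returns
  its best point flagged `converged = FALSE` rather than erroring, matching
  the manual-follow-up workflow.
* **Sessions.** Every CLI fit appends one row to an append-only session
  log (angles in degrees, MD5 content fingerprints of the input files).
  Replaying the last row in mode `fixed` must reproduce the logged loss to
  $10^{-9}$ relative; whether the original fit normalised the spectra is
  recovered from the action tag (`fit` vs `fit_raw`).

## Problem sizes in the test suite

Unit tests run on 512–2048-point grids; the end-to-end recovery and noise
studies use the full 4096-point demonstration conditions (one noiseless
full fit, twenty noisy full fits at the 3% regime, twenty spike-contaminated
proportion fits per loss). These sizes were chosen as the smallest grids on
which the sharp crystalline lines are still well resolved (several points
per half-width).

## Known limitations

* Exactly two templates; multi-form mixtures are out of scope.
* No baseline term in the model: baseline distortions alias into the
  proportion estimate.
* Local optimisation only — a severely wrong $\varphi_1$ start can converge
  to a local minimum; the seeded multistart option and the residual display
  are the mitigations.
* No standard errors on $\alpha_2$; uncertainty must come from calibration
  or replication.
* The automatic PH0 initialiser is a heuristic with a documented
  few-degree bias on dispersive data; it is a starting value, not an
  estimator.
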