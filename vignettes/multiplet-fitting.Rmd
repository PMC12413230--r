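---
title: "Multiplet-aware lineshape fitting: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplet-aware lineshape fitting: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipletfit)
```

## The model

A processed 1D NMR spectrum is a vector of intensities $a_i$ on a
chemical-shift grid $x_i$ (ppm). We model it as a sum of *signals*, each
the resonance of one nucleus (or equivalent group) split into a
first-order multiplet. A signal with chemical shift $x_s$, total
intensity $I$, width $lw$, Gaussian fraction $a$ and couplings
$J_1, \dots, J_m$ contributes

$$y(x) = I \sum_{c} w_c \left[ a\, e^{-(x - x_c)^2/(2\,lw^2)}
  + \frac{1-a}{1 + \left((x - x_c)/lw\right)^2} \right],
\qquad x_c = x_s + \sum_k o_{ck} J_k ,$$

where the offsets $o_{ck}$ are signed half-integer coefficients and the
weights $w_c$ are the binomial convolution of the splitting pattern,
normalized to $\sum_c w_c = 1$. Both shape terms equal 1 at the apex, so
a component's apex height is $I w_c$ whenever components are resolved,
and $I$ is the sum of component amplitudes. A doublet sits at
$x_s \pm J/2$; a triplet at $x_s - J, x_s, x_s + J$ with weights
¼, ½, ¼; a quadruplet at $x_s \pm J/2, \pm 3J/2$ with ⅛, ⅜, ⅜, ⅛; a
doublet of doublets at the four sign combinations of $\pm J_1/2 \pm
J_2/2$. Triplet and quadruplet weights are the standard weak-coupling
binomial ratios. Second-order (strong-coupling) distortions — "roofing",
asymmetric intensities — are deliberately out of scope: in their presence
the fitted intensities are first-order approximations.

### The width parameter

`lw` enters the Gaussian as a standard deviation ($2\,lw^2$ in the
exponent) and the Lorentzian as its half width at half maximum. These
are different conventions for "linewidth", so neither term's full width
at half maximum equals $2\,lw$ in general; to avoid ambiguity, outputs
report a numerically computed FWHM of the mixed profile alongside `lw`
(`peak_fwhm()`: $2\sqrt{2\ln 2}\,lw \approx 2.355\,lw$ for $a = 1$,
$2\,lw$ for $a = 0$). The analytic signal area is
$I\,lw\,(a\sqrt{2\pi} + (1-a)\pi)$.

### Units

All fitting happens on the ppm axis, so couplings are *internally* ppm;
they are reported in Hz as well whenever a spectrometer frequency (MHz)
is attached to the spectrum, since Hz is the field-independent,
conventional unit. One shared `lw` and `a` per signal: all components of
one multiplet share a relaxation environment.

## Parameters, defaults and bounds

Each model carries a spec table per parameter: default initial value,
bounds, and a *bound mode*. Absolute bounds are taken as-is (the Gaussian
fraction: $[0, 1]$). Relative bounds resolve around the initial value at
initialization time, and the resolution rule follows the parameter's
geometry:

* position-like parameters (`x0`, couplings, ppm): the bound numbers are
  signed ppm offsets added to the init (default ±0.05 ppm). A
  multiplicative rule would make the allowed wander depend on the ppm
  origin, which is physically meaningless.
* scale-like parameters (`I`, `lw`): multiplicative factors (defaults
  ×0.01…×100 for `I`, ×0.1…×10 for `lw`), because their natural error is
  relative.

Couplings are additionally floored at 0 — this removes the $J \mapsto
-J$ reflection degeneracy — and `I` at 0 unless a signal opts into
negative intensities (difference spectra). Initialization from a peak
list takes `x0` as the centre of the member peak positions, `I` as the
sum of apex intensities (weights sum to 1), and solves the couplings
from the peak positions by least squares against the pattern's offset
coefficients, which reproduces the obvious rules (doublet: the position
difference; doublet of doublets: half-sums and half-differences of the
pair spacings) and generalizes to user patterns. The linewidth starts
from the median measured half-height width when the peaks are resolved,
else from the model default, else `region span / (20 n_peaks)`.

## Peak picking

Local maxima (strict; plateaus resolve to their centre point) are kept if
both their height *and* their topographic prominence exceed the
threshold. The prominence condition matters on noisy flanks of real
peaks, where noise wiggles form local maxima whose absolute height passes
any reasonable threshold. The auto threshold is $k\,\hat\sigma$ with $k =
5$ and $\hat\sigma$ the MAD estimate ($1.4826 \times$ median absolute
deviation) over the outer 10% of region samples on each side — robust as
long as the region edges are mostly baseline. For signals filling their
whole region, pass an explicit threshold.

## Optimization

The cost $c(p) = \sum_i (a_i - y_i(p))^2$ is minimized with L-BFGS-B
under the resolved bounds. Numerical choices that matter:

* parameters are rescaled to the unit bound box, so the optimizer sees
  comparable magnitudes regardless of units (ppm vs intensity);
* the cost is normalized by $\sum_i a_i^2$ inside the optimizer, making
  the relative-reduction stopping rule (`factr = 100`, i.e. ~1e-14
  relative) scale-invariant across spectra;
* gradients are forward finite differences (step 1e-8 on the unit box).
  Models only promise a simulate contract, so analytic gradients are not
  assumed; an L-BFGS-B memory of 20 compensates (a pilot on the
  noiseless two-multiplet problem: relative error 1.4e-4 in 632
  evaluations at the default memory 5, versus 3e-8 in 94 evaluations at
  memory 20);
* a second L-BFGS-B run polishes from the first optimum. If the polish
  makes no relative progress the point is stationary, and a line-search
  abort there (a known artifact of finite-difference gradients at the
  noise floor) is reported as convergence;
* the reported solution never has higher cost than the initialization —
  if the optimizer fails to improve, the initial point is returned and
  flagged, so monotone improvement holds unconditionally;
* optional global refinement: a small differential-evolution search
  (rand/1/bin, population $15k$, 200 generations, F = 0.8, CR = 0.9) on
  the unit box, seeded from the fit options, whose best point seeds the
  descent. Off by default — it multiplies cost evaluations by orders of
  magnitude and is needed only when initializations may be out of basin
  (the batch pipeline turns it on automatically when retrying a failed
  row). With a fixed seed the whole fit is bit-reproducible.

## Uncertainties

Standard deviations come from the standard nonlinear-least-squares
covariance estimate $s^2 (J^\top J)^{-1}$, with $J$ the finite-difference
residual Jacobian at the optimum (relative step 1e-6, stepping backwards
at an active bound) and $s^2 = c(\hat p)/(n - k)$ estimated from the
residuals themselves — no separate noise region is required. Exports
provide both the sd and a 95% normal-approximation interval
($\pm 1.96\,\mathrm{sd}$), labelled as such. Parameters sitting at an
active bound are flagged: curvature there does not reflect sampling
variance. A singular $J^\top J$ (unidentifiable parameters, e.g. two
signals modelling one peak) falls back to a pseudo-inverse and is
flagged rather than prevented — overlapping signals sharing a peak are a
supported modelling idiom, and identifiability problems are supposed to
surface as large uncertainties.

## Batch fitting of pseudo-2D series

The reference row is fitted first, then rows are visited outward
(`ref+1…n`, then `ref−1…1`). In the default `prev` mode each row starts
from its already-fitted neighbour, which tracks smooth drifts; `ref` mode
restarts every row from the reference, for series with abrupt jumps.
Relative bounds travel with the propagated inits (they are re-resolved
around each row's starting values), so a slowly drifting peak never walks
out of its box, while absolute bounds stay fixed. A row that fails is
retried once from the reference with global refinement on, then recorded
as failed; later rows fall back to the reference initialization, so one
bad row cannot poison the rest of the series.

## The synthetic bench: what a green test establishes

The generator produces spectra by simulating the model and adding i.i.d.
Gaussian noise (SNR defined as max noiseless intensity over noise sd),
seeded and bit-reproducible. It emulates thermal noise after Fourier
transform on a perfectly processed spectrum. It does **not** emulate
baseline roll, phase errors, solvent tails, lineshape distortions from
shimming, or correlated noise — so green recovery tests establish
correctness of the estimator under its own assumptions, not robustness to
pre-processing failures (which the underlying workflow explicitly assumes
are handled beforehand).

Fixture worlds, chosen once:

* *two-multiplet validation design*: a 1:2:1 triplet ($I = 1.0$,
  $J = 0.03$ ppm) and a 1:3:3:1 quartet ($I = 0.8$, $J = 0.02$ ppm),
  $lw = 0.004$ ppm, $a = 0.5$, centres `gap_lw` linewidths apart on a
  2048-point grid — the default gap of 20 linewidths is "well separated"
  (tails still overlap), 5 is heavy overlap; the recovery experiment
  crosses gaps {20, 10, 5} with SNR {∞, 100, 50, 20};
* *isotopologue fixture*: four co-located methyl signals (singlet;
  doublet with a 6 Hz two-bond coupling; doublet with a 127 Hz one-bond
  coupling; doublet of doublets with both) at 500 MHz, fractions
  0.05/0.10/0.75/0.10 — a mid-exchange state of a labeling experiment
  where the provided labeled form still dominates;
* *kinetic series*: linear chemical-shift drift and exponential intensity
  decay, plus a closed-form three-step cascade
  (substrate → two intermediates → product) for coupled trajectories.

Starting values for recovery experiments perturb the truth by 10%
multiplicatively for `I`, `lw`, `a`. For position-like parameters a
*relative* perturbation is not meaningful: 10% of a chemical shift is
dozens of linewidths (and depends on the arbitrary ppm origin), which no
real initialization produces — peak-picked positions are accurate to a
grid step. The perturbation is therefore 10% of five linewidths for
`x0`, and coupling shifts are capped at two linewidths. This emulates
realistic peak-list error while still starting well away from the
optimum.

### The multiplet-vs-individual-peaks comparison

Two readings of "fitting individual peaks" exist. Fitting the two
doublet components as a *joint* sum of two unconstrained singlets turns
out to be statistically equivalent for the coupling: across 100 paired
replicates at every overlap level we tried (J from 2.5 to 7.5
linewidths), the joint-singlet J estimates correlate with the doublet
model's at r = 0.998 and win half the pairs. The reason is structural:
position derivatives are antisymmetric about each peak while
width/height derivatives are symmetric, so the extra freedom barely
couples into the position difference. The comparison implemented here is
the one that distinguishes real tools: each component fitted
*independently*, alone in its own half-region, with the neighbour's tail
unmodelled — the behaviour of software that treats every peak as an
independent signal. The unmodelled tail biases both the positions
(apparent attraction) and the intensities, and the constrained multiplet
fit wins the paired comparison decisively (100% of pairs at
$J = 5\,lw$, SNR 50 in the pilot; the acceptance criterion asserts
≥ 80%).

### Uncertainty calibration at 20 replicates

The acceptance suite compares reported sds with the replicate-ensemble
sd. With 20 replicates, the ensemble sd itself carries roughly ±35%
sampling error at 95% confidence, so a per-parameter 30% check would
mostly measure that sampling noise. The suite therefore asserts the
*median* ratio across the four headline quantities (both couplings, both
intensities) to be within 30% — a calibration test rather than a
chi-square lottery. The per-parameter ratios are still computed and
reported by `recovery_experiment()`.

## File formats and reproducibility

* **Bruker processed data**: `pdata/<procno>/1r` (1D) and `2rr`
  (pseudo-2D) as int32 scaled by $2^{NC\_proc}$, axis reconstructed as
  $\mathrm{ppm}_i = \mathrm{OFFSET} - i\,\mathrm{SW\_p}/(\mathrm{SF}\cdot
  \mathrm{SI})$. Submatrix-blocked 2D layouts and float processed data
  are not supported; the package's own `write_bruker()` emits the
  supported subset and is used for fixtures (integer quantization bounds
  the intensity round-trip error at about $2^{-28}$ relative).
* **Text spectra**: ppm column plus one intensity column per row;
  delimiter auto-detected; descending axes normalized to ascending;
  writes are full-double-precision and byte-stable.
* **Sessions**: a versioned JSON archive (not a language-native binary
  serialization, which does not survive language versions and cannot be
  inspected); doubles are serialized at 17 significant digits, which
  round-trips IEEE doubles exactly, so re-exported CSVs are
  byte-identical after reload. Loading a newer schema version fails with
  an explicit message. Pseudo-2D row labels default to the acquisition
  index; a time vector, if wanted, is supplied by the user.

## Known limitations

* First-order multiplets only; no Voigt-by-convolution profile (the
  pseudo-Voigt approximation is standard for quantitative work).
* One linewidth per signal. Per-peak linewidths exist only in the
  individual-peak comparison mode of the bench.
* No baseline or phase model: spectra must be pre-processed.
* The covariance-based sd assumes approximately Gaussian residuals and a
  locally quadratic cost; at active bounds or near-degenerate overlaps it
  is flagged rather than corrected.
* Batch fitting is sequential by contract (previous-row propagation);
  rows are not fitted in parallel.
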