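---
title: "Methods: robust strip reading, from camera screening to inverse prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust strip reading, from camera screening to inverse prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

`lfaquant` treats a lateral-flow strip reader as a measurement system to
be *designed*, not just used: first make the acquisition chain behave
(orthogonal-array screening of camera parameters under the dynamic S/N
statistic), then calibrate grayscale against concentration and invert.
This vignette records the models, the defaults and their units, the
numerical conventions, and the design choices that were genuinely open.

## 1. The dynamic characteristic

A reader should report a measured grayscale $y$ proportional to the
true reference grayscale $M$ with slope near one. Each screening run
measures the five reference levels $M = (247, 249, 251, 253, 255)$ —
deliberately placed in the faint-line regime where a strip reader earns
its keep — and is scored by

$$\mathrm{S/N} = -10\log_{10}\!\frac{S_d^2}{\beta^2}, \qquad
\beta = \frac{\sum M_i y_i}{\sum M_i^2}, \qquad
S_d = \sqrt{\frac{\sum (y_i - \beta M_i)^2}{n-1}},$$

a larger-the-better quantity in decibels. Conventions, each of which the
data source leaves open:

* **Through-origin regression.** A zero reference must read zero, so the
  slope is the zero-point-proportional estimator — the standard dynamic
  characteristic. An ordinary intercept fit is available behind
  `fit_dynamic(method = "intercept")` for diagnosing offset drift.
* **$n-1$ divisor** for $S_d$ (one parameter fitted).
* **Base-10 logarithm**, the dB convention.
* **Signal normalization.** `run_responses()` divides both $M$ and $y$
  by 255 before fitting. This matters: joint rescaling of the signals
  leaves $\beta$ unchanged but scales $S_d$, shifting the S/N by
  $-20\log_{10}c$ (+48.13 dB for $c = 1/255$). Reference S/N values in
  the 43–53 dB range are only meaningful on the normalized 0–1 scale,
  so that is the default; `normalize = FALSE` gives the raw-scale
  value, 48.13 dB lower.
* **Perfect fits.** $S_d = 0$ is reported as `Inf` — an explicit
  unbounded-S/N outcome rather than an arbitrary large number; a zero
  slope is an error.

## 2. Screening designs and their analysis

The catalogue holds L4, L8 and the 12-run Plackett–Burman L12
(cyclic-generator construction), selected as the smallest array with
enough columns. Balance and pairwise orthogonality are checked
exhaustively in the test suite, not assumed.

**Response table.** Per column: level means, effect (level-2 mean minus
level-1 mean), range (absolute effect), rank by descending range with
ties broken by column order. For a balanced design the mean of the two
level means equals the grand mean in every column — a structural
identity the tests enforce to 1e-9.

**ANOVA.** Each two-level column carries one degree of freedom with
$SS = (n/4)\,\mathrm{effect}^2$; the column SS decompose the total SS
about the grand mean exactly. The error term pools (i) every unassigned
column — a spare column is the cheapest honest noise estimate — plus
(ii) any factor whose range falls below the largest unassigned-column
range, plus (iii) a top-up of the smallest-range factors until the error
has at least `min_error_df = 2` degrees of freedom. The top-up is part
of the default because a single error degree of freedom makes the F test
essentially powerless (the 95% critical value for F(1,1) is 161). On
pure-noise inputs the rule could pool everything; the strongest assigned
factor is then kept testable. Confidence is $100(1-p)$ from the upper
tail of F at (1, error df); factors pass the screen when confidence
strictly exceeds the threshold (default 95%).

**Interactions.** `interaction_cells()` crosses two columns into a 2×2
table of cell means (each cell holds exactly $n/4$ runs) and reports the
non-parallelism $|(m_{22}-m_{21})-(m_{12}-m_{11})|$, zero iff the
profiles are parallel. For L12 the function *always* warns: in a
Plackett–Burman design two-factor interactions are partially confounded
with every other column, so cell means are screening evidence only. The
documented remedy is a dedicated 2×2 full-factorial follow-up — the
route the reference study itself took for its backlight × sharpness
interaction, re-levelling sharpness before concluding.

**Optimal levels.** The selection rule is baseline-preserving: only
factors that pass the ANOVA screen move to their better level; everything
else keeps its baseline setting, minimizing gratuitous change to a
working instrument. The predicted S/N is the additive estimate
$\bar{T} + \sum_{\text{significant}} (\bar{m}_{\text{chosen}} - \bar{T})$.

## 3. Densitometry

The image path is deliberately plain: BT.601 luma conversion
($0.299R + 0.587G + 0.114B$, rounded half-up), per-row averaging across
the lane width into a longitudinal profile, and band calling as maximal
runs dipping at least `min_depth` below background. The background is
the median of non-band rows, estimated in two passes (whole-profile
median, then median excluding provisional band rows). Roles follow
position: the band toward the absorbent-pad end is the control line
(orientation configurable). A strip with no control band is invalid and
yields no concentration.

Defaults and why:

* `min_depth = 5` grayscale units. The profile averages ~60 pixels per
  row, so its noise is ~0.15 units and 5 units is a very conservative
  call; at the same time the test line at the 6.25 mIU/mL detection
  limit dips ~10 units, leaving a 2× margin so strips at the claimed
  limit are not dropped.
* Band `center` is the midpoint of the called extent. For flat-topped
  bands the deepest pixel is noise-selected anywhere in the band; the
  midpoint is stable to ±1 row.
* **Polarity.** A darker line means *more* analyte but *lower* raw
  grayscale. The package reports both the raw test-band mean and the
  background-corrected net signal (background − band mean) and defaults
  to the net signal, which increases with concentration; calibration
  accepts either monotone orientation.
* The lane is supplied in configuration, not auto-located: the physical
  carrier of a reader fixes strip position, so auto-registration is out
  of scope.

## 4. Calibration and inverse prediction

Classical calibration: signal is regressed on concentration by OLS
(`signal ~ concentration`), $R^2 = 1 - SS_{res}/SS_{tot}$, residual SD
with $n-2$ divisor, and unknowns are quantified by algebraic inversion
$(s - b_0)/b_1$ with an in-range flag against the fitted concentration
span (6.25–50 mIU/mL by default; estimates outside it are flagged
extrapolations). The model is linear in concentration, matching the
observed straight-line response over the working range; a
log-concentration variant exists behind an option but is off by default.
A flat signal (zero slope) produces a rejected, non-invertible model
rather than silent nonsense. Precision is summarized per level as
$CV = 100\,\mathrm{sd}/\mathrm{mean}$ of the *back-calculated*
concentrations — the denominator convention chosen because it is the
quantity a user of the reader experiences — plus the percent error of
the mean estimate against nominal. The concentration ladder is
standardized on (6.25, 12.5, 25, 37.5, 50) mIU/mL, bracketing the 25
mIU/mL assay cut-off with two-fold steps.

## 5. The synthetic generator: what it does and does not emulate

`render_strip()` draws a light membrane (default luma 200), a control
band (depth 60) and a test band whose depth is linear in concentration,
$80 \cdot \min(c/50, 1)$ — zero at blank, clamped above 50 mIU/mL as a
crude stand-in for hook saturation. Bands are reddish (colloidal gold):
channel drops are weighted so the *luma* drop equals the nominal depth
exactly, which gives the noiseless closed-form render its exact
pixel-value contract. Two noise sources:

* `noise_sd = 1` grayscale unit of per-pixel Gaussian noise — camera
  shot/read noise. Averaged over a band ROI this contributes almost
  nothing to replicate scatter.
* `depth_cv = 0.04` relative SD on realized band depth — strip-to-strip
  line-intensity variability of a manufactured lot, the component that
  actually limits replicate precision. 4% is a realistic figure for an
  optimized LFA and places the synthetic study's per-level CVs in the
  mid-single digits, comfortably inside the sub-10% regime a usable
  reader must reach.

The camera pipeline applies, in a fixed documented order: exposure →
gain → brightness → contrast (pivot at mid-gray 127.5) → gamma → white
balance (temperature-based R/B gains; "Auto" is neutral) →
hue/saturation (YIQ rotation/chroma scale) → sharpness (3×3 unsharp
mask, strength 0.1·k) → backlight compensation (highlight knee above
240), then clips to [0, 255] and quantizes half-up. Neutral defaults
make the pipeline an exact identity, which anchors the generator's
closed-form test cases.

**Simulated screenings.** `simulate_run_sn()` draws run S/N directly
from a declared effect model (additive ±effect/2 per column, optional
product interactions, Gaussian run noise, default 0.5 dB) — the fast
route for replicated recovery studies. `simulate_l12()` additionally
*renders* the five reference patches per run and measures them
densitometrically; the target S/N is translated into a residual vector
realized exactly (slope held at 1), so the measurement chain (pixel
noise, 8-bit quantization, ROI averaging) is exercised while the
declared effects remain the exact ground truth. Camera transforms are
held neutral in this simulation on purpose: driving them physically
would create effects of unknowable size and destroy the ground-truth
contract that recovery tests rely on. The default effect model injects
the three influential parameters at +3.15, −7.36 and +3.87 dB — the
effect pattern of the reference screening — and leaves the other seven
inert.

**What passing tests therefore show — and not.** They show the
*analysis chain* is correct: orthogonality, exact reconstruction,
ANOVA decomposition, recovery of known injected effects, calibration
round trips, precision arithmetic. They do not show that a particular
physical camera obeys an additive dB effect model, that real membranes
have flat-topped uniform bands, or that real inter-strip variability is
4% — illumination fields, membrane texture, flow artefacts and hook
effects beyond the clamp are all outside the generator.

## 6. Study sizes and determinism

The shipped studies are desk-scale by design: 5 levels × 3 replicates
for calibration (per-strip seeds increment from the study seed), 100
seeded repetitions for factor recovery, 1000 random instances for the
fit-oracle comparison, 100 strips for band-center recovery. Every
simulation-facing function takes an explicit seed and restores the
caller's RNG state; identical seeds give bit-identical images and
tables.

## 7. Known limitations

* Two-level designs only; no 3-level or mixed arrays, no inner/outer
  noise arrays, no static S/N variants.
* The L12 interaction caveat is a warning, not a prohibition — the
  package will happily compute confounded cell means if asked.
* Densitometry assumes a fixed lane and a roughly uniform background;
  no illumination flattening, perspective correction or color-card
  normalization.
* Calibration is strictly linear (optionally log-linear); no 4PL/5PL
  sigmoid, no blank-based 3σ LOD machinery — the working range is the
  fitted standards' span.
* The confirmation S/N summaries shipped as data are five-replicate
  averages; per-run values are not recoverable from them, so the
  dynamic formula evaluated at the summary slope and spread need not
  equal the summary S/N exactly.
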