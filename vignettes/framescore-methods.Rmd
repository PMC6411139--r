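---
title: "Quality-based frame scoring and selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-based frame scoring and selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fluorescence intravital microscopy of moving tissue — the beating heart is
the canonical case — produces image stacks in which sharp, analysable frames
alternate with blurred or out-of-focus ones. Manual triage does not scale to
thousands of frames, reference-frame methods require per-stack operator
input and make binary decisions, and naive quality filtering destroys the
chronology of the record. `framescore` addresses all three: it *learns* what
the user means by quality from a small scored sample, scores every frame,
and offers a selection mode that preserves macro-chronology.

## The scoring model

Each frame is summarised by eleven statistics computed on the pixel grey
values treated as a population: the number of unique grey values, mean,
maximum, population standard deviation, population skewness (Fisher–Pearson
coefficient \(m_3/m_2^{3/2}\)), population excess kurtosis
(\(m_4/m_2^2-3\)), Shannon entropy of the exact grey-level histogram in
bits, integrated density \(\sum I(x,y)\), sum of squares
\(\sum I(x,y)^2\), and two custom statistics described below.

Given manual scores \(S_{ip}\in[0,5]\) for a training subset, the package
fits an ordinary least-squares model

\[ y_i = \beta_0 + \beta_1 X_{i1} + \dots + \beta_n X_{in}, \]

with the statistics as explanatory variables and the manual score as the
dependent variable, and then applies the fitted coefficients to every frame
to obtain calculated scores \(S_{ic}\). Scores are deliberately never
clamped: out-of-range values (below 0, above 5) are informative and occur in
practice; `range_adjust()` provides the optional affine map
\((C_i - C_{\min})/(C_{\max} - C_{\min})\times 5\) when a 0–5 range is
required, e.g. after applying coefficients transferred from another stack.

Agreement with human scoring is quantified by the Pearson correlation
(primarily on the frames *not* used for training), the mean absolute
distance \(d_i = |S_{ip} - S_{ic}|\), and conventional verbal strength
bands on \(|r|\) (very weak < .20 ≤ weak < .40 ≤ moderate < .60 ≤ strong
< .80 ≤ very strong).

## The two custom statistics

**Sum pixel ramp** is a stepped vertical-gradient sharpness proxy: the sum
of \(|I(x,y) - I(x,y-p)|\) over a sampling lattice with stride equal to the
comparison offset \(p\) (the *pixel step*, default 3) in both axes, with the
first sampled row at \(y=p\) so every comparison partner stays inside the
frame, and the first sampled column at \(x=0\). Bright cells on a dark
background have a crisp intensity interface at their edge; defocus flattens
that interface and lowers the statistic.

**Segment intensity deviation (SID)** measures illumination/focus
uniformity: the frame is partitioned into a rectangular grid of segments
(default 4×4; remainder rows/columns are absorbed into the last segment),
the sampled intensities of each segment are summed, and the population
standard deviation of the segment values is returned. A perfectly uniform
frame scores 0; partial focus or uneven illumination raises the value.

**Normalization.** Both custom statistics are sums, so their raw magnitude
scales with the number of sampled pixels and therefore falls roughly as
\(1/p^2\) as the pixel step grows. With `normalize = TRUE` (the default)
the ramp is divided by the number of comparisons and each SID segment sum by
that segment's sampled count, which removes the count dependence and also
neutralises unequal segment sizes. The flag is stored in saved coefficient
files so training and scoring cannot silently disagree. Two limits of
normalization are worth knowing:

* Exact zero SID on a uniform image for *arbitrary* grids holds in
  normalized mode. Raw segment sums differ on a uniform image whenever the
  sampling lattice gives segments unequal counts (the first sampled row is
  \(y=p\), so row counts are rarely balanced); normalization is what makes
  the zero law grid-independent.
* Normalization removes the *count* dependence, not the *offset*
  dependence. The per-comparison magnitude of the ramp still grows with
  \(p\) for high-contrast sharp edges (along a monotone edge profile the
  summed differences telescope to the total rise, while the comparison
  count falls). In noise-limited captures — dim fluorescence with
  substantial read noise, optics that never deliver pixel-sharp edges —
  the noise floor dominates the per-comparison magnitude and the normalized
  means are essentially independent of the step. The package therefore
  demonstrates step-consistency on the low-light population
  (`low_snr_population()`), which is the regime the normalization claim is
  about.
* Normalized SID carries a second, smaller step effect: at large steps each
  segment's mean is estimated from few sampled pixels (a 4×4 grid on a
  256×256 frame at step 5 leaves ~170 pixels per segment), and that
  sampling noise adds in quadrature to the true across-segment deviation,
  mildly inflating SID. Consistency across steps is therefore good but not
  exact; very coarse steps combined with fine grids should be avoided.

## Automated variable selection

In automated mode the package starts from all eleven statistics and applies
backward elimination: fit, and while any coefficient has \(p > 0.05\),
tentatively remove the variable with the highest p-value and refit; if the
refit's adjusted \(R^2\) is *lower* than before the removal, the variable
is returned to the model and the process stops; otherwise the removal is
accepted. If removal would leave no variables, the procedure fails
explicitly and asks for user intervention. Details fixed by design:

* p-values are classical two-sided OLS t-tests with \(n-k-1\) degrees of
  freedom; the significance threshold is 0.05.
* "falls" is read literally: a tie in adjusted \(R^2\) counts as
  not-fallen and the removal stands.
* Ties on the maximal p-value remove the variable that comes *later* in the
  canonical statistics order (the CSV column order), for determinism.
* A consequence of the stop rule worth knowing: removing any variable with
  \(|t|>1\) lowers adjusted \(R^2\), so the final model may legitimately
  retain variables with p-values between 0.05 and ≈0.32. The procedure is
  conservative by construction, which is also why it should be used with
  operator oversight on real data.
* Predictors are standardized internally for numerical stability;
  coefficients are reported on the original scale.
* Exactly collinear predictors are dropped with a warning naming them
  before the elimination loop starts. On fixed-size stacks
  `integrated_density` (= mean × pixel count) is exactly collinear with
  `mean` and is always the one dropped; this is expected, not an error.

This elimination rule is implemented in the package itself rather than via
`stats::step()`, whose AIC criterion is a different procedure.

## Frame selection

Two modes reduce a scored stack:

* **QA (quality alone)** retains every frame with
  \(S_{ic} \ge\) cutoff. The comparison is inclusive: frames *below* the
  cutoff are removed, so a frame exactly at the cutoff is kept. Long poor
  stretches can leave large temporal gaps.
* **FW (frame windowing)** partitions the stack into consecutive windows of
  length \(n\) and keeps the single best-scoring frame per window (ties go
  to the earliest frame; the trailing partial window is kept rather than
  silently truncating the record). Consecutive retained frames are then
  never more than \(2n-1\) apart, which is the chronology guarantee.
* The **minimum window size** scan finds the smallest \(n\), searched in
  increments of 1 up to 25% of the stack length (`floor(0.25 N)`, minimum
  1), such that every window contains at least one frame meeting a quality
  target; "not found" is reported as `NA`, a value rather than an error.

## The synthetic study conditions

Real intravital stacks with multi-rater human scores are not shippable, so
the package carries a generator whose output drives all tests and the
acceptance script. Each frame is a dark background plus randomly placed
bright disks (count, positions and radii redrawn per frame, emulating
circulating labelled cells), Gaussian-blurred with a per-frame defocus
sigma, plus Gaussian read noise, clipped and rounded to the bit depth.
Ground-truth quality is \(5(1-\sigma/\sigma_{\max})\) and the simulated
human score adds \(N(0, 0.35)\) score noise, rounds, and clips to 0..5 —
roughly the inter-rater spread of a small volunteer panel.

The **standard benchmark** (`standard_benchmark()`) is 200 frames of
256×256 16-bit: 20–24 cells of radius 5–8 px at intensity 30 000 on
background 2 000 with read noise sd 600; defocus sigma up to 4 px follows a
"runs" profile — alternating stretches (lengths 5 + Poisson(4)) of good
frames (\(\sigma \le 0.8\)) and poor frames (\(\sigma \ge 2.8\)) — which
mimics the bursts of usable frames between contractions. The cell-count
spread is kept narrow (±9%) so that the variance of the sharpness statistic
is dominated by defocus rather than by how many cells happen to be in view;
with this geometry the rank correlation between blur sigma and sum pixel
ramp is ≤ −0.8 (a design contract of the generator, verified in the test
suite across seeds).

The **low-light population** (`low_snr_population()`) is 50 frames with
cell intensity 8 000, read noise sd 1 500 and optical blur sigma uniform on
[1, 4] px — a dim, noise-limited capture in which no edge is pixel-sharp.
This is the population used to demonstrate pixel-step consistency of the
normalized statistics. The `blur_sigma_min` parameter exists precisely to
express this optical resolution floor.

What the generator does *not* emulate: in-frame motion shear or
displacement (defocus blur is the surrogate for degradation, because
displacement without blur barely moves per-frame statistics),
photobleaching, vessel geometry, or spatially structured illumination.
Passing tests on synthetic stacks therefore show that the machinery is
correct and that the method works when frame statistics do track quality;
they cannot show how well any particular real preparation satisfies that
premise.

## Numerical and interface conventions

* Coordinates are 0-based, x = column, y = row; frame indices are 0-based
  in all files and messages.
* Constant frames have skewness and kurtosis defined as 0 (zero-variance
  convention) so they remain scoreable; kurtosis is the excess form
  (normal → 0); entropy uses the exact integer histogram, no binning. The
  conventions travel inside saved model files.
* Grey values are used raw, never rescaled to [0, 1]; the bit depth is
  recorded so cross-depth coefficient transfer can be warned about.
* Degenerate score ranges in `range_adjust()` map to all-zero with a
  warning rather than an error, so pipelines continue.
* Directory stacks are read in lexicographic filename order (zero-pad
  numeric names); this is documented loudly because silent natural-order
  assumptions are a classic source of frame mix-ups.
* A saved model file records the statistics configuration and is refused on
  version or schema mismatch; scoring statistics computed under a different
  configuration than the model was trained with produces a warning.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the 200-frame benchmark (fitting on 20 and 60 scored frames, scoring all
200), the 50-frame low-light population for the step-consistency check,
150+ random small frames (≤ 8×8) for exact brute-force equivalence of the
custom statistics, and ~1 000 random score vectors for the windowing
properties. These sizes mirror the scale of the original use case (stacks
of a few hundred frames, training samples of 14–62) while keeping a full
run in tens of seconds.

## Known limitations

* The method presumes a roughly linear statistics→quality relationship
  within a stack; strongly nonlinear quality criteria (e.g. "usable only if
  a specific structure is visible") are outside its reach.
* Backward elimination under multicollinearity can discard variables an
  experimenter knows to matter; automated mode is a convenience, not a
  substitute for inspecting the retained model.
* Coefficients transfer between stacks only as well as the underlying
  imaging conditions match; range adjustment fixes the scale, not the
  ordering, of transferred scores.
* No regularized regression, no orthogonalization of collinear predictors,
  and no forward/bidirectional stepwise — deliberate scope limits.
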