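---
title: "Analysing two-person imitation kinematics with imikin"
author: "imikin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing two-person imitation kinematics with imikin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imikin)
```

# The analysis problem

In a two-person imitation experiment a confederate actor performs meaningful
or meaningless hand and finger gestures, a participant imitates them, and
both are motion-tracked (8 electromagnetic trackers per person — shoulder,
elbow, wrist and the five digit tips — each recording x/y/z position and
three orientation angles at 240 Hz). Repetitive transcranial magnetic
stimulation (rTMS) is applied over the ventral premotor cortex (PMv), the
dorsal premotor cortex (PMd) or a vertex control site, during either action
observation or imitation. The questions are kinematic: does stimulation
change how fast the imitator moves (peak velocity, acceleration,
deceleration of the digits), and does it change how well the imitator's
velocity profile matches the actor's?

`imikin` implements the full analysis chain for this design: artifact-robust
preprocessing of the tracker signals, segmentation of the primary movement,
imitation-accuracy scoring by correlation of normalized velocity curves,
cluster-length permutation inference on sample-wise paired-t time-series,
finger–thumb opposition task metrics, and fully-within repeated-measures
ANOVA. Because no public recording of this kind is available, the package
also contains a first-class synthetic-data generator with known ground
truth; every stage of the pipeline is validated against it.

# The synthetic movement model

## Beta-profile reaches

The canonical smooth reach is the minimum-jerk trajectory,
$x(\tau) = x_0 + D\,(10\tau^3 - 15\tau^4 + 6\tau^5)$ on normalized time
$\tau \in [0,1]$, whose speed is the bell
$v(\tau) = \frac{D}{T}\,30\,\tau^2(1-\tau)^2$ with peak $1.875\,D/T$ at
$\tau = 1/2$. The generator works in the slightly larger Beta family

$$v(\tau) = \frac{D}{T}\,\mathrm{dbeta}(\tau; a, b), \qquad
  x(\tau) = x_0 + D\,\mathrm{pbeta}(\tau; a, b),$$

which reduces to minimum jerk exactly at $a = b = 3$
(`dbeta(tau, 3, 3)` $= 30\tau^2(1-\tau)^2$). These closed forms give the
oracle values used throughout the test suite (analytic threshold crossings,
peak speed $1.875\,D/T$, exact positions).

```{r}
tau <- seq(0, 1, length.out = 7)
all.equal(minjerk_speed(tau), dbeta(tau, 3, 3))
```

## Condition effects reshape, not rescale

A subtlety of this pipeline is that the accuracy and cluster analyses
operate on speed curves that are resampled to 120 samples over the movement
and divided by their maximum. Any *self-similar* change — a faster movement
of proportionally larger amplitude, or the same path covered in less time —
produces an identical normalized curve and is therefore invisible
downstream. A condition that raises peak velocity at fixed amplitude and
duration must change the *shape* of the profile. `imikin` realizes a
peak-velocity factor $f > 1$ by skewing the Beta profile
($a = 3$, $b > 3$ solving $\mathrm{peak} = 1.875 f$): the peak rises by $f$
and moves earlier, lengthening the deceleration phase — the standard
kinematic signature of faster reaching. On normalized curves this produces
differences concentrated around the peak-velocity period, which is exactly
where the cluster test is expected to find supra-threshold runs.

## Actor–imitator coupling

The imitator's curve shares the actor's canonical profile; each person
additionally receives an independent smooth perturbation. If the common
profile has variance $V_b$ across the 120-sample grid and the perturbations
have variance $\varepsilon^2$, the expected Pearson correlation of the two
curves is the attenuation ratio

$$r = \frac{V_b}{V_b + \varepsilon^2}
  \quad\Longrightarrow\quad
  \varepsilon^2 = V_b\,\frac{1 - r}{r},$$

so a requested coupling is hit in expectation by choosing $\varepsilon$.
Three implementation constraints make the closed form hold in-sample rather
than only asymptotically: the perturbation (a 4-component sine series) is
(i) confined to the middle 80% of the supra-threshold segment, so the
12 cm/s threshold crossings that delimit the movement are identical for
every realization; (ii) constrained to zero in-sample covariance with the
canonical profile; and (iii) normalized to exactly unit variance across the
grid (a covariance-metric normalization of the basis coefficients). Without
(ii) and (iii) the realized mean correlation is biased upward by the
sampling variability of the basis; without (i) the noise moves the
completion crossing along the shallow tail of the bell by tens of samples
and biases it downward.

## What the generator emulates, and what it does not

Emulated: the trial timeline (go tones 1000 ms after image onset, 2000 ms
holds, stimulation trains at 3 Hz for 3 s during observation from
image + 333 ms or during imitation from 1000 ms before the go tone), the
3-site × 2-time × 2-meaning × 2-effector condition structure with
counterbalanced site order and meaning-blocked sessions, single-sample
electromagnetic spikes (10 cm, Poisson-distributed), brief (8 ms, 15 cm)
stimulation-locked artifact transients in every channel, Gaussian sensor
jitter (0.02 cm s.d., the magnitude of electromagnetic-tracker
sample-to-sample noise), between-participant speed variation (log-normal,
8% s.d.), and the cyclic finger–thumb opposition task with known touch
times (index–middle–ring–little–ring–middle order, thumb lift arcs between
contacts).

Not emulated: orientation-angle dynamics (angles are carried and
round-tripped but constant within trial), biomechanical coupling between
trackers (each tracker moves along its own straight 3-D direction),
gesture-specific spatial form, EMG, and participant × condition
interactions beyond the injected effect map. Passing tests therefore show
that the *analysis chain* is correct and calibrated under known ground
truth — not that these models capture every property of real recordings.

# Preprocessing

Four cleaning stages run in a fixed order, each on every position axis:

1. **Spike removal** (`detect_spikes`, `repair_spikes`). A sample is a
   spike when its second difference (the double-differentiated series)
   deviates from the trial-and-axis mean by more than 3 s.d.; the second
   difference is computed per axis because that is the most sensitive
   reading of a per-trial criterion. Flagged samples are repaired by linear
   interpolation across 3 samples either side, anchored on the first clean
   samples beyond the window; overlapping windows merge rather than stack,
   and boundary windows clamp to the nearest valid anchor.
2. **Local-regression outliers** (`lowess_outliers`). A weighted linear
   least-squares fit (first-degree polynomial, tricube weights) over a
   5-sample moving window; residuals beyond 3 s.d. (configurable — the
   criterion is a package default, not a fixed claim) are repaired with the
   same interpolation rule. Axes whose residuals sit at numerical rounding
   level are skipped.
3. **Stimulation-artifact excision** (`excise_tms_artifacts`). All samples
   within 25 ms either side of each artifact onset (the pulse times) are
   removed, overlapping windows merged, and the gap filled with a cubic
   spline fitted to the remaining data (`stats::splinefun`, `"fmm"`), which
   reconstructs cubic paths exactly. The interpolation report gives
   per-period lengths, their total and the maximum run, in samples and in
   milliseconds (`ms = samples / fs * 1000`, rounded half away from zero:
   integers for single runs, 0.1 ms for means — at 240 Hz a 53-sample run
   is 221 ms).
4. **Zero-phase low-pass filtering** (`lowpass`). A fourth-order Butterworth
   design at 12 Hz applied forward and backward. The bidirectional pass is
   implemented with direct-form-II-transposed recursion, steady-state
   initial conditions and odd-reflection padding, so a constant signal
   passes through to within 1e-9 and the output has exactly zero phase; the
   two-pass amplitude response is the squared single-pass magnitude
   $|H(f)|^2 = (1 + (f/12)^{8})^{-1}$ per pass. Users matching a convention
   in which "fourth order" describes the combined response should halve the
   order.

# Segmentation, exclusions and peak parameters

3-D speed is the Euclidean norm of the position derivative (central
differences in the interior, one-sided at the edges — second-order accurate
with no phase shift). The **primary movement** runs from the first sample at
or above 12 cm/s to the first sample after the global speed peak strictly
below it; onset ties break earlier, completion ties later. Trials are
excluded, with a single reason assigned in fixed order, when

* `premature_start` — any imitator tracker crosses the movement threshold
  in the 500 ms before the imitator's go tone;
* `late_finish` — the primary movement has not completed within 200 ms of
  the return tone (judged on the fastest of the wrist and digit trackers);
* `overspeed` — any of the 16 trackers exceeds 250 cm/s anywhere.

Peak parameters (PV, PA, PD) are taken on the original, non-resampled
segment: PV is the maximum speed, acceleration is the derivative of speed,
PA its maximum and PD its minimum (reported negative). Digit-level summaries
average the five digit trackers per trial, then per participant per cell.

# Imitation accuracy

Per trial and tracker the actor and imitator speed segments are resampled
to 120 samples (linear interpolation, resample-then-normalize) and divided
by their maxima, and the Pearson correlation $r$ of the paired samples is
Fisher-transformed, $Z = \tfrac12 \ln\frac{1+r}{1-r} = \operatorname{atanh} r$,
before averaging within condition cells. Correlations of exactly $\pm 1$
are clipped to $1 - 10^{-7}$ in magnitude ($Z \approx 8.06$) so means stay
finite; zero-variance curves yield an undefined correlation and the record
is dropped with a warning. Note that $r$ itself is invariant to the
amplitude normalization — normalization matters for plotting and for the
cluster test's grand-mean curves, not for the correlation.

# Cluster-length permutation inference

For a paired contrast, each participant contributes a mean resampled curve
per cell; at each of the 120 samples a paired t across participants is
computed. Runs of consecutive samples with $|t|$ strictly above the
two-tailed critical value (2.201 for 12 participants at $\alpha = .05$) are
the candidate effects. Their lengths are referred to an empirical null: on
each of 10 000 iterations every participant's condition labels are
independently flipped (sign-flip of the paired differences, the canonical
exchangeable null for paired designs), the t series is recomputed exactly,
and the *maximum* run length is recorded — the maximum-statistic convention
that controls family-wise error across the 120 samples. Run p-values use
add-one smoothing, $p = (1 + \#\{\text{null} \ge \ell\})/(N + 1)$, bounded
below by $1/(N+1)$.

Significant runs are labelled by the phase of the grand-mean curve they
intersect. The "period covering PV" is the contiguous block of samples
within 10% of the curve maximum; samples before it are the acceleration
phase and samples after it the deceleration phase. A plateau rather than
the single argmax is used deliberately: on amplitude-normalized curves two
conditions agree exactly at their own peaks, so a shape difference yields
runs that approach but need not contain the argmax sample.

Two simulation studies validate the chain end to end (run by
`scripts/acceptance.R` and the acceptance tests):

* **Type-I calibration** (`cluster_type1_study`): 500 replicate null
  experiments, 12 participants × 8 trials per cell, 1000 permutations each;
  the proportion of replicates with any run at $p < .05$ estimates the
  family-wise false-positive rate (observed ≈ 0.044).
* **Effect recovery** (`effect_recovery_study`): 100 replicate experiments
  with a 15% digit peak-velocity effect injected in one cell
  (12 participants × 32 trials per cell); each replicate must show an
  elevated mean digit PV in that cell and a significant run overlapping the
  PV period. The problem sizes (8/32 trials per cell, 1000 permutations)
  are the package's validation choices; the per-contrast study default
  remains 10 000 permutations.

# Finger–thumb opposition task

The recording spans three half-open 5 s epochs (pre-stimulation,
stimulation, post-stimulation; a sample at exactly 5.000 s belongs to the
stimulation epoch), with the 3 Hz train delivering 15 pulses from 5.00 to
9.67 s. A touch is the distance minimum of a contiguous excursion of the
thumb–fingertip distance below 5 mm, with a 100 ms refractory gap keeping
the deeper of two close events; grouping by excursion (rather than taking
every local minimum) is what makes detection robust to sensor noise during
the ~100 ms contact dwell. Inter-touch intervals pool all digits into one
back-and-forth stream; each interval is assigned to the epoch containing
its later touch, and the s.d. uses the $n-1$ form. Epoch speeds are the
time-average of 3-D speed, with the four fingertips averaged into the
finger speed.

# Group statistics

`rm_anova` implements the classical sums-of-squares decomposition for
complete, balanced fully-within designs (one observation per subject ×
cell), by inclusion–exclusion over effect subsets with the effect × subject
interaction as each effect's error term; partial
$\eta^2 = SS_E / (SS_E + SS_{err})$. For effects with $\ge 2$ numerator
degrees of freedom, sphericity is tested with Mauchly's W and, when it
rejects at 0.05 (the conditional convention; `always`/`never` are
available), both degrees of freedom are multiplied by the
Greenhouse–Geisser $\hat\varepsilon$ computed from the covariance of
orthonormal contrast scores. The decomposition is cross-checked in the test
suite against `stats::aov` error strata and, for $\hat\varepsilon$ and
Mauchly, against `car::Anova`.

Post-hoc paired t-tests use Bonferroni control; the corrected $\alpha$ is
displayed rounded half away from zero to 4 decimals (0.05 over 8 trackers
displays as 0.0063). Effect sizes use Hedges'
$g_{rm} = \dfrac{m_1 - m_2}{\sqrt{s_1^2 + s_2^2 - 2 r s_1 s_2}}
\sqrt{2(1-r)}\; J(n-1)$ with $J(\nu) = 1 - 3/(4\nu - 1)$.

# Numerical choices and degenerate inputs

* Threshold comparisons: onset at $\ge$, completion at $<$; supra-threshold
  runs use strict $|t| >$ critical value.
* A paired-t sample with zero-variance differences is 0 when the mean
  difference is 0 and $\pm\infty$ otherwise; permutation t-series map
  non-finite values to 0 (they arise only in degenerate all-equal cells).
* An ANOVA effect with zero effect SS is reported as $F = 0$ even when the
  error SS also vanishes.
* Excision refuses windows covering > 90% of a trial and warns above 50%;
  onsets outside the trial are errors.
* Segments shorter than 2 samples cannot be resampled; zero-maximum
  segments raise a degenerate-curve error.
* All randomness derives from a single master seed through a deterministic
  multiplicative sub-seed scheme, so per-trial and per-permutation streams
  are independent of execution order.

# Known limitations

* The generator's trackers are kinematically independent; analyses that
  would exploit inter-tracker covariance (e.g. joint exclusion logic) see
  an unrealistically diagonal structure.
* Coupling below $V_b/(V_b + \varepsilon_{max}^2)$ cannot be represented by
  the shared-profile scheme (the canonical curve itself is common to both
  persons); couplings of 0 are rejected.
* The opposition task's absolute speeds depend on the chosen hand geometry
  and movement amplitudes and are not comparable to any particular
  laboratory's values; only the relative and inferential behaviour is
  validated.
* `rm_anova` requires complete balanced data; missing cells must be handled
  upstream (they are reported by `condition_means`).
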