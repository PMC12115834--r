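---
title: "Models and methods behind loomstrike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loomstrike}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomstrike)
```

loomstrike analyses how a perching fly's escape apparatus performs against
an aerial predator, along three linked axes: the visual stimulus (a looming
expansion), the predator's attack (3D kinematics from digitized high-speed
video), and the behavioural and fitness outcomes (take-off timing modes and
prey-survival competition indices). This vignette documents the models, the
tunable parameters, and the numerical and design decisions in enough detail
that a reader can judge what the package's passing tests do and do not
establish.

## The looming model

A dark disk that mimics an object of radius $r$ approaching at constant
speed $v$ subtends a visual angle

$$\theta(t) = 2\,\tan^{-1}\!\frac{r/v}{|t|},$$

where $t$ is time before (virtual) contact. The expansion profile depends on
$r$ and $v$ only through the size-to-speed ratio $r/v$ (ms): a large, fast
object and a small, slow one with equal $r/v$ are indistinguishable on the
retina if they start at the same angular size. `loom_stimulus()` stores
$r/v$ together with two display conventions: the onset size (default 10
degrees) and the fixed final size at which expansion stops (default 90
degrees). Neither convention is a measured quantity; both are configurable
and both merely clip the law above. `theoretical_contact_time()` anchors the
hypothetical contact to the onset: contact occurs
$(r/v)/\tan(\theta_{\text{onset}}/2)$ ms after the stimulus appears, which
is what `fraction_escaped_before_contact()` compares escape times against.

Angles are handled in radians internally and degrees at every interface;
times are ms. The inverse law `time_to_reach()` is the exact algebraic
inverse, and a property test asserts the round trip to $10^{-9}$.

## Attack kinematics from digitized points

The input is a DLTdv-style table of per-frame 3D coordinates (mm) for three
labels — damselfly head, damselfly tail, fly centroid — at a known frame
rate (1000 Hz for the predation videography this emulates). Frames with
blank cells become flagged gaps; interior gaps of at most 5 frames are
bridged by linear interpolation, and anything longer truncates the event to
its longest clean segment containing the end frame, with a warning, rather
than inventing data.

**Smoothing.** Each component axis passes through a zero-phase
(forward-backward) Butterworth low-pass and then a Savitzky-Golay
polynomial smoother. Defaults: order 2, cutoff 30 Hz; window 11 frames,
polynomial order 3. The cutoff deserves a note. Strike dynamics at this
scale live below roughly 20 Hz, while digitization jitter is broadband, so
any cutoff between about 25 and 50 Hz preserves the signal; we chose 30 Hz
because the package's own parameter-recovery tests (programmed peak speed
and peak time under 0.1 mm jitter) showed peak-*time* recovery degrading
noticeably by 50 Hz (mean error ~3 ms there versus ~1 ms at 30 Hz). Two
implementation details matter more than the cutoff: the filter runs on the
residual around the line through the series' endpoints (otherwise
`filtfilt`'s zero initial conditions leave a transient proportional to the
signal's absolute magnitude — constants and ramps now pass through
exactly, and rigid translation invariance holds to machine precision), and
the series is padded by odd reflection before filtering.

**Differentiation.** Central differences on the filtered positions
(one-sided at the boundaries) give the velocity vector; speed is its norm
(m/s); acceleration is the derivative of that scalar speed (m/s²) — the
along-path acceleration, matching how attack kinematics are usually
plotted — rather than the vector-acceleration magnitude.

**Attack window.** Damselflies hover near prey height before darting. The
attack window starts at the first frame after the last run of at least 50 ms
during which speed stays below 0.05 m/s, and ends at the event's
contact-or-escape frame (t = 0). No qualifying hover falls back to the full
series with a warning; a series that stays sub-threshold through the end
raises a "no attack" condition.

**Prey-centred angles.** The reference frame puts +x along the mesh-wall
normal into the chamber and +z up, with the fly's perching position (its
centroid at the attack-window start, configurable to per-frame) as origin.
Elevation is $\tan^{-1}(\Delta z / \lVert\Delta xy\rVert) \in [-90°, 90°]$.
Because the data cannot distinguish left from right approaches, the lateral
coordinate enters as $|\Delta y|$, folding azimuth into $[0°, 180°]$ while
preserving front/back. The fly's body axis is *not* used — a single
centroid cannot orient the fly — so azimuth is wall-anchored, not
head-anchored. Mean angles are arithmetic means of the per-frame angles
over the attack window (not path-length weighted). Frames where the
damselfly sits exactly on the fly (zero vector) or exactly overhead
(undefined azimuth) are flagged NA rather than given arbitrary values.

**Peaks and retinal size.** Peak speed and acceleration are maxima over the
attack window, with ties broken to the latest frame, reported in ms
relative to t = 0 (negative = before contact/escape). The damselfly's
retinal angular size at the event end is $\theta = 2\tan^{-1}(r/d)$ with
$2r$ the damselfly head width and $d$ the head-to-fly distance at the end
frame. The head width default (2.2 mm) is a configuration value derived
from the correspondence between the ~40-degree giant-fibre activation
threshold and a ~3 mm approach distance; it is never hard-coded inside a
computation. Frame indices are 1-based throughout (R convention); t = 0
always sits on the end frame.

`align_and_average()` aligns events of different durations at t = 0 and
reports per-timepoint mean, SD and coverage count, so averages may show
step changes where shorter events drop out — the count series makes that
explicit.

## Escape ethograms and take-off modes

Take-off annotations give two times per fly, both in ms from stimulus
onset: the *reaction time* (first frame of wing raising) and the *escape
time* (first frame the middle jumping legs leave the ground). Their
difference is the take-off sequence duration. Durations are bimodal: a
fast, giant-fibre-driven *short* mode and a slower *long* mode, split at a
7 ms default boundary. A duration exactly at the boundary classifies as
long — the definitions "short (< 7 ms)" and "> 7 ms" leave equality open,
and assigning it to long is conservative for short-mode claims.

`estimate_mode_boundary()` provides a data-driven check on the fixed
boundary: a two-component Gaussian mixture on log-durations (positive,
right-skewed), fitted with mclust's deterministic model-based
initialisation, with the boundary taken as the point between the component
means where the posterior responsibilities are equal. The solver is a
bracketed root find on the log-density difference (tolerance 1e-12), and
tests cross-check it against a dense-grid intersection oracle. Degenerate
situations — a one-component fit preferred by BIC, merged means, a
vanishing weight, or no crossing between the means — raise a condition
with class `loomstrike_unimodal_error` instead of returning a number. The
mixture route is a check, not the default classifier; classification uses
the fixed boundary.

`timing_summaries()` reports per-group median, IQR and mean for both timing
quantities plus a two-sample Student t-test (equal variances, matching
classical usage; Welch by flag). The scientifically interesting signature —
silencing the giant fibre removes the short mode, lengthening escape times
without touching reaction times — is asserted as a property test on
generator data built with identical reaction-time distributions.

## Competition indices and statistics

For a trial in which two marked groups are exposed to predators together,
the consumption indices are

$$\mathrm{WCB} = \frac{L - R}{L + R}, \qquad
  \mathrm{PCI} = \frac{S - C}{S + C},$$

with $L, R$ the left-/right-wing-clipped eaten counts and $S, C$ the
silenced/control eaten counts. Both live in $[-1, 1]$, are antisymmetric
under swapping the groups, and are undefined (NA, excluded with a logged
count) when nothing was eaten — the formulas use eaten counts only, with no
reference to the number released. Index means are tested against zero with
a one-sample Student t-test; zero-variance degeneracies follow documented
conventions (all values at the null: p = 1; all at some other value: p = 0
with a flag) rather than erroring mid-pipeline.

Binomial proportions (take-off rates, escape proportions, slow/fast splits)
carry Wilson score intervals. The speed-split threshold is always an input
parameter — a dataset's grand-mean attack speed (0.167 m/s in the example
configuration) is a derived constant, not a package constant. Group
comparisons of mean approach angles use one-way ANOVA with Tukey HSD post
hoc comparisons at family level 0.95.

One caveat worth stating: at n = 30 the Wilson interval's *exact* coverage
(computable by enumerating the binomial support) is 97.4% at p = 0.1 or
0.9 — above the 95% nominal — because of binomial discreteness. The test
suite therefore validates the implementation against exact-enumeration
coverage, not against the nominal level.

## What the synthetic generators emulate — and what they do not

The generators exist so that every stage is testable without the original
videography, and so that parameter recovery can be measured against known
truth.

`gen_attack()` builds a hover-then-dart event: Gaussian positional jitter
about a hover point (default 30 mm out, 100 ms, 0.2 mm jitter), then a
straight-line approach along a programmed elevation/azimuth. The approach
speed is either constant or an accelerating profile — a Gaussian bump over
a base speed (default 35% of peak, bump SD 25 ms) peaking a programmed
time before the event end (default 30 ms) — entered through a 60 ms
sinusoidal onset ramp, because an instantaneous hover-to-dart speed step is
both unphysical and an artefact generator for any zero-phase filter. The
schedule is integrated per frame (midpoint rule) backwards from the event
end; since the ramp is anchored at dart onset while the bump is anchored at
contact, the event duration is found as the smallest frame count whose
self-consistent schedule covers the approach distance (the covered distance
is monotone in the frame count, so this is well defined). Capture events
end at grab range (default 2 mm head-to-fly), escapes at the fly's escape
distance (default 4 mm, just beyond the close-approach grab range).
Digitization noise is i.i.d. Gaussian per coordinate per frame.

Deliberate simplifications: no autocorrelated tracking error, no curved
pursuit, no wing or leg pose, a damselfly body fixed along the approach
direction, and a stationary fly. Passing recovery tests therefore show the
*pipeline* is accurate under the stated noise model; they do not certify
performance against correlated digitization artefacts or manoeuvring
attacks.

`gen_ethograms()` draws, per fly: a Bernoulli take-off, a Gaussian reaction
time, a Bernoulli mode choice, and a log-normal duration from the chosen
mode's distribution (escape time = reaction + duration). Silencing is
emulated purely as a short-mode weight near zero with the reaction-time
distribution untouched. `gen_trials()` draws eaten counts as independent
binomials per group per trial. Fly-level non-independence within a chamber
(a real possibility with 10 predators sharing 200 prey) is not modelled.

All generators are reproducible: one master seed fans out to substreams via
`substream_seed()` (seed + 7919·index, mod 2³¹−1), and identical seeds give
bit-identical outputs.

## The bundled scenarios

Two YAML configurations ship in `inst/extdata` and load via
`load_scenario()`:

* `null_scenario` — no genotype effect anywhere; used for calibration
  checks (index means covering zero, test sizes near nominal).
* `silencing_phenotype` — the silencing phenotype: short-mode weight 0.70 → 0.02
  with take-off probability 0.85 → 0.55; identical reaction-time
  distributions (mean 95 ms, SD 10 ms for the fast stimulus); per-fly
  consumption probability 0.15 → 0.30 over 15 trials of 100 + 100 flies;
  and a capture model that is logistic in peak attack speed for controls
  (steep: slow attacks essentially always escapable) but *flat* for
  silenced flies (slope zero, capture probability ≈ 0.55 at every speed) —
  reflecting that silencing abolishes the speed-dependence of capture
  rather than shifting it. Capture events end at 3.4 mm (control) versus
  1.8 mm (silenced), so only silenced-capture events exceed the 40-degree
  retinal threshold; escapes end at 4.2 mm.

These rates were fixed once, from the qualitative structure the analyses
are meant to exhibit, and are study conditions, not tuning knobs. Problem
sizes in the shipped configuration (100 simulated predation events per
genotype, ethogram groups of 80 and 29, 15 trials) were chosen as the
package's own desk-scale defaults: large enough that the qualitative
signatures are stable across seeds, small enough that the full pipeline
runs in seconds.

```{r, eval = FALSE}
report <- run_full_analysis(load_scenario("silencing_phenotype"), seed = 1)
report$competition$pci$mean      # positive: silenced flies eaten more
report$ethogram$timing           # reaction p large, escape p small
```

## Known limitations

* Azimuth is wall-normal-anchored; analyses that need the angle on the
  fly's *retina* in the horizontal plane would require a body-axis
  estimate the three-point digitization cannot provide.
* Acceleration is the scalar speed derivative; centripetal components of
  curved attacks are invisible to it (by design, and switchable only by
  differentiating the velocity vector externally).
* The mixture boundary assumes exactly two log-normal-ish modes; heavier
  contamination is reported as degeneracy rather than fitted.
* The competition model treats flies as independent Bernoulli prey; chamber-
  or predator-level random effects are out of scope.
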