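---
title: "Single-molecule dwell-time kinetics: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule dwell-time kinetics: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smKinetics)
```

# The measurement problem

In single-molecule TIRF experiments on actin regulators, a labeled protein
(an Arp2/3 complex, a nucleation-promoting factor such as Abp1, or a
debranching factor such as GMF) binds transiently to a target — a filament
side, a branch junction, or an anchored partner molecule — and the movie
records how long each fluorescent spot persists. Three complications stand
between the raw movie and the dissociation kinetics:

1. **Frame quantization.** The camera samples at discrete instants
   $0, \Delta t, 2\Delta t, \dots$ (typical $\Delta t$ here: 0.15, 0.25 or
   1 s). A dwell is observed only as the number of acquisition instants
   $k$ it spans, so the reported lifetime is $k \Delta t$.
2. **Detection censoring.** A binding event shorter than the gap to the
   next acquisition instant spans no frame at all and is never seen.
   Short-lived events are systematically lost, and the loss depends on
   $\Delta t$.
3. **Right censoring.** Events still bound at the last acquisition
   instant have unknown remaining lifetime.

`smKinetics` packages the full analysis chain — synthetic ground truth,
spot detection and colocalization, censored maximum-likelihood dwell
fitting with bootstrap errors, binding-frequency and occupancy statistics,
photobleaching step counting, branch nucleation/debranching curves, and
gel-based stoichiometry — with every stage validated by recovery of known
generating parameters.

# The dwell-time observation model

A molecule binds at a time uniformly distributed relative to the frame
clock (binding chemistry is asynchronous with the camera) and stays bound
for a duration $d$. With phase $u \sim U[0, \Delta t)$ to the next
acquisition instant, the observed frame count is

$$ K = \lfloor (d - u) / \Delta t \rfloor + 1 \quad (d > u), $$

and the event goes undetected when $d \le u$. For an exponential dwell
with mean $\tau$, memorylessness gives two clean results that the package
exploits throughout:

* the detection probability is
  $p(\tau) = (\tau / \Delta t)\,(1 - e^{-\Delta t / \tau})$, and
* given detection, $K$ is geometric:
  $P(K = k) = (1 - q)\, q^{k-1}$ with $q = e^{-\Delta t / \tau}$.

Both are verified against brute-force simulation in the test suite.

## Estimators

`fitExponential()` exposes two estimators because published dwell analyses
often do not state how quantization was treated:

* **naive** maximizes the continuous exponential likelihood of the
  observed $k \Delta t$ values; the MLE is the sample mean. It
  overestimates $\tau$ when dwells are comparable to $\Delta t$, because
  sub-frame events are missing and every count is effectively rounded
  outward. The package reproduces this bias and its growth with
  $\Delta t$ as a property test: the same 0.46 s process measured at 1 s
  intervals reads out well above 0.46 s.
* **phase_marginalized** (default) maximizes the exact discrete
  likelihood above. On uncensored data the MLE has the closed form
  $\hat\tau = \Delta t / \log(\bar k / (\bar k - 1))$; right-censored
  events contribute geometric survival factors $q^{k-1}$, and the MLE
  remains closed-form. This estimator is unbiased under the sampling
  convention of the package's own simulator, which closes the
  recovery loop the acceptance checks rely on.

```{r closed-form}
s <- DwellSample(c(1, 1, 2, 3), frameIntervalS = 0.25)
fitExponential(s)
```

If every event spans a single frame the MLE sits on the boundary
($\tau \to 0$); the fit warns and reports $\tau$ at a small lower bound
$\Delta t / \log(4n + 4)$ rather than failing.

## Two-exponential mixtures

Conditions with a stabilizing co-factor show two kinetic populations: a
fast filament-lattice-like component and a long-lived component (for
example at branch junctions). `fitTwoExponential()` fits

$$ f(d) = (1 - a)\,\mathrm{Exp}(T_\mathrm{short}) +
          a\,\mathrm{Exp}(T_\mathrm{long}) $$

by bounded quasi-Newton (`optim`, L-BFGS-B) on
$(\log T_\mathrm{short}, \log T_\mathrm{long}, \operatorname{logit} a)$,
with multi-start initialization (the single-exponential solution, a
median-split moment start, a small-weight start, a near-degenerate start
that reproduces the nested single-exponential likelihood, and jittered
variants; 10 starts by default, convergence tolerance $10^{-8}$ on the
log-likelihood via `factr`). Component means are reported in canonical
order $T_\mathrm{short} < T_\mathrm{long}$; bootstrap replicates are
sorted the same way before aggregation so label switching cannot inflate
the standard errors.

**What `fracLong` means.** Under the phase-marginalized likelihood the
mixture weight $a$ is the *latent, continuous-time* weight: the
likelihood conditions on detection with component-specific detection
probabilities $p(T_c)$, so the re-weighting that detection censoring
applies to the observed events (short-component events are lost
preferentially) is part of the model rather than part of the estimate.
This is a deliberate design choice: with
$T_\mathrm{short} = 0.37$ s at $\Delta t = 0.15$ s, roughly 18% of
short-component events go undetected, and an estimator that reported the
weight *among detected events* would read ~15% where the generating
weight is 13%. The naive estimator, which has no notion of detection,
reports the detected-event weight. Parameter-recovery tests pin the
phase-marginalized estimator to the generating values.

## Bootstrap errors and model choice

`bootstrapSE()` resamples events with replacement and refits
(nonparametric bootstrap; the study-scale convention is 10,000
replicates — unit tests and the acceptance checks use 300–2,000 because
the SE of a SD estimate scales as $1/\sqrt{2B}$, making larger $B$
indistinguishable at test tolerances). Mixture refits start from the
full-sample fit (`init`), the standard variance-reduction device for
bootstrap refitting. Replicate fit failures are counted and more than 5%
triggers a warning. `compareModels()` reports AIC with $p = 1$ vs $3$;
the mixture nests the single exponential, so $\Delta \log L \ge 0$
always, and equal likelihoods prefer the single model.

## Survival curves

`survivalCurve()` evaluates $S(t) = P(\text{dwell} \ge t)$ on the frame
grid. With right-censored events it uses the product-limit
(Kaplan–Meier) estimator; the $\ge$ convention makes the curve
left-continuous, so it equals the standard right-continuous estimator
evaluated just above each event time — the test suite pins this
correspondence against `survival::survfit()` while the package computes
the curve itself (the convention differs, and dwell tables are small).

# Site statistics

`bindingFrequency()` implements the available-time convention: per
detection box (a square of 1.14 µm², centred on the target), the rate is
the number of event starts divided by the observation time *minus the
union* of intervals during which the box was already occupied — a box
cannot register a new arrival while occupied, so dividing by wall-clock
time would underestimate the rate at busy sites.

`occupancy()` is total bound time over `nSites × observationS`, clipped
at 1, with the field's site-accounting conventions: 370 side-binding
sites per µm of F-actin, one site per branch junction
(`countSites()`). Occupancy refers to labeled molecules; an optional
`labeledFraction` rescaling is available but off by default, since the
measured quantity in the motivating experiments is labeled-molecule
occupancy. The conservation identity
`occupancy × nSites × observationS = total bound time` holds exactly and
is asserted in tests.

# Photobleaching steps

`countSteps()` segments a trace by greedy binary change-point search and
selects the number of change points with a change-point-adjusted BIC:
$n \log(\mathrm{RSS}/n) + (4m + 2)\log n$ for $m$ change points. The
plain two-parameters-per-step BIC penalty ($2\log n$) sits exactly at
the expected gain of the best spurious split in pure noise
($\approx 2\sigma^2 \log n$), so it over-segments; the $4 \log n$
coefficient covers the search-over-positions multiple-testing cost.
Only downward level changes count as steps (no blinking recovery).
Same-frame double bleaches register as one step, and a fluorophore that
bleaches on the first frame or survives the whole trace is unresolvable
in principle — the tests separate these physical limits from counter
accuracy, which is ≥95% on resolvable two-step traces at a step-to-noise
ratio of 5.

# Branch dynamics and bulk curves

`cumulativeBranching()` counts appearances per field of view (default
area 18,000 µm²) on a time grid with mean ± SEM across FOVs;
`branchSurvival()` builds per-trial survival of initially present
branches, censored branches surviving through the window, with mean ±
SEM across trials. `elongationRate()` is an ordinary least-squares slope
(µm/s, optionally ×370 to subunits/s). `normalizePyrene()` rescales bulk
assembly curves to [0, 1]: baseline = curve minimum; plateau detection =
least-squares slope over the final 10% of points below 1% of the curve
range per 100 s (a pinned, configurable convention — bulk records end at
operator-chosen times, so "reached plateau" needs an explicit rule);
curves that never plateau are scaled by the mean baseline-to-plateau
span of those that did, and if no curve plateaus the function refuses
with an explanatory error rather than guessing.

# Stoichiometry from gels

Band intensity against loaded amount is fitted as
$I = b_1 c + b_2 c^2$ **through the origin** (`fitStandardCurve()`), the
standard form for stain-free tryptophan-fluorescence densitometry, one
curve per species (tryptophan content differs between species, so no
cross-species intensity conversion is attempted). `inferConcentration()`
inverts by the quadratic formula with a linear fallback when
$|b_2| \approx 0$; inversion is an exact identity on noiseless data.
`molarRatio()` summarizes per-replicate concentration ratios; the ratio
is invariant to any common rescaling of one species' lanes because its
standards rescale identically.

# The synthetic-data generator

Every analysis stage is validated against `simulate*` functions with
known truth:

* `simulateBindingEvents()` — homogeneous Poisson arrivals per site
  (branch junctions are point sites; each filament polyline is one side
  site with positions uniform along its length; background events fall
  uniformly on the non-filament area), dwells i.i.d. exponential or
  two-exponential.
* `quantizeToFrames()` — the instantaneous-sampling observation model
  above (exposure, ~50 ms, is short relative to every $\Delta t$ used,
  so integrating over exposure would change nothing material). Events
  running past the final acquisition instant are emitted with a
  right-censoring flag by default (`endHandling = "drop"` exists); the
  downstream fit decides their treatment.
* `simulateDwells()` — fixed-size detected samples for recovery
  experiments at published event counts.
* `renderMovie()` — Gaussian PSF spots with Poisson or Gaussian noise,
  for detector/linker round-trip tests.
* `simulatePhotobleachTraces()` — one or two fluorophores per spot,
  geometric bleaching frames, additive Gaussian noise; two-state
  (on → bleached), no blinking.
* `simulateDebranching()`, `simulateOccupancyTrace()`,
  `simulateGelStandards()` — window-censored lifetimes, stationary
  alternating bound/unbound site processes, and noisy through-zero
  quadratic band intensities.

All randomness flows from explicit seeds through a local RNG scope, so
identical (seed, inputs) pairs are byte-identical and global RNG state
is never disturbed.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: molecular diffusion and photophysics
(blinking, triplet states), camera EM gain and read-noise structure,
drift, uneven illumination, filament growth during acquisition, and
cooperative or spatially correlated binding. Recovery results certify
the inference chain under the stated model, not robustness to every
property of real recordings.

# Problem sizes and numerical conventions

Recovery experiments run at the event counts the motivating measurements
report (200–10,000 dwells; 1,000 photobleaching traces; 26 occupancy
sites over 600 s; 3 gel replicates), which keeps the full test suite
under a minute of CPU while leaving Monte-Carlo error well inside the
asserted tolerances. Times are seconds, lengths µm, intensities
arbitrary units; frames are 0-based with pixel centres at integer
coordinates; event intervals are half-open
$[\mathrm{start}, \mathrm{start} + k\Delta t)$. Optimizer bounds confine
component means to $[\Delta t / 50, 10^5 \Delta t]$ and the mixture
weight to $[10^{-4}, 1 - 10^{-4}]$ on the logit scale; ties in track
linking resolve by smallest distance, then lowest spot index.

# Known limitations

* Greedy nearest-neighbour tracking, not global assignment — adequate
  for the sparse fields simulated here.
* The spatial-overlap radius for colocalization (default: 1 pixel) is a
  declared convention, configurable but not inferred from data.
* No ≥3-component mixtures, no hidden-Markov kinetics, no
  photobleaching-rate correction of dwell times.
* Mixture fits with poorly separated components or tiny weights sit on
  a likelihood ridge; `compareModels()` will prefer the single
  exponential there, which is the correct behaviour, not a failure.
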