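---
title: "Kinetic modelling and smFRET analysis of ribosomal decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling and smFRET analysis of ribosomal decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodecode)
```

## The model

Selection of an aminoacyl-tRNA by the ribosome proceeds through a
branched sequence of elementary steps. The ternary complex of
elongation factor EF-Tu, GTP and the aminoacyl-tRNA first contacts the
ribosome in a codon-independent initial-binding step (pseudo-first-order
association `k1_app`, dissociation `k_rev1`). Codon recognition (`k2`)
pairs the anticodon with the A-site codon; the codon-reading complex can
decay back to the unbound state (`k_rev2`) or trigger GTPase activation
and GTP hydrolysis (lumped here into `k_gtp`). After hydrolysis, Pi
release and accommodation of the tRNA into the peptidyl-transferase
center (lumped composite `k45`) complete decoding and peptide bond
formation, in competition with proofreading drop-off (`k7`). The
peptidyl-tRNA then fluctuates between classical (A/A, A/P) and hybrid
(A/P*) configurations at `k_hyb_fwd` / `k_hyb_rev`. N6-methyladenosine
on the codon does not block any forward step outright; it destabilizes
the binding intermediates, raising the dissociation rates and the
drop-off flux, which is the mechanism this package is built to explore
quantitatively.

`ribodecode` represents this scheme as a continuous-time Markov chain
(`build_scheme()`), simulated exactly by the Gillespie algorithm
(`simulate_trajectory()`) and solved analytically: occupancy time
courses by the matrix exponential (`ensemble_timecourse()`), reaction
times as conditional mean first-passage times (`mean_first_passage()`),
and branching outcomes as absorption probabilities
(`absorption_probability()`). Drop-off makes the unconditional hitting
time infinite, so first-passage results are always reported conditional
on reaching the target together with the probability of doing so.
`chain_cycles()` concatenates several codons' schemes; when no drop-off
occurs, the conditional passage time through the chain is exactly the
sum of the per-cycle times, which is how a slow codon late in a message
adds its full delay on top of upstream synthesis.

Three protocols mirror the experimental designs: `wildtype` (all
steps), `H84A` (a GTPase-deficient EF-Tu: `k_gtp` is exactly zero, the
complex stalls in codon reading, and the codon-reading decay reports
dissociation), and `hybrid_only` (preformed post-decoding complexes
restricted to the classical/hybrid two-state cycle).

### Rate parameters

Units are seconds and s^-1 throughout. The shipped per-codon rate sets
(`decoding_rates()`) carry the published single-molecule estimates for
the dissociation and fluctuation rates (for AAA: `k_rev1` 8.1,
`k_rev2` 0.34, `k_hyb_fwd` 2.9, `k_hyb_rev` 4.4; for the
first-position-modified codon: 15, 1.1, 2.8, 4.2) and the
codon-reading forward decay (6.3 / 7.2). The remaining entries are
declared simulation defaults, not measured values: `k1_app = 0.5`
corresponds to delivery at single-molecule imaging concentrations
(a few binding events per half-minute trace), `k2 = 30` is fast codon
recognition consistent with the stopped-flow apparent rate, `k7` is a
small drop-off rate (0.1 / 0.5; larger for the modified codon, which
enhances rejection), and the accommodation composite `k45` is
calibrated so that the aggregate codon-reading-to-hybrid transition
time matches the published aggregate rate:
`1/k45 = 1/k_aggregate - 1/k_gtp`, giving 2.93 (AAA) and 1.16
(modified). None of these defaults is claimed as a measured quantity;
they only have to produce realistic trace phenology.

## The synthetic-data generator

`generate_dataset()` is the raw-data stand-in for the single-molecule
experiments: mechanistic trajectories are rendered into two-channel
intensity traces through an explicit camera model and returned with
complete ground truth per molecule. The generator emulates:

* exponential dwells from the decoding scheme;
* state-dependent FRET means (0 unbound, 0.9 for initial
  binding/codon reading/post-hydrolysis — these are not distinguishable
  by FRET level, only by progression — 0.8 classical, 0.6 hybrid;
  widths default 0.05);
* camera integration at 30.3 frames/s, frame *i* integrating
  ((i-1)dt, i dt], with occupancy-weighted averaging of state FRET
  within a frame;
* additive Gaussian channel noise (derived from the requested
  FRET-state width by error propagation at a reference efficiency of
  0.8 — a single channel noise level cannot give every state exactly
  the same FRET width);
* donor-to-acceptor bleed-through of 0.13, added after noise;
* single-step photobleaching at 0.03 s^-1, the affected dye drawn with
  equal probability (a donor bleach darkens both channels; an acceptor
  bleach darkens the acceptor and unquenches the donor);
* a 33-s observation window and N = 3 independent replicates.

What it does not emulate — and what passing tests therefore do not
establish about real data — includes dye blinking (the published
analysis truncates blinking events; an injector is deliberately left
out of the default model), shot-noise/EMCCD gain statistics,
background and neighbouring-spot crosstalk, drift, and any
heterogeneity beyond the optional long-lived codon-reading
subpopulation (`stalled_fraction`), which reproduces the stalled
phenotype without asserting a mechanism, since the data do not decide
whether stalling is a distinct substate or the tail of the
codon-reading dwell distribution.

Ensemble stopped-flow/quench-flow records are emulated by
`generate_ensemble_timecourse()` (analytic occupancy plus Gaussian
noise per replicate; scheme mixtures give biphasic courses) and by
`simulate_exponential_course()` for directly specified one- or
two-phase protocols.

## The trace-analysis chain

`analyze_traces()` runs the reduction in acquisition order:

1. **Quality control** (`qc_select()`): keep traces whose
   frame-difference donor/acceptor correlation is at most -0.1 and
   whose total-intensity step detector finds at most one bleach step
   (two or more indicate multiple fluorophores); the truncation index
   is set at the detected bleach. Zero detected steps are accepted:
   with a 0.03 s^-1 bleaching rate about a third of genuine single
   molecules survive the 33-s window unbleached. The thresholds are
   declared defaults; the original semi-automated selection did not
   publish its values.
2. **Corrections**: `correct_bleedthrough()` subtracts `0.13 * donor`
   from the acceptor; `compute_fret()` forms
   `E = acceptor / (donor + acceptor)` and masks frames beyond the
   truncation index or with non-positive total intensity.
3. **Idealization** (`idealize()`): maximum-likelihood
   Gaussian-emission HMMs with 1..`max_states` states (Baum-Welch,
   quantile- and k-means-based deterministic initialization, BIC state
   selection, Viterbi decoding). Two numerical choices matter. State
   widths are bounded into [0.001, 0.15]: the floor keeps the
   likelihood finite on noise-free traces, and the ceiling prevents a
   pathology in which one broad component acts as an outlier
   catch-all for camera-integration boundary frames and beats the
   true fit in likelihood while destroying the state structure.
   The BIC scan stops only after two consecutive increases, because a
   single increase is often an EM local optimum at the intermediate
   state count. The default `max_states` is one more than the number
   of declared FRET levels; the extra state absorbs boundary frames.
4. **Transition filtering** (`filter_transitions()`): adjacent dwells
   whose fitted means differ by less than the larger of the two state
   widths are merged (smallest gap first, duration-weighted mean),
   implementing the rule that FRET changes below the state width
   cannot be distinguished from noise.
5. **Level assignment** (`assign_levels()`): each dwell is mapped to
   the nearest declared FRET level using its interior-frame median
   FRET (`mu_obs`) — the first and last frame of a dwell average over
   the state switch, and for one- and two-frame dwells the fitted
   state mean can sit halfway between levels. Exact ties go to the
   previous dwell's level, which absorbs single boundary frames.
6. **Classification** (`classify_trace()`): the first resolved bright
   phase (at least 2 frames) decides the phenotype — `post_decoding`
   if it sits at the 0.8/0.6 levels *and* starts within 10 frames
   (post-decoding complexes are already fluctuating when recording
   starts); `decoding` if a high-FRET phase is followed by a resolved
   post-decoding phase, or if a post-decoding phase appears late
   without resolved codon reading (a sub-frame codon-reading dwell);
   `rejected` if the high phase returns to dark; `stalled` if it
   persists to the end of the valid window. Traces with no resolved
   bright phase are excluded and counted. The same rule, applied to
   the true state path truncated at the bleach, defines the
   generator's ground-truth labels, so the classifier is scored
   against what an ideal observer of the same movie could know.
7. **Dwell analysis** (`extract_dwells()`, `fit_dwell()`,
   `correct_rate()`, `correct_missed_events()`): see below.
8. **Summaries**: replicate class fractions with across-replicate
   mean and s.d. and two-tailed Welch tests (`class_fractions()`),
   Gaussian-sum FRET histogram fits per replicate
   (`fit_fret_histogram()`), and post-synchronized contour histograms
   (`synchronize_contour()`, synchronizing each trace to its first
   run of at least 2 frames with E at or above 0.125 — the declared
   dark-state noise floor for "FRET > 0").

### Dwell-time rate estimation

Dwells of a transition class are residences in the source level that
end in the class's destination level; dwells cut short by the bleach
or the window end are right-censored, counted, and excluded from the
decay fit (no survival machinery — the window term of the published
correction formula is the intended treatment of the finite
observation). Two estimators are computed:

* the **histogram fit** `y = y0 + A exp(-t/tau)` on the
  maximum-normalized dwell histogram (2-frame bins), starting at the
  later of the modal bin and a 3-frame dead time — dwells shorter
  than a few frames are under-detected, and an exponential is
  memoryless, so the late start is free of bias on ideal data;
* a **quantization-aware maximum-likelihood estimate**: idealized
  durations are whole numbers of frames, so frame counts above the
  dead time follow a truncated geometric law, giving
  `k = -log(r_hat)/dt` with `r_hat = (M - m)/(1 + M - m)`. This
  estimator is exact for exponential dwells at any frame rate,
  whereas the binned least-squares fit becomes sensitive to bin-edge
  alignment once the mean dwell approaches a few frames. The
  high-level analysis therefore uses the ML estimate as the rate of
  record and reports the histogram fit alongside; histograms an
  exponential describes poorly (R^2 below 0.9) are flagged.

Rates are then corrected in two steps. For a reversible two-state
phase analyzed in both directions, `correct_missed_events()` inverts
the first-order concatenation bias of finite time resolution:
excursions shorter than an effective dead time of 0.75 frames are
invisible, so flanking dwells concatenate and both rates read low (by
15-20% at the classical/hybrid rates and 30.3 frames/s). Finally the
published photobleach/window correction
`k_corrected = k_observed - k_photobleach - 1/T` is applied; negative
results are returned with a warning flag, never clamped. The
competing-risk algebra makes this consistent with censoring: complete
dwells decay at the molecular rate plus the bleaching hazard, and
entries spread over the window contribute an approximately `1/T`
truncation term.

### Ensemble fits

`fit_exponential()` fits rising or decaying one- or two-phase
exponentials. One-phase fits use Levenberg-Marquardt from a grid of
rate starts. Two-phase fits use variable projection — for fixed rates
the amplitudes are linear — over a log-rate grid restricted to the
identifiable region (rate ratio at least 3), polished by Nelder-Mead;
an unrestricted search lets the flat least-squares valley split a
single fast phase between the two components. The major phase is the
component realizing the larger signal change within the observed
window (a near-zero rate with a large raw coefficient is baseline
drift, not a kinetic phase). A second phase is dropped, with a note,
when its amplitude fraction is below 5% or when the rates are within
3-fold of each other *and* an extra-sum-of-squares F-test cannot
justify it at p < 0.01; the pure rate-ratio rule alone misfires on
genuinely biphasic data whose minor rate drifts along the flat
valley. When the protocol defines the course's structure, that
knowledge can be supplied: `fix_y0` pins the known offset of a
normalized course (1 for relative fluorescence, 0 for product
fractions), `rate_ratio` and `amplitude_fractions` constrain a
calibrated two-phase design, and `aggregate = "average"` fits the
point-wise average of technical replicates, as stopped-flow records
are assembled. In Monte-Carlo sweeps over dataset seeds these
constraints take the major-phase rate estimate from roughly 5% to
roughly 1% relative standard deviation without detectable bias.
Replicate-level fits are otherwise aggregated as mean +/- SEM of the
estimates, `tau = 1/k_app`, and `delay_between()` and `compare_tau()`
(two-tailed unpaired Student's or Welch's t, no multiplicity
adjustment) provide the construct comparisons.

## Worked example

```{r example, eval = FALSE}
# simulate the GTPase-deficient experiment for the modified codon
rates <- decoding_rates("m6AAA")
ts <- generate_dataset(rates, fret_map(), camera_model(),
                       n_traces = 200, protocol = "H84A",
                       scenario = "injection", n_replicates = 3, seed = 1)
cfg <- analysis_config(levels = c(dark = 0, high = 0.9))
res <- analyze_traces(ts, cfg,
                      dwell_classes = list(diss = c("high", "dark")))
res$dwells$diss$k_corrected_mean     # ~1.1 s^-1, the generating k_rev2
```

## Problem sizes and numerical choices

The validation suites run at desk scale: 3 replicates of 150-300
traces per condition for rate recovery (several thousand dwells per
class), 60-100 traces per replicate for state-histogram and
classification checks, 10^4 stochastic paths against each analytic
first-passage value, and 500-point stopped-flow courses. These sizes
put the Monte-Carlo error of each check well inside its acceptance
tolerance. Degenerate inputs are handled explicitly: zero-rate states
are absorbing, empty time grids return empty courses, all-dark traces
are excluded and counted, fits with fewer than 20 dwells or 8 points
are refused rather than reported, and Welch comparisons of
zero-variance groups return p = 1 (identical) or p = 0 (different).

## Known limitations

The FRET levels of initial binding and codon reading are identical, so
"rejected" and "stalled" phenotypes differ from decoding only by
progression and duration, and sub-frame codon-reading dwells are
invisible — the classifier attributes such traces to `decoding` on the
strength of their post-decoding phase. Rates beyond roughly the frame
rate (the ">30 s^-1" appearances) are not estimable from the traces
and are reported only as fast-appearance phenotypes. The missed-event
correction is first-order and assumes a two-state phase; it is not
applied to branched transitions. The dwell estimators assume
exponential dwells within a class; genuinely multi-exponential classes
are flagged by the histogram diagnostic but not decomposed.
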