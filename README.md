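# ribodecode

Kinetic modelling and single-molecule FRET analysis of ribosomal
decoding, built to quantify how mRNA modifications such as
N6-methyladenosine (m6A) modulate aminoacyl-tRNA selection. The package
is aimed at researchers who study translation kinetics with smFRET
and ensemble rapid-kinetics experiments and want a reproducible,
fully synthetic test bed for their analysis chain: every estimator in
the package can be exercised against simulated data whose ground truth
is known exactly.

## The model

Decoding is represented as a branched continuous-time Markov chain over
the states

```
UNBOUND <-> IB <-> CR -> POST_GTP -> ACCOMMODATED (A/A, A/P) <-> HYBRID (A/P*)
                                \-> DROPPED
```

with pseudo-first-order association k1_app, dissociation rates k-1
(from initial binding, IB) and k-2 (from codon reading, CR), a lumped
GTPase-activation/GTP-hydrolysis step k_gtp, a lumped Pi-release +
accommodation composite k45, proofreading drop-off k7, and the
classical/hybrid fluctuations k(0.8->0.6), k(0.6->0.8) of the
peptidyl-tRNA. The chain is simulated exactly (Gillespie) and solved
analytically: occupancy time courses p(t) = p(0) exp(Qt), conditional
mean first-passage times, absorption probabilities, and multi-codon
chaining.

On top of the kinetic core sit

* a **synthetic smFRET generator** — camera integration at 30.3
  frames/s, per-state FRET means (0 unbound, ~0.9 codon reading, ~0.8
  classical, ~0.6 hybrid), Gaussian channel noise, donor bleed-through
  0.13, single-step photobleaching at 0.03 s^-1, 33-s observation
  window, replicate structure, full ground truth per molecule;
* the **trace-analysis chain** — quality control, bleed-through
  correction, E = I_acceptor / (I_donor + I_acceptor), Gaussian-HMM
  idealization with BIC state selection, width-based transition
  filtering, dwell-time decay fitting with the photobleach/window
  correction k_corrected = k_observed - k_photobleach - 1/T,
  Gaussian-sum FRET histograms, mechanistic trace classification
  (rejected / decoding / post-decoding / stalled) with replicate
  statistics, and post-synchronized contour histograms;
* the **ensemble pipeline** — one/two-exponential fits of stopped-flow
  and quench-flow courses (k_app, tau = 1/k_app, end levels), delays
  between constructs, and the group comparisons (Student/Welch t).

## Worked example

Simulate the GTPase-deficient (H84A) single-molecule experiment for
the m6A-modified AAA codon and recover the codon-reading dissociation
rate from scratch:

```r
library(ribodecode)

rates <- decoding_rates("m6AAA")      # published k-1 = 15, k-2 = 1.1 s^-1
ts <- generate_dataset(rates, fret_map(), camera_model(),
                       n_traces = 200, protocol = "H84A",
                       scenario = "injection", n_replicates = 3, seed = 1)
cfg <- analysis_config(levels = c(dark = 0, high = 0.9))
res <- analyze_traces(ts, cfg,
                      dwell_classes = list(diss = c("high", "dark")))
res$dwells$diss$k_corrected_mean
#> [1] 1.1044
res$dwells$diss$k_corrected_sd
#> [1] 0.0574
```

The pipeline idealizes ~600 traces, extracts ~3600 codon-reading
dwells, fits their decay per replicate, and corrects for
photobleaching and the finite window; the recovered 1.10 +/- 0.06
s^-1 reproduces the generating k-2 = 1.1 s^-1 within a few percent.
The same workflow with `decoding_rates("AAA")` (k-2 = 0.34 s^-1)
yields ~0.34 s^-1 — a 3.2-fold destabilization of the codon-reading
complex by the modification.

Ensemble example — the delay caused by the modification at a late
codon, from fitted reaction times:

```r
tc_aaa <- simulate_exponential_course(1/2, 1, seq(0, 60, length.out = 30),
                                      noise_sd = 0.02, n_replicates = 3,
                                      seed = 10)
tc_m6  <- simulate_exponential_course(1/18, 1, seq(0, 60, length.out = 30),
                                      noise_sd = 0.02, n_replicates = 3,
                                      seed = 11)
delay_between(fit_exponential(tc_aaa), fit_exponential(tc_m6))
#> [1] 16.262     # seconds of extra decoding time
```

A thin command-line wrapper is installed at
`inst/cli/ribodecode.R` (subcommands `simulate`, `analyze`,
`fit-ensemble`, `report`). The methods vignette
(`vignettes/decoding-kinetics.Rmd`) documents the model, the
generator's scope, every estimator and the numerical design choices.

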