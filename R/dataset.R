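#' Construct an ensemble time course
#'
#' @param time time points (s), non-negative and strictly increasing
#'   within a replicate.
#' @param signal signal values (relative fluorescence or product
#'   fraction).
#' @param replicate replicate identifier (recycled).
#' @param condition condition label (codon / construct), recycled.
#' @return A `time_course` data frame.
#' @export
time_course <- function(time, signal, replicate = 1L, condition = "") {
  df <- data.frame(time = time, signal = signal,
                   replicate = rep_len(replicate, length(time)),
                   condition = rep_len(condition, length(time)))
  for (r in unique(df$replicate)) {
    tt <- df$time[df$replicate == r]
    if (length(tt) && (any(tt < 0) || is.unsorted(tt, strictly = TRUE)))
      stop("time must be non-negative and strictly increasing per replicate")
  }
  class(df) <- c("time_course", "data.frame")
  df
}

#' Generate a synthetic single-molecule FRET dataset with ground truth
#'
#' The raw-data stand-in of the package: mechanistic trajectories are
#' simulated from the decoding scheme, rendered through the camera model,
#' and returned together with complete ground truth (source trajectory,
#' bleach event, mechanistic class) for every molecule. Two scenarios are
#' supported: `"injection"` starts every molecule unbound at t = 0
#' (ternary complex delivered into the flow chamber at the start of
#' imaging), `"preformed_postdecoding"` starts molecules inside the
#' classical/hybrid fluctuation cycle (complexes that completed decoding
#' before imaging), drawn from the stationary distribution of the
#' two-state cycle.
#'
#' @param rates a [rate_set].
#' @param fmap a [fret_map].
#' @param cam a [camera_model].
#' @param n_traces traces per replicate.
#' @param protocol scheme protocol, see [build_scheme]. The
#'   `"preformed_postdecoding"` scenario always uses the `"hybrid_only"`
#'   scheme.
#' @param scenario `"injection"` or `"preformed_postdecoding"`.
#' @param n_replicates number of independent replicates (default 3).
#' @param seed master integer seed; every molecule's seed derives from it.
#' @param stalled_fraction optional fraction of injected molecules drawn
#'   from a long-lived codon-reading subpopulation (codon-reading exits
#'   disabled), for robustness studies of the trace classifier. The
#'   mechanism behind experimentally observed stalled traces is not
#'   modelled, only their phenotype.
#' @param bleach_mode passed to [render_trace].
#' @return A `trace_set`: list with `traces` (list of intensity traces),
#'   `manifest` (one row per molecule: id, replicate, seed, ground-truth
#'   class, bleach time/mode) and `params`.
#' @examples
#' ts <- generate_dataset(decoding_rates("AAA"), fret_map(), camera_model(),
#'                        n_traces = 3, protocol = "wildtype",
#'                        scenario = "injection", n_replicates = 1, seed = 1)
#' ts$manifest
#' @export
generate_dataset <- function(rates, fmap = fret_map(), cam = camera_model(),
                             n_traces, protocol = "wildtype",
                             scenario = c("injection",
                                          "preformed_postdecoding"),
                             n_replicates = 3L, seed = 1L,
                             stalled_fraction = 0,
                             bleach_mode = "donor_or_acceptor") {
  scenario <- match.arg(scenario)
  if (n_traces <= 0) stop("'n_traces' must be > 0")
  if (scenario == "preformed_postdecoding") protocol <- "hybrid_only"
  scheme <- build_scheme(rates, protocol)
  stalled_scheme <- NULL
  if (stalled_fraction > 0) {
    r2 <- rates; r2$k_rev2 <- 0; r2$k_gtp <- 0
    class(r2) <- "rate_set"
    stalled_scheme <- build_scheme(r2, "H84A")
  }

  n_total <- n_traces * n_replicates
  seeds <- derive_seeds(seed, 2L * n_total)
  traces <- vector("list", n_total)
  man <- vector("list", n_total)
  for (j in seq_len(n_total)) {
    rep_id <- ((j - 1L) %/% n_traces) + 1L
    sj <- seeds[2L * j - 1L]
    use_stalled <- FALSE
    if (scenario == "injection") {
      init <- scheme$states[1]
      if (!is.null(stalled_scheme))
        use_stalled <- with_seed(seeds[2L * j],
                                 stats::runif(1) < stalled_fraction)
    } else {
      p_acc <- rates$k_hyb_rev / (rates$k_hyb_fwd + rates$k_hyb_rev)
      init <- with_seed(seeds[2L * j],
                        if (stats::runif(1) < p_acc)
                          "ACCOMMODATED_CLASSICAL" else "HYBRID_APstar")
    }
    traj <- simulate_trajectory(if (use_stalled) stalled_scheme else scheme,
                                horizon = cam$window, seed = sj,
                                init = init)
    tr <- render_trace(traj, fmap, cam, seed = sj + 1L,
                       bleach_mode = bleach_mode)
    id <- sprintf("rep%02d_mol%04d", rep_id, ((j - 1L) %% n_traces) + 1L)
    attr(tr, "molecule_id") <- id
    traces[[j]] <- tr
    truth <- attr(tr, "truth")
    man[[j]] <- data.frame(molecule_id = id, replicate = rep_id,
                           seed = sj, class = truth$class,
                           bleach_time = truth$bleach_time,
                           bleach_mode = truth$bleach_mode)
  }
  structure(list(traces = traces,
                 manifest = do.call(rbind, man),
                 params = list(rates = rates, fmap = fmap, cam = cam,
                               protocol = protocol, scenario = scenario,
                               n_traces = n_traces,
                               n_replicates = n_replicates, seed = seed,
                               stalled_fraction = stalled_fraction)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("Synthetic smFRET trace set:", length(x$traces), "traces,",
      x$params$n_replicates, "replicate(s),",
      "scenario", x$params$scenario, "\n")
  print(table(x$manifest$class))
  invisible(x)
}

#' Generate noisy replicate ensemble time courses from a scheme
#'
#' The synthetic twin of stopped-flow / quench-flow data: the analytic
#' occupancy of the observable state set plus i.i.d. Gaussian noise per
#' point and replicate. A list of schemes with mixture weights produces a
#' kinetically heterogeneous (e.g. biphasic) ensemble, as arises when
#' parallel accommodation routes coexist.
#'
#' @param scheme a `scheme_graph`, or a list of them for a mixture.
#' @param observable observable state set (see [ensemble_timecourse]).
#' @param t_grid time grid (s).
#' @param noise_sd Gaussian noise s.d. per point (>= 0).
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param weights mixture weights when `scheme` is a list (normalized).
#' @return A `time_course` with `n_replicates` replicates.
#' @export
generate_ensemble_timecourse <- function(scheme, observable, t_grid,
                                         noise_sd = 0, n_replicates = 3L,
                                         seed = 1L, weights = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  schemes <- if (inherits(scheme, "scheme_graph")) list(scheme) else scheme
  if (is.null(weights)) weights <- rep(1, length(schemes))
  weights <- weights / sum(weights)
  base <- Reduce(`+`, Map(function(sc, w)
    w * ensemble_timecourse(sc, observable, t_grid)$signal,
    schemes, weights))
  seeds <- derive_seeds(seed, n_replicates)
  out <- lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_sd > 0)
      with_seed(seeds[r], stats::rnorm(length(t_grid), 0, noise_sd))
    else 0
    time_course(t_grid, base + noise, replicate = r,
                condition = schemes[[1]]$rateset_label)
  })
  structure(do.call(rbind, out), class = c("time_course", "data.frame"))
}

#' Generate synthetic exponential reaction courses
#'
#' Direct generator of one- or two-phase exponential time courses with
#' replicate structure, used to emulate stopped-flow fluorescence changes
#' (rising, amplitudes relative) and quench-flow product formation
#' (normalized 0 to 1).
#'
#' @param k rate constant(s) of the phase(s), s^-1.
#' @param amplitudes amplitude(s), same length as `k`.
#' @param t_grid time grid (s).
#' @param y0 offset (signal at t = 0 for the rising form).
#' @param noise_sd Gaussian noise s.d. per point.
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param form `"rising"` (`y0 + sum A_i (1 - exp(-k_i t))`) or
#'   `"decaying"` (`y0 + sum A_i exp(-k_i t)`).
#' @param condition condition label.
#' @return A `time_course`.
#' @examples
#' tc <- simulate_exponential_course(70, 1, seq(0, 0.1, length.out = 200),
#'                                   noise_sd = 0.01, n_replicates = 3,
#'                                   seed = 2)
#' @export
simulate_exponential_course <- function(k, amplitudes = rep(1, length(k)),
                                        t_grid, y0 = 0, noise_sd = 0,
                                        n_replicates = 1L, seed = 1L,
                                        form = c("rising", "decaying"),
                                        condition = "") {
  form <- match.arg(form)
  stopifnot(length(k) == length(amplitudes), all(k > 0))
  base <- y0 + Reduce(`+`, Map(function(ki, Ai) {
    if (form == "rising") Ai * (1 - exp(-ki * t_grid))
    else Ai * exp(-ki * t_grid)
  }, k, amplitudes))
  seeds <- derive_seeds(seed, n_replicates)
  out <- lapply(seq_len(n_replicates), function(r) {
    noise <- if (noise_sd > 0)
      with_seed(seeds[r], stats::rnorm(length(t_grid), 0, noise_sd))
    else 0
    time_course(t_grid, base + noise, replicate = r, condition = condition)
  })
  structure(do.call(rbind, out), class = c("time_course", "data.frame"))
}
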