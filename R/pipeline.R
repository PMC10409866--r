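#' Correct donor bleed-through in the acceptor channel
#'
#' Subtracts the experimentally determined fraction of donor emission
#' detected in the acceptor channel, framewise:
#' `acceptor' = acceptor - beta * donor`. The donor channel is unchanged.
#'
#' @param trace an `intensity_trace`.
#' @param beta bleed-through coefficient in `[0, 1)` (default 0.13).
#' @return The corrected trace.
#' @export
correct_bleedthrough <- function(trace, beta = 0.13) {
  if (beta < 0 || beta >= 1) stop("'beta' must be in [0, 1)")
  trace$acceptor <- trace$acceptor - beta * trace$donor
  trace
}

#' Compute the FRET efficiency trace
#'
#' Per-frame FRET efficiency `E = acceptor / (donor + acceptor)` on the
#' bleed-through-corrected channels. Frames with non-positive total
#' intensity and frames at or beyond the trace's truncation index
#' (photobleaching) are masked invalid; a fully invalid trace is flagged
#' and excluded downstream.
#'
#' @param trace a bleed-through-corrected `intensity_trace`.
#' @param truncate_at optional 1-based frame index of the first frame to
#'   discard (from QC bleach detection); frames `>= truncate_at` are
#'   masked.
#' @return A `fret_trace`: data frame with `frame`, `E`, `valid`;
#'   attributes `dt`, `molecule_id`, `truncate_at`.
#' @export
compute_fret <- function(trace, truncate_at = attr(trace, "truncate_at")) {
  tot <- trace$donor + trace$acceptor
  E <- ifelse(tot > 0, trace$acceptor / tot, NA_real_)
  valid <- tot > 0
  if (!is.null(truncate_at) && is.finite(truncate_at))
    valid <- valid & trace$frame < truncate_at
  out <- data.frame(frame = trace$frame, E = E, valid = valid)
  structure(out, dt = attr(trace, "dt"),
            molecule_id = attr(trace, "molecule_id"),
            truncate_at = truncate_at,
            all_invalid = !any(valid),
            class = c("fret_trace", "data.frame"))
}

# Count persistent downward steps in the total intensity (donor bleach
# events, or the stepwise darkening of a multi-fluorophore spot). Median
# smoothing suppresses single-frame noise; consecutive step frames are
# clustered into one event.
detect_bleach_steps <- function(trace, rel_threshold = 0.3, gap = 4L) {
  tot <- trace$donor + trace$acceptor
  n <- length(tot)
  if (n < 3L * gap) return(list(n_steps = 0L, first_step = NA_integer_))
  sm <- stats::runmed(tot, 7)
  scale <- max(abs(sm))
  if (scale <= 0) return(list(n_steps = 0L, first_step = NA_integer_))
  # level change across a short gap: the median filter spreads a sharp
  # step over several frames, so single-frame differences underestimate
  # its size
  d <- sm[(gap + 1L):n] - sm[1:(n - gap)]
  idx <- which(d < -rel_threshold * scale)
  if (!length(idx)) return(list(n_steps = 0L, first_step = NA_integer_))
  groups <- cumsum(c(1L, diff(idx) > gap))
  firsts <- tapply(idx, groups, min)
  list(n_steps = length(firsts),
       first_step = as.integer(firsts[[1]]) + gap %/% 2L)
}

#' Quality-control selection of single-molecule traces
#'
#' Keeps traces that behave like a single donor/acceptor pair: the
#' frame-difference correlation between the two channels must be at or
#' below the anticorrelation threshold (donor and acceptor move in
#' opposite directions at FRET transitions), and step detection on the
#' total intensity must find at most one photobleach step (more than one
#' indicates multiple fluorophores). The truncation index of kept traces
#' is set at the detected bleach step.
#'
#' @param traces a `trace_set` or list of `intensity_trace`s.
#' @param anticorr_threshold maximum allowed frame-difference correlation
#'   (default -0.1; traces must be at least this anticorrelated).
#' @param max_bleach_steps maximum number of bleach steps (default 1).
#' @param beta bleed-through coefficient used internally when assessing
#'   anticorrelation (donor bleed-through masks it); the returned traces
#'   themselves are not modified.
#' @return List with `traces` (kept, with `truncate_at` attribute set)
#'   and `report` (one row per input trace: molecule id, correlation,
#'   step count, kept flag).
#' @export
qc_select <- function(traces, anticorr_threshold = -0.1,
                      max_bleach_steps = 1L, beta = 0.13) {
  trs <- if (inherits(traces, "trace_set")) traces$traces else traces
  if (!length(trs)) stop("no traces supplied")
  rows <- vector("list", length(trs))
  kept <- vector("list", length(trs))
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    steps <- detect_bleach_steps(tr)
    # anticorrelation is assessed on the pre-bleach segment only: the
    # bleach step itself drops both channels together and would cancel
    # the FRET anticorrelation
    last <- if (!is.na(steps$first_step)) max(steps$first_step - 2L, 2L)
            else nrow(tr)
    acc <- tr$acceptor[1:last] - beta * tr$donor[1:last]
    dc <- suppressWarnings(stats::cor(diff(tr$donor[1:last]), diff(acc)))
    ok <- !is.na(dc) && dc <= anticorr_threshold &&
      steps$n_steps <= max_bleach_steps
    if (ok) {
      attr(tr, "truncate_at") <-
        if (steps$n_steps >= 1L) steps$first_step else Inf
      kept[[i]] <- tr
    }
    rows[[i]] <- data.frame(molecule_id = attr(tr, "molecule_id") %||%
                              as.character(i),
                            diff_correlation = dc,
                            n_bleach_steps = steps$n_steps,
                            kept = ok)
  }
  list(traces = Filter(Negate(is.null), kept),
       report = do.call(rbind, rows))
}

#' Extract dwell times for one transition class
#'
#' Collects, over a set of level-assigned idealized traces, the
#' residence times in the `from` level that end by a transition into the
#' `to` level. Dwells cut short by the end of the valid window
#' (photobleach or observation end) are right-censored: they are counted
#' and reported but excluded from the decay fit, and dwells ending in a
#' different destination level belong to a different transition class
#' and are ignored here.
#'
#' @param itraces list of [assign_levels] results.
#' @param from,to level names of the transition class, e.g.
#'   `"high" -> "dark"` for dissociation from codon reading.
#' @return A `dwell_distribution`: list with `dwells` (s), `n`,
#'   `n_censored`, `from`, `to`, `dt`.
#' @export
extract_dwells <- function(itraces, from, to) {
  dwells <- numeric(0)
  n_cens <- 0L
  dt <- NULL
  for (it in itraces) {
    if (is.null(it)) next
    segs <- it$segments
    if (is.null(segs$level)) stop("run assign_levels() before extract_dwells()")
    dt <- dt %||% it$dt
    m <- nrow(segs)
    if (m == 0L) next
    for (i in seq_len(m)) {
      if (segs$level[i] != from) next
      if (i == m) {                      # ends with the observation
        n_cens <- n_cens + 1L
      } else if (segs$level[i + 1L] == to) {
        dwells <- c(dwells, segs$t_end[i] - segs$t_start[i])
      }
    }
  }
  structure(list(dwells = dwells, n = length(dwells),
                 n_censored = n_cens, from = from, to = to, dt = dt),
            class = "dwell_distribution")
}

#' @export
print.dwell_distribution <- function(x, ...) {
  cat("Dwell distribution ", x$from, " -> ", x$to, ": n = ", x$n,
      " (+", x$n_censored, " censored)\n", sep = "")
  if (x$n) cat("mean dwell:", round(mean(x$dwells), 4), "s\n")
  if (!is.null(x$fit)) {
    cat("exponential fit: tau =", signif(x$fit$tau, 4),
        "s, k_observed =", signif(x$fit$k_observed, 4), "s^-1\n")
    if (!is.null(x$fit$k_corrected))
      cat("k_corrected =", signif(x$fit$k_corrected, 4), "s^-1\n")
  }
  invisible(x)
}

#' Fit an exponential decay to a dwell-time distribution
#'
#' Bins the (uncensored) dwell times, normalizes the histogram by its
#' maximum, and fits `y = y0 + A * exp(-t / tau)` by nonlinear least
#' squares. The fit starts at the later of the maximal bin and the
#' camera dead time: dwells shorter than roughly two frames are
#' under-detected at the acquisition's time resolution, so the first
#' bins of an observed histogram are depleted and would flatten the
#' decay if included (an exponential is memoryless, so on ideal data
#' the late start changes nothing). The decay rate from the histogram
#' fit is `k_observed = 1 / tau`.
#'
#' Because idealized dwell durations are quantized to whole camera
#' frames, the histogram least-squares estimate is sensitive to how bin
#' edges align with the frame grid when the mean dwell is only a few
#' frames. A quantization-aware maximum-likelihood estimate is
#' therefore computed alongside: frame counts at or above the dead time
#' follow a truncated geometric law whose per-frame survival equals
#' `exp(-k dt)`, giving `k_mle = -log(r_hat) / dt` with
#' `r_hat = (M - m) / (1 + M - m)` (`M` the mean frame count above the
#' truncation `m`). `k_mle` is exact for exponential dwells at any
#' frame rate and is what the high-level analysis uses for rate
#' estimation. Histograms that an exponential describes poorly (R^2
#' below `poor_fit_r2`) are flagged.
#'
#' @param d a `dwell_distribution`.
#' @param bin_frames histogram bin width in camera frames (default 2).
#' @param min_dwells minimum number of dwells required for a fit
#'   (default 20); below it the fit is refused and the dwells are
#'   returned unfitted.
#' @param dead_time detection dead time in seconds (default: 3 camera
#'   frames); bins below it are excluded from the fit and frame counts
#'   below it from the maximum-likelihood estimate.
#' @param poor_fit_r2 R^2 threshold below which `poor_fit` is flagged.
#' @return The `dwell_distribution` with a `fit` element: `y0`, `A`,
#'   `tau`, `k_observed`, `k_mle`, `r_squared`, `poor_fit`, and the
#'   histogram used.
#' @export
fit_dwell <- function(d, bin_frames = 2L, min_dwells = 20L,
                      dead_time = NULL, poor_fit_r2 = 0.9) {
  if (d$n < min_dwells) {
    warning("only ", d$n, " dwells (< ", min_dwells, "): fit refused")
    return(d)
  }
  dt <- d$dt %||% (1 / 30.3)
  bw <- bin_frames * dt
  dead_time <- dead_time %||% (3 * dt)
  breaks <- seq(0, max(d$dwells) + bw, by = bw)
  h <- graphics::hist(d$dwells, breaks = breaks, plot = FALSE)
  y <- h$counts / max(h$counts)
  t <- h$mids
  i_dead <- which(breaks >= dead_time - 1e-9)[1]
  if (is.na(i_dead)) i_dead <- 1L
  i0 <- min(max(which.max(h$counts), i_dead),
            max(1L, length(t) - 3L))
  t_fit <- t[i0:length(t)]
  y_fit <- y[i0:length(y)]
  tau0 <- max(mean(d$dwells), bw)
  fit <- tryCatch(
    minpack.lm::nlsLM(y_fit ~ y0 + A * exp(-t_fit / tau),
                      start = list(y0 = 0, A = max(y_fit), tau = tau0),
                      lower = c(-0.5, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("dwell fit did not converge")
    return(d)
  }
  cf <- stats::coef(fit)
  resid <- y_fit - stats::predict(fit)
  tss <- sum((y_fit - mean(y_fit))^2)
  r2 <- if (tss > 0) 1 - sum(resid^2) / tss else 1
  m <- max(1, round(dead_time / dt))
  fr <- round(d$dwells / dt)
  fr <- fr[fr >= m]
  k_mle <- if (length(fr) >= min_dwells && mean(fr) > m) {
    r_hat <- (mean(fr) - m) / (1 + mean(fr) - m)
    -log(r_hat) / dt
  } else 1 / mean(d$dwells)
  d$fit <- list(y0 = unname(cf["y0"]), A = unname(cf["A"]),
                tau = unname(cf["tau"]),
                k_observed = 1 / unname(cf["tau"]),
                k_mle = k_mle,
                r_squared = r2, poor_fit = r2 < poor_fit_r2,
                histogram = data.frame(t = t, y = y),
                fit_from_bin = i0)
  d
}

#' Photobleach and observation-window rate correction
#'
#' The decay of an observed dwell distribution contains, besides the
#' molecular transition of interest, the photobleaching hazard and the
#' finite observation window. The corrected rate is
#' `k_corrected = k_observed - k_photobleach - 1/T`. A negative result
#' means the molecular rate is indistinguishable from photobleaching at
#' this window; it is returned as-is with a warning attribute rather
#' than clamped.
#'
#' @param k_observed observed dwell decay rate (s^-1), or a fitted
#'   `dwell_distribution`.
#' @param k_photobleach photobleaching rate (s^-1, default 0.03).
#' @param window observation window T (s, default 33); must be > 0.
#' @return Corrected rate (s^-1) with logical attribute `below_floor`,
#'   or the `dwell_distribution` with `fit$k_corrected` added.
#' @examples
#' correct_rate(1.0, 0.03, 33)   # 0.9397
#' @export
correct_rate <- function(k_observed, k_photobleach = 0.03, window = 33) {
  if (window <= 0) stop("'window' must be > 0")
  if (inherits(k_observed, "dwell_distribution")) {
    d <- k_observed
    if (is.null(d$fit)) stop("fit the dwell distribution first")
    d$fit$k_corrected <- as.numeric(
      correct_rate(d$fit$k_observed, k_photobleach, window))
    return(d)
  }
  k <- k_observed - k_photobleach - 1 / window
  if (any(k < 0)) warning("corrected rate is negative: ",
                          "indistinguishable from photobleaching")
  structure(k, below_floor = k < 0)
}

#' Missed-event (dead-time) correction for a reversible two-state phase
#'
#' At a finite frame rate, excursions to the opposite state that are
#' shorter than the detection dead time are not resolved; the flanking
#' dwells are then concatenated, which biases both fitted decay rates
#' downward. For a two-state fluctuation (e.g. the classical/hybrid
#' tRNA cycle) the first-order correction of the mean observed dwell is
#' `E[obs_A] = (1/k_A) / (1 - p_B) + p_B/(1 - p_B) * g_B`, where
#' `p_B = 1 - exp(-k_B * tau_d)` is the probability that a B excursion
#' falls below the dead time `tau_d` and `g_B = E[d_B | d_B < tau_d]`.
#' The pair of equations is solved for the true rates by fixed-point
#' iteration from the raw fitted rates.
#'
#' @param k_fwd,k_rev raw fitted decay rates (s^-1) of the A->B and
#'   B->A dwell distributions.
#' @param dead_time effective detection dead time (s); default 0.75
#'   camera frames at 30.3 fps — excursions below roughly half to one
#'   frame are invisible after frame averaging.
#' @param max_iter,tol fixed-point iteration controls.
#' @return Named vector `c(k_fwd, k_rev)` of corrected rates.
#' @export
correct_missed_events <- function(k_fwd, k_rev,
                                  dead_time = 0.75 / 30.3,
                                  max_iter = 50L, tol = 1e-10) {
  stopifnot(k_fwd > 0, k_rev > 0, dead_time >= 0)
  if (dead_time == 0) return(c(k_fwd = k_fwd, k_rev = k_rev))
  mean_obs <- c(1 / k_fwd, 1 / k_rev)
  k <- c(k_fwd, k_rev)
  short_mean <- function(k) {          # E[d | d < tau_d] for exp(k)
    p <- 1 - exp(-k * dead_time)
    1 / k - dead_time * exp(-k * dead_time) / p
  }
  for (it in seq_len(max_iter)) {
    k_old <- k
    for (a in 1:2) {
      b <- 3L - a
      p_b <- 1 - exp(-k[b] * dead_time)
      inv <- (1 - p_b) * mean_obs[a] - p_b * short_mean(k[b])
      if (inv > 0) k[a] <- 1 / inv
    }
    if (max(abs(k - k_old) / k_old) < tol) break
  }
  c(k_fwd = k[1], k_rev = k[2])
}

#' Fit a sum of Gaussians to pooled FRET histograms
#'
#' Pools the selected frames of each replicate into a FRET histogram and
#' fits a sum of `n_components` Gaussian functions by nonlinear least
#' squares (with quantile-based starts and jittered restarts on
#' non-convergence). Component means are reported per replicate and
#' aggregated as mean +/- s.d. across replicates; components are ordered
#' by increasing mean.
#'
#' @param E_by_replicate list of numeric vectors: the selected FRET
#'   values of each replicate.
#' @param n_components number of Gaussian components.
#' @param binwidth histogram bin width in FRET units (default 0.01).
#' @param min_frames minimum pooled frames required (default 100).
#' @return A `fret_mixture`: list with `replicates` (per-replicate
#'   component tables `mu`, `sigma`, `weight`), `mu_mean`, `mu_sd`
#'   (across replicates, by component), `n_frames`.
#' @export
fit_fret_histogram <- function(E_by_replicate, n_components = 1L,
                               binwidth = 0.01, min_frames = 100L) {
  if (is.numeric(E_by_replicate)) E_by_replicate <- list(E_by_replicate)
  E_by_replicate <- lapply(E_by_replicate, function(e) e[is.finite(e)])
  n_tot <- sum(lengths(E_by_replicate))
  if (n_tot < min_frames)
    stop("only ", n_tot, " frames selected (need >= ", min_frames, ")")
  fit_one <- function(E) {
    breaks <- seq(min(E) - binwidth, max(E) + binwidth, by = binwidth)
    h <- graphics::hist(E, breaks = breaks, plot = FALSE)
    x <- h$mids; y <- h$density
    qs <- stats::quantile(E, probs = (seq_len(n_components) - 0.5) /
                            n_components)
    s0 <- max(stats::sd(E) / n_components, binwidth)
    nm <- seq_len(n_components)
    form <- stats::as.formula(paste(
      "y ~", paste(sprintf("A%d * exp(-(x - mu%d)^2 / (2 * s%d^2))",
                           nm, nm, nm), collapse = " + ")))
    make_start <- function(jit) {
      st <- c(as.list(stats::setNames(pmax(qs + jit, 0), paste0("mu", nm))),
              as.list(stats::setNames(rep(s0, n_components),
                                      paste0("s", nm))),
              as.list(stats::setNames(rep(max(y), n_components),
                                      paste0("A", nm))))
      st
    }
    fit <- NULL
    for (jit in c(0, -0.03, 0.03)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = data.frame(x = x, y = y),
                          start = make_start(jit),
                          lower = c(rep(-0.2, n_components),
                                    rep(binwidth / 4, n_components),
                                    rep(0, n_components)),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("Gaussian-sum histogram fit did not converge")
    cf <- stats::coef(fit)
    mu <- cf[paste0("mu", nm)]
    s <- cf[paste0("s", nm)]
    A <- cf[paste0("A", nm)]
    area <- A * s
    ord <- order(mu)
    data.frame(mu = unname(mu[ord]), sigma = unname(s[ord]),
               weight = unname(area[ord] / sum(area)))
  }
  reps <- lapply(E_by_replicate, fit_one)
  mu_mat <- vapply(reps, function(r) r$mu, numeric(n_components))
  mu_mat <- matrix(mu_mat, nrow = n_components)
  structure(list(replicates = reps,
                 mu_mean = rowMeans(mu_mat),
                 mu_sd = apply(mu_mat, 1L, stats::sd),
                 n_frames = n_tot),
            class = "fret_mixture")
}

#' @export
print.fret_mixture <- function(x, ...) {
  cat("Gaussian-sum FRET histogram fit over", length(x$replicates),
      "replicate(s),", x$n_frames, "frames\n")
  for (i in seq_along(x$mu_mean))
    cat(sprintf("  component %d: mu = %.3f +/- %.3f\n", i,
                x$mu_mean[i],
                if (is.na(x$mu_sd[i])) 0 else x$mu_sd[i]))
  invisible(x)
}

#' @export
coef.fret_mixture <- function(object, ...) object$mu_mean

#' Classify an idealized trace mechanistically
#'
#' Assigns one of the four observable trace phenotypes based on the
#' sequence of resolved FRET levels: `rejected` (FRET appears at the
#' high codon-reading level and returns to dark without visiting the
#' post-decoding 0.8/0.6 levels), `decoding` (high-FRET phase followed
#' by at least one post-decoding dwell), `post_decoding` (the first
#' resolved phase is already at the 0.8/0.6 levels), and `stalled`
#' (high-FRET phase persisting to the end of the valid window without
#' progression). A phase counts as resolved when it lasts at least
#' `min_frames` frames; classification follows the trace's first
#' resolved bright phase, and traces with none are `"dark"`
#' (unclassifiable, excluded from fractions but counted). The
#' post-decoding call additionally requires that the first resolved
#' phase begins within `early_window` (post-decoding complexes are
#' already fluctuating when the recording starts); a later-appearing
#' classical/hybrid phase without a resolved codon-reading phase is a
#' decoding event whose brief codon-reading dwell fell below the frame
#' rate.
#'
#' @param itrace an [assign_levels] result.
#' @param min_frames minimum resolved phase duration in frames.
#' @param early_window latest start (s) of the first resolved phase for
#'   a post-decoding call; default 10 frames.
#' @return A character class.
#' @export
classify_trace <- function(itrace, min_frames = 2L,
                           early_window = 10 * itrace$dt) {
  segs <- itrace$segments
  if (is.null(segs$level)) stop("run assign_levels() before classify_trace()")
  if (nrow(segs) == 0L) return("dark")
  lev <- segs$level
  dur <- segs$t_end - segs$t_start
  resolved <- dur >= min_frames * itrace$dt
  bright <- resolved & lev != "dark"
  if (!any(bright)) return("dark")
  classify_phase_sequence(lev, resolved, which(bright)[1],
                          segs$t_start, early_window)
}

#' Class fractions with replicate statistics
#'
#' Computes, per replicate, the percentage of classified traces in each
#' mechanistic class, aggregates across replicates (mean +/- s.d.), and,
#' when two conditions are supplied, compares each class fraction
#' between conditions with a two-tailed Welch's t-test (no multiplicity
#' adjustment).
#'
#' @param classes character vector of per-trace classes.
#' @param replicate parallel replicate ids.
#' @param condition optional parallel condition labels (at most two
#'   distinct values for testing).
#' @return A `classification_result`: list with `fractions` (one row per
#'   condition x replicate x class), `summary` (mean +/- s.d. by
#'   condition and class) and `tests` (Welch's t per class, `NULL` if
#'   fewer than two replicates or one condition).
#' @export
class_fractions <- function(classes, replicate, condition = NULL) {
  keep <- classes != "dark"
  df <- data.frame(class = classes[keep],
                   replicate = replicate[keep],
                   condition = if (is.null(condition)) ""
                               else condition[keep])
  all_classes <- c("rejected", "decoding", "post_decoding", "stalled")
  frac <- do.call(rbind, lapply(split(df, df[c("replicate", "condition")],
                                      drop = TRUE), function(g) {
    tab <- table(factor(g$class, levels = all_classes))
    data.frame(condition = g$condition[1], replicate = g$replicate[1],
               class = all_classes,
               percent = 100 * as.numeric(tab) / sum(tab))
  }))
  rownames(frac) <- NULL
  summ <- do.call(rbind, lapply(split(frac, frac[c("class", "condition")],
                                      drop = TRUE), function(g)
    data.frame(condition = g$condition[1], class = g$class[1],
               mean = mean(g$percent),
               sd = if (nrow(g) > 1) stats::sd(g$percent) else NA_real_,
               n_replicates = nrow(g))))
  rownames(summ) <- NULL
  tests <- NULL
  conds <- unique(frac$condition)
  if (length(conds) == 2L &&
      min(table(frac$condition)) >= 2L * length(all_classes)) {
    tests <- do.call(rbind, lapply(all_classes, function(cl) {
      a <- frac$percent[frac$class == cl & frac$condition == conds[1]]
      b <- frac$percent[frac$class == cl & frac$condition == conds[2]]
      ht <- welch_or_degenerate(a, b)
      data.frame(class = cl, statistic = ht$statistic, p_value = ht$p.value,
                 test = "Welch two-sample t-test")
    }))
  }
  structure(list(fractions = frac, summary = summ, tests = tests),
            class = "classification_result")
}

# Welch's t that tolerates degenerate (zero-variance) groups: identical
# constant groups compare as p = 1, constant but different groups as
# p = 0.
welch_or_degenerate <- function(a, b) {
  out <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
  if (!is.null(out))
    return(list(statistic = unname(out$statistic), p.value = out$p.value))
  if (isTRUE(all.equal(mean(a), mean(b))))
    list(statistic = 0, p.value = 1)
  else
    list(statistic = Inf, p.value = 0)
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Trace class fractions (percent, mean +/- s.d. across replicates):\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nPairwise Welch tests between conditions:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Post-synchronized FRET contour histogram
#'
#' Time-shifts every trace so that its first FRET appearance (the first
#' run of at least `min_frames` frames with `E >= threshold`) sits at
#' t = 0, then pools the shifted frames into a two-dimensional
#' (time x FRET) histogram. Traces without a qualifying event are
#' excluded and counted.
#'
#' @param ftraces list of `fret_trace` objects.
#' @param threshold detection threshold for "FRET > 0" (default 0.125,
#'   the dark-state noise floor).
#' @param min_frames consecutive frames required above threshold.
#' @param t_max contour duration after synchronization (s).
#' @param e_breaks FRET bin edges.
#' @return A `fret_contour`: list with `counts` (time x FRET matrix),
#'   `t_mids`, `e_mids`, `n_traces`, `n_excluded`.
#' @export
synchronize_contour <- function(ftraces, threshold = 0.125,
                                min_frames = 2L, t_max = 10,
                                e_breaks = seq(-0.2, 1.2, by = 0.02)) {
  dt <- NULL
  shifted_t <- numeric(0)
  shifted_E <- numeric(0)
  n_used <- 0L; n_excl <- 0L
  for (ft in ftraces) {
    dt <- dt %||% attr(ft, "dt")
    E <- ft$E; ok <- ft$valid & is.finite(E)
    above <- ok & E >= threshold
    r <- rle(above)
    hit <- which(r$values & r$lengths >= min_frames)
    if (!length(hit)) { n_excl <- n_excl + 1L; next }
    first <- sum(r$lengths[seq_len(hit[1] - 1L)]) + 1L
    sel <- which(ok & ft$frame >= ft$frame[first])
    tt <- (ft$frame[sel] - ft$frame[first]) * dt
    keep <- tt <= t_max
    shifted_t <- c(shifted_t, tt[keep])
    shifted_E <- c(shifted_E, E[sel][keep])
    n_used <- n_used + 1L
  }
  t_breaks <- seq(0, t_max + dt, by = dt)
  ti <- findInterval(shifted_t, t_breaks, rightmost.closed = TRUE)
  ei <- findInterval(shifted_E, e_breaks, rightmost.closed = TRUE)
  inb <- ti >= 1 & ti < length(t_breaks) & ei >= 1 & ei < length(e_breaks)
  counts <- matrix(0L, length(t_breaks) - 1L, length(e_breaks) - 1L)
  if (any(inb)) {
    tab <- table(factor(ti[inb], levels = seq_len(nrow(counts))),
                 factor(ei[inb], levels = seq_len(ncol(counts))))
    counts <- matrix(as.integer(tab), nrow(counts), ncol(counts))
  }
  structure(list(counts = counts,
                 t_mids = t_breaks[-length(t_breaks)] + dt / 2,
                 e_mids = (e_breaks[-length(e_breaks)] +
                             e_breaks[-1]) / 2,
                 n_traces = n_used, n_excluded = n_excl),
            class = "fret_contour")
}

#' @export
print.fret_contour <- function(x, ...) {
  cat("Synchronized FRET contour:", x$n_traces, "traces pooled,",
      x$n_excluded, "excluded (no FRET appearance);",
      nrow(x$counts), "time bins x", ncol(x$counts), "FRET bins\n")
  invisible(x)
}
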