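#' Draw a single-step photobleaching time
#'
#' Photobleaching of the dye pair is modelled as a single exponential
#' event with the camera model's `k_photobleach`; a rate of zero means no
#' bleaching within any window.
#'
#' @param cam a [camera_model].
#' @param seed optional integer seed.
#' @return Bleaching time in seconds (`Inf` if the rate is 0).
#' @export
sample_bleach_time <- function(cam, seed = NULL) {
  if (cam$k_photobleach == 0) return(Inf)
  with_seed(seed, stats::rexp(1L, cam$k_photobleach))
}

# Occupancy-time-weighted mean state FRET per camera frame. Frame i
# (1-based) integrates the interval ((i-1) dt, i dt]; a state switch
# inside a frame contributes proportionally to its residence time.
frame_average_fret <- function(traj, fmap, n_frames, dt) {
  E <- numeric(n_frames)
  for (s in seq_len(nrow(traj))) {
    e_state <- fmap$means[[traj$state[s]]]
    if (is.null(e_state)) stop("no FRET mean for state ", traj$state[s])
    f0 <- floor(traj$t_enter[s] / dt) + 1L
    f1 <- min(ceiling(traj$t_exit[s] / dt), n_frames)
    if (f0 > n_frames || f1 < f0) next
    fr <- f0:f1
    overlap <- pmin(traj$t_exit[s], fr * dt) -
               pmax(traj$t_enter[s], (fr - 1) * dt)
    E[fr] <- E[fr] + e_state * overlap / dt
  }
  E
}

#' Render a mechanistic trajectory into a two-channel intensity trace
#'
#' Forward model of the acquisition: per frame the true FRET efficiency
#' is the occupancy-time-weighted mean of the state FRET values within
#' the frame; donor and acceptor intensities are
#' `I_tot * (1 - E)` and `I_tot * E` plus Gaussian channel noise; the
#' recorded acceptor additionally receives the bleed-through fraction
#' `beta * donor`. After the sampled photobleaching event the affected
#' channel(s) drop: a donor bleach darkens both channels, an acceptor
#' bleach darkens the acceptor while the donor recovers its full
#' unquenched intensity.
#'
#' @param traj a [simulate_trajectory] result.
#' @param fmap a [fret_map].
#' @param cam a [camera_model].
#' @param seed optional integer seed.
#' @param bleach_mode `"donor_or_acceptor"` (default: the bleaching
#'   fluorophore is drawn with equal probability), `"donor"`,
#'   `"acceptor"`, or `"none"`.
#' @param noiseless if `TRUE`, channel noise is suppressed (useful for
#'   exact checks of the rendering algebra).
#' @return An `intensity_trace`: a data frame with columns `frame`,
#'   `donor`, `acceptor`; attributes `dt`, `molecule_id`, and a `truth`
#'   list carrying the source trajectory, bleach time/mode and the
#'   ground-truth trace class.
#' @examples
#' sc <- build_scheme(decoding_rates("AAA"), "wildtype")
#' tr <- simulate_trajectory(sc, 33, seed = 7)
#' it <- render_trace(tr, fret_map(), camera_model(), seed = 7)
#' head(it)
#' @export
render_trace <- function(traj, fmap, cam, seed = NULL,
                         bleach_mode = c("donor_or_acceptor", "donor",
                                         "acceptor", "none"),
                         noiseless = FALSE) {
  bleach_mode <- match.arg(bleach_mode)
  horizon <- attr(traj, "horizon")
  if (is.null(horizon) || nrow(traj) == 0L)
    stop("empty trajectory: nothing to render")
  n_frames <- floor(horizon * cam$frame_rate + 1e-9)
  if (n_frames < 1L) stop("trajectory horizon shorter than one frame")
  dt <- cam$dt

  with_seed(seed, {
    E <- frame_average_fret(traj, fmap, n_frames, dt)
    if (bleach_mode == "none") {
      t_bleach <- Inf; which_dye <- "none"
    } else {
      t_bleach <- sample_bleach_time(cam)
      which_dye <- switch(bleach_mode,
        donor_or_acceptor = if (stats::runif(1) < 0.5) "donor" else "acceptor",
        bleach_mode)
    }
    # fraction of each frame acquired before the bleach event
    f_pre <- pmin(pmax(t_bleach / dt - (seq_len(n_frames) - 1L), 0), 1)
    I <- cam$total_intensity
    donor <- I * (1 - E) * f_pre
    acceptor <- I * E * f_pre
    if (which_dye == "acceptor") {
      # donor is unquenched once the acceptor is gone
      donor <- donor + I * (1 - f_pre)
    }
    if (!noiseless) {
      donor <- donor + stats::rnorm(n_frames, 0, cam$noise_sd)
      acceptor <- acceptor + stats::rnorm(n_frames, 0, cam$noise_sd)
    }
    acceptor <- acceptor + cam$bleed_through * donor
    truth <- list(trajectory = traj,
                  bleach_time = t_bleach,
                  bleach_mode = which_dye,
                  class = trajectory_class(traj, cam,
                                           t_bleach = t_bleach,
                                           fmap = fmap))
    structure(data.frame(frame = seq_len(n_frames),
                         donor = donor, acceptor = acceptor),
              dt = dt, molecule_id = NA_character_, truth = truth,
              class = c("intensity_trace", "data.frame"))
  })
}

#' Add donor bleed-through to the acceptor channel
#'
#' The forward counterpart of [correct_bleedthrough]; adding and then
#' correcting with the same coefficient is the identity.
#'
#' @param trace an `intensity_trace`.
#' @param beta bleed-through coefficient in `[0, 1)`.
#' @return The trace with `acceptor + beta * donor`.
#' @export
add_bleedthrough <- function(trace, beta) {
  if (beta < 0 || beta >= 1) stop("'beta' must be in [0, 1)")
  trace$acceptor <- trace$acceptor + beta * trace$donor
  trace
}

# Map mechanistic states to observable FRET levels.
state_level <- function(states) {
  lv <- c(UNBOUND = "dark", DROPPED = "dark",
          IB = "high", CR = "high", POST_GTP = "high",
          ACCOMMODATED_CLASSICAL = "classical", HYBRID_APstar = "hybrid")
  unname(lv[states])
}

# Ground-truth class of a trajectory as an ideal observer would see it:
# the state path is truncated at min(bleach, horizon), mapped to FRET
# levels, and only bright phases lasting at least `min_frames` camera
# frames count as resolved. Classification follows the first resolved
# phase: post-decoding if it is already classical/hybrid; otherwise
# decoding if a classical/hybrid phase follows, rejected if the
# high-FRET phase returns to dark within the observation, stalled if it
# persists to the end.
trajectory_class <- function(traj, cam, t_bleach = Inf, fmap = NULL,
                             min_frames = 2L) {
  t_end <- min(attr(traj, "horizon"), t_bleach)
  keep <- traj$t_enter < t_end
  if (!any(keep)) return("dark")
  seg <- traj[keep, , drop = FALSE]
  seg$t_exit <- pmin(seg$t_exit, t_end)
  lev <- state_level(seg$state)
  r <- rle(lev)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  dur <- seg$t_exit[idx_end] - seg$t_enter[idx_start]
  level <- r$values
  resolved <- dur >= min_frames * cam$dt
  bright <- resolved & level != "dark"
  if (!any(bright)) return("dark")
  first <- which(bright)[1]
  classify_phase_sequence(level, resolved, first,
                          seg$t_enter[idx_start],
                          early_window = 10 * cam$dt)
}

# Shared first-phase classification rule, applied identically to true
# state paths and to idealized traces. Post-decoding means the complex
# is already fluctuating at the 0.8/0.6 levels when recording starts,
# so the first resolved bright phase must both sit at those levels and
# begin within `early_window`. A classical/hybrid phase appearing later
# implies the tRNA accommodated during the observation with the brief
# codon-reading phase unresolved at the frame rate: a decoding event.
# A first high phase is classified by what follows it: a resolved
# classical/hybrid phase (decoding), a resolved dark phase (rejected),
# or nothing until the end of the valid window (stalled);
# sub-resolution blips between phases are ignored.
classify_phase_sequence <- function(level, resolved, first, t_start,
                                    early_window) {
  if (level[first] %in% c("classical", "hybrid"))
    return(if (t_start[first] <= early_window) "post_decoding"
           else "decoding")
  i <- first + 1L
  while (i <= length(level)) {
    if (resolved[i]) {
      if (level[i] %in% c("classical", "hybrid")) return("decoding")
      if (level[i] == "dark") return("rejected")
      # another resolved high phase: continuation, keep scanning
    }
    i <- i + 1L
  }
  "stalled"
}
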