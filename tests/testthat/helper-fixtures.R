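# Shared builders for synthetic fixtures; everything is generated in
# code at test time.

rs_simple <- function(k1_app = 0.5, k_rev1 = 8.1, k2 = 30, k_rev2 = 0.34,
                      k_gtp = 6.3, k45 = 2.9, k7 = 0.1, k_hyb_fwd = 2.9,
                      k_hyb_rev = 4.4, label = "test") {
  rate_set(k1_app = k1_app, k_rev1 = k_rev1, k2 = k2, k_rev2 = k_rev2,
           k_gtp = k_gtp, k45 = k45, k7 = k7, k_hyb_fwd = k_hyb_fwd,
           k_hyb_rev = k_hyb_rev, label = label)
}

# random small rate set for property sweeps
rs_random <- function() {
  rate_set(k1_app = runif(1, 0.2, 2), k_rev1 = runif(1, 1, 20),
           k2 = runif(1, 5, 40), k_rev2 = runif(1, 0.1, 2),
           k_gtp = runif(1, 1, 10), k45 = runif(1, 0.5, 5),
           k7 = runif(1, 0, 2), k_hyb_fwd = runif(1, 1, 5),
           k_hyb_rev = runif(1, 1, 6), label = "random")
}

# hand-built mechanistic trajectory
traj_manual <- function(states, t_enter, t_exit, horizon) {
  structure(data.frame(state = states, t_enter = t_enter, t_exit = t_exit),
            horizon = horizon, seed = NULL, rateset_label = "manual",
            class = c("state_trajectory", "data.frame"))
}

# hand-built FRET trace (already corrected)
fret_manual <- function(E, dt = 1 / 30.3, valid = rep(TRUE, length(E)),
                        id = "manual") {
  structure(data.frame(frame = seq_along(E), E = E, valid = valid),
            dt = dt, molecule_id = id, truncate_at = Inf,
            all_invalid = !any(valid),
            class = c("fret_trace", "data.frame"))
}

# hand-built idealized trace (for filter/assignment unit tests)
itrace_manual <- function(mu, dur_frames, sigma = 0.05, dt = 1 / 30.3,
                          mu_obs = mu) {
  ends <- cumsum(dur_frames)
  starts <- c(1, head(ends, -1) + 1)
  structure(list(segments = data.frame(
    state = seq_along(mu), mu = mu, mu_obs = mu_obs, sigma = sigma,
    start_frame = starts, end_frame = ends,
    t_start = (starts - 1) * dt, t_end = ends * dt),
    n_states = length(unique(mu)), bic = NA_real_, dt = dt,
    molecule_id = "manual", n_valid = sum(dur_frames)),
    class = "idealized_trace")
}

# standard small analysis configs
cfg_high <- function(...) analysis_config(levels = c(dark = 0, high = 0.9),
                                          ...)
cfg_hybrid <- function(...) analysis_config(
  levels = c(dark = 0, classical = 0.8, hybrid = 0.6), ...)
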