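#' Per-state FRET emission parameters
#'
#' Maps each mechanistic state to the mean FRET efficiency and Gaussian
#' width of the donor/acceptor pair reporting on tRNA position (donor on
#' ribosomal protein L11, acceptor on the tRNA elbow). Defaults: no FRET
#' while unbound; ~0.9 for initial binding, codon reading and the
#' post-hydrolysis state (not distinguishable by FRET level, only by
#' progression); ~0.8 for the classical A/A, A/P configurations; ~0.6 for
#' the hybrid A/P* state.
#'
#' @param means named numeric vector of state FRET means in `[0, 1]`;
#'   names must cover the states being rendered.
#' @param sd per-state Gaussian width; a single value is recycled. This
#'   width is informational ground truth for the generator (the rendered
#'   noise level is set by the [camera_model]).
#' @return An object of class `fret_map`.
#' @examples
#' fret_map()            # package defaults
#' fret_map(means = c(ACCOMMODATED_CLASSICAL = 0.79, HYBRID_APstar = 0.58))
#' @export
fret_map <- function(means = NULL, sd = 0.05) {
  defaults <- c(UNBOUND = 0, IB = 0.9, CR = 0.9, POST_GTP = 0.9,
                ACCOMMODATED_CLASSICAL = 0.8, HYBRID_APstar = 0.6,
                DROPPED = 0)
  if (!is.null(means)) defaults[names(means)] <- means
  if (any(defaults < 0 | defaults > 1))
    stop("state FRET means must lie in [0, 1]")
  sds <- rep_len(sd, length(defaults))
  names(sds) <- names(defaults)
  if (any(sds <= 0)) stop("state FRET widths must be > 0")
  structure(list(means = defaults, sds = sds), class = "fret_map")
}

#' Camera and photophysics model for trace rendering
#'
#' Describes the acquisition: EMCCD frame rate, total emitted intensity
#' per frame, Gaussian read noise per channel, donor-to-acceptor
#' bleed-through, the observation window, and single-step photobleaching.
#' If `noise_sd` is not given it is derived from the requested FRET-level
#' width `fret_sd` by linear error propagation of E = A / (D + A) at a
#' reference efficiency of 0.8, so that rendered FRET states have
#' approximately the requested Gaussian width.
#'
#' @param frame_rate frames per second (default 30.3).
#' @param total_intensity summed donor + acceptor intensity per frame
#'   while the pair is active (arbitrary units).
#' @param fret_sd target Gaussian width of rendered FRET states.
#' @param noise_sd per-channel additive Gaussian noise s.d.; overrides
#'   `fret_sd` when supplied.
#' @param bleed_through fraction of donor emission detected in the
#'   acceptor channel (beta, default 0.13).
#' @param window observation window T (s, default 33).
#' @param k_photobleach single-step photobleaching rate (s^-1, default
#'   0.03).
#' @return An object of class `camera_model`.
#' @examples
#' camera_model()
#' @export
camera_model <- function(frame_rate = 30.3, total_intensity = 1000,
                         fret_sd = 0.05, noise_sd = NULL,
                         bleed_through = 0.13, window = 33,
                         k_photobleach = 0.03) {
  if (frame_rate <= 0) stop("'frame_rate' must be > 0")
  if (bleed_through < 0 || bleed_through >= 1)
    stop("'bleed_through' must be in [0, 1)")
  if (window <= 0) stop("'window' must be > 0")
  if (k_photobleach < 0) stop("'k_photobleach' must be >= 0")
  ref_E <- 0.8
  if (is.null(noise_sd))
    noise_sd <- fret_sd * total_intensity / sqrt(ref_E^2 + (1 - ref_E)^2)
  structure(list(frame_rate = frame_rate, dt = 1 / frame_rate,
                 total_intensity = total_intensity, noise_sd = noise_sd,
                 fret_sd = fret_sd, bleed_through = bleed_through,
                 window = window, k_photobleach = k_photobleach),
            class = "camera_model")
}
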