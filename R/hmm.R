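#' Idealize a FRET trace with a Gaussian-emission hidden Markov model
#'
#' Fits maximum-likelihood Gaussian-emission HMMs with 1 to `max_states`
#' states to the valid portion of the trace (Baum-Welch), selects the
#' state count by BIC, and decodes the most probable state path
#' (Viterbi) into a piecewise-constant idealization. Means are
#' initialized at evenly spaced quantiles of the data, which makes the
#' fit deterministic.
#'
#' @param ftrace a `fret_trace` from [compute_fret].
#' @param max_states maximum number of HMM states considered (default 4).
#' @param min_frames minimum number of valid frames required (default
#'   10); shorter traces return `NULL` with a message.
#' @param sigma_floor lower bound on fitted state widths; keeps the
#'   likelihood bounded on noise-free data.
#' @param sigma_ceiling upper bound on fitted state widths (default
#'   0.15 FRET units). Genuine FRET states are narrow; without the
#'   ceiling the likelihood can favour one broad component that acts as
#'   an outlier catch-all for camera-integration boundary frames and
#'   swallows real states.
#' @return An `idealized_trace`: list with `segments` (data frame:
#'   `state`, `mu`, `sigma`, `start_frame`, `end_frame`, `t_start`,
#'   `t_end`), the chosen `n_states`, the per-candidate `bic` vector,
#'   `dt`, and `molecule_id`. Segment times are relative to the first
#'   valid frame's start.
#' @examples
#' sc <- build_scheme(decoding_rates("AAA"), "hybrid_only")
#' tr <- simulate_trajectory(sc, 20, seed = 3,
#'                           init = "ACCOMMODATED_CLASSICAL")
#' it <- render_trace(tr, fret_map(), camera_model(), seed = 3,
#'                    bleach_mode = "none")
#' ft <- compute_fret(correct_bleedthrough(it, 0.13))
#' idealize(ft)$n_states
#' @export
idealize <- function(ftrace, max_states = 4L, min_frames = 10L,
                     sigma_floor = 1e-3, sigma_ceiling = 0.15) {
  valid <- which(ftrace$valid)
  if (length(valid) < min_frames) {
    message("trace ", attr(ftrace, "molecule_id") %||% "?",
            " skipped: fewer than ", min_frames, " valid frames")
    return(NULL)
  }
  x <- ftrace$E[valid]
  n <- length(x)
  fits <- vector("list", max_states)
  bic <- rep(NA_real_, max_states)
  for (K in seq_len(max_states)) {
    # two deterministic initializations: evenly spaced quantiles, and
    # k-means-refined centres; keep the better likelihood
    mu_q <- unname(stats::quantile(x, probs = (seq_len(K) - 0.5) / K))
    s_all <- max(stats::sd(x), sigma_floor, na.rm = TRUE)
    inits <- list(list(mu = mu_q, s = rep(max(s_all / sqrt(K), sigma_floor),
                                          K)))
    if (K > 1 && length(unique(mu_q)) == K) {
      km <- tryCatch(stats::kmeans(x, centers = mu_q, iter.max = 25L),
                     error = function(e) NULL)
      if (!is.null(km)) {
        ord <- order(km$centers[, 1])
        s_km <- sqrt(km$withinss / pmax(km$size - 1, 1))[ord]
        inits <- c(inits, list(list(mu = km$centers[ord, 1],
                                    s = pmax(s_km, sigma_floor))))
      }
    }
    fit <- NULL
    for (ini in inits) {
      f <- ghmm_em_cpp(x, ini$mu, pmin(ini$s, sigma_ceiling),
                       max_iter = 50L, tol = 1e-7,
                       sigma_floor = sigma_floor,
                       sigma_ceiling = sigma_ceiling)
      if (is.null(fit) || f$loglik > fit$loglik) fit <- f
    }
    n_par <- (K - 1) + K * (K - 1) + 2 * K
    bic[K] <- -2 * fit$loglik + n_par * log(n)
    fits[[K]] <- fit
    # stop scanning only after two consecutive BIC increases: a single
    # increase can be an EM local optimum at the intermediate K
    if (K > 2 && bic[K] > bic[K - 1] && bic[K - 1] > bic[K - 2]) break
  }
  K <- which.min(bic)
  fit <- fits[[K]]
  path <- ghmm_viterbi_cpp(x, fit$mu, fit$sigma, fit$trans, fit$init)
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- attr(ftrace, "dt")
  # robust per-dwell level estimate: median over interior frames (the
  # first/last frame of a dwell average over the state switch)
  mu_obs <- vapply(seq_along(starts), function(i) {
    ix <- starts[i]:ends[i]
    if (length(ix) >= 3L) ix <- ix[-c(1L, length(ix))]
    stats::median(x[ix])
  }, numeric(1))
  segs <- data.frame(state = r$values,
                     mu = fit$mu[r$values],
                     mu_obs = mu_obs,
                     sigma = fit$sigma[r$values],
                     start_frame = valid[starts],
                     end_frame = valid[ends],
                     t_start = (valid[starts] - 1L) * dt,
                     t_end = valid[ends] * dt)
  structure(list(segments = segs, n_states = K, bic = bic, dt = dt,
                 molecule_id = attr(ftrace, "molecule_id"),
                 n_valid = n),
            class = "idealized_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.idealized_trace <- function(x, ...) {
  cat("Idealized trace", x$molecule_id %||% "", "-", x$n_states,
      "state(s),", nrow(x$segments), "dwell(s)\n")
  print(utils::head(x$segments))
  invisible(x)
}

#' Merge idealized transitions smaller than the state widths
#'
#' FRET changes smaller than the Gaussian width of the states cannot be
#' distinguished from noise; adjacent dwells whose mean difference is
#' below the larger of the two state widths are therefore merged and the
#' dwell times re-accumulated. Merging is iterative: the smallest mean
#' gap is merged first (duration-weighted mean, the larger width kept)
#' until every remaining adjacent pair differs by at least the width
#' criterion.
#'
#' @param itrace an [idealize] result.
#' @return The filtered `idealized_trace`.
#' @export
filter_transitions <- function(itrace) {
  segs <- itrace$segments
  repeat {
    if (nrow(segs) < 2L) break
    gap <- abs(diff(segs$mu))
    thr <- pmax(segs$sigma[-nrow(segs)], segs$sigma[-1L])
    viol <- which(gap < thr)
    if (!length(viol)) break
    i <- viol[which.min(gap[viol])]
    d1 <- segs$t_end[i] - segs$t_start[i]
    d2 <- segs$t_end[i + 1L] - segs$t_start[i + 1L]
    segs$mu[i] <- (segs$mu[i] * d1 + segs$mu[i + 1L] * d2) / (d1 + d2)
    if (!is.null(segs$mu_obs))
      segs$mu_obs[i] <- (segs$mu_obs[i] * d1 +
                           segs$mu_obs[i + 1L] * d2) / (d1 + d2)
    segs$sigma[i] <- max(segs$sigma[i], segs$sigma[i + 1L])
    segs$t_end[i] <- segs$t_end[i + 1L]
    segs$end_frame[i] <- segs$end_frame[i + 1L]
    segs <- segs[-(i + 1L), , drop = FALSE]
  }
  rownames(segs) <- NULL
  itrace$segments <- segs
  itrace
}

#' Assign idealized dwells to named FRET levels
#'
#' Maps each dwell to the nearest of a set of declared FRET levels
#' (e.g. `c(dark = 0, high = 0.9)` for codon-reading experiments,
#' `c(dark = 0, classical = 0.8, hybrid = 0.6)` for post-decoding
#' experiments), using the dwell's interior-frame median FRET where
#' available (robust against boundary frames that average over a state
#' switch) and the fitted state mean otherwise. An exact tie is broken
#' toward the previous dwell's level (first dwell: the lower level),
#' which absorbs single camera-integration boundary frames into the
#' flanking dwell. Adjacent dwells mapped to the same level are merged.
#'
#' @param itrace an [idealize] (optionally [filter_transitions]) result.
#' @param levels named numeric vector of level FRET values.
#' @return The `idealized_trace` with a `level` column added to
#'   `segments` and same-level neighbours merged.
#' @export
assign_levels <- function(itrace, levels) {
  if (is.null(names(levels)) || any(!nzchar(names(levels))))
    stop("'levels' must be a named numeric vector")
  segs <- itrace$segments
  if (nrow(segs) == 0L) { itrace$segments <- segs; return(itrace) }
  ord <- order(levels)
  levels <- levels[ord]
  mu_for_level <- if (!is.null(segs$mu_obs)) segs$mu_obs else segs$mu
  lv <- character(nrow(segs))
  prev <- NA_character_
  for (i in seq_len(nrow(segs))) {
    d <- abs(mu_for_level[i] - levels)
    best <- which(d <= min(d) + 1e-12)
    if (length(best) > 1L) {
      cand <- names(levels)[best]
      lv[i] <- if (!is.na(prev) && prev %in% cand) prev else cand[1L]
    } else lv[i] <- names(levels)[best]
    prev <- lv[i]
  }
  segs$level <- lv
  # merge adjacent same-level dwells
  keep <- c(TRUE, lv[-1L] != lv[-length(lv)])
  grp <- cumsum(keep)
  merged <- do.call(rbind, lapply(split(seq_len(nrow(segs)), grp),
    function(ix) {
      d <- segs$t_end[ix] - segs$t_start[ix]
      data.frame(state = segs$state[ix[1L]],
                 mu = sum(segs$mu[ix] * d) / sum(d),
                 mu_obs = if (!is.null(segs$mu_obs))
                   sum(segs$mu_obs[ix] * d) / sum(d) else NA_real_,
                 sigma = max(segs$sigma[ix]),
                 start_frame = segs$start_frame[ix[1L]],
                 end_frame = segs$end_frame[ix[length(ix)]],
                 t_start = segs$t_start[ix[1L]],
                 t_end = segs$t_end[ix[length(ix)]],
                 level = segs$level[ix[1L]])
    }))
  rownames(merged) <- NULL
  itrace$segments <- merged
  itrace$levels <- levels
  itrace
}
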