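# Run code with a locally pinned RNG state; the caller's stream is
# untouched when a seed is supplied.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

#' Derive reproducible child seeds from a master seed
#'
#' Every stochastic step in the package takes its own integer seed; child
#' seeds are drawn from the master seed's stream so that a whole dataset
#' (or a whole analysis run) is reproducible from a single integer while
#' individual molecules remain independently re-simulable.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n, replace = TRUE))
}

#' Exact stochastic simulation of one decoding trajectory
#'
#' Gillespie realization of the scheme's continuous-time Markov chain:
#' the dwell in each state is exponential with rate equal to minus the
#' generator diagonal, and the successor state is drawn proportionally to
#' the off-diagonal rates. The path is recorded as contiguous segments
#' until the horizon is reached or an absorbing state is entered.
#'
#' @param scheme a [build_scheme] result.
#' @param horizon total simulated time (s).
#' @param seed optional integer seed; a fixed seed reproduces the segment
#'   list exactly.
#' @param init initial state (name or index); defaults to the scheme's
#'   first state.
#' @return A `state_trajectory`: a data frame with columns `state`,
#'   `t_enter`, `t_exit`, and attributes `horizon`, `seed`,
#'   `rateset_label`.
#' @examples
#' sc <- build_scheme(decoding_rates("AAA"), "wildtype")
#' traj <- simulate_trajectory(sc, horizon = 33, seed = 1)
#' head(traj)
#' @export
simulate_trajectory <- function(scheme, horizon, seed = NULL,
                                init = scheme$states[1]) {
  if (horizon < 0) stop("'horizon' must be >= 0")
  Q <- scheme$generator
  i <- state_index(scheme, init)
  with_seed(seed, {
    st <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
    t <- 0
    if (horizon > 0) repeat {
      rate <- -Q[i, i]
      if (rate <= 0) {                       # absorbing: spans the horizon
        st <- c(st, i); t0 <- c(t0, t); t1 <- c(t1, horizon)
        break
      }
      dwell <- stats::rexp(1L, rate)
      if (t + dwell >= horizon) {
        st <- c(st, i); t0 <- c(t0, t); t1 <- c(t1, horizon)
        break
      }
      st <- c(st, i); t0 <- c(t0, t); t1 <- c(t1, t + dwell)
      t <- t + dwell
      w <- Q[i, ]; w[i] <- 0
      i <- sample.int(length(w), 1L, prob = w)
    }
    structure(data.frame(state = scheme$states[st],
                         t_enter = t0, t_exit = t1),
              horizon = horizon, seed = seed,
              rateset_label = scheme$rateset_label,
              class = c("state_trajectory", "data.frame"))
  })
}

#' Monte-Carlo first-passage sample of the scheme
#'
#' Simulates many independent paths and records, for each, the time of
#' first entry into the target set, or `Inf` if the path is captured by a
#' competing closed class first. Serves as the stochastic cross-check of
#' [mean_first_passage] and [absorption_probability].
#'
#' @inheritParams simulate_trajectory
#' @param start starting state.
#' @param targets target state set.
#' @param n number of paths.
#' @param t_max bail-out horizon per path (s).
#' @return Numeric vector of `n` hitting times (s), `Inf` for paths that
#'   never reach the target set.
#' @export
simulate_hitting <- function(scheme, start, targets, n, seed = NULL,
                             t_max = 1e6) {
  Q <- scheme$generator
  i0 <- state_index(scheme, start)
  iB <- state_index(scheme, targets)
  with_seed(seed, {
    vapply(seq_len(n), function(j) {
      i <- i0; t <- 0
      repeat {
        if (i %in% iB) return(t)
        rate <- -Q[i, i]
        if (rate <= 0 || t > t_max) return(Inf)
        t <- t + stats::rexp(1L, rate)
        w <- Q[i, ]; w[i] <- 0
        i <- sample.int(length(w), 1L, prob = w)
      }
    }, numeric(1))
  })
}
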