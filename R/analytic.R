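#' Mean first-passage time to a set of states
#'
#' Solves the linear first-passage equations of the scheme's generator for
#' the expected time to first reach any state in `targets` starting from
#' `start`. Because the decoding pathway branches (drop-off competes with
#' accommodation), the unconditional hitting time is infinite whenever a
#' competing closed class can be reached; the estimator therefore reports
#' the mean first-passage time *conditional on hitting the target set*,
#' together with the hitting probability. This is the analytic counterpart
#' of the reaction times obtained from ensemble time courses.
#'
#' @param scheme a [build_scheme] result.
#' @param start starting state (name or index).
#' @param targets character/integer vector of target states.
#' @return The conditional mean first-passage time in seconds, with
#'   attribute `p_hit` (probability of ever reaching the target set).
#'   `+Inf` (with a warning) if the targets are unreachable from `start`.
#' @examples
#' sc <- build_scheme(decoding_rates("AAA"), "hybrid_only")
#' mean_first_passage(sc, "ACCOMMODATED_CLASSICAL", "HYBRID_APstar")
#' @export
mean_first_passage <- function(scheme, start, targets) {
  Q <- scheme$generator
  n <- nrow(Q)
  i_start <- state_index(scheme, start)
  i_B <- state_index(scheme, targets)
  if (i_start %in% i_B) return(structure(0, p_hit = 1))

  # states from which the target set is reachable
  reach <- (Q > 0) | diag(TRUE, n)
  for (k in seq_len(n))
    reach <- reach | (reach[, k] %o% reach[k, ])
  can_hit <- apply(reach[, i_B, drop = FALSE], 1L, any)
  if (!can_hit[i_start]) {
    warning("target set unreachable from '", scheme$states[i_start], "'")
    return(structure(Inf, p_hit = 0))
  }

  i_N <- setdiff(which(can_hit), i_B)            # unknowns
  QNN <- Q[i_N, i_N, drop = FALSE]
  b_hit <- rowSums(Q[i_N, i_B, drop = FALSE])
  h <- solve(QNN, -b_hit)                        # P(hit B) from each x in N
  u <- solve(QNN, -h)                            # E[time * 1{hit B}]
  j <- match(i_start, i_N)
  structure(unname(u[j] / h[j]), p_hit = unname(h[j]))
}

#' Probability of absorption into a terminal fate
#'
#' Computes the probability that the chain, started at `start`, is
#' eventually captured by the closed class containing `target`. For the
#' decoding scheme the two terminal fates are DROPPED (the aa-tRNA is
#' rejected) and the classical/hybrid post-decoding class (decoding is
#' completed and a peptide bond formed); their probabilities sum to one.
#'
#' @inheritParams mean_first_passage
#' @param target a state belonging to a closed class (e.g. `"DROPPED"` or
#'   `"ACCOMMODATED_CLASSICAL"`).
#' @param start starting state; defaults to the first state of the scheme.
#' @return Probability in `[0, 1]`.
#' @examples
#' sc <- build_scheme(decoding_rates("m6AAA"), "wildtype")
#' absorption_probability(sc, "DROPPED")
#' @export
absorption_probability <- function(scheme, target, start = scheme$states[1]) {
  classes <- closed_classes(scheme)
  i_t <- state_index(scheme, target)
  in_class <- vapply(classes, function(cl) scheme$states[i_t] %in% cl,
                     logical(1))
  if (!any(in_class))
    stop("'", scheme$states[i_t], "' is not in a closed (absorbing) class")
  res <- mean_first_passage(scheme, start, classes[[which(in_class)]])
  p <- attr(res, "p_hit")
  if (is.null(p)) p <- if (is.infinite(res)) 0 else 1
  min(max(p, 0), 1)
}

#' Deterministic occupancy time course of the scheme
#'
#' Evaluates the matrix-exponential solution of the master equation,
#' `p(t) = p(0) exp(Q t)`, and returns the total occupancy of a set of
#' observable states on a time grid. This is the deterministic twin of an
#' ensemble (stopped-flow / quench-flow) time course: with all mass
#' initially unbound and the observable set equal to the post-decoding
#' states, it is the product-formation curve.
#'
#' @inheritParams mean_first_passage
#' @param observable character/integer vector of states whose occupancy
#'   is summed.
#' @param t_grid increasing vector of times (s), starting at >= 0.
#' @param start initial state (all mass there at t = 0).
#' @return A `time_course` data frame with columns `time`, `signal`,
#'   `replicate` (1) and `condition` (the rate-set label).
#' @examples
#' sc <- build_scheme(decoding_rates("AAA"), "wildtype")
#' tc <- ensemble_timecourse(sc, c("ACCOMMODATED_CLASSICAL", "HYBRID_APstar"),
#'                           seq(0, 10, by = 0.5))
#' head(tc)
#' @export
ensemble_timecourse <- function(scheme, observable, t_grid,
                                start = scheme$states[1]) {
  if (length(t_grid) == 0L)
    return(time_course(numeric(0), numeric(0),
                       condition = scheme$rateset_label))
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] < 0)
    stop("'t_grid' must be strictly increasing and start at >= 0")
  i_obs <- state_index(scheme, observable)
  i_0 <- state_index(scheme, start)
  Q <- scheme$generator
  p0 <- numeric(nrow(Q)); p0[i_0] <- 1
  occ <- vapply(t_grid, function(t) {
    if (t == 0) return(sum(p0[i_obs]))
    pt <- p0 %*% as.matrix(Matrix::expm(Q * t))
    sum(pt[i_obs])
  }, numeric(1))
  time_course(t_grid, occ, condition = scheme$rateset_label)
}

#' Chain several decoding cycles into one scheme
#'
#' Concatenates the schemes of consecutive codons: the accommodation exit
#' of each non-final cycle feeds the unbound state of the next cycle (the
#' product of one elongation round is the substrate of the next), drop-off
#' from any cycle ends in the shared DROPPED state, and the final cycle
#' keeps its post-decoding classical/hybrid states. The total conditional
#' mean first-passage time through the chain equals the sum of the
#' per-cycle conditional times when no drop-off occurs, which is the
#' kinetic basis of position-dependent decoding delays (a slow codon late
#' in the message adds its full delay on top of the time needed to
#' synthesize the upstream peptide).
#'
#' @param ratesets an ordered list of [rate_set] objects, one per codon.
#' @return A `scheme_graph` whose states are suffixed `.1`, `.2`, ... by
#'   cycle; protocol `"chained"`.
#' @examples
#' ch <- chain_cycles(list(decoding_rates("AAA"), decoding_rates("m6AAA")))
#' ch$states
#' @export
chain_cycles <- function(ratesets) {
  if (inherits(ratesets, "rate_set")) ratesets <- list(ratesets)
  if (length(ratesets) == 0L) stop("need at least one cycle")
  if (!all(vapply(ratesets, inherits, logical(1), "rate_set")))
    stop("'ratesets' must be a list of rate_set objects")
  m <- length(ratesets)
  if (m == 1L) return(build_scheme(ratesets[[1]], "wildtype"))

  cyc_states <- c("UNBOUND", "IB", "CR", "POST_GTP")
  states <- c(unlist(lapply(seq_len(m - 1L), function(i)
                paste0(cyc_states, ".", i))),
              paste0(c(cyc_states, "ACCOMMODATED_CLASSICAL",
                       "HYBRID_APstar"), ".", m),
              "DROPPED")
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  for (i in seq_len(m)) {
    r <- ratesets[[i]]
    s <- function(nm) paste0(nm, ".", i)
    Q[s("UNBOUND"), s("IB")] <- r$k1_app
    Q[s("IB"), s("UNBOUND")] <- r$k_rev1
    Q[s("IB"), s("CR")] <- r$k2
    Q[s("CR"), s("UNBOUND")] <- r$k_rev2
    Q[s("CR"), s("POST_GTP")] <- r$k_gtp
    Q[s("POST_GTP"), "DROPPED"] <- r$k7
    if (i < m) {
      Q[s("POST_GTP"), paste0("UNBOUND.", i + 1L)] <- r$k45
    } else {
      Q[s("POST_GTP"), s("ACCOMMODATED_CLASSICAL")] <- r$k45
      Q[s("ACCOMMODATED_CLASSICAL"), s("HYBRID_APstar")] <- r$k_hyb_fwd
      Q[s("HYBRID_APstar"), s("ACCOMMODATED_CLASSICAL")] <- r$k_hyb_rev
    }
  }
  diag(Q) <- -rowSums(Q)
  structure(list(states = states,
                 generator = Q,
                 absorbing = states[rowSums(abs(Q)) == 0],
                 protocol = "chained",
                 rateset_label = paste(vapply(ratesets, `[[`, "", "label"),
                                       collapse = "+")),
            class = "scheme_graph")
}
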