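#' @useDynLib ribodecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical mechanistic state labels, in generator order.
SCHEME_STATES <- c("UNBOUND", "IB", "CR", "POST_GTP",
                   "ACCOMMODATED_CLASSICAL", "HYBRID_APstar", "DROPPED")

#' Build the decoding scheme as a continuous-time Markov chain
#'
#' Translates a [rate_set] into a generator matrix over the mechanistic
#' states UNBOUND, IB (initial binding), CR (codon reading), POST_GTP
#' (after GTP hydrolysis), ACCOMMODATED_CLASSICAL (A/A, A/P), HYBRID_APstar
#' (A/P*), and DROPPED (irreversible rejection). Edges:
#' UNBOUND <-> IB (`k1_app`, `k_rev1`), IB -> CR (`k2`),
#' CR -> UNBOUND (`k_rev2`; the codon-reading decay is full dissociation
#' as seen by the FRET observable), CR -> POST_GTP (`k_gtp`),
#' POST_GTP -> ACCOMMODATED_CLASSICAL (`k45`), POST_GTP -> DROPPED (`k7`),
#' ACCOMMODATED_CLASSICAL <-> HYBRID_APstar (`k_hyb_fwd`, `k_hyb_rev`).
#'
#' Protocols: `"wildtype"` uses all rates; `"H84A"` models a
#' GTPase-deficient EF-Tu by setting `k_gtp = 0` exactly, so no state
#' beyond CR is reachable and the CR decay reports dissociation; and
#' `"hybrid_only"` restricts the chain to the two post-decoding states,
#' for preformed complexes that fluctuate between classical and hybrid
#' tRNA configurations.
#'
#' @param rates a [rate_set].
#' @param protocol one of `"wildtype"`, `"H84A"`, `"hybrid_only"`.
#' @return An object of class `scheme_graph` with elements `states`,
#'   `generator` (rows sum to zero over transient states), `absorbing`
#'   (states with no exit), `protocol`, and `rateset_label`.
#' @examples
#' sc <- build_scheme(decoding_rates("AAA"), "wildtype")
#' sc$generator["CR", ]
#' @export
build_scheme <- function(rates,
                         protocol = c("wildtype", "H84A", "hybrid_only")) {
  if (!inherits(rates, "rate_set")) stop("'rates' must be a rate_set")
  protocol <- match.arg(protocol)

  if (protocol == "hybrid_only") {
    states <- c("ACCOMMODATED_CLASSICAL", "HYBRID_APstar")
    Q <- matrix(0, 2, 2, dimnames = list(states, states))
    Q["ACCOMMODATED_CLASSICAL", "HYBRID_APstar"] <- rates$k_hyb_fwd
    Q["HYBRID_APstar", "ACCOMMODATED_CLASSICAL"] <- rates$k_hyb_rev
  } else {
    k_gtp <- if (protocol == "H84A") 0 else rates$k_gtp
    states <- SCHEME_STATES
    Q <- matrix(0, 7, 7, dimnames = list(states, states))
    Q["UNBOUND", "IB"] <- rates$k1_app
    Q["IB", "UNBOUND"] <- rates$k_rev1
    Q["IB", "CR"] <- rates$k2
    Q["CR", "UNBOUND"] <- rates$k_rev2
    Q["CR", "POST_GTP"] <- k_gtp
    Q["POST_GTP", "ACCOMMODATED_CLASSICAL"] <- rates$k45
    Q["POST_GTP", "DROPPED"] <- rates$k7
    Q["ACCOMMODATED_CLASSICAL", "HYBRID_APstar"] <- rates$k_hyb_fwd
    Q["HYBRID_APstar", "ACCOMMODATED_CLASSICAL"] <- rates$k_hyb_rev
  }
  diag(Q) <- -rowSums(Q)
  structure(list(states = states,
                 generator = Q,
                 absorbing = states[rowSums(abs(Q)) == 0],
                 protocol = protocol,
                 rateset_label = rates$label),
            class = "scheme_graph")
}

#' @export
print.scheme_graph <- function(x, ...) {
  cat("Decoding scheme (", x$protocol, ") for rate set '", x$rateset_label,
      "'\n", sep = "")
  cat("States:", paste(x$states, collapse = ", "), "\n")
  if (length(x$absorbing))
    cat("Absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  cat("Generator (s^-1):\n")
  print(round(x$generator, 4))
  invisible(x)
}

# Resolve state names/indices against a scheme; errors on unknown states.
state_index <- function(scheme, states) {
  if (is.numeric(states)) {
    idx <- as.integer(states)
  } else {
    idx <- match(states, scheme$states)
  }
  if (anyNA(idx) || any(idx < 1L | idx > length(scheme$states)))
    stop("unknown state(s): ",
         paste(states[is.na(idx) | idx < 1 | idx > length(scheme$states)],
               collapse = ", "))
  idx
}

# Closed communicating classes of the chain (sets with no exit). A single
# absorbing state is a class of size one; the classical/hybrid pair forms
# a closed class once accommodation is irreversible. Used by
# absorption_probability(): completing decoding means entering the
# classical/hybrid class, rejection means entering DROPPED.
closed_classes <- function(scheme) {
  Q <- scheme$generator
  n <- nrow(Q)
  reach <- (abs(Q) > 0) | diag(TRUE, n)
  for (k in seq_len(n))                     # Warshall transitive closure
    reach <- reach | (reach[, k] %o% reach[k, ])
  comm <- reach & t(reach)
  classes <- unique(apply(comm, 1L, function(r) which(r), simplify = FALSE))
  keep <- vapply(classes, function(cl) {
    all(rowSums(Q[cl, -cl, drop = FALSE] > 0) == 0)
  }, logical(1))
  lapply(classes[keep], function(cl) scheme$states[cl])
}
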