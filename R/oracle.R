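# Exact finite Markov chain over all 3^S chromatin configurations for
# small S. Enumerates the per-attempt update kernel directly from the
# stated rules (uniform target; 0.5 feedback with uniform mediator among
# the other S-1; 0.5 feedback-independent) and composes attempts into a
# one-sweep transition matrix. Serves as the ground-truth comparator for
# the stochastic simulator; it shares no code with the simulation path.

.state_index <- function(st) {
  sum((st + 1L) * 3L^(seq_along(st) - 1L)) + 1L
}

.enumerate_states <- function(S) {
  as.matrix(do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), S)))
}

#' Build the exact chromatin Markov chain
#'
#' @param S array size, at most 4 (<= 81 states).
#' @param params a [chromatin_params()] object.
#' @param attempts_per_sweep attempts composing one sweep (default `S`).
#' @return an object of class `exact_chain` with the state enumeration,
#'   the one-attempt and one-sweep transition matrices.
#' @export
build_exact_chain <- function(S, params, attempts_per_sweep = S) {
  S <- as.integer(S)
  if (S < 2L || S > 4L) stop("S must be between 2 and 4")
  states <- .enumerate_states(S)
  n <- nrow(states)
  A <- matrix(0, n, n)
  p3 <- params$p3; p4 <- params$p4; p5 <- params$p5
  for (i in seq_len(n)) {
    st <- states[i, ]
    add <- function(newst, p) {
      j <- .state_index(newst)
      A[i, j] <<- A[i, j] + p
    }
    for (t in seq_len(S)) {
      pt <- 1 / S
      # feedback branch: mediator uniform among the other S - 1
      for (m in setdiff(seq_len(S), t)) {
        pm <- pt * 0.5 / (S - 1)
        med <- st[m]
        if (med == 1L && st[t] < 1L) {
          ns <- st; ns[t] <- st[t] + 1L
          add(ns, pm * p4); add(st, pm * (1 - p4))
        } else if (med == -1L && st[t] > -1L) {
          ns <- st; ns[t] <- st[t] - 1L
          add(ns, pm * p3); add(st, pm * (1 - p3))
        } else {
          add(st, pm)
        }
      }
      # feedback-independent branch
      pn <- pt * 0.5
      if (st[t] != 0L) {
        ns <- st; ns[t] <- 0L
        add(ns, pn * p5); add(st, pn * (1 - p5))
      } else {
        up <- st; up[t] <- 1L
        dn <- st; dn[t] <- -1L
        add(up, pn * p5 * 0.5); add(dn, pn * p5 * 0.5)
        add(st, pn * (1 - p5))
      }
    }
  }
  P <- diag(n)
  for (k in seq_len(attempts_per_sweep)) P <- P %*% A
  structure(list(S = S, params = params, states = states, attempt = A,
                 sweep = P, attempts_per_sweep = attempts_per_sweep),
            class = "exact_chain")
}

#' Exact state distribution after k sweeps
#' @param chain an `exact_chain`.
#' @param k number of sweeps.
#' @param init initial configuration: "U", "A", "M" or an integer state
#'   vector of length `S`.
#' @return probability vector over the 3^S states.
#' @export
exact_distribution <- function(chain, k, init = "U") {
  if (is.character(init))
    init <- unclass(chromatin_array(chain$S, init))
  d <- numeric(nrow(chain$states))
  d[.state_index(as.integer(init))] <- 1
  for (i in seq_len(k)) d <- as.numeric(d %*% chain$sweep)
  d
}

#' Compare the stochastic simulator with the exact chain
#'
#' Runs `n` independent replicates of `k` sweeps from `init` with the
#' package's chromatin update kernel, and measures the total-variation
#' distance between the empirical state distribution and the exactly
#' computed k-step distribution.
#'
#' @param chain an `exact_chain`.
#' @param k sweeps per replicate.
#' @param n replicates.
#' @param init initial configuration (as in [exact_distribution()]).
#' @param tolerance pass threshold on the total-variation distance.
#' @param params optional [chromatin_params()] for the simulator side
#'   (defaults to the chain's; a deliberate mismatch makes the check a
#'   negative control).
#' @return list with `tv` (total-variation distance) and `pass`.
#' @export
compare_to_oracle <- function(chain, k = 5, n = 1e5, init = "U",
                              tolerance = 0.02, params = NULL) {
  if (is.null(params)) params <- chain$params
  if (is.character(init))
    init <- unclass(chromatin_array(chain$S, init))
  codes <- cpp_sweep_batch(as.integer(init), params$p3, params$p4,
                           params$p5, chain$attempts_per_sweep,
                           as.integer(k), as.integer(n))
  emp <- tabulate(codes + 1L, nbins = nrow(chain$states)) / n
  exact <- exact_distribution(chain, k, init)
  tv <- 0.5 * sum(abs(emp - exact))
  list(tv = tv, pass = tv <= tolerance)
}
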