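# PRE/TRE nucleosome array: A (active), U (neutral), M (silent), encoded
# internally as +1 / 0 / -1 so that the signed state metric is a mean.

.chrom_code <- c(M = -1L, U = 0L, A = 1L)
.chrom_letter <- c("M", "U", "A")  # index by code + 2

#' Chromatin parameters
#'
#' Per-attempt probabilities of the PRE/TRE update rules: `p3` converts a
#' nucleosome one step toward M when the mediator is M, `p4` one step
#' toward A when the mediator is A, and `p5` is the probability of a
#' feedback-independent one-step transition (A->U, M->U, or U->A/M with
#' equal probability).
#'
#' @param p3,p4,p5 probabilities in \[0, 1\].
#' @return an object of class `chromatin_params`.
#' @export
chromatin_params <- function(p3 = 0.25, p4 = 0.25, p5 = 0.04) {
  for (p in c(p3, p4, p5)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("chromatin parameters must be single probabilities in [0, 1]")
  }
  structure(list(p3 = p3, p4 = p4, p5 = p5), class = "chromatin_params")
}

#' Construct a chromatin (PRE/TRE) array
#'
#' @param S number of nucleosomes (>= 2).
#' @param fill single letter or length-`S` vector of letters in
#'   `c("A", "U", "M")`.
#' @return an object of class `chromatin_array` (integer vector with
#'   M = -1, U = 0, A = +1).
#' @export
chromatin_array <- function(S = 60L, fill = "U") {
  S <- as.integer(S)
  if (is.na(S) || S < 2L) stop("S must be an integer >= 2")
  if (length(fill) == 1L) fill <- rep(fill, S)
  if (length(fill) != S || !all(fill %in% names(.chrom_code)))
    stop("fill must be letters in c('A', 'U', 'M'), length 1 or S")
  structure(unname(.chrom_code[fill]), class = "chromatin_array")
}

#' Parse a chromatin array from an "AUM..." string
#' @param x single string over the alphabet A/U/M.
#' @return a `chromatin_array`.
#' @export
as_chromatin_array <- function(x) {
  chromatin_array(nchar(x), strsplit(x, "")[[1]])
}

#' Serialise a chromatin array as a string
#' @param x a `chromatin_array`.
#' @param ... unused.
#' @return single string over A/U/M.
#' @export
chrom_string <- function(x, ...) {
  paste(.chrom_letter[unclass(x) + 2L], collapse = "")
}

#' @export
print.chromatin_array <- function(x, ...) {
  cat("<chromatin_array> S =", length(x), "\n ", chrom_string(x), "\n")
  invisible(x)
}

#' Nucleosome configuration counts
#' @param array a `chromatin_array`.
#' @return named integer vector `c(A=, U=, M=)`.
#' @export
chromatin_counts <- function(array) {
  v <- unclass(array)
  c(A = sum(v == 1L), U = sum(v == 0L), M = sum(v == -1L))
}

#' Signed PRE/TRE state
#'
#' The PRE/TRE state on a scale of -1 (fully silent) to +1 (fully active),
#' computed as (N_A - N_M) / S.
#'
#' @param array a `chromatin_array`.
#' @return numeric in \[-1, 1\].
#' @export
pretre_state <- function(array) {
  mean(unclass(array))
}

.check_index <- function(i, n, what) {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i < 1 || i > n ||
      i != as.integer(i))
    stop(sprintf("invalid %s index", what))
}

#' Single feedback conversion attempt
#'
#' If the mediator nucleosome is in the A configuration, the target moves
#' one step toward A (M->U or U->A) with probability `p4`; if the mediator
#' is M, one step toward M with probability `p3`; a U mediator changes
#' nothing. Conversions are stepwise only (never A<->M directly).
#'
#' @param array a `chromatin_array`.
#' @param target,mediator distinct 1-based indices.
#' @param params a [chromatin_params()] object.
#' @return the updated array.
#' @export
feedback_attempt <- function(array, target, mediator, params) {
  S <- length(array)
  .check_index(target, S, "target")
  .check_index(mediator, S, "mediator")
  if (target == mediator) stop("target and mediator must differ")
  v <- unclass(array)
  med <- v[mediator]
  if (med == 1L) {
    if (v[target] < 1L && runif(1) < params$p4) v[target] <- v[target] + 1L
  } else if (med == -1L) {
    if (v[target] > -1L && runif(1) < params$p3) v[target] <- v[target] - 1L
  }
  structure(v, class = "chromatin_array")
}

#' Single feedback-independent transition attempt
#'
#' With probability `p5` the target moves one step: A->U or M->U; a U
#' target becomes A or M with equal probability.
#'
#' @inheritParams feedback_attempt
#' @return the updated array.
#' @export
noise_attempt <- function(array, target, params) {
  S <- length(array)
  .check_index(target, S, "target")
  v <- unclass(array)
  if (runif(1) < params$p5) {
    if (v[target] != 0L) v[target] <- 0L
    else v[target] <- if (runif(1) < 0.5) 1L else -1L
  }
  structure(v, class = "chromatin_array")
}

#' One sweep of stochastic chromatin updates
#'
#' Performs `attempts` sequential update attempts. Each attempt picks a
#' target uniformly at random; with probability 0.5 it is a feedback
#' attempt with a mediator drawn uniformly from the other S - 1
#' nucleosomes (unbounded-range feedback), otherwise a
#' feedback-independent attempt.
#'
#' @param array a `chromatin_array`.
#' @param params a [chromatin_params()] object.
#' @param attempts number of update attempts (default: one per nucleosome).
#' @return the updated array.
#' @export
chromatin_sweep <- function(array, params, attempts = length(array)) {
  attempts <- as.integer(attempts)
  if (is.na(attempts) || attempts < 1L) stop("attempts must be >= 1")
  structure(
    cpp_chromatin_sweep(unclass(array), params$p3, params$p4, params$p5,
                        attempts),
    class = "chromatin_array"
  )
}

#' Replication dilution of nucleosome states
#'
#' Models random partitioning of parental histones at replication: each
#' nucleosome is independently set to U with probability `wipe_prob`.
#'
#' @param array a `chromatin_array`.
#' @param wipe_prob probability in \[0, 1\] (default 0.5).
#' @return the updated array.
#' @export
replicate_chromatin <- function(array, wipe_prob = 0.5) {
  if (wipe_prob < 0 || wipe_prob > 1) stop("wipe_prob must be in [0, 1]")
  structure(cpp_replicate_chromatin(unclass(array), wipe_prob),
            class = "chromatin_array")
}
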