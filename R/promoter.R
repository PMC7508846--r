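# Promoter binding-site array: F (free) = 0, B (bound) = 1.

#' Promoter parameters
#'
#' `p1` is the per-sweep probability that a free site becomes bound
#' (transcription-factor binding), `p2` the per-sweep probability that a
#' bound site becomes free (dissociation).
#'
#' @param p1,p2 probabilities in \[0, 1\].
#' @return an object of class `promoter_params`.
#' @export
promoter_params <- function(p1, p2 = 0.1) {
  for (p in c(p1, p2)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("promoter parameters must be single probabilities in [0, 1]")
  }
  structure(list(p1 = p1, p2 = p2), class = "promoter_params")
}

#' Construct a promoter array
#'
#' @param s number of binding sites (>= 1).
#' @param fill single letter or length-`s` vector of letters in
#'   `c("F", "B")`.
#' @return an object of class `promoter_array` (integer vector, F = 0,
#'   B = 1).
#' @export
promoter_array <- function(s = 10L, fill = "F") {
  s <- as.integer(s)
  if (is.na(s) || s < 1L) stop("s must be an integer >= 1")
  if (length(fill) == 1L) fill <- rep(fill, s)
  if (length(fill) != s || !all(fill %in% c("F", "B")))
    stop("fill must be letters in c('F', 'B'), length 1 or s")
  structure(as.integer(fill == "B"), class = "promoter_array")
}

#' @export
print.promoter_array <- function(x, ...) {
  cat("<promoter_array> s =", length(x), "\n ",
      paste(c("F", "B")[unclass(x) + 1L], collapse = ""), "\n")
  invisible(x)
}

#' One sweep of promoter updates
#'
#' Each site updates independently: a free site becomes bound with
#' probability `p1`, a bound site becomes free with probability `p2`.
#'
#' @param array a `promoter_array`.
#' @param params a [promoter_params()] object.
#' @return the updated array.
#' @export
promoter_sweep <- function(array, params) {
  structure(cpp_promoter_sweep(unclass(array), params$p1, params$p2),
            class = "promoter_array")
}

#' Mitotic reset of the promoter
#'
#' All sites are set to F, modelling the global dissociation of
#' transcription factors from mitotic chromatin at each division.
#'
#' @param array a `promoter_array`.
#' @return the reset array.
#' @export
mitotic_reset <- function(array) {
  structure(rep(0L, length(array)), class = "promoter_array")
}

#' Promoter activity
#'
#' Fraction of sites in the bound configuration, N_B / s.
#'
#' @param array a `promoter_array`.
#' @return numeric in \[0, 1\].
#' @export
promoter_activity <- function(array) {
  mean(unclass(array))
}
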