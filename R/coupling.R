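# Bidirectional PRE/TRE <-> promoter coupling. Each engine step the four
# parameters (p1, p2, p3, p4) are re-derived from the scenario's base
# values using the current signed states; adjustments are never
# compounded across steps.

#' Coupling specification
#'
#' `C` sets the strength of the bidirectional coupling; `model` selects
#' the functional form. Model 1 (default, asymmetric multiplicative): a
#' parameter q favoured by signal x becomes q*(1 + C*x) for x >= 0 and
#' q/(1 + C*|x|) otherwise. Model 2 (signed-linear): q*(1 + C*x). Both
#' are clamped to \[0, 1\]. Signals: p1 is favoured by the PRE/TRE state E,
#' p2 by -E, p4 by the signed promoter state P, p3 by -P. C = 0 is an
#' exact pass-through.
#'
#' @param C coupling strength >= 0.
#' @param model 1 or 2.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(C = 4, model = 1L) {
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C < 0)
    stop("C must be a single non-negative number")
  model <- as.integer(model)
  if (!model %in% c(1L, 2L)) stop("model must be 1 or 2")
  structure(list(C = C, model = model), class = "coupling_spec")
}

#' Signed promoter state
#'
#' Puts the promoter activity (fraction bound) on the same signed scale
#' as the PRE/TRE state: 2 * activity - 1.
#'
#' @param activity fraction in \[0, 1\].
#' @return numeric in \[-1, 1\].
#' @export
signed_promoter_state <- function(activity) {
  if (any(activity < 0 | activity > 1)) stop("activity must be in [0, 1]")
  2 * activity - 1
}

#' Coupled parameter adjustment
#'
#' Adjusts the promoter parameters (p1, p2) by the PRE/TRE state `E` and
#' the chromatin feedback parameters (p3, p4) by the signed promoter
#' state `P`, using the coupling model and strength in `spec`. `p5` is
#' never adjusted. The adjustment is computed from the base parameters,
#' not from previously adjusted values.
#'
#' @param base_prom a [promoter_params()] object.
#' @param base_chrom a [chromatin_params()] object.
#' @param E PRE/TRE state in \[-1, 1\].
#' @param P signed promoter state in \[-1, 1\].
#' @param spec a [coupling_spec()] object.
#' @return list with elements `promoter` and `chromatin`, the adjusted
#'   parameter objects.
#' @export
adjust_parameters <- function(base_prom, base_chrom, E, P, spec) {
  if (!is.numeric(E) || length(E) != 1L || is.na(E) || abs(E) > 1)
    stop("E must be in [-1, 1]")
  if (!is.numeric(P) || length(P) != 1L || is.na(P) || abs(P) > 1)
    stop("P must be in [-1, 1]")
  v <- cpp_adjust_params(base_prom$p1, base_prom$p2,
                         base_chrom$p3, base_chrom$p4,
                         E, P, spec$C, spec$model)
  list(promoter = promoter_params(v[1], v[2]),
       chromatin = chromatin_params(v[3], v[4], base_chrom$p5))
}
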