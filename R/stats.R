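# Summary statistics over trajectories and ensembles.

.window_rows <- function(traj, window) {
  if (length(window) != 2L || window[2] < window[1])
    stop("window must be c(start, end) in minutes")
  sel <- traj$time >= window[1] & traj$time <= window[2]
  if (!any(sel)) stop("empty window")
  sel
}

#' Memory score of a trajectory
#'
#' Mean over the window of the promoter activity (target "active") or of
#' one minus the activity (target "repressed"); 1 indicates perfect
#' memory of the target state throughout the window, and the score
#' degrades smoothly with deviations. For a given trajectory and window
#' the active and repressed scores sum to 1.
#'
#' @param traj a `pretre_trajectory`.
#' @param target "active" or "repressed".
#' @param window minutes `c(start, end)`.
#' @return numeric in \[0, 1\].
#' @export
memory_score <- function(traj, target = c("active", "repressed"), window) {
  target <- match.arg(target)
  sel <- .window_rows(traj, window)
  m <- mean(traj$activity[sel])
  if (target == "active") m else 1 - m
}

#' Memory scores across an ensemble
#' @param ensemble a `pretre_ensemble`.
#' @inheritParams memory_score
#' @return numeric vector, one score per replicate.
#' @export
ensemble_memory_scores <- function(ensemble, target = c("active",
                                                        "repressed"),
                                   window) {
  target <- match.arg(target)
  vapply(ensemble$trajectories, memory_score, 0, target = target,
         window = window)
}

#' Window-mean promoter activity of a trajectory
#' @param traj a `pretre_trajectory`.
#' @param window minutes `c(start, end)` (default 90-100 h, the adult-eye
#'   pigmentation proxy window).
#' @return numeric in \[0, 1\].
#' @export
window_mean_activity <- function(traj, window = c(5400, 6000)) {
  mean(traj$activity[.window_rows(traj, window)])
}

#' Window-mean activities across an ensemble
#' @param ensemble a `pretre_ensemble`.
#' @inheritParams window_mean_activity
#' @return numeric vector, one mean per replicate.
#' @export
ensemble_window_means <- function(ensemble, window = c(5400, 6000)) {
  vapply(ensemble$trajectories, window_mean_activity, 0, window = window)
}

#' Variegation index
#'
#' Bimodality of an ensemble of per-replicate window means:
#' 2 * min(fraction below `lo`, fraction above `hi`). 0 for a unimodal
#' mid-centred ensemble, 1 for an even split of fully silent and fully
#' active replicates.
#'
#' @param values numeric vector of per-replicate window means (>= 2).
#' @param lo,hi tail thresholds.
#' @return numeric in \[0, 1\].
#' @export
variegation_index <- function(values, lo = 0.25, hi = 0.75) {
  if (length(values) < 2L) stop("need at least 2 values")
  2 * min(mean(values < lo), mean(values > hi))
}

#' Ensemble derepression time
#'
#' First sampled time at which the per-time median promoter activity
#' exceeds `threshold` and remains above it to the horizon; `NA` if it
#' never does. Defined on the ensemble median so that single-replicate
#' flicker does not register.
#'
#' @param ensemble a `pretre_ensemble`.
#' @param threshold activity threshold (default 0.5).
#' @return time in minutes, or `NA_real_`.
#' @export
derepression_time <- function(ensemble, threshold = 0.5) {
  A <- ensemble_matrix(ensemble, "activity")
  med <- apply(A, 2, median)
  above <- med > threshold
  persistent <- rev(cumprod(rev(above))) == 1
  if (!any(persistent)) return(NA_real_)
  ensemble$times[which(persistent)[1]]
}

#' Mean accumulation curves of modified nucleosomes
#'
#' Pointwise ensemble means of the A, U and M composition fractions over
#' time.
#'
#' @param ensemble a `pretre_ensemble`.
#' @return data frame with columns `time`, `a_frac`, `u_frac`, `m_frac`.
#' @export
accumulation_curves <- function(ensemble) {
  data.frame(time = ensemble$times,
             a_frac = colMeans(ensemble_matrix(ensemble, "a_frac")),
             u_frac = colMeans(ensemble_matrix(ensemble, "u_frac")),
             m_frac = colMeans(ensemble_matrix(ensemble, "m_frac")))
}

#' Anterior-posterior expression profile of a simulated disc
#'
#' Per-position window-mean promoter activity, optionally normalised to
#' a maximum of 1 (mirroring the per-disc intensity normalisation used
#' for imaged discs).
#'
#' @param disc a `pretre_disc` from [run_disc()].
#' @param normalise divide by the profile maximum.
#' @return data frame with columns `x`, `zone`, `value`.
#' @export
gradient_profile <- function(disc, normalise = TRUE) {
  if (!inherits(disc, "pretre_disc")) stop("disc must be a pretre_disc")
  if (nrow(disc$positions) < 3L) stop("need at least 3 positions")
  value <- disc$positions$window_mean
  if (normalise) {
    mx <- max(value)
    if (mx > 0) value <- value / mx
  }
  data.frame(x = disc$positions$x, zone = disc$positions$zone,
             value = value)
}
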