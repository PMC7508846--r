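# Simulation engine. One engine step = one simulated minute: read the
# pre-step promoter activity and PRE/TRE state, adjust parameters via the
# coupling model, one promoter sweep, `attempts_per_minute` chromatin
# attempts, then (at cycle ends) mitotic reset + replication wipe.

.step_values <- function(program_times, values, t) {
  values[findInterval(t, program_times)]
}

# Expand a timeline into per-minute parameter vectors. Step i (1-based)
# covers the interval (i-1, i]; its parameters are those in force at the
# step start, time i-1. Divisions are flagged on the step whose end
# coincides with a cycle boundary.
.compile_timeline <- function(timeline) {
  horizon <- timeline$schedule$phase_bounds$horizon
  T <- as.integer(round(horizon))
  if (abs(horizon - T) > 1e-9)
    stop("the schedule horizon must be an integer number of minutes")
  t0 <- 0:(T - 1L)
  p1v <- .step_values(timeline$p1_program$time, timeline$p1_program$value, t0)
  p2v <- rep(timeline$p2, T)
  p3v <- rep(timeline$chromatin$p3, T)
  p4v <- rep(timeline$chromatin$p4, T)
  p5v <- rep(timeline$chromatin$p5, T)
  Cv <- .step_values(timeline$C_program$time, timeline$C_program$C, t0)
  modelv <- as.integer(.step_values(timeline$C_program$time,
                                    timeline$C_program$model, t0))
  for (ev in timeline$events) {
    hi <- if (is.null(ev$duration)) horizon else ev$time + ev$duration
    idx <- which(t0 >= ev$time & t0 < hi)
    if (ev$param == "p1") p1v[idx] <- ev$value
    else if (ev$param == "p3") p3v[idx] <- ev$value
    else if (ev$param == "p4") p4v[idx] <- ev$value
  }
  divide <- rep(FALSE, T)
  ends <- round(division_times(timeline$schedule))
  divide[ends[ends >= 1 & ends <= T]] <- TRUE
  list(T = T, p1v = p1v, p2v = p2v, p3v = p3v, p4v = p4v, p5v = p5v,
       Cv = Cv, modelv = modelv, divide = divide)
}

#' Run a single replicate
#'
#' Simulates one coupled promoter + PRE/TRE lineage over the timeline's
#' schedule, recording promoter activity, the signed PRE/TRE state and
#' the A/U/M composition fractions on a fixed minute grid.
#'
#' @param timeline a [scenario_timeline()].
#' @param seed integer seed; identical (timeline, seed) give bit-identical
#'   trajectories.
#' @param attempts_per_minute chromatin update attempts per simulated
#'   minute (default [default_attempts_per_minute()] of the array size).
#' @param sample_every keep every k-th minute of the recorded series
#'   (time 0 is always kept).
#' @return a `pretre_trajectory`: a data frame with columns `time`,
#'   `activity`, `state`, `a_frac`, `u_frac`, `m_frac` and attributes
#'   `seed` and `scenario`.
#' @export
run_single <- function(timeline, seed, attempts_per_minute = NULL,
                       sample_every = 1L) {
  if (!inherits(timeline, "scenario_timeline"))
    stop("timeline must be a scenario_timeline")
  if (is.null(attempts_per_minute))
    attempts_per_minute <- default_attempts_per_minute(timeline$S)
  cp <- .compile_timeline(timeline)
  set.seed(as.integer(seed))
  chrom0 <- unclass(chromatin_array(timeline$S, timeline$initial_chromatin))
  prom0 <- unclass(promoter_array(timeline$s, "F"))
  mat <- cpp_run_engine(chrom0, prom0, cp$p1v, cp$p2v, cp$p3v, cp$p4v,
                        cp$p5v, cp$Cv, cp$modelv, cp$divide,
                        as.integer(attempts_per_minute),
                        timeline$wipe_prob)
  keep <- seq(1L, cp$T + 1L, by = as.integer(sample_every))
  out <- data.frame(time = (keep - 1L),
                    activity = mat[keep, 1],
                    state = mat[keep, 2] - mat[keep, 4],
                    a_frac = mat[keep, 2],
                    u_frac = mat[keep, 3],
                    m_frac = mat[keep, 4])
  attr(out, "seed") <- as.integer(seed)
  attr(out, "scenario") <- timeline$label
  class(out) <- c("pretre_trajectory", "data.frame")
  out
}

#' Run an ensemble of independent replicates
#'
#' Replicate i uses seed `base_seed + i - 1`; replicates are fully
#' isolated, so results are independent of execution order and of the
#' total replicate count.
#'
#' @param timeline a [scenario_timeline()].
#' @param n number of replicates.
#' @param base_seed integer base seed.
#' @param ... passed to [run_single()].
#' @return a `pretre_ensemble`: list with `trajectories`, `times`,
#'   `base_seed`, `label` and `config_digest`.
#' @export
run_ensemble <- function(timeline, n, base_seed = 1L, ...) {
  if (n < 1) stop("n must be >= 1")
  trajectories <- lapply(seq_len(n), function(i)
    run_single(timeline, seed = base_seed + i - 1L, ...))
  structure(list(trajectories = trajectories,
                 times = trajectories[[1]]$time,
                 base_seed = as.integer(base_seed),
                 label = timeline$label,
                 config_digest = timeline_digest(timeline)),
            class = "pretre_ensemble")
}

#' Digest of a scenario timeline
#'
#' MD5 checksum of the timeline's canonical (name-sorted) deparsed
#' content, stable under field reordering; recorded in ensemble results
#' and run metadata so a stored result can be re-validated against its
#' configuration.
#'
#' @param timeline a `scenario_timeline`.
#' @return character MD5 digest.
#' @export
timeline_digest <- function(timeline) {
  x <- unclass(timeline)
  x$schedule <- unclass(x$schedule)
  x <- x[order(names(x))]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Extract an ensemble field as a replicate x time matrix
#' @param ensemble a `pretre_ensemble`.
#' @param field one of "activity", "state", "a_frac", "u_frac", "m_frac".
#' @return numeric matrix, one row per replicate.
#' @export
ensemble_matrix <- function(ensemble, field = "activity") {
  field <- match.arg(field, c("activity", "state", "a_frac", "u_frac",
                              "m_frac"))
  do.call(rbind, lapply(ensemble$trajectories, function(tr) tr[[field]]))
}

#' @export
print.pretre_ensemble <- function(x, ...) {
  cat("<pretre_ensemble>", x$label, "\n ", length(x$trajectories),
      "replicates, base seed", x$base_seed, ", span 0 -",
      max(x$times), "min\n")
  invisible(x)
}

#' @export
summary.pretre_ensemble <- function(object, ...) {
  A <- ensemble_matrix(object, "activity")
  E <- ensemble_matrix(object, "state")
  final <- ncol(A)
  out <- data.frame(
    replicates = nrow(A),
    final_activity_median = median(A[, final]),
    final_state_median = median(E[, final]),
    mean_activity = mean(A),
    mean_state = mean(E)
  )
  cat("Ensemble:", object$label, "\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Kymograph plot of an ensemble
#'
#' Replicate-by-time heat map of promoter activity or PRE/TRE state,
#' mirroring the stacked single-run displays used for this class of
#' simulation.
#'
#' @param x a `pretre_ensemble`.
#' @param field plotted quantity (default "activity").
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot.pretre_ensemble <- function(x, field = "activity", ...) {
  M <- ensemble_matrix(x, field)
  graphics::image(x = x$times, y = seq_len(nrow(M)), z = t(M),
                  xlab = "time (min)", ylab = "replicate",
                  main = paste(x$label, "-", field),
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  ...)
  invisible(M)
}

#' Run a spatial eye-disc scenario
#'
#' Runs one independent lineage per disc position (position i uses seed
#' `base_seed + i - 1`) and records the per-position mean promoter
#' activity over the readout window.
#'
#' @param disc a [eyedisc_scenario()] object.
#' @param base_seed integer base seed.
#' @param window readout window in minutes (default 90-100 h).
#' @param ... passed to [run_single()].
#' @return a `pretre_disc`: list with `positions` (including a
#'   `window_mean` column), `trajectories`, `window` and `pretre`.
#' @export
run_disc <- function(disc, base_seed = 1L, window = c(5400, 6000), ...) {
  if (!inherits(disc, "disc_scenario")) stop("disc must be a disc_scenario")
  trajectories <- lapply(seq_along(disc$timelines), function(i)
    run_single(disc$timelines[[i]], seed = base_seed + i - 1L, ...))
  pos <- disc$positions
  pos$window_mean <- vapply(trajectories, window_mean_activity, 0,
                            window = window)
  structure(list(positions = pos, trajectories = trajectories,
                 window = window, pretre = disc$pretre,
                 zone1_end = disc$zone1_end, furrow = disc$furrow,
                 base_seed = as.integer(base_seed)),
            class = "pretre_disc")
}

#' @export
print.pretre_disc <- function(x, ...) {
  cat("<pretre_disc>", x$pretre, "PRE/TRE,", nrow(x$positions),
      "positions, readout", x$window[1], "-", x$window[2], "min\n")
  invisible(x)
}

#' Parameter-grid scan of the silencing-memory assay
#'
#' For every combination of feedback strength (p3 = p4), p5 and coupling
#' C, runs anterior and posterior silencing-memory ensembles and
#' summarises memory scores (anterior target repressed, posterior target
#' active, maintenance window), the variegation index of the anterior
#' maintenance-window activities, and mean final states.
#'
#' @param p34 vector of feedback values (used for both p3 and p4).
#' @param p5 vector of feedback-independent transition values.
#' @param C vector of coupling strengths.
#' @param n replicates per cell and compartment.
#' @param base_seed integer base seed (each cell uses an offset stream).
#' @param ... passed to [run_single()].
#' @return data frame, one row per grid cell.
#' @export
run_grid <- function(p34, p5, C, n = 50, base_seed = 1L, ...) {
  for (v in list(p34 = p34, p5 = p5, C = C)) {
    if (anyDuplicated(v)) warning("duplicate grid values deduplicated")
  }
  p34 <- unique(p34); p5 <- unique(p5); C <- unique(C)
  grid <- expand.grid(p34 = p34, p5 = p5, C = C,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    chrom <- chromatin_params(g$p34, g$p34, g$p5)
    seed_i <- base_seed + (i - 1L) * 2L * n
    res <- lapply(c("anterior", "posterior"), function(comp) {
      tl <- silencing_memory(comp, C_im = g$C, chromatin = chrom)
      off <- if (comp == "anterior") 0L else n
      ens <- run_ensemble(tl, n, base_seed = seed_i + off, ...)
      win <- c(tl$schedule$phase_bounds$maintenance_start,
               tl$schedule$phase_bounds$horizon)
      target <- if (comp == "anterior") "repressed" else "active"
      scores <- ensemble_memory_scores(ens, target = target, window = win)
      means <- ensemble_window_means(ens, window = win)
      finals <- vapply(ens$trajectories,
                       function(tr) tr$state[nrow(tr)], 0)
      list(scores = scores, means = means, finals = finals)
    })
    names(res) <- c("anterior", "posterior")
    data.frame(
      p34 = g$p34, p5 = g$p5, C = g$C, n = n,
      memory_anterior_median = median(res$anterior$scores),
      memory_anterior_iqr = stats::IQR(res$anterior$scores),
      memory_posterior_median = median(res$posterior$scores),
      memory_posterior_iqr = stats::IQR(res$posterior$scores),
      variegation_anterior = variegation_index(res$anterior$means),
      mean_state_anterior = mean(res$anterior$finals),
      mean_state_posterior = mean(res$posterior$finals)
    )
  })
  do.call(rbind, rows)
}
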