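# Scenario timelines: piecewise-constant programs for p1 and for the
# coupling (C, model), plus timed interventions, an initial state, and a
# cell-cycle schedule. Built-in factories reproduce the four study
# designs: silencing memory, activation memory (heat shock), uncoupled
# accumulation, and the spatial eye-disc assay.

.check_program <- function(df, cols, horizon, what) {
  if (!is.data.frame(df) || !all(cols %in% names(df)) || nrow(df) < 1L)
    stop(what, " must be a data frame with columns ",
         paste(cols, collapse = ", "))
  if (df$time[1] != 0) stop(what, " must start at time 0")
  if (any(diff(df$time) <= 0)) stop(what, " times must be increasing")
  if (any(df$time < 0 | df$time > horizon))
    stop(what, " breakpoints must lie within [0, horizon]")
  df
}

#' Construct a scenario timeline
#'
#' @param schedule a [cell_cycle_schedule()].
#' @param chromatin base [chromatin_params()].
#' @param p2 transcription-factor dissociation probability (constant).
#' @param p1_program data frame `time`, `value`: p1 takes `value` from
#'   `time` (minutes) until the next breakpoint.
#' @param C_program data frame `time`, `C`, `model`: coupling strength
#'   and model, piecewise constant.
#' @param events list of `list(time =, param =, value =, duration =)`
#'   interventions; `param` is one of "p1", "p3", "p4"; `duration`
#'   (optional) limits the override, otherwise it lasts to the horizon.
#' @param initial_chromatin "U", "A" or "M" (all nucleosomes).
#' @param S number of nucleosomes (default 60).
#' @param s number of promoter sites (default 10; the initial promoter is
#'   always all-F).
#' @param wipe_prob replication wipe probability at divisions.
#' @param label scenario identifier carried into trajectories.
#' @return an object of class `scenario_timeline`.
#' @export
scenario_timeline <- function(schedule,
                              chromatin = chromatin_params(),
                              p2 = 0.1,
                              p1_program = data.frame(time = 0, value = 0),
                              C_program = data.frame(time = 0, C = 0,
                                                     model = 1),
                              events = list(),
                              initial_chromatin = c("U", "A", "M"),
                              S = 60L, s = 10L,
                              wipe_prob = 0.5,
                              label = "custom") {
  if (!inherits(schedule, "cc_schedule")) stop("schedule must be a cc_schedule")
  horizon <- schedule$phase_bounds$horizon
  p1_program <- .check_program(p1_program, c("time", "value"), horizon,
                               "p1_program")
  C_program <- .check_program(C_program, c("time", "C", "model"), horizon,
                              "C_program")
  if (any(p1_program$value < 0 | p1_program$value > 1))
    stop("p1 values must be probabilities in [0, 1]")
  if (any(C_program$C < 0)) stop("C must be non-negative")
  if (!all(C_program$model %in% c(1, 2))) stop("coupling model must be 1 or 2")
  for (ev in events) {
    if (!all(c("time", "param", "value") %in% names(ev)) ||
        !ev$param %in% c("p1", "p3", "p4"))
      stop("events must be list(time=, param= p1/p3/p4, value=)")
    if (ev$time < 0 || ev$time > horizon)
      stop("event time outside [0, horizon]")
    if (ev$value < 0 || ev$value > 1)
      stop("event value must be a probability")
  }
  initial_chromatin <- match.arg(initial_chromatin)
  structure(list(schedule = schedule, chromatin = chromatin, p2 = p2,
                 p1_program = p1_program, C_program = C_program,
                 events = events, initial_chromatin = initial_chromatin,
                 S = as.integer(S), s = as.integer(s),
                 wipe_prob = wipe_prob, label = label),
            class = "scenario_timeline")
}

#' @export
print.scenario_timeline <- function(x, ...) {
  cat("<scenario_timeline>", x$label, "\n  S =", x$S, " s =", x$s,
      " p3 =", x$chromatin$p3, " p4 =", x$chromatin$p4,
      " p5 =", x$chromatin$p5, " p2 =", x$p2, "\n  horizon =",
      x$schedule$phase_bounds$horizon, "min,", length(x$events),
      "event(s)\n")
  invisible(x)
}

#' Silencing-memory scenario
#'
#' Reporter silencing assay: the enhancer is repressed in the anterior
#' compartment during initiation (small p1) and active in the posterior;
#' at maintenance onset the anterior repressors disappear (p1 rises to
#' the active value) and any persistent repression is PRE/TRE memory.
#' Coupling is `C_e` (default 0) during the rapid cycles 1-13 and `C_im`
#' afterwards. A Polycomb-group mutant is modelled by dropping p3 to
#' 0.001 at maintenance onset.
#'
#' @param compartment "anterior" or "posterior".
#' @param pcg_mutant simulate PcG loss of function.
#' @param C_im coupling strength during initiation and maintenance.
#' @param C_e coupling strength during cycles 1-13.
#' @param model coupling model (1 or 2).
#' @param p1_repressed,p1_active promoter binding probabilities for the
#'   repressed and active regimes.
#' @param p2 dissociation probability.
#' @param chromatin base [chromatin_params()].
#' @param early_cycle_factor multiplies cycle 1-13 durations.
#' @param horizon optional horizon override (minutes).
#' @return a `scenario_timeline`.
#' @export
silencing_memory <- function(compartment = c("anterior", "posterior"),
                             pcg_mutant = FALSE,
                             C_im = 4, C_e = 0, model = 1,
                             p1_repressed = 0.01, p1_active = 0.19,
                             p2 = 0.1,
                             chromatin = chromatin_params(0.25, 0.25, 0.04),
                             early_cycle_factor = 1,
                             horizon = NULL) {
  compartment <- match.arg(compartment)
  sch <- default_embryo_schedule(horizon = horizon,
                                 early_cycle_factor = early_cycle_factor)
  init <- sch$phase_bounds$initiation_start
  maint <- sch$phase_bounds$maintenance_start
  p1_program <- if (compartment == "anterior") {
    data.frame(time = c(0, maint), value = c(p1_repressed, p1_active))
  } else {
    data.frame(time = 0, value = p1_active)
  }
  events <- if (pcg_mutant) {
    list(list(time = maint, param = "p3", value = 0.001))
  } else list()
  scenario_timeline(
    schedule = sch, chromatin = chromatin, p2 = p2,
    p1_program = p1_program,
    C_program = data.frame(time = c(0, init), C = c(C_e, C_im),
                           model = model),
    events = events,
    label = paste0("silencing_memory_", compartment,
                   if (pcg_mutant) "_pcg_mutant" else "")
  )
}

#' Activation-memory (heat-shock) scenario
#'
#' Reporter activation assay: the promoter is weakly driven throughout
#' (`p1_silent`); a 1-h heat shock raises p1 to `p1_heatshock` either
#' during the initiation phase ("early") or after its end ("late"). The
#' run continues to 100 h on the eye-disc lineage schedule; promoter
#' activity averaged over 90-100 h proxies adult eye pigmentation.
#'
#' @param heatshock "none", "early" or "late".
#' @param initial_chromatin initial nucleosome state, "U", "A" or "M".
#' @param C_im,C_e,model coupling as in [silencing_memory()].
#' @param p1_silent,p1_heatshock baseline and heat-shock p1.
#' @param p2 dissociation probability.
#' @param chromatin base [chromatin_params()].
#' @param schedule lineage schedule (default [eyedisc_schedule()]).
#' @param hs_early,hs_late heat-shock windows, minutes `c(start, end)`.
#' @return a `scenario_timeline`.
#' @export
activation_memory <- function(heatshock = c("none", "early", "late"),
                              initial_chromatin = "U",
                              C_im = 4, C_e = 0, model = 1,
                              p1_silent = 0.05, p1_heatshock = 0.8,
                              p2 = 0.1,
                              chromatin = chromatin_params(0.25, 0.25, 0.04),
                              schedule = eyedisc_schedule(),
                              hs_early = c(135, 195),
                              hs_late = c(300, 360)) {
  heatshock <- match.arg(heatshock)
  init <- schedule$phase_bounds$initiation_start
  win <- switch(heatshock, none = NULL, early = hs_early, late = hs_late)
  p1_program <- if (is.null(win)) {
    data.frame(time = 0, value = p1_silent)
  } else {
    data.frame(time = c(0, win[1], win[2]),
               value = c(p1_silent, p1_heatshock, p1_silent))
  }
  scenario_timeline(
    schedule = schedule, chromatin = chromatin, p2 = p2,
    p1_program = p1_program,
    C_program = data.frame(time = c(0, init), C = c(C_e, C_im),
                           model = model),
    initial_chromatin = initial_chromatin,
    label = paste0("activation_memory_", heatshock)
  )
}

#' Uncoupled accumulation scenario
#'
#' The chromatin array alone (C = 0 throughout) under the somatic embryo
#' schedule or the germline (pole-cell) schedule, used to follow the
#' developmental accumulation of A and M nucleosomes.
#'
#' @param lineage "soma" or "germline".
#' @param horizon minutes (default 660, 11 h).
#' @param chromatin base [chromatin_params()].
#' @return a `scenario_timeline`.
#' @export
accumulation_scenario <- function(lineage = c("soma", "germline"),
                                  horizon = 660,
                                  chromatin = chromatin_params(0.25, 0.25,
                                                               0.04)) {
  lineage <- match.arg(lineage)
  sch <- if (lineage == "soma") default_embryo_schedule(horizon = horizon)
         else germline_schedule(horizon = horizon)
  scenario_timeline(
    schedule = sch, chromatin = chromatin,
    p1_program = data.frame(time = 0, value = 0),
    C_program = data.frame(time = 0, C = 0, model = 1),
    label = paste0("accumulation_", lineage)
  )
}

# Target uncoupled promoter activity across the disc: 0 gradient in zone
# 1 (ahead of activation), linear rise across zone 2 to a peak at the
# morphogenetic furrow, linear decline across zone 3 to a posterior
# plateau.
.disc_activity_target <- function(x, zone1_end, furrow, act_repressed,
                                  act_peak, act_posterior) {
  ifelse(x < zone1_end, act_repressed,
         ifelse(x < furrow,
                act_repressed + (act_peak - act_repressed) *
                  (x - zone1_end) / (furrow - zone1_end),
                act_peak + (act_posterior - act_peak) *
                  (x - furrow) / (1 - furrow)))
}

#' Spatial eye-disc scenario
#'
#' One independent lineage per anterior-posterior position x in \[0, 1\].
#' Zone 1 (x < `zone1_end`) stays repressed and uncoupled to the horizon.
#' Zones 2-3 activate at a position-dependent onset (a linear temporal
#' sweep from posterior to anterior during third instar): from the onset,
#' coupling switches from 0 to `C_late` and p1 follows the enhancer
#' gradient profile, which rises ahead of the morphogenetic furrow
#' (x = `furrow`) and declines behind it. The `eya` parameterisation
#' (p3 = p4 = 0.2, p5 = 0.17) gives a flexible, fine-tuning PRE/TRE; the
#' `bxd` parameterisation (p3 = p4 = 0.25, p5 = 0.04) a strongly bistable
#' one that variegates under this late coupling.
#'
#' @param pretre "eya" or "bxd".
#' @param n_positions number of positions (>= 3).
#' @param C_late coupling strength from the activation onset (default
#'   2.5).
#' @param model coupling model.
#' @param zone1_end,furrow positions of the zone-1/2 boundary and the
#'   furrow, in \[0, 1\].
#' @param act_peak,act_posterior target uncoupled activities at the
#'   furrow and the posterior edge.
#' @param onset_posterior,onset_anterior activation onset (minutes) at
#'   x = 1 and at `zone1_end`.
#' @param p1_repressed repressed-state p1.
#' @param p2 dissociation probability.
#' @param horizon minutes (default 6000).
#' @return an object of class `disc_scenario`: a list with `positions`
#'   (data frame x, zone, activation_onset, act_target, p1_target) and
#'   `timelines` (one `scenario_timeline` per position).
#' @export
eyedisc_scenario <- function(pretre = c("eya", "bxd"),
                             n_positions = 100,
                             C_late = 2.5, model = 1,
                             zone1_end = 0.3, furrow = 0.6,
                             act_peak = 0.9, act_posterior = 0.45,
                             onset_posterior = 3600, onset_anterior = 4800,
                             p1_repressed = 0.01, p2 = 0.1,
                             horizon = 6000) {
  pretre <- match.arg(pretre)
  if (n_positions < 3) stop("n_positions must be >= 3")
  chrom <- if (pretre == "eya") chromatin_params(0.2, 0.2, 0.17)
           else chromatin_params(0.25, 0.25, 0.04)
  sch <- eyedisc_schedule(horizon = horizon)
  x <- seq(0, 1, length.out = n_positions)
  zone <- ifelse(x < zone1_end, 1L, ifelse(x < furrow, 2L, 3L))
  act_repressed <- p1_repressed / (p1_repressed + p2)
  act <- .disc_activity_target(x, zone1_end, furrow, act_repressed,
                               act_peak, act_posterior)
  p1_target <- p2 * act / (1 - act)
  onset <- ifelse(zone == 1L, NA_real_,
                  onset_anterior - (x - zone1_end) / (1 - zone1_end) *
                    (onset_anterior - onset_posterior))
  timelines <- lapply(seq_len(n_positions), function(i) {
    if (zone[i] == 1L) {
      p1_program <- data.frame(time = 0, value = p1_repressed)
      C_program <- data.frame(time = 0, C = 0, model = model)
    } else {
      p1_program <- data.frame(time = c(0, onset[i]),
                               value = c(p1_repressed, p1_target[i]))
      C_program <- data.frame(time = c(0, onset[i]), C = c(0, C_late),
                              model = model)
    }
    scenario_timeline(schedule = sch, chromatin = chrom, p2 = p2,
                      p1_program = p1_program, C_program = C_program,
                      label = sprintf("eyedisc_%s_x%.3f", pretre, x[i]))
  })
  structure(list(positions = data.frame(x = x, zone = zone,
                                        activation_onset = onset,
                                        act_target = act,
                                        p1_target = p1_target),
                 timelines = timelines, pretre = pretre, C_late = C_late,
                 zone1_end = zone1_end, furrow = furrow,
                 horizon = horizon),
            class = "disc_scenario")
}

#' @export
print.disc_scenario <- function(x, ...) {
  cat("<disc_scenario>", x$pretre, "PRE/TRE,", nrow(x$positions),
      "positions, C_late =", x$C_late, ", horizon =", x$horizon, "min\n")
  invisible(x)
}
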