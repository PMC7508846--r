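# Shared fixtures, all built in code.

# A division-free schedule for stationary-state checks.
flat_schedule <- function(horizon = 2000) {
  stopifnot(horizon > 290)
  half <- floor(horizon / 2)
  cell_cycle_schedule(
    data.frame(index = 1:2, duration_min = c(half, horizon - half),
               divide_at_end = FALSE),
    list(pre_MBT_end = 130, initiation_start = 130,
         maintenance_start = 290, horizon = horizon)
  )
}

# Minimal uncoupled timeline with a constant p1.
flat_timeline <- function(p1, chromatin = chromatin_params(),
                          horizon = 2000, C = 0) {
  scenario_timeline(flat_schedule(horizon), chromatin = chromatin,
                    p1_program = data.frame(time = 0, value = p1),
                    C_program = data.frame(time = 0, C = C, model = 1),
                    label = "flat")
}

# Hand-built ensemble from given activity series (for statistic unit
# tests that need exact inputs).
fake_ensemble <- function(activity_rows, times = NULL) {
  if (is.null(times)) times <- seq_len(ncol(activity_rows)) - 1
  trajectories <- lapply(seq_len(nrow(activity_rows)), function(i) {
    structure(data.frame(time = times, activity = activity_rows[i, ],
                         state = 0, a_frac = 0, u_frac = 1, m_frac = 0),
              class = c("pretre_trajectory", "data.frame"))
  })
  structure(list(trajectories = trajectories, times = times,
                 base_seed = 0L, label = "fake", config_digest = ""),
            class = "pretre_ensemble")
}
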