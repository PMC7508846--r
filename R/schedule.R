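# Developmental cell-cycle schedules. A schedule is an ordered table of
# cycles (duration in minutes, whether a division ends the cycle) plus
# named phase bounds in minutes. Divisions trigger a mitotic promoter
# reset and a replication wipe of the chromatin array in the engine.

# Reconstructed pre-MBT cycle durations (minutes), chosen to sum to 130
# so that cycle 14 starts at 2h10. Overridable via schedule TSV files.
.pre_mbt_durations <- c(rep(8, 8), 9, 10, 11, 14, 22)

#' Construct and validate a cell-cycle schedule
#'
#' @param cycles data frame with columns `index` (strictly increasing
#'   integers), `duration_min` (positive minutes) and `divide_at_end`
#'   (logical).
#' @param phase_bounds named list with numeric elements `pre_MBT_end`,
#'   `initiation_start`, `maintenance_start` and `horizon` (minutes).
#'   `pre_MBT_end` must equal `initiation_start`, the bounds must be
#'   increasing, and the cycle durations must sum to `horizon`.
#' @return an object of class `cc_schedule`.
#' @export
cell_cycle_schedule <- function(cycles, phase_bounds) {
  need <- c("index", "duration_min", "divide_at_end")
  if (!is.data.frame(cycles) || !all(need %in% names(cycles)))
    stop("cycles must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (any(cycles$duration_min <= 0))
    stop("cycle durations must be positive (row ",
         which(cycles$duration_min <= 0)[1], ")")
  if (any(diff(cycles$index) <= 0))
    stop("cycle indices must be strictly increasing")
  pb <- phase_bounds
  needb <- c("pre_MBT_end", "initiation_start", "maintenance_start",
             "horizon")
  if (!all(needb %in% names(pb)))
    stop("phase_bounds must name ", paste(needb, collapse = ", "))
  pb <- lapply(pb[needb], as.numeric)
  if (pb$pre_MBT_end != pb$initiation_start)
    stop("pre_MBT_end must equal initiation_start")
  if (!(pb$initiation_start < pb$maintenance_start &&
        pb$maintenance_start < pb$horizon))
    stop("phase bounds must satisfy initiation_start < maintenance_start ",
         "< horizon")
  if (abs(sum(cycles$duration_min) - pb$horizon) > 1e-9)
    stop("cycle durations must sum to the horizon")
  cycles$end_min <- cumsum(cycles$duration_min)
  structure(list(cycles = cycles, phase_bounds = pb), class = "cc_schedule")
}

#' @export
print.cc_schedule <- function(x, ...) {
  pb <- x$phase_bounds
  cat("<cc_schedule>", nrow(x$cycles), "cycles,",
      sum(x$cycles$divide_at_end), "divisions, horizon", pb$horizon,
      "min\n  pre-MBT end:", pb$pre_MBT_end,
      " maintenance start:", pb$maintenance_start, "\n")
  invisible(x)
}

.make_cycles <- function(durations, divide) {
  data.frame(index = seq_along(durations), duration_min = durations,
             divide_at_end = divide)
}

#' Default embryonic cell-cycle schedule
#'
#' Thirteen rapid pre-MBT cycles ending at 130 min (2h10), the cycle-14
#' initiation phase ending with a division at 290 min (4h50), maintenance
#' cycles 15 and 16 dividing at 6h20 and 7h30, and (if `horizon` extends
#' beyond 450 min) a final division-free segment.
#'
#' @param horizon total simulated span in minutes (default: end of cycle
#'   16 at 450 min, i.e. 7.5 h).
#' @param early_cycle_factor multiplies the durations of cycles 1-13 (and
#'   shifts the phase bounds accordingly); used to probe the role of the
#'   rapid early cycles.
#' @return a `cc_schedule`.
#' @export
default_embryo_schedule <- function(horizon = NULL, early_cycle_factor = 1) {
  pre <- .pre_mbt_durations * early_cycle_factor
  t13 <- sum(pre)
  dur <- c(pre, 160, 90, 70)
  div <- rep(TRUE, length(dur))
  base_end <- t13 + 320
  if (is.null(horizon)) horizon <- base_end
  if (horizon < base_end) stop("horizon must be >= ", base_end, " min")
  if (horizon > base_end) {
    dur <- c(dur, horizon - base_end)
    div <- c(div, FALSE)
  }
  cell_cycle_schedule(
    .make_cycles(dur, div),
    list(pre_MBT_end = t13, initiation_start = t13,
         maintenance_start = t13 + 160, horizon = horizon)
  )
}

#' Germline (pole-cell) cell-cycle schedule
#'
#' Cycles 1-9 as in the embryo schedule, a 2-h cycle 10 ending with a
#' division, then G2 arrest (no further divisions) to the horizon.
#'
#' @param horizon total simulated span in minutes (default 660, 11 h).
#' @return a `cc_schedule`.
#' @export
germline_schedule <- function(horizon = 660) {
  pre9 <- .pre_mbt_durations[1:9]
  t10 <- sum(pre9) + 120
  if (horizon <= t10) stop("horizon must exceed ", t10, " min")
  dur <- c(pre9, 120, horizon - t10)
  div <- c(rep(TRUE, 10), FALSE)
  cell_cycle_schedule(
    .make_cycles(dur, div),
    list(pre_MBT_end = 130, initiation_start = 130,
         maintenance_start = 290, horizon = horizon)
  )
}

#' Eye-disc lineage cell-cycle schedule
#'
#' The embryonic schedule followed by post-embryonic (larval) cycles of
#' fixed length until the horizon (default 100 h, covering eye-disc
#' development to mid third instar); any remainder is division-free.
#'
#' @param horizon total simulated span in minutes (default 6000, 100 h).
#' @param larval_cycle post-embryonic cycle length in minutes (default
#'   600).
#' @param early_cycle_factor passed to [default_embryo_schedule()].
#' @return a `cc_schedule`.
#' @export
eyedisc_schedule <- function(horizon = 6000, larval_cycle = 600,
                             early_cycle_factor = 1) {
  emb <- default_embryo_schedule(early_cycle_factor = early_cycle_factor)
  dur <- emb$cycles$duration_min
  div <- emb$cycles$divide_at_end
  t <- sum(dur)
  if (horizon < t) stop("horizon must be >= the embryonic span (", t, " min)")
  while (t + larval_cycle <= horizon) {
    dur <- c(dur, larval_cycle)
    div <- c(div, TRUE)
    t <- t + larval_cycle
  }
  if (t < horizon) {
    dur <- c(dur, horizon - t)
    div <- c(div, FALSE)
  }
  pb <- emb$phase_bounds
  pb$horizon <- horizon
  cell_cycle_schedule(.make_cycles(dur, div), pb)
}

#' Division times of a schedule
#' @param schedule a `cc_schedule`.
#' @return numeric vector of minutes at which divisions occur.
#' @export
division_times <- function(schedule) {
  with(schedule$cycles, end_min[divide_at_end])
}

#' Time window spanned by a range of cycles
#' @param schedule a `cc_schedule`.
#' @param from,to cycle indices (as in the schedule's `index` column).
#' @return numeric `c(start, end)` in minutes.
#' @export
cycle_window <- function(schedule, from, to) {
  cy <- schedule$cycles
  i1 <- match(from, cy$index)
  i2 <- match(to, cy$index)
  if (is.na(i1) || is.na(i2) || i2 < i1) stop("invalid cycle range")
  start <- if (i1 == 1L) 0 else cy$end_min[i1 - 1L]
  c(start, cy$end_min[i2])
}

#' Write a schedule to TSV
#'
#' Format: '#'-prefixed `name<TAB>value` lines for the four phase bounds,
#' then a header line and one row per cycle (`index`, `duration_min`,
#' `divide_at_end`).
#'
#' @param schedule a `cc_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  pb <- schedule$phase_bounds
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s\t%s", names(pb), unlist(pb)), con)
  write.table(schedule$cycles[c("index", "duration_min", "divide_at_end")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a schedule from TSV
#'
#' @param path file written by [write_schedule()] (or hand-edited in the
#'   same format).
#' @return a `cc_schedule`.
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- lines[is_meta]
  if (length(meta) == 0L)
    stop("missing phase-bounds stanza ('# name\\tvalue' lines)")
  kv <- strsplit(sub("^#\\s*", "", meta), "\t")
  bad <- which(lengths(kv) != 2L)
  if (length(bad))
    stop("malformed phase-bound line ", which(is_meta)[bad[1]])
  pb <- setNames(as.list(as.numeric(vapply(kv, `[`, "", 2L))),
                 vapply(kv, `[`, "", 1L))
  body <- lines[!is_meta]
  cyc <- tryCatch(
    read.delim(text = paste(body, collapse = "\n")),
    error = function(e) stop("malformed schedule table: ",
                             conditionMessage(e))
  )
  if (any(cyc$duration_min <= 0)) {
    row <- which(cyc$duration_min <= 0)[1]
    stop("non-positive duration at table row ", row,
         " (file line ", which(!is_meta)[row + 1L], ")")
  }
  cyc$divide_at_end <- as.logical(cyc$divide_at_end)
  cell_cycle_schedule(cyc, pb)
}
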