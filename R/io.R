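# Configuration and result serialisation: YAML run configs, long-format
# trajectory TSV, kymograph CSV, statistics TSV and JSON run metadata.
# The command-line driver in inst/cli/pretre.R is a thin wrapper over
# these functions.

#' Read and validate a run configuration
#'
#' YAML with sections `scenario` (required key `name`, plus any factory
#' arguments), `run` (`n_replicates`, `base_seed`, `sample_every`) and
#' `output` (`dir`). Scenario names: "silencing_memory",
#' "activation_memory", "accumulation", "eyedisc", plus "grid" for
#' parameter scans (section `grid` with `p34`, `p5`, `C` lists).
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario) || is.null(cfg$scenario$name))
    stop("config error: missing key 'scenario.name'")
  known <- c("silencing_memory", "activation_memory", "accumulation",
             "eyedisc", "grid")
  if (!cfg$scenario$name %in% known)
    stop("config error: unknown scenario '", cfg$scenario$name, "'")
  run <- cfg$run %||% list()
  cfg$run <- list(n_replicates = run$n_replicates %||% 50L,
                  base_seed = run$base_seed %||% 1L,
                  sample_every = run$sample_every %||% 1L)
  cfg$output <- cfg$output %||% list()
  cfg$output$dir <- cfg$output$dir %||% "pretre_out"
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Digest of a run configuration
#'
#' Stable under key reordering (keys are sorted recursively before
#' hashing).
#'
#' @param cfg a config list.
#' @return character MD5 digest.
#' @export
config_digest <- function(cfg) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)))
      x <- lapply(x[order(names(x))], sort_rec)
    x
  }
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(sort_rec(unclass(cfg))), f)
  unname(tools::md5sum(f))
}

.scenario_from_config <- function(cfg) {
  args <- cfg$scenario
  args$name <- NULL
  switch(cfg$scenario$name,
         silencing_memory = do.call(silencing_memory, args),
         activation_memory = do.call(activation_memory, args),
         accumulation = do.call(accumulation_scenario, args),
         eyedisc = do.call(eyedisc_scenario, args),
         stop("config error: unknown scenario"))
}

#' Write an ensemble as long-format TSV
#'
#' Columns: time_min, replicate, activity, state, a_frac, u_frac, m_frac.
#'
#' @param ensemble a `pretre_ensemble`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path) {
  rows <- lapply(seq_along(ensemble$trajectories), function(i) {
    tr <- ensemble$trajectories[[i]]
    data.frame(time_min = tr$time, replicate = i, activity = tr$activity,
               state = tr$state, a_frac = tr$a_frac, u_frac = tr$u_frac,
               m_frac = tr$m_frac)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a replicate x time kymograph matrix as CSV
#' @param ensemble a `pretre_ensemble`.
#' @param path output CSV path.
#' @param field recorded quantity (default "activity").
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(ensemble, path, field = "activity") {
  M <- ensemble_matrix(ensemble, field)
  colnames(M) <- ensemble$times
  utils::write.csv(M, path, row.names = FALSE)
  invisible(path)
}

#' Execute a simulate-type run configuration
#'
#' Runs the configured scenario ensemble and writes trajectory TSV,
#' activity kymograph CSV, a statistics TSV (memory scores over the
#' maintenance window and window-mean activities) and a JSON metadata
#' sidecar (config digest, seeds, package version).
#'
#' @param cfg a `run_config` (from [read_run_config()]).
#' @param quiet suppress the resolved-parameter log.
#' @return output directory, invisibly.
#' @export
run_from_config <- function(cfg, quiet = FALSE) {
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  tl <- .scenario_from_config(cfg)
  if (inherits(tl, "disc_scenario"))
    stop("use run_disc_from_config() for eyedisc configs")
  if (!quiet) {
    message("scenario: ", tl$label)
    message("schedule: horizon ", tl$schedule$phase_bounds$horizon,
            " min; divisions at ",
            paste(division_times(tl$schedule), collapse = ", "))
    message("params: p3=", tl$chromatin$p3, " p4=", tl$chromatin$p4,
            " p5=", tl$chromatin$p5, " p2=", tl$p2)
  }
  ens <- run_ensemble(tl, n = cfg$run$n_replicates,
                      base_seed = cfg$run$base_seed,
                      sample_every = cfg$run$sample_every)
  out <- cfg$output$dir
  write_trajectories(ens, file.path(out, "trajectories.tsv"))
  write_kymograph(ens, file.path(out, "kymograph_activity.csv"))
  win <- c(tl$schedule$phase_bounds$maintenance_start,
           tl$schedule$phase_bounds$horizon)
  stats_df <- data.frame(
    replicate = seq_len(cfg$run$n_replicates),
    window_start = win[1], window_end = win[2],
    memory_score_repressed =
      ensemble_memory_scores(ens, "repressed", win),
    memory_score_active = ensemble_memory_scores(ens, "active", win),
    window_mean_activity = ensemble_window_means(ens, win)
  )
  write.table(stats_df, file.path(out, "statistics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(config_digest = config_digest(cfg),
               scenario = tl$label,
               base_seed = cfg$run$base_seed,
               n_replicates = cfg$run$n_replicates,
               package_version =
                 as.character(utils::packageVersion("pretre")))
  jsonlite::write_json(meta, file.path(out, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Execute an eye-disc run configuration
#'
#' Writes raw and normalised anterior-posterior profiles (two-column
#' TSV), the zone-2/3 variegation index, and JSON metadata.
#'
#' @inheritParams run_from_config
#' @return output directory, invisibly.
#' @export
run_disc_from_config <- function(cfg, quiet = FALSE) {
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  disc <- .scenario_from_config(cfg)
  if (!inherits(disc, "disc_scenario"))
    stop("config error: scenario.name must be 'eyedisc'")
  res <- run_disc(disc, base_seed = cfg$run$base_seed,
                  sample_every = cfg$run$sample_every)
  out <- cfg$output$dir
  raw <- gradient_profile(res, normalise = FALSE)
  norm <- gradient_profile(res, normalise = TRUE)
  write.table(raw[c("x", "value")], file.path(out, "profile_raw.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(norm[c("x", "value")],
              file.path(out, "profile_normalised.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  vals <- res$positions$window_mean[res$positions$zone > 1L]
  meta <- list(config_digest = config_digest(cfg),
               pretre = disc$pretre,
               variegation_index_zones23 = variegation_index(vals),
               base_seed = cfg$run$base_seed,
               package_version =
                 as.character(utils::packageVersion("pretre")))
  jsonlite::write_json(meta, file.path(out, "disc_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!quiet)
    message("variegation index (zones 2-3): ",
            signif(meta$variegation_index_zones23, 3))
  invisible(out)
}

#' Execute a grid-scan configuration
#'
#' Drives [run_grid()] from a config with a `grid` section and writes
#' one TSV row per grid cell.
#'
#' @inheritParams run_from_config
#' @return output directory, invisibly.
#' @export
run_scan_from_config <- function(cfg, quiet = FALSE) {
  if (is.null(cfg$grid) || !all(c("p34", "p5", "C") %in% names(cfg$grid)))
    stop("config error: grid section must list p34, p5 and C")
  if (any(lengths(cfg$grid[c("p34", "p5", "C")]) == 0))
    stop("config error: empty grid")
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run_grid(unlist(cfg$grid$p34), unlist(cfg$grid$p5),
                  unlist(cfg$grid$C), n = cfg$run$n_replicates,
                  base_seed = cfg$run$base_seed,
                  sample_every = cfg$run$sample_every)
  write.table(tab, file.path(cfg$output$dir, "grid.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(cfg$output$dir)
}
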