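#' Read a run configuration from JSON or YAML
#'
#' The configuration has optional blocks `map` (`A_khz`, `a_decades`, `k`,
#' `L_mm`), `perfusion` (`flow_mm_per_min`, `start_offset_min`),
#' `simulation` (any [sim_config()] argument except `map`/`model`),
#' `stats` (`n_perm`, `estimator`) and a top-level `seed`.  Unknown keys at
#' any level are rejected so that typos cannot silently fall back to
#' defaults.
#'
#' @param x path to a `.json`/`.yaml`/`.yml` file, or an equivalent named
#'   list.
#' @return a validated list of class `"run_config"` with elements `map`,
#'   `model`, `sim`, `n_perm`, `estimator`, `seed`.
#' @export
read_run_config <- function(x = list()) {
  if (is.character(x)) {
    stopifnot(file.exists(x))
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE))
      yaml::read_yaml(x)
    else jsonlite::read_json(x, simplifyVector = TRUE)
  }
  stopifnot(is.list(x))
  known_top <- c("map", "perfusion", "simulation", "stats", "seed")
  check_keys <- function(lst, known, where) {
    bad <- setdiff(names(lst), known)
    if (length(bad))
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
  }
  check_keys(x, known_top, "top level")
  check_keys(x$map, c("A_khz", "a_decades", "k", "L_mm"), "map")
  check_keys(x$perfusion, c("flow_mm_per_min", "start_offset_min"),
             "perfusion")
  sim_args <- setdiff(names(formals(sim_config)), c("map", "model", "seed"))
  check_keys(x$simulation, sim_args, "simulation")
  check_keys(x$stats, c("n_perm", "estimator"), "stats")
  map <- do.call(freq_place_map, x$map %||% list())
  model <- do.call(perfusion_model, x$perfusion %||% list())
  seed <- x$seed %||% 1L
  sim <- do.call(sim_config, c(x$simulation %||% list(),
                               list(map = map, model = model, seed = seed)))
  structure(list(map = map, model = model, sim = sim,
                 n_perm = x$stats$n_perm %||% 1e5,
                 estimator = x$stats$estimator %||% "paper",
                 seed = seed),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export trajectories as a long-format data frame
#'
#' @param study a `"synthetic_study"` from [simulate_trajectories()], or a
#'   list of [amp_series()].
#' @return data frame with columns `ear_id`, `group`, `freq_khz`,
#'   `level_db_sl`, `time_min`, `amplitude_uv`.
#' @export
series_to_df <- function(study) {
  series <- if (inherits(study, "synthetic_study")) study$series else study
  do.call(rbind, lapply(series, function(s)
    data.frame(ear_id = s$ear_id, group = s$group, freq_khz = s$freq_khz,
               level_db_sl = s$level_db_sl, time_min = s$times_min,
               amplitude_uv = s$amplitudes_uv)))
}

#' Rebuild amplitude series from a long-format data frame
#'
#' Inverse of [series_to_df()]; used to ingest trajectory CSV files.
#'
#' @param df data frame with the [series_to_df()] columns.
#' @return list of [amp_series()].
#' @export
df_to_series <- function(df) {
  need <- c("ear_id", "group", "freq_khz", "level_db_sl", "time_min",
            "amplitude_uv")
  stopifnot(all(need %in% names(df)))
  key <- interaction(df$ear_id, df$freq_khz, df$level_db_sl, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_min), ]
    amp_series(d$time_min, d$amplitude_uv, ear_id = d$ear_id[1],
               group = d$group[1], freq_khz = d$freq_khz[1],
               level_db_sl = d$level_db_sl[1])
  })
}

# extract the full reduction-time set from a list of raw series
extract_reductions <- function(series, k = 2) {
  rows <- lapply(series, function(s) {
    s <- normalize_to_baseline(s)
    r <- function(fr) as.numeric(reduction_time(s, fr, k = k))
    data.frame(ear_id = s$ear_id, group = s$group, freq_khz = s$freq_khz,
               level_db_sl = s$level_db_sl,
               t80_min = r(0.8), t50_min = r(0.5), t20_min = r(0.2))
  })
  do.call(rbind, rows)
}

#' Run a complete synthetic study through the pipeline
#'
#' Simulates CAP amplitude trajectories, normalizes them, extracts 80/50/20
#' reduction times, builds per-ear tuning curves and group averages, forms
#' the 10 dB SL 50% reduction-time table, converts group-mean differences
#' to octave shifts under the frequency-place map, and runs the full
#' permutation inference.  If `outdir` is given, writes `reductions.csv`,
#' `t50_table.csv`, `tuning_curves.csv`, `octave_shifts.csv`,
#' `inference.json` and `run_log.txt` there; a rerun with the same
#' configuration and seed reproduces the files exactly.
#'
#' @param config a `"run_config"` (see [read_run_config()]), a path to a
#'   config file, or `NULL` for the study defaults.
#' @param outdir optional output directory (created if needed).
#' @return class `"capmap_study"`: the synthetic study, extracted reduction
#'   table, tuning curves, group averages, octave-shift table and the
#'   `"capmap_inference"` report.
#' @export
run_study <- function(config = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config %||% list())
  study <- simulate_trajectories(cfg$sim)
  red <- extract_reductions(study$series)
  at10 <- red[red$level_db_sl == 10, ]
  if (anyNA(at10$t50_min))
    stop("incomplete 50% reduction-time table at 10 dB SL")
  tab <- t50_table(data.frame(ear_id = at10$ear_id, group = at10$group,
                              freq_khz = at10$freq_khz,
                              t50_min = at10$t50_min))
  # per-ear tuning curves (warnings about omitted noisy levels are expected)
  keys <- unique(red[, c("ear_id", "freq_khz")])
  tcs <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- vapply(study$series, function(s)
      s$ear_id == keys$ear_id[i] && s$freq_khz == keys$freq_khz[i],
      logical(1))
    build_tuning_curve(lapply(study$series[sel], normalize_to_baseline))
  })
  tc_avg <- list(
    operated = lapply(cfg$sim$freqs_khz, function(f)
      group_average_tc(Filter(function(tc) tc$freq_khz == f, tcs),
                       "operated")),
    control = lapply(cfg$sim$freqs_khz, function(f)
      group_average_tc(Filter(function(tc) tc$freq_khz == f, tcs),
                       "control")))
  shifts <- octave_shift_table(tab, cfg$model, cfg$map)
  inference <- run_full_inference(tab, n_perm = cfg$n_perm, seed = cfg$seed,
                                  estimator = cfg$estimator)
  out <- structure(list(config = cfg, study = study, reductions = red,
                        t50_table = tab, tuning_curves = tcs,
                        tc_averages = tc_avg, octave_shifts = shifts,
                        inference = inference),
                   class = "capmap_study")
  if (!is.null(outdir)) write_study(out, outdir)
  out
}

#' Octave-shift summary of a reduction-time table
#'
#' Per frequency: group means and SEMs of the 50% reduction times, the
#' control-minus-operated difference in minutes, and the equivalent CF
#' shift in octaves obtained by mapping both group means through the
#' perfusion model and frequency-place map.
#'
#' @param table a [t50_table()].
#' @param model,map perfusion model and frequency-place map.
#' @return data frame, one row per frequency.
#' @export
octave_shift_table <- function(table, model = perfusion_model(),
                               map = freq_place_map()) {
  stopifnot(inherits(table, "t50_table"))
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  op <- table$group == "operated"
  do.call(rbind, lapply(seq_along(table$freqs_khz), function(j) {
    v <- table$t50[, j]
    m_c <- mean(v[!op]); m_o <- mean(v[op])
    data.frame(freq_khz = table$freqs_khz[j],
               control_mean_min = m_c, control_sem_min = sem(v[!op]),
               operated_mean_min = m_o, operated_sem_min = sem(v[op]),
               diff_min = m_c - m_o,
               shift_octaves = octave_shift(m_c, m_o, model, map))
  }))
}

write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(outdir, f),
                                          row.names = FALSE)
  wcsv(study$reductions, "reductions.csv")
  wcsv(as.data.frame(study$t50_table), "t50_table.csv")
  tc_df <- do.call(rbind, lapply(study$tuning_curves, function(tc) {
    base <- data.frame(ear_id = tc$ear_id, group = tc$group,
                       freq_khz = tc$freq_khz)
    rbind(cbind(base, level_db_sl = 10, t80_min = NA_real_,
                t50_min = tc$tip_time_min, t20_min = NA_real_),
          if (nrow(tc$edges))
            cbind(base[rep(1, nrow(tc$edges)), ],
                  level_db_sl = tc$edges$level_db_sl,
                  t80_min = tc$edges$t80_min, t50_min = NA_real_,
                  t20_min = tc$edges$t20_min))
  }))
  wcsv(tc_df, "tuning_curves.csv")
  wcsv(study$octave_shifts, "octave_shifts.csv")
  inf <- study$inference
  jsonlite::write_json(
    list(per_freq = inf$per_freq, grand = inf$grand,
         settings = list(n_perm = inf$n_perm, seed = inf$seed,
                         estimator = inf$estimator)),
    file.path(outdir, "inference.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("capmap %s run", as.character(utils::packageVersion("capmap"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", study$config$seed),
    sprintf("n_perm: %g", study$config$n_perm),
    sprintf("ears: %d operated + %d control",
            study$config$sim$n_operated, study$config$sim$n_control),
    sprintf("frequencies_khz: %s",
            paste(study$config$sim$freqs_khz, collapse = ", "))),
    file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.capmap_study <- function(x, ...) {
  cat("Apex-to-base perfusion study analysis\n\n")
  print(x$octave_shifts, row.names = FALSE, digits = 3)
  cat("\n")
  print(x$inference)
  invisible(x)
}

#' Human-readable study summary
#'
#' Per-frequency mean 50% reduction-time differences with SEM, their octave
#' equivalents under the map, and the permutation p values.
#'
#' @param study a `"capmap_study"` from [run_study()].
#' @return invisibly, the octave-shift data frame; prints the report.
#' @export
report <- function(study) {
  stopifnot(inherits(study, "capmap_study"))
  if (nrow(study$octave_shifts) == 0) stop("empty study: no frequencies")
  mpo <- minutes_per_octave(study$config$model, study$config$map)
  cat(sprintf(
    "Perfusion: %g mm/min (%.2f min per CF octave in the basal map region)\n\n",
    study$config$model$flow_mm_per_min, mpo))
  df <- merge(study$octave_shifts,
              study$inference$per_freq[, c("freq_khz", "p_exact_one",
                                           "p_mc_one")],
              by = "freq_khz")
  cat("Control - operated 50% reduction times (10 dB SL):\n")
  print(data.frame(freq_khz = df$freq_khz,
                   diff_min = round(df$diff_min, 2),
                   shift_octaves = round(df$shift_octaves, 2),
                   p_exact = signif(df$p_exact_one, 3),
                   p_mc = signif(df$p_mc_one, 3)),
        row.names = FALSE)
  cat("\nGrand average over frequencies (one-sided):\n")
  print(study$inference$grand, row.names = FALSE, digits = 4)
  invisible(study$octave_shifts)
}
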