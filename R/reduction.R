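#' CAP amplitude trajectory over perfusion time
#'
#' One ear x tone frequency x stimulus level trajectory of peak-to-peak CAP
#' amplitude against time relative to perfusion start.  Stimulus level is in
#' dB sensation level (SL), i.e. dB above that ear's CAP threshold at that
#' frequency.
#'
#' @param times_min sample times re perfusion start (min), strictly
#'   increasing; the study sampled roughly every minute starting 5-10 min
#'   before the perfusion.
#' @param amplitudes_uv raw peak-to-peak amplitudes (microvolts).
#' @param ear_id ear identifier.
#' @param group `"operated"` or `"control"`.
#' @param freq_khz tone frequency (kHz).
#' @param level_db_sl tone level (dB SL).
#' @return An object of class `"amp_series"`.
#' @export
amp_series <- function(times_min, amplitudes_uv, ear_id = NA_character_,
                       group = NA_character_, freq_khz = NA_real_,
                       level_db_sl = NA_real_) {
  stopifnot(is.numeric(times_min), is.numeric(amplitudes_uv),
            length(times_min) == length(amplitudes_uv),
            length(times_min) >= 2, all(diff(times_min) > 0))
  if (!is.na(group)) group <- match.arg(group, c("operated", "control"))
  structure(list(times_min = as.numeric(times_min),
                 amplitudes_uv = as.numeric(amplitudes_uv),
                 normalized = NULL, baseline_uv = NA_real_,
                 ear_id = ear_id, group = group, freq_khz = freq_khz,
                 level_db_sl = level_db_sl),
            class = "amp_series")
}

#' @export
print.amp_series <- function(x, ...) {
  cat(sprintf(
    "CAP amplitude series: ear %s (%s), %g kHz @ %g dB SL, %d samples (%g to %g min)%s\n",
    x$ear_id, x$group, x$freq_khz, x$level_db_sl, length(x$times_min),
    min(x$times_min), max(x$times_min),
    if (is.null(x$normalized)) "" else
      sprintf(", normalized (baseline %.3g uV)", x$baseline_uv)))
  invisible(x)
}

#' Normalize a trajectory to its pre-perfusion baseline
#'
#' Divides the amplitudes by the mean of the samples whose times fall in the
#' baseline window (-5 to +5 min re perfusion start by default), so that the
#' windowed mean of the normalized trace is 1.
#'
#' @param series an [amp_series()].
#' @param window_min `c(lo, hi)` baseline window (min).
#' @return the series with its `normalized` field filled.
#' @export
normalize_to_baseline <- function(series, window_min = c(-5, 5)) {
  stopifnot(inherits(series, "amp_series"), length(window_min) == 2,
            window_min[1] < window_min[2])
  sel <- series$times_min >= window_min[1] & series$times_min <= window_min[2]
  if (sum(sel) < 2)
    stop("need at least 2 samples in the baseline window for normalization")
  series$baseline_uv <- mean(series$amplitudes_uv[sel])
  if (series$baseline_uv <= 0) stop("non-positive baseline amplitude")
  series$normalized <- series$amplitudes_uv / series$baseline_uv
  series
}

#' Time at which a normalized trajectory is reduced to a given fraction
#'
#' Finds the first downward crossing of `fraction` that is sustained for at
#' least `k` consecutive samples (so single-sample noise dips are ignored),
#' and interpolates the crossing time linearly between the bracketing
#' samples.  A sample lying exactly at the fraction is taken as the crossing
#' time itself.  The 50% time of a low-level response marks when the
#' perfusion front reached the tone's CF place; 80% and 20% times mark the
#' apical and basal edges of the response region.
#'
#' @param series a normalized [amp_series()] (see [normalize_to_baseline()]).
#' @param fraction target fraction of baseline, typically 0.8, 0.5 or 0.2.
#' @param k sustained-crossing run length (samples at or below the fraction).
#' @param smooth optional `"median3"` applies a 3-point running median
#'   before crossing detection; default `"none"` uses the raw trace.
#' @return crossing time (min).  `NA` with attribute `reason = "no
#'   reduction"` if the trace never sustains a crossing; if the trace is
#'   already below the fraction at its first sample the first time is
#'   returned with attribute `flag = "before start"`.
#' @export
reduction_time <- function(series, fraction, k = 2,
                           smooth = c("none", "median3")) {
  stopifnot(inherits(series, "amp_series"))
  if (is.null(series$normalized))
    stop("series must be normalized first (normalize_to_baseline)")
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction < 1, k >= 1)
  smooth <- match.arg(smooth)
  a <- series$normalized
  if (smooth == "median3" && length(a) >= 3)
    a <- stats::runmed(a, 3, endrule = "keep")
  tt <- series$times_min
  n <- length(a)
  below <- a <= fraction
  # length of the at-or-below run starting at each index
  runlen <- integer(n)
  run <- 0L
  for (j in n:1) {
    run <- if (below[j]) run + 1L else 0L
    runlen[j] <- run
  }
  # crossing = run start (previous sample above fraction) whose run is
  # sustained for >= k samples, or reaches the end of the record
  starts <- which(below & c(TRUE, !below[-n]))
  starts <- starts[runlen[starts] >= k | starts + runlen[starts] - 1L == n]
  if (length(starts) == 0)
    return(structure(NA_real_, reason = "no reduction"))
  i <- starts[1]
  if (i == 1L)
    return(structure(tt[1], flag = "before start"))
  if (a[i] == fraction) return(tt[i])
  tt[i - 1] + (tt[i] - tt[i - 1]) * (a[i - 1] - fraction) / (a[i - 1] - a[i])
}

#' CAP reduction-time tuning curve for one ear and frequency
#'
#' The tuning-curve tip is the 50% reduction time of the threshold-level
#' (10 dB SL) response.  At each higher level the 80% reduction time marks
#' the apical edge and the 20% time the basal edge of the cochlear region
#' contributing to the CAP; 80/20 times are not computed at 10 dB SL because
#' low-level response SNR does not support them.
#'
#' @param series_list list of normalized [amp_series()] for one ear and
#'   frequency across levels; must include a 10 dB SL series.
#' @param k,smooth passed to [reduction_time()].
#' @return An object of class `"rt_tuning_curve"`: `ear_id`, `freq_khz`,
#'   `tip_time_min`, and `edges`, a data frame with columns `level_db_sl`,
#'   `t80_min`, `t20_min`.  Levels whose crossings cannot be determined, or
#'   whose extracted edges are inverted by noise, are omitted with a warning.
#' @export
build_tuning_curve <- function(series_list, k = 2,
                               smooth = c("none", "median3")) {
  smooth <- match.arg(smooth)
  stopifnot(is.list(series_list), length(series_list) >= 1)
  lv <- vapply(series_list, function(s) s$level_db_sl, numeric(1))
  stopifnot(!anyDuplicated(lv))
  i_tip <- which(lv == 10)
  if (length(i_tip) != 1)
    stop("a 10 dB SL series is required for the tuning-curve tip")
  tip <- reduction_time(series_list[[i_tip]], 0.5, k = k, smooth = smooth)
  if (is.na(tip)) stop("no 50% reduction at 10 dB SL; cannot place the tip")
  s0 <- series_list[[i_tip]]
  edges <- data.frame(level_db_sl = numeric(0), t80_min = numeric(0),
                      t20_min = numeric(0))
  for (j in order(lv)) {
    if (lv[j] <= 10) next
    t80 <- reduction_time(series_list[[j]], 0.8, k = k, smooth = smooth)
    t20 <- reduction_time(series_list[[j]], 0.2, k = k, smooth = smooth)
    if (is.na(t80) || is.na(t20)) {
      warning(sprintf("ear %s %g kHz: crossing missing at %g dB SL; level omitted",
                      s0$ear_id, s0$freq_khz, lv[j]))
      next
    }
    if (t80 > t20) {
      warning(sprintf("ear %s %g kHz: t80 > t20 at %g dB SL; level omitted",
                      s0$ear_id, s0$freq_khz, lv[j]))
      next
    }
    edges <- rbind(edges, data.frame(level_db_sl = lv[j],
                                     t80_min = as.numeric(t80),
                                     t20_min = as.numeric(t20)))
  }
  structure(list(ear_id = s0$ear_id, group = s0$group, freq_khz = s0$freq_khz,
                 tip_time_min = as.numeric(tip), edges = edges),
            class = "rt_tuning_curve")
}

#' @export
print.rt_tuning_curve <- function(x, ...) {
  cat(sprintf("Reduction-time tuning curve: ear %s (%s), %g kHz\n",
              x$ear_id, x$group, x$freq_khz))
  cat(sprintf("  tip (50%% @ 10 dB SL): %.2f min\n", x$tip_time_min))
  if (nrow(x$edges)) {
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %g dB SL: t80 = %.2f, t20 = %.2f min\n",
                  x$edges$level_db_sl[i], x$edges$t80_min[i],
                  x$edges$t20_min[i]))
  }
  invisible(x)
}

#' @export
plot.rt_tuning_curve <- function(x, add = FALSE, col = 1, ...) {
  tmin <- c(x$tip_time_min, x$edges$t80_min, x$edges$t20_min)
  lv <- c(10, x$edges$level_db_sl)
  if (!add)
    plot(range(tmin), range(lv), type = "n",
         xlab = "Perfusion time (min)", ylab = "Level (dB SL)", ...)
  lines(c(rev(x$edges$t80_min), x$tip_time_min, x$edges$t20_min),
        c(rev(x$edges$level_db_sl), 10, x$edges$level_db_sl),
        col = col, type = "o", pch = 16)
  invisible(x)
}

#' Group-average reduction-time tuning curve
#'
#' Averages tuning curves across ears at each sensation level.  The SEM is
#' reported only where at least two ears contribute; the number of ears per
#' point is recorded.
#'
#' @param tcs list of [build_tuning_curve()] results (one ear each).
#' @param group optional group label to filter on.
#' @return class `"rt_tc_average"`: `tip` (mean/sem/n of the tips) and
#'   `edges`, a data frame with per-level mean, SEM and n for t80 and t20.
#' @export
group_average_tc <- function(tcs, group = NULL) {
  stopifnot(is.list(tcs), length(tcs) >= 1)
  if (!is.null(group))
    tcs <- Filter(function(tc) identical(tc$group, group), tcs)
  if (length(tcs) == 0) stop("no tuning curves in the requested group")
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  tips <- vapply(tcs, function(tc) tc$tip_time_min, numeric(1))
  lv_all <- sort(unique(unlist(lapply(tcs, function(tc) tc$edges$level_db_sl))))
  edges <- do.call(rbind, lapply(lv_all, function(l) {
    t80 <- unlist(lapply(tcs, function(tc)
      tc$edges$t80_min[tc$edges$level_db_sl == l]))
    t20 <- unlist(lapply(tcs, function(tc)
      tc$edges$t20_min[tc$edges$level_db_sl == l]))
    data.frame(level_db_sl = l,
               t80_mean = mean(t80), t80_sem = sem(t80), t80_n = length(t80),
               t20_mean = mean(t20), t20_sem = sem(t20), t20_n = length(t20))
  }))
  structure(list(group = if (is.null(group)) tcs[[1]]$group else group,
                 freq_khz = tcs[[1]]$freq_khz,
                 tip = list(mean = mean(tips), sem = sem(tips),
                            n = length(tips)),
                 edges = if (is.null(edges))
                   data.frame(level_db_sl = numeric(0)) else edges),
            class = "rt_tc_average")
}

#' @export
print.rt_tc_average <- function(x, ...) {
  cat(sprintf("Average reduction-time tuning curve (%s, %g kHz, n = %d ears)\n",
              x$group, x$freq_khz, x$tip$n))
  cat(sprintf("  tip: %.2f min (SEM %s)\n", x$tip$mean,
              if (is.na(x$tip$sem)) "n/a" else sprintf("%.2f", x$tip$sem)))
  if (nrow(x$edges))
    print(x$edges, row.names = FALSE, digits = 4)
  invisible(x)
}
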