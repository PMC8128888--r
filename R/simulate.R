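#' Configuration of a synthetic perfusion study
#'
#' Defines the statistical structure of a simulated apex-to-base perfusion
#' experiment: group sizes, test frequencies, the per-frequency apical
#' shifts of the operated group, a shared-across-frequency random ear
#' effect (which makes ear variation highly correlated across frequency),
#' a responder probability (allowing operated ears that show no map shift
#' and look like controls at every frequency), the sigmoidal amplitude
#' decline, and measurement noise.
#'
#' `group_shift_min` is the expected control-minus-operated group-mean
#' difference at each frequency; internally each *responding* operated ear
#' is shifted by `group_shift_min / responder_prob` so that the configured
#' values are recovered in expectation even when some ears do not respond.
#' The defaults are the study's printed mean differences at 2, 4, 6, 8 and
#' 12 kHz.
#'
#' @param n_operated,n_control ears per group.
#' @param freqs_khz test frequencies (kHz).
#' @param group_shift_min expected control-minus-operated mean difference of
#'   50% reduction times per frequency (min).
#' @param responder_prob probability that an operated ear expresses the
#'   shift.
#' @param ear_sd_min SD of the ear-level random offset shared across
#'   frequency (min).
#' @param resid_sd_min SD of the per-cell residual (min).
#' @param logistic_slope_min slope of the logistic amplitude decline (min).
#' @param delta_lo_min,delta_hi_min per 10 dB above 10 dB SL, the 80%
#'   (apical-edge) time moves earlier by `delta_lo_min` and the 20%
#'   (basal-edge) time later by `delta_hi_min`; the high side moves more,
#'   as in normal-ear tuning curves.
#' @param levels_db_sl stimulus levels (dB SL) simulated per ear/frequency.
#' @param noise_sd SD of additive Gaussian noise on the normalized
#'   amplitude traces.
#' @param baseline_uv mean raw baseline CAP amplitude (microvolts).
#' @param times_min sampling grid of the trajectories (min re perfusion
#'   start).
#' @param map,model the frequency-place map and perfusion model.
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_operated = 5, n_control = 8,
                       freqs_khz = c(2, 4, 6, 8, 12),
                       group_shift_min = c(5.8, 3.8, 4.3, 2.4, 3.4),
                       responder_prob = 0.8,
                       ear_sd_min = 2.0, resid_sd_min = 0.5,
                       logistic_slope_min = 0.8,
                       delta_lo_min = 0.8, delta_hi_min = 2.0,
                       levels_db_sl = c(10, 20, 30, 40),
                       noise_sd = 0.02, baseline_uv = 40,
                       times_min = seq(-10, 45, by = 1),
                       map = freq_place_map(), model = perfusion_model(),
                       seed = 1) {
  stopifnot(n_operated >= 1, n_control >= 1,
            length(group_shift_min) == length(freqs_khz),
            all(is.finite(group_shift_min)),
            responder_prob >= 0, responder_prob <= 1,
            ear_sd_min >= 0, resid_sd_min >= 0, logistic_slope_min > 0,
            delta_lo_min >= 0, delta_hi_min >= 0, noise_sd >= 0,
            10 %in% levels_db_sl)
  structure(list(n_operated = n_operated, n_control = n_control,
                 freqs_khz = freqs_khz, group_shift_min = group_shift_min,
                 responder_prob = responder_prob, ear_sd_min = ear_sd_min,
                 resid_sd_min = resid_sd_min,
                 logistic_slope_min = logistic_slope_min,
                 delta_lo_min = delta_lo_min, delta_hi_min = delta_hi_min,
                 levels_db_sl = levels_db_sl, noise_sd = noise_sd,
                 baseline_uv = baseline_uv, times_min = times_min,
                 map = map, model = model, seed = seed),
            class = "sim_config")
}

# ground-truth t50 draw shared by the table- and trajectory-level
# generators; assumes the RNG is already seeded
draw_t50_truth <- function(cfg) {
  n_ear <- cfg$n_operated + cfg$n_control
  group <- rep(c("operated", "control"), c(cfg$n_operated, cfg$n_control))
  base_t <- time_from_cf(cfg$freqs_khz, cfg$model, cfg$map)
  u_ear <- stats::rnorm(n_ear, 0, cfg$ear_sd_min)
  z_ear <- ifelse(group == "operated",
                  stats::rbinom(n_ear, 1, cfg$responder_prob), 0)
  shift <- if (cfg$responder_prob > 0)
    cfg$group_shift_min / cfg$responder_prob else 0 * cfg$group_shift_min
  t50 <- outer(u_ear, base_t, `+`) -
    outer(z_ear, shift) +
    matrix(stats::rnorm(n_ear * length(cfg$freqs_khz), 0, cfg$resid_sd_min),
           n_ear)
  dimnames(t50) <- list(sprintf("ear%02d", seq_len(n_ear)),
                        as.character(cfg$freqs_khz))
  list(t50 = t50, group = group, responder = z_ear == 1 |
         group == "control")
}

#' Simulate a table of ground-truth 50% reduction times
#'
#' Draws `t50(ear, f) = time_from_cf(f) + u_ear - I[operated] z_ear s_f +
#' eps` with `u_ear ~ N(0, ear_sd^2)` shared across frequencies (inducing
#' across-frequency correlation), `z_ear ~ Bernoulli(responder_prob)` per
#' operated ear, per-responder shift `s_f = group_shift_min[f] /
#' responder_prob`, and `eps ~ N(0, resid_sd^2)`.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` if given.
#' @return list with `table` (a [t50_table()]), `truth` (the same matrix),
#'   and `responder` (logical per ear; controls are `TRUE`).
#' @export
simulate_t50_table <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  tr <- with_seed(seed, draw_t50_truth(config))
  list(table = t50_table(tr$t50, tr$group, config$freqs_khz),
       truth = tr$t50, responder = tr$responder)
}

# noiseless normalized logistic decline with level-dependent centre/width.
# At 10 dB SL the curve is centred on t50 with the base slope; above it the
# 80% point moves earlier by delta_lo and the 20% point later by delta_hi
# per 10 dB, so the curve widens asymmetrically with level.
logistic_trace <- function(t, t50, level_db_sl, cfg) {
  if (level_db_sl <= 10) {
    centre <- t50
    slope <- cfg$logistic_slope_min
  } else {
    g <- (level_db_sl - 10) / 10
    t80 <- t50 - log(4) * cfg$logistic_slope_min - cfg$delta_lo_min * g
    t20 <- t50 + log(4) * cfg$logistic_slope_min + cfg$delta_hi_min * g
    centre <- (t80 + t20) / 2
    slope <- (t20 - t80) / (2 * log(4))
  }
  1 / (1 + exp((t - centre) / slope))
}

#' Simulate CAP amplitude trajectories for a whole study
#'
#' Generates, for every ear x frequency x level, a normalized logistic
#' amplitude decline centred on that cell's ground-truth reduction time,
#' scaled by a raw baseline amplitude, with additive Gaussian noise, on a
#' 1-minute sampling grid starting 10 min before the perfusion.
#'
#' @inheritParams simulate_t50_table
#' @return class `"synthetic_study"`: `series` (list of [amp_series()]),
#'   `truth_t50` (ears x frequencies matrix of the 50% times at 10 dB SL),
#'   `responder`, `group`, and the `config` echo.
#' @export
simulate_trajectories <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(seed, {
    tr <- draw_t50_truth(config)
    n_ear <- nrow(tr$t50)
    series <- list()
    for (i in seq_len(n_ear)) {
      for (j in seq_along(config$freqs_khz)) {
        for (lv in config$levels_db_sl) {
          a <- logistic_trace(config$times_min, tr$t50[i, j], lv, config) +
            stats::rnorm(length(config$times_min), 0, config$noise_sd)
          series[[length(series) + 1L]] <- amp_series(
            config$times_min, a * config$baseline_uv,
            ear_id = rownames(tr$t50)[i], group = tr$group[i],
            freq_khz = config$freqs_khz[j], level_db_sl = lv)
        }
      }
    }
    structure(list(series = series, truth_t50 = tr$t50,
                   responder = tr$responder, group = tr$group,
                   config = config),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic perfusion study: %d operated + %d control ears, %d freqs x %d levels (%d series)\n",
    x$config$n_operated, x$config$n_control, length(x$config$freqs_khz),
    length(x$config$levels_db_sl), length(x$series)))
  invisible(x)
}

# biphasic CAP template (microvolts) with unit peak-to-peak amplitude;
# N1 trough near 1.5 ms, P1 peak near 2.3 ms post-onset
cap_template <- function(t_s) {
  v <- -exp(-((t_s - 0.0015) / 0.00035) ^ 2) +
    0.6 * exp(-((t_s - 0.0023) / 0.00045) ^ 2)
  v / diff(range(v))
}

#' Simulate a pair of alternating-polarity CAP waveforms
#'
#' A polarity-invariant biphasic CAP template of the requested peak-to-peak
#' amplitude plus a polarity-inverting cochlear-microphonic sinusoid; the
#' microphonic cancels in [average_alternating()].
#'
#' @param pp_uv CAP peak-to-peak amplitude (microvolts).
#' @param f_hz stimulus (and microphonic) frequency.
#' @param fs sampling rate (Hz).
#' @param dur_s record duration (s).
#' @param cm_uv microphonic amplitude (microvolts).
#' @param noise_uv additive noise SD (microvolts); 0 by default.
#' @param seed seed used when `noise_uv > 0`.
#' @return list with elements `pos` and `neg` ([evoked_waveform()]).
#' @export
simulate_cap_pair <- function(pp_uv, f_hz = 4000, fs = 96000,
                              dur_s = 0.0139, cm_uv = 5, noise_uv = 0,
                              seed = 1) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  cap <- pp_uv * cap_template(t)
  cm <- cm_uv * sin(2 * pi * f_hz * t)
  mk <- function(sgn, pol) {
    noise <- if (noise_uv > 0)
      with_seed(seed + (sgn + 1) / 2, stats::rnorm(length(t), 0, noise_uv))
      else 0
    evoked_waveform(cap + sgn * cm + noise, fs, stim_freq_hz = f_hz,
                    polarity = pol)
  }
  list(pos = mk(1, "condensation"), neg = mk(-1, "rarefaction"))
}

#' Simulate an ear-canal OAE recording
#'
#' Sum of stimulus tones and (optionally) an emission tone, each specified
#' as frequency / level pairs, plus Gaussian microphone noise.  Levels are
#' dB SPL (RMS re 20 uPa).
#'
#' @param tones data frame with columns `f_hz`, `db_spl` and optionally
#'   `phase_rad`.
#' @param fs sampling rate (Hz).
#' @param dur_s duration (s).
#' @param noise_pa additive noise SD (Pa).
#' @param seed seed used when `noise_pa > 0`.
#' @return a [pressure_rec()].
#' @export
simulate_oae_recording <- function(tones, fs = 48000, dur_s = 1,
                                   noise_pa = 0, seed = 1) {
  stopifnot(is.data.frame(tones), all(c("f_hz", "db_spl") %in% names(tones)))
  if (is.null(tones$phase_rad)) tones$phase_rad <- 0
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  s <- rep(0, length(t))
  for (i in seq_len(nrow(tones))) {
    amp_peak <- sqrt(2) * P_REF_PA * 10 ^ (tones$db_spl[i] / 20)
    s <- s + amp_peak * cos(2 * pi * tones$f_hz[i] * t + tones$phase_rad[i])
  }
  if (noise_pa > 0)
    s <- s + with_seed(seed, stats::rnorm(length(t), 0, noise_pa))
  pressure_rec(s, fs)
}
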