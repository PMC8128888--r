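#' Ear-canal pressure recording
#'
#' @param samples pressure samples (Pa).
#' @param fs sampling rate (Hz); must exceed twice the highest analysis
#'   frequency.
#' @param stimulus optional named list describing the stimulus (e.g. `f1`,
#'   `f2`, `L1`, `L2` for a DPOAE primary pair; probe/suppressor frequencies
#'   and levels for SFOAE).
#' @return An object of class `"pressure_rec"`.
#' @export
pressure_rec <- function(samples, fs, stimulus = list()) {
  stopifnot(is.numeric(samples), length(samples) >= 2,
            all(is.finite(samples)), is.numeric(fs), fs > 0,
            is.list(stimulus))
  structure(list(samples = as.numeric(samples), fs = fs,
                 stimulus = stimulus),
            class = "pressure_rec")
}

#' @export
print.pressure_rec <- function(x, ...) {
  cat(sprintf("Ear-canal pressure recording: %d samples @ %g kHz (%.3g s)\n",
              length(x$samples), x$fs / 1000, length(x$samples) / x$fs))
  invisible(x)
}

P_REF_PA <- 20e-6   # 0 dB SPL reference (RMS)

pa_rms_to_db_spl <- function(p) ifelse(p > 0, 20 * log10(p / P_REF_PA), -Inf)

# complex least-squares amplitude at frequency f over a sample window.
# Returns the complex RMS amplitude c with |c| the RMS pressure (Pa) of the
# fitted sinusoid and Arg(c) its cosine phase.
ls_tone_fit <- function(samples, fs, f_hz, idx) {
  t <- (idx - 1) / fs
  cc <- cos(2 * pi * f_hz * t)
  ss <- sin(2 * pi * f_hz * t)
  y <- samples[idx]
  # closed-form 2x2 least squares
  G <- rbind(c(sum(cc * cc), sum(cc * ss)), c(sum(cc * ss), sum(ss * ss)))
  b <- c(sum(cc * y), sum(ss * y))
  ab <- solve(G, b)
  complex(real = ab[1], imaginary = -ab[2]) / sqrt(2)
}

# integer-cycle sample window for frequency f within [t_start, t_end] (s)
cycle_window <- function(fs, f_hz, n_samples, t_start = 0,
                         t_end = n_samples / fs) {
  i0 <- floor(t_start * fs) + 1L
  i1 <- min(n_samples, floor(t_end * fs))
  n_cyc <- floor((i1 - i0 + 1L) / fs * f_hz)
  if (n_cyc < 1) stop("analysis window shorter than one cycle of f")
  i0:(i0 + round(n_cyc * fs / f_hz) - 1L)
}

#' Amplitude and phase of a tone component
#'
#' Least-squares fit of a sinusoid at exactly `f_hz` over an integer number
#' of cycles of the analysis window (truncated by whole cycles, so
#' components at frequencies orthogonal over the window do not leak in).
#'
#' @param rec a [pressure_rec()].
#' @param f_hz analysis frequency (Hz).
#' @param window `c(start, end)` in seconds, or `NULL` for the whole record.
#' @return list with `db_spl` (RMS re 20 uPa; `-Inf` for a zero record),
#'   `phase_rad`, `amp_pa_rms` and the complex RMS amplitude `camp`.
#' @export
tone_amplitude <- function(rec, f_hz, window = NULL) {
  stopifnot(inherits(rec, "pressure_rec"), f_hz > 0, rec$fs > 2 * f_hz)
  n <- length(rec$samples)
  idx <- if (is.null(window)) cycle_window(rec$fs, f_hz, n)
         else cycle_window(rec$fs, f_hz, n, window[1], window[2])
  camp <- ls_tone_fit(rec$samples, rec$fs, f_hz, idx)
  amp <- Mod(camp)
  list(db_spl = pa_rms_to_db_spl(amp), phase_rad = Arg(camp),
       amp_pa_rms = amp, camp = camp)
}

#' OAE noise floor from repetition-to-repetition variability
#'
#' Standard error, across stimulus repetitions, of the per-repetition tone
#' amplitudes, expressed in dB SPL.  By default the SE is computed on the
#' complex amplitudes (real and imaginary SEs combined in quadrature), which
#' captures both amplitude and phase variability; `mode = "magnitude"` uses
#' the scalar magnitudes instead.
#'
#' @param amps complex (or numeric magnitude) RMS amplitudes in Pa, one per
#'   repetition; at least 2.
#' @param mode `"complex"` or `"magnitude"`.
#' @param floor_db_spl value returned when the repetitions are identical
#'   (SE of 0).
#' @return noise floor in dB SPL.
#' @export
oae_noise_floor <- function(amps, mode = c("complex", "magnitude"),
                            floor_db_spl = -120) {
  mode <- match.arg(mode)
  stopifnot(length(amps) >= 2)
  n <- length(amps)
  se <- if (mode == "complex") {
    a <- as.complex(amps)
    sqrt((stats::var(Re(a)) + stats::var(Im(a))) / n)
  } else {
    stats::sd(Mod(amps)) / sqrt(n)
  }
  if (se <= 0) return(floor_db_spl)
  max(pa_rms_to_db_spl(se), floor_db_spl)
}

#' Distortion-product OAE amplitude at 2f1 - f2
#'
#' Coherently averages the repetitions, extracts the tone amplitude at the
#' cubic distortion frequency `2 f1 - f2`, and estimates the noise floor
#' from the repetition-to-repetition variability of the per-repetition
#' amplitudes at that frequency.  The study used f2/f1 = 1.22 with L1, L2 of
#' 60 and 50 dB SPL and 12 repetitions per frequency.
#'
#' @param recs list of [pressure_rec()] repetitions (>= 2 for a noise
#'   floor).
#' @param f1,f2 primary frequencies (Hz), f2 > f1.
#' @param ratio_tol tolerance on f2/f1 relative to `expected_ratio`.
#' @param expected_ratio nominal primary ratio.
#' @param window analysis window in seconds (`NULL` = whole record).
#' @param nf_mode noise-floor mode, see [oae_noise_floor()].
#' @return list with `f_dp_hz`, `amplitude_db_spl`, `noise_floor_db_spl`,
#'   `n_reps`.
#' @export
dpoae_amplitude <- function(recs, f1, f2, expected_ratio = 1.22,
                            ratio_tol = 0.05, window = NULL,
                            nf_mode = c("complex", "magnitude")) {
  nf_mode <- match.arg(nf_mode)
  stopifnot(is.list(recs), length(recs) >= 1, f2 > f1)
  if (abs(f2 / f1 - expected_ratio) > ratio_tol)
    stop(sprintf("f2/f1 = %.3f outside tolerance of %.2f", f2 / f1,
                 expected_ratio))
  f_dp <- 2 * f1 - f2
  stopifnot(f_dp > 0)
  len <- vapply(recs, function(r) length(r$samples), integer(1))
  fs <- vapply(recs, function(r) r$fs, numeric(1))
  if (length(unique(len)) != 1 || length(unique(fs)) != 1)
    stop("repetitions must share length and sampling rate")
  mean_rec <- pressure_rec(
    rowMeans(vapply(recs, function(r) r$samples, numeric(len[1]))), fs[1])
  amp <- tone_amplitude(mean_rec, f_dp, window)
  nf <- if (length(recs) >= 2) {
    camps <- vapply(recs, function(r) tone_amplitude(r, f_dp, window)$camp,
                    complex(1))
    oae_noise_floor(camps, nf_mode)
  } else NA_real_
  list(f_dp_hz = f_dp, amplitude_db_spl = amp$db_spl,
       noise_floor_db_spl = nf, n_reps = length(recs))
}

#' Double-evoked SFOAE residual
#'
#' The stimulus-frequency OAE is isolated by the double-evoked method:
#' `residual = probe_alone + suppressor_alone - both`.  For a strictly
#' linear ear the three responses superpose and the residual is zero; a
#' probe-frequency emission that the suppressor removes survives in the
#' residual.  The study used 40 dB SPL probes with 60 dB SPL suppressors
#' 50 Hz above the probe frequency.
#'
#' @param probe_alone,suppressor_alone,both [pressure_rec()] responses to
#'   the probe alone, suppressor alone, and both together.
#' @return the residual as a [pressure_rec()].
#' @export
sfoae_residual <- function(probe_alone, suppressor_alone, both) {
  recs <- list(probe_alone, suppressor_alone, both)
  stopifnot(all(vapply(recs, inherits, logical(1), "pressure_rec")))
  len <- vapply(recs, function(r) length(r$samples), integer(1))
  fs <- vapply(recs, function(r) r$fs, numeric(1))
  if (length(unique(len)) != 1 || length(unique(fs)) != 1)
    stop("recordings must share length and sampling rate")
  pressure_rec(probe_alone$samples + suppressor_alone$samples - both$samples,
               fs[1], stimulus = probe_alone$stimulus)
}

#' SFOAE amplitude from the double-evoked residual
#'
#' @inheritParams sfoae_residual
#' @param f_probe_hz probe frequency (Hz).
#' @param window analysis window (s), typically the steady state excluding
#'   the 10 ms rise/fall ramps.
#' @return list with `amplitude_db_spl`, `phase_rad`, `amp_pa_rms`.
#' @export
sfoae_amplitude <- function(probe_alone, suppressor_alone, both, f_probe_hz,
                            window = NULL) {
  res <- sfoae_residual(probe_alone, suppressor_alone, both)
  a <- tone_amplitude(res, f_probe_hz, window)
  list(amplitude_db_spl = a$db_spl, phase_rad = a$phase_rad,
       amp_pa_rms = a$amp_pa_rms)
}
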