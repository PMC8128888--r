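#' Evoked-potential waveform record
#'
#' Container for a single averaged evoked waveform (CAP or ANOW).  Sample
#' `i` occurs at time `(i - 1) / fs` seconds from the start of the record;
#' `t0` marks the stimulus onset within the record.
#'
#' @param samples voltage samples (microvolts).
#' @param fs sampling rate (Hz); the study recorded at 96 kHz.
#' @param stim_freq_hz tone-burst frequency (Hz), or `NA`.
#' @param stim_level_db tone-burst level (dB SPL), or `NA`.
#' @param polarity `"condensation"`, `"rarefaction"` or `NA` for an average.
#' @param t0 stimulus onset time within the record (s).
#' @return An object of class `"evoked_waveform"`.
#' @export
evoked_waveform <- function(samples, fs, stim_freq_hz = NA_real_,
                            stim_level_db = NA_real_,
                            polarity = NA_character_, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 2, all(is.finite(samples)),
            is.numeric(fs), fs > 0, is.numeric(t0), t0 >= 0)
  if (!is.na(polarity))
    polarity <- match.arg(polarity, c("condensation", "rarefaction"))
  structure(list(samples = as.numeric(samples), fs = fs,
                 stim_freq_hz = stim_freq_hz, stim_level_db = stim_level_db,
                 polarity = polarity, t0 = t0),
            class = "evoked_waveform")
}

#' @export
print.evoked_waveform <- function(x, ...) {
  cat(sprintf(
    "Evoked waveform: %d samples @ %g kHz (%.2f ms), stim %g Hz / %g dB SPL\n",
    length(x$samples), x$fs / 1000, 1000 * length(x$samples) / x$fs,
    x$stim_freq_hz, x$stim_level_db))
  invisible(x)
}

# sample times (s) of an evoked_waveform
wave_times <- function(w) (seq_along(w$samples) - 1) / w$fs

#' Average condensation and rarefaction responses
#'
#' Sample-wise mean of the responses to the two tone-burst polarities.
#' Any signal component that inverts with stimulus polarity (cochlear
#' microphonic, stimulus artifact) cancels; polarity-invariant neural
#' components (CAP) are preserved.
#'
#' @param pos,neg [evoked_waveform()] records of equal length and rate.
#' @return an averaged [evoked_waveform()].
#' @export
average_alternating <- function(pos, neg) {
  stopifnot(inherits(pos, "evoked_waveform"), inherits(neg, "evoked_waveform"))
  if (length(pos$samples) != length(neg$samples) || pos$fs != neg$fs)
    stop("waveforms must have equal length and sampling rate")
  evoked_waveform((pos$samples + neg$samples) / 2, pos$fs,
                  stim_freq_hz = pos$stim_freq_hz,
                  stim_level_db = pos$stim_level_db, t0 = pos$t0)
}

#' Peak-to-peak CAP amplitude
#'
#' Max minus min of the waveform within a post-onset search window.  The
#' default window of 0.5-6 ms spans guinea-pig CAP N1/P1 latencies.
#'
#' @param w an [evoked_waveform()].
#' @param search_window_ms `c(start, end)` in ms relative to stimulus onset.
#' @return peak-to-peak amplitude (microvolts, >= 0).
#' @export
cap_amplitude <- function(w, search_window_ms = c(0.5, 6)) {
  stopifnot(inherits(w, "evoked_waveform"), length(search_window_ms) == 2,
            search_window_ms[1] < search_window_ms[2])
  tt <- wave_times(w) - w$t0
  sel <- tt >= search_window_ms[1] / 1000 & tt <= search_window_ms[2] / 1000
  if (!any(sel)) stop("search window contains no samples")
  diff(range(w$samples[sel]))
}

#' CAP threshold from a level series
#'
#' The sound level at which the peak-to-peak CAP amplitude reaches a
#' criterion (10 microvolts in the study).  The amplitude-vs-level function
#' is monotonized by an isotonic fit (so single-sample noise dips cannot
#' create spurious crossings) and the criterion level is found by linear
#' interpolation between the bracketing tested levels.
#'
#' @param levels_db tested levels (dB SPL), any order.
#' @param amplitudes_uv peak-to-peak amplitudes (microvolts), same length.
#' @param criterion_uv amplitude criterion (microvolts).
#' @return threshold in dB SPL.  If no amplitude reaches the criterion,
#'   `NA` with attribute `reason = "no threshold"`; if all amplitudes exceed
#'   it, the lowest tested level with attribute `flag = "<= min level"`.
#' @export
cap_threshold <- function(levels_db, amplitudes_uv, criterion_uv = 10) {
  stopifnot(is.numeric(levels_db), is.numeric(amplitudes_uv),
            length(levels_db) == length(amplitudes_uv),
            length(levels_db) >= 2, !anyDuplicated(levels_db),
            criterion_uv > 0)
  o <- order(levels_db)
  lv <- levels_db[o]
  am <- amplitudes_uv[o]
  # monotone non-decreasing fit; exact data pass through unchanged
  am <- stats::isoreg(lv, am)$yf
  if (max(am) < criterion_uv)
    return(structure(NA_real_, reason = "no threshold"))
  i <- which(am >= criterion_uv)[1]
  if (i == 1)
    return(structure(lv[1], flag = "<= min level"))
  if (am[i] == criterion_uv) return(lv[i])
  lv[i - 1] + (lv[i] - lv[i - 1]) *
    (criterion_uv - am[i - 1]) / (am[i] - am[i - 1])
}

#' Auditory Nerve Overlapped Waveform (ANOW)
#'
#' Half the sum of the responses to the two tone-burst polarities, which
#' cancels polarity-inverting hair-cell potentials and retains the
#' low-frequency neural component.  Of the 33.3 ms response, the first 5 ms
#' and final 8.3 ms are removed and the remaining 20 ms is ramped on and off
#' with raised-cosine ramps of duration `1/f` seconds.
#'
#' @param pos,neg [evoked_waveform()] responses to the two polarities.
#' @param f_hz tone-burst frequency (Hz); must satisfy `2/f` < retained
#'   duration.  Study frequencies: 300, 480, 720, 1020 Hz.
#' @param trim_ms `c(head, tail)` removed from the two ends (ms).
#' @return the trimmed, ramped ANOW [evoked_waveform()].
#' @export
anow_waveform <- function(pos, neg, f_hz, trim_ms = c(5, 8.3)) {
  stopifnot(inherits(pos, "evoked_waveform"), inherits(neg, "evoked_waveform"),
            f_hz > 0)
  if (length(pos$samples) != length(neg$samples) || pos$fs != neg$fs)
    stop("waveforms must have equal length and sampling rate")
  fs <- pos$fs
  dur_s <- length(pos$samples) / fs
  keep_s <- dur_s - sum(trim_ms) / 1000
  if (keep_s <= 0) stop("trim exceeds record duration")
  if (2 / f_hz >= keep_s)
    stop("onset and offset ramps (1/f each) overlap the retained window")
  s <- 0.5 * (pos$samples + neg$samples)
  i0 <- round(trim_ms[1] / 1000 * fs) + 1L
  n_keep <- round(keep_s * fs)
  s <- s[i0:(i0 + n_keep - 1L)]
  n_ramp <- round(fs / f_hz)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 0.5) / n_ramp))
  env <- rep(1, n_keep)
  env[seq_len(n_ramp)] <- ramp
  env[n_keep + 1L - seq_len(n_ramp)] <- ramp
  evoked_waveform(s * env, fs, stim_freq_hz = f_hz, t0 = 0)
}

#' RMS amplitude of the ANOW steady state
#'
#' Root-mean-square of the unramped interior of an ANOW waveform.  The study
#' does not state how ANOW magnitude was quantified; this RMS measure is the
#' package's documented stand-in for level-series work.
#'
#' @param w an ANOW [evoked_waveform()] from [anow_waveform()].
#' @return RMS amplitude (microvolts).
#' @export
anow_rms <- function(w) {
  stopifnot(inherits(w, "evoked_waveform"), is.finite(w$stim_freq_hz))
  n_ramp <- round(w$fs / w$stim_freq_hz)
  core <- w$samples[(n_ramp + 1L):(length(w$samples) - n_ramp)]
  sqrt(mean(core ^ 2))
}

#' CAP stimulus cycle timing
#'
#' The CAP stimulus cycle consists of equal-duration segments (the 13.9 ms
#' tone burst plus interleaved silent periods), giving a 69.5 ms cycle and a
#' repetition rate of about 14.38 per second with the defaults.
#'
#' @param segment_ms duration of one segment (ms).
#' @param n_segments segments per cycle.
#' @return list with `cycle_ms` and `rate_hz`.
#' @export
cap_stimulus_cycle <- function(segment_ms = 13.9, n_segments = 5) {
  stopifnot(segment_ms > 0, n_segments >= 1)
  cycle <- segment_ms * n_segments
  list(cycle_ms = cycle, rate_hz = 1000 / cycle)
}
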