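#' Guinea-pig cochlear frequency-place map
#'
#' Constructs a parametric characteristic-frequency (CF) versus distance map
#' of the Greenwood form \deqn{CF(x) = A (10^{a x / L} - k)} where `x` is
#' distance from the cochlear apex in mm.  The defaults are the Greenwood
#' constants for the guinea pig; with a 0.5 mm/min perfusion-front speed they
#' imply roughly 5 minutes of perfusion time per octave of CF.
#'
#' Distances are always measured from the *apical* end, because the perfusion
#' used throughout this package runs apex to base.
#'
#' @param A_khz kHz multiplier of the map (kHz).
#' @param a_decades decades of frequency spanned by the full cochlear length.
#' @param k dimensionless integration constant; `k > 0` flattens the map near
#'   the apex so that `CF(0) = A_khz * (1 - k) > 0` requires `k < 1`.
#' @param L_mm cochlear length (mm).
#' @return An object of class `"freq_place_map"`.
#' @examples
#' m <- freq_place_map()
#' cf_from_place(0, m)      # apical CF, 0.0525 kHz
#' place_from_cf(2, m)      # ~7.2 mm from the apex
#' @export
freq_place_map <- function(A_khz = 0.35, a_decades = 2.1, k = 0.85,
                           L_mm = 18.5) {
  stopifnot(is.numeric(A_khz), A_khz > 0,
            is.numeric(a_decades), a_decades > 0,
            is.numeric(k), k < 1,
            is.numeric(L_mm), L_mm > 0)
  structure(list(A_khz = A_khz, a_decades = a_decades, k = k, L_mm = L_mm),
            class = "freq_place_map")
}

#' @export
print.freq_place_map <- function(x, ...) {
  cat("Cochlear frequency-place map: CF(x) = A (10^(a x / L) - k)\n")
  cat(sprintf("  A = %g kHz, a = %g decades, k = %g, L = %g mm\n",
              x$A_khz, x$a_decades, x$k, x$L_mm))
  cat(sprintf("  CF range: %.4g - %.4g kHz (apex to base)\n",
              cf_from_place(0, x), cf_from_place(x$L_mm, x)))
  invisible(x)
}

#' Perfusion-front model
#'
#' A constant-speed model of the neurotoxin front moving along scala tympani
#' from apex to base.  The front position at time `t` minutes after perfusion
#' start is `(t - start_offset_min) * flow_mm_per_min` mm from the apex.
#'
#' @param flow_mm_per_min front speed (mm/min); the study value is 0.5.
#' @param start_offset_min dead time before the front enters the mapped
#'   region (min).
#' @return An object of class `"perfusion_model"`.
#' @export
perfusion_model <- function(flow_mm_per_min = 0.5, start_offset_min = 0) {
  stopifnot(is.numeric(flow_mm_per_min), flow_mm_per_min > 0,
            is.numeric(start_offset_min), start_offset_min >= 0)
  structure(list(flow_mm_per_min = flow_mm_per_min,
                 start_offset_min = start_offset_min),
            class = "perfusion_model")
}

#' @export
print.perfusion_model <- function(x, ...) {
  cat(sprintf("Perfusion front: %g mm/min, start offset %g min\n",
              x$flow_mm_per_min, x$start_offset_min))
  invisible(x)
}

#' Perfusion time to cochlear place
#'
#' @param t_min time since perfusion start (min); vectorised.
#' @param model a [perfusion_model()].
#' @return distance of the front from the apex (mm).
#' @export
place_from_time <- function(t_min, model = perfusion_model()) {
  stopifnot(inherits(model, "perfusion_model"), is.numeric(t_min))
  if (any(t_min < model$start_offset_min))
    stop("t_min earlier than start_offset_min: front not yet in the cochlea")
  (t_min - model$start_offset_min) * model$flow_mm_per_min
}

#' Cochlear place to characteristic frequency
#'
#' @param x_mm distance from the apex (mm); vectorised.
#' @param map a [freq_place_map()].
#' @return CF in kHz.
#' @export
cf_from_place <- function(x_mm, map = freq_place_map()) {
  stopifnot(inherits(map, "freq_place_map"), is.numeric(x_mm))
  if (any(x_mm < 0 | x_mm > map$L_mm))
    stop("x_mm outside [0, L_mm]")
  map$A_khz * (10 ^ (map$a_decades * x_mm / map$L_mm) - map$k)
}

#' Characteristic frequency to cochlear place (analytic inverse)
#'
#' @param f_khz CF in kHz; vectorised.
#' @param map a [freq_place_map()].
#' @return distance from the apex (mm).
#' @export
place_from_cf <- function(f_khz, map = freq_place_map()) {
  stopifnot(inherits(map, "freq_place_map"), is.numeric(f_khz))
  f_min <- map$A_khz * (1 - map$k)
  if (any(f_khz < f_min * (1 - 1e-12)))
    stop(sprintf("f_khz below the apical CF %.4g kHz", f_min))
  (map$L_mm / map$a_decades) * log10(f_khz / map$A_khz + map$k)
}

#' Perfusion time to characteristic frequency
#'
#' Composition of [place_from_time()] and [cf_from_place()]: the CF of the
#' cochlear place the perfusion front has reached at time `t_min`.
#'
#' @inheritParams place_from_time
#' @inheritParams cf_from_place
#' @return CF in kHz.
#' @export
cf_from_time <- function(t_min, model = perfusion_model(),
                         map = freq_place_map()) {
  cf_from_place(place_from_time(t_min, model), map)
}

#' Characteristic frequency to perfusion time
#'
#' Time at which the perfusion front reaches the CF place of `f_khz`; the
#' inverse of [cf_from_time()].
#'
#' @inheritParams place_from_cf
#' @inheritParams place_from_time
#' @return minutes since perfusion start.
#' @export
time_from_cf <- function(f_khz, model = perfusion_model(),
                         map = freq_place_map()) {
  stopifnot(inherits(model, "perfusion_model"))
  place_from_cf(f_khz, map) / model$flow_mm_per_min + model$start_offset_min
}

#' Perfusion minutes per octave of CF
#'
#' For the exponential part of the map, one octave of CF spans
#' `L log10(2) / a` mm, so the front traverses an octave in
#' `L log10(2) / (a flow)` minutes, independent of position.  (The additive
#' constant `k` bends the map near the apex, where octaves are traversed
#' slightly faster; this is the basal/asymptotic rate.)
#'
#' @inheritParams cf_from_time
#' @return min/octave.
#' @export
minutes_per_octave <- function(model = perfusion_model(),
                               map = freq_place_map()) {
  stopifnot(inherits(model, "perfusion_model"),
            inherits(map, "freq_place_map"))
  (map$L_mm * log10(2) / map$a_decades) / model$flow_mm_per_min
}

#' Octave shift between two perfusion times
#'
#' `log2` ratio of the CFs reached at a reference and a test time.  Positive
#' values mean the test time is earlier, i.e. the test response originated
#' more apically (lower CF) than the reference.  A 50% reduction time 5 min
#' earlier than normal corresponds to roughly one octave more apical CF under
#' the default map and 0.5 mm/min flow.
#'
#' @param t_reference,t_test perfusion times (min).
#' @inheritParams cf_from_time
#' @return shift in octaves.
#' @export
octave_shift <- function(t_reference, t_test, model = perfusion_model(),
                         map = freq_place_map()) {
  log2(cf_from_time(t_reference, model, map) /
         cf_from_time(t_test, model, map))
}
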