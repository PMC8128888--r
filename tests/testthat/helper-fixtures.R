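# shared fixtures built in code

# normalized-scale logistic amplitude trajectory as a raw-uV series
logistic_series <- function(t50, slope = 1, times = seq(-10, 45, by = 1),
                            baseline_uv = 40, level_db_sl = 10, ...) {
  amp_series(times, baseline_uv / (1 + exp((times - t50) / slope)),
             level_db_sl = level_db_sl, ...)
}

# the worked 3-vs-4 ear example: one-sided exact p is 1/35
toy_table <- function() {
  t50_table(cbind(c(1, 2, 3, 8, 9, 10, 11)),
            rep(c("operated", "control"), c(3, 4)), freqs_khz = 2)
}

# a 5 + 8 ear table across the study frequencies, fixed seed
study_table <- function(seed = 42, ...) {
  simulate_t50_table(sim_config(...), seed = seed)$table
}

# independent brute-force one-sided permutation p: enumerate every subset
# of size N as pseudo-operated with raw mean differences (no shared code
# with the package's sum-based path)
brute_force_p <- function(values, group, sided = "one") {
  N <- sum(group == "operated")
  osd <- mean(values[group == "control"]) - mean(values[group == "operated"])
  idx <- utils::combn(length(values), N)
  pds <- apply(idx, 2, function(ii)
    mean(values[-ii]) - mean(values[ii]))
  if (sided == "one") mean(pds >= osd) else mean(abs(pds) >= abs(osd))
}
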