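#' Table of 50% reduction times for group testing
#'
#' Ears x frequencies matrix of 50% CAP reduction times, with an
#' operated/control label per ear.  This is the input to the permutation
#' tests; the matrix must be complete (no missing cells) for every analysis
#' frequency.  The study had N = 5 operated and M = 8 control ears at
#' 2, 4, 6, 8 and 12 kHz.
#'
#' @param t50 numeric matrix, ears in rows, frequencies in columns; or a
#'   long data frame with columns `ear_id`, `group`, `freq_khz`, `t50_min`.
#' @param group character vector of `"operated"`/`"control"`, one per row
#'   of the matrix form; ignored for the data-frame form.
#' @param freqs_khz column frequencies (kHz) for the matrix form.
#' @return An object of class `"t50_table"`.
#' @export
t50_table <- function(t50, group = NULL, freqs_khz = NULL) {
  if (is.data.frame(t50)) {
    stopifnot(all(c("ear_id", "group", "freq_khz", "t50_min") %in%
                    names(t50)))
    m <- stats::xtabs(t50_min ~ ear_id + freq_khz, data = t50)
    cnt <- stats::xtabs(~ear_id + freq_khz, data = t50)
    if (any(cnt != 1)) stop("t50 table incomplete or duplicated cells")
    gr <- t50$group[match(rownames(m), t50$ear_id)]
    mm <- matrix(as.numeric(m), nrow(m), ncol(m),
                 dimnames = list(rownames(m), colnames(m)))
    return(t50_table(mm, gr, as.numeric(colnames(m))))
  }
  stopifnot(is.matrix(t50), is.numeric(t50), !anyNA(t50))
  group <- as.character(group)
  stopifnot(all(group %in% c("operated", "control")),
            length(group) == nrow(t50),
            any(group == "operated"), any(group == "control"))
  if (is.null(freqs_khz)) freqs_khz <- as.numeric(colnames(t50))
  stopifnot(length(freqs_khz) == ncol(t50), !anyNA(freqs_khz))
  colnames(t50) <- as.character(freqs_khz)
  if (is.null(rownames(t50)))
    rownames(t50) <- sprintf("ear%02d", seq_len(nrow(t50)))
  structure(list(t50 = t50, group = group, freqs_khz = freqs_khz),
            class = "t50_table")
}

#' @export
print.t50_table <- function(x, ...) {
  cat(sprintf("50%% reduction-time table: %d operated + %d control ears, %d frequencies (kHz: %s)\n",
              sum(x$group == "operated"), sum(x$group == "control"),
              length(x$freqs_khz), paste(x$freqs_khz, collapse = ", ")))
  print(round(x$t50, 2))
  invisible(x)
}

#' @export
as.data.frame.t50_table <- function(x, ...) {
  data.frame(ear_id = rep(rownames(x$t50), times = ncol(x$t50)),
             group = rep(x$group, times = ncol(x$t50)),
             freq_khz = rep(x$freqs_khz, each = nrow(x$t50)),
             t50_min = as.numeric(x$t50))
}

freq_col <- function(table, freq) {
  j <- match(as.character(freq), colnames(table$t50))
  if (is.na(j)) stop(sprintf("frequency %s kHz not in table", freq))
  j
}

#' Observed set difference (OSD) at one frequency
#'
#' Mean control-ear 50% reduction time minus mean operated-ear 50% reduction
#' time.  Positive when the operated ears' responses were reduced earlier,
#' i.e. originated more apically than control.
#'
#' @param table a [t50_table()].
#' @param freq frequency (kHz) present in the table.
#' @return difference in minutes.
#' @export
set_difference <- function(table, freq) {
  stopifnot(inherits(table, "t50_table"))
  v <- table$t50[, freq_col(table, freq)]
  mean(v[table$group == "control"]) - mean(v[table$group == "operated"])
}

# Sums over pseudo-operated subsets turned into pseudo-differences.
# pool: pooled values; N operated, M control.  sum_op: sum over the chosen
# pseudo-operated subset(s).
pd_from_opsum <- function(sum_op, pool_sum, N, M) {
  (pool_sum - sum_op) / M - sum_op / N
}

# run expr with a locally-set RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

perm_result <- function(osd, n_perm, exceed, method, sided, seed,
                        freqs, estimator = "paper") {
  p <- if (estimator == "plus_one") (exceed + 1) / (n_perm + 1)
       else exceed / n_perm
  structure(list(osd = osd, n_perm = n_perm, exceed_count = exceed, p = p,
                 method = method, sided = sided, seed = seed,
                 freqs_khz = freqs, estimator = estimator),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  lab <- c(exact = "exact enumeration", mc_single = "Monte-Carlo",
           mc_grand1 = "grand average, independent permutations (method 1)",
           mc_grand2 = "grand average, common permutation (method 2)")
  cat(sprintf("Permutation test (%s), %s-sided\n", lab[[x$method]], x$sided))
  cat(sprintf("  frequencies: %s kHz\n", paste(x$freqs_khz, collapse = ", ")))
  cat(sprintf("  observed set difference (control - operated): %.3f min\n",
              x$osd))
  cat(sprintf("  exceedances: %d of %d permutations; p = %.4g\n",
              x$exceed_count, x$n_perm, x$p))
  invisible(x)
}

#' Exact permutation test at one frequency
#'
#' Enumerates every unique assignment of the N + M pooled ears to a
#' pseudo-operated group of size N (`choose(N + M, N)` assignments; 1287 for
#' the study's 5 + 8 ears) and counts assignments whose pseudo-difference PD
#' meets or exceeds the observed set difference OSD (one-sided), or with
#' `|PD| >= |OSD|` (two-sided).  The observed assignment is in the
#' enumeration, so p >= 1 / choose(N + M, N).
#'
#' @param table a [t50_table()].
#' @param freq frequency (kHz) to test.
#' @param sided `"one"` (control minus operated, positive tail; the study's
#'   test) or `"two"`.
#' @return a `"perm_test_result"`.
#' @export
exact_perm_test <- function(table, freq, sided = c("one", "two")) {
  stopifnot(inherits(table, "t50_table"))
  sided <- match.arg(sided)
  v <- table$t50[, freq_col(table, freq)]
  N <- sum(table$group == "operated")
  n <- length(v)
  n_comb <- choose(n, N)
  if (n_comb > 1e7) stop("enumeration too large; use mc_perm_test")
  osd <- set_difference(table, freq)
  M <- n - N
  sums <- utils::combn(v, N, sum)
  pd <- pd_from_opsum(sums, sum(v), N, M)
  exceed <- if (sided == "one") sum(pd >= osd) else sum(abs(pd) >= abs(osd))
  perm_result(osd, n_comb, exceed, "exact", sided, NA_integer_, freq)
}

# n_perm random pseudo-operated subset sums from a pooled vector
rand_op_sums <- function(pool, N, n_perm) {
  n <- length(pool)
  vapply(seq_len(n_perm), function(i) sum(pool[sample.int(n, N)]),
         numeric(1))
}

#' Monte-Carlo permutation test at one frequency
#'
#' Randomly permutes the pooled ear labels `n_perm` times, takes the first N
#' as pseudo-operated, and estimates p as the fraction of permutations with
#' PD >= OSD (ties count as exceedances).  The default estimator is the
#' plain count / n_perm; `estimator = "plus_one"` gives the
#' (count + 1) / (n_perm + 1) variant, which cannot return zero.
#'
#' @inheritParams exact_perm_test
#' @param n_perm number of random permutations (the study used 1e7).
#' @param seed integer seed; results are reproducible given the seed and do
#'   not disturb the caller's RNG state.
#' @param estimator `"paper"` (count / n_perm) or `"plus_one"`.
#' @return a `"perm_test_result"`.
#' @export
mc_perm_test <- function(table, freq, n_perm = 1e5, seed = 1,
                         sided = c("one", "two"),
                         estimator = c("paper", "plus_one")) {
  stopifnot(inherits(table, "t50_table"), n_perm >= 1)
  sided <- match.arg(sided)
  estimator <- match.arg(estimator)
  v <- table$t50[, freq_col(table, freq)]
  N <- sum(table$group == "operated")
  M <- length(v) - N
  osd <- set_difference(table, freq)
  pd <- with_seed(seed, pd_from_opsum(rand_op_sums(v, N, n_perm), sum(v),
                                      N, M))
  exceed <- if (sided == "one") sum(pd >= osd) else sum(abs(pd) >= abs(osd))
  perm_result(osd, n_perm, exceed, "mc_single", sided, seed, freq, estimator)
}

#' Grand-average multi-frequency permutation test
#'
#' Combines the per-frequency set differences by summing them and tests the
#' sum against permutations, in one of the study's two ways:
#' `method = "independent"` (method 1) draws a separate, independent
#' permutation of ear labels at each frequency in every trial;
#' `method = "common"` (method 2) applies the same permutation of ears to
#' every frequency, preserving the across-frequency correlation of ear
#' effects.  With a single frequency both reduce to [mc_perm_test()].
#'
#' For the independent method each frequency uses its own RNG stream derived
#' from the master seed by a fixed offset, so results do not depend on the
#' order in which frequencies are listed.
#'
#' @inheritParams mc_perm_test
#' @param freqs frequencies (kHz) to combine; default all in the table.
#' @param method `"independent"` (method 1) or `"common"` (method 2).
#' @return a `"perm_test_result"` with method `"mc_grand1"` or `"mc_grand2"`.
#' @export
grand_perm_test <- function(table, freqs = NULL,
                            method = c("independent", "common"),
                            n_perm = 1e5, seed = 1,
                            sided = c("one", "two"),
                            estimator = c("paper", "plus_one")) {
  stopifnot(inherits(table, "t50_table"), n_perm >= 1)
  method <- match.arg(method)
  sided <- match.arg(sided)
  estimator <- match.arg(estimator)
  if (is.null(freqs)) freqs <- table$freqs_khz
  cols <- vapply(freqs, function(f) freq_col(table, f), integer(1))
  N <- sum(table$group == "operated")
  n <- nrow(table$t50)
  M <- n - N
  osd_f <- vapply(freqs, function(f) set_difference(table, f), numeric(1))
  osd <- sum(osd_f)
  if (method == "independent") {
    pd_sum <- rep(0, n_perm)
    for (i in seq_along(cols)) {
      v <- table$t50[, cols[i]]
      pd_sum <- pd_sum + with_seed(
        seed + 1000L * i,
        pd_from_opsum(rand_op_sums(v, N, n_perm), sum(v), N, M))
    }
    pd <- pd_sum
    meth <- "mc_grand1"
  } else {
    m <- table$t50[, cols, drop = FALSE]
    colsum <- colSums(m)
    pd <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, N)
      op <- colSums(m[idx, , drop = FALSE])
      sum((colsum - op) / M - op / N)
    }, numeric(1)))
    meth <- "mc_grand2"
  }
  exceed <- if (sided == "one") sum(pd >= osd) else sum(abs(pd) >= abs(osd))
  perm_result(osd, n_perm, exceed, meth, sided, seed, freqs, estimator)
}

#' Full permutation-inference report
#'
#' Runs, for a complete reduction-time table: the exact and Monte-Carlo
#' single-frequency tests at every frequency (one- and two-sided) and both
#' grand-average combination methods, recording seeds and counts.
#'
#' @inheritParams mc_perm_test
#' @return class `"capmap_inference"`: a list with `per_freq` (data frame of
#'   per-frequency OSDs and p values) and `grand` (data frame for the two
#'   combination methods), plus the settings used.
#' @export
run_full_inference <- function(table, n_perm = 1e5, seed = 1,
                               estimator = c("paper", "plus_one")) {
  stopifnot(inherits(table, "t50_table"))
  estimator <- match.arg(estimator)
  per <- do.call(rbind, lapply(seq_along(table$freqs_khz), function(i) {
    f <- table$freqs_khz[i]
    ex1 <- exact_perm_test(table, f, "one")
    ex2 <- exact_perm_test(table, f, "two")
    mc1 <- mc_perm_test(table, f, n_perm, seed + i, "one", estimator)
    mc2 <- mc_perm_test(table, f, n_perm, seed + i, "two", estimator)
    data.frame(freq_khz = f, osd_min = ex1$osd,
               p_exact_one = ex1$p, p_exact_two = ex2$p,
               p_mc_one = mc1$p, p_mc_two = mc2$p)
  }))
  g1 <- grand_perm_test(table, method = "independent", n_perm = n_perm,
                        seed = seed, sided = "one", estimator = estimator)
  g2 <- grand_perm_test(table, method = "common", n_perm = n_perm,
                        seed = seed, sided = "one", estimator = estimator)
  grand <- data.frame(method = c("independent (1)", "common (2)"),
                      osd_sum_min = c(g1$osd, g2$osd),
                      p_one = c(g1$p, g2$p),
                      n_perm = c(g1$n_perm, g2$n_perm))
  structure(list(per_freq = per, grand = grand, n_perm = n_perm,
                 seed = seed, estimator = estimator,
                 n_operated = sum(table$group == "operated"),
                 n_control = sum(table$group == "control")),
            class = "capmap_inference")
}

#' @export
print.capmap_inference <- function(x, ...) {
  cat(sprintf("Permutation inference: %d operated vs %d control ears (n_perm = %g, seed = %d)\n",
              x$n_operated, x$n_control, x$n_perm, x$seed))
  cat("Per frequency (OSD = mean control - mean operated 50% reduction time):\n")
  print(x$per_freq, row.names = FALSE, digits = 4)
  cat("Grand average over frequencies:\n")
  print(x$grand, row.names = FALSE, digits = 4)
  invisible(x)
}
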