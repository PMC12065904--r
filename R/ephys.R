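## Whole-cell electrophysiology analysis.
##
## Conventions: currents in pA (inward negative), voltages in mV, time in ms.
## With those units a charge integral in pA*ms is directly in fC, and the
## variance-mean axes of the stationary noise analysis are in nS
## (conductance); unitary conductance is reported in pS.
##
## Model: unitary current i = gamma * (Vm - Vrev) (Ohmic unitary
## conductance), macroscopic current I = n * gamma * (Vm - Vrev) * Po, and
## for n independent binomial channels
##   sigma^2 / (I * (Vm - Vrev)) = -(1/n) * (I / (Vm - Vrev)) + gamma,
## a straight line whose intercept gives gamma and slope gives -1/n. The
## maximal open probability follows as Po_max = I_max / (n * i).

#' Construct a set of repeated current sweeps
#'
#' @param sweeps List (one element per voltage) of numeric matrices, rows =
#'   time points, columns = repeated sweeps; currents in pA, inward negative.
#' @param voltages Step potentials in mV (one per list element).
#' @param dt Sampling interval in ms.
#' @param step_start,step_end Step window in ms (within the trace).
#' @param v_rev Reversal potential in mV.
#' @return List of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, voltages, dt, step_start, step_end, v_rev) {
  if (length(sweeps) != length(voltages))
    stop("one sweep matrix per voltage is required")
  len <- unique(vapply(sweeps, nrow, integer(1)))
  if (length(len) != 1) stop("all sweeps must have equal length")
  if (dt <= 0) stop("dt must be positive")
  if (step_start < 0 || step_end > (len - 1) * dt || step_start >= step_end)
    stop("step window outside the trace")
  structure(list(sweeps = lapply(sweeps, as.matrix), voltages = voltages,
                 dt = dt, step_start = step_start, step_end = step_end,
                 v_rev = v_rev),
            class = "sweep_set")
}

#' Write / read a sweep set as CSV matrices with a JSON sidecar
#'
#' One headerless CSV per voltage (rows = time points, columns = repeated
#' sweeps) plus `sweeps.json` carrying `dt`, the step window, `v_rev`, the
#' voltages and the file names.
#'
#' @param s A [sweep_set()].
#' @param dir Directory to write into (created if needed).
#' @return `dir` (write) or a [sweep_set()] (read).
#' @export
write_sweep_set <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sweeps_%03d.csv", seq_along(s$voltages))
  for (i in seq_along(files))
    write.table(s$sweeps[[i]], file.path(dir, files[i]), sep = ",",
                row.names = FALSE, col.names = FALSE)
  meta <- list(dt = s$dt, step_start = s$step_start, step_end = s$step_end,
               v_rev = s$v_rev, voltages = s$voltages, files = files)
  jsonlite::write_json(meta, file.path(dir, "sweeps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sweeps.json"),
                              simplifyVector = TRUE)
  sweeps <- lapply(meta$files, function(f)
    as.matrix(read.csv(file.path(dir, f), header = FALSE)))
  sweep_set(sweeps, voltages = meta$voltages, dt = meta$dt,
            step_start = meta$step_start, step_end = meta$step_end,
            v_rev = meta$v_rev)
}

step_indices <- function(s) {
  t <- (seq_len(nrow(s$sweeps[[1]])) - 1) * s$dt
  which(t >= s$step_start & t <= s$step_end)
}

#' Per-voltage peak current
#'
#' Peak (most-negative, inward) current within the step window after 2-point
#' smoothing of the sweep-averaged trace.
#'
#' @param s A [sweep_set()].
#' @return data.frame with `voltage` (mV) and `peak` (pA).
#' @export
peak_currents <- function(s) {
  idx <- step_indices(s)
  peaks <- vapply(s$sweeps, function(m) {
    avg <- rowMeans(m)[idx]
    min(roll_mean(avg, 2))
  }, numeric(1))
  data.frame(voltage = s$voltages, peak = peaks)
}

#' Boltzmann activation curve
#'
#' `P_open(V) = 1 / (1 + exp(-(Vm - V_half) / k))`.
#'
#' @param v Membrane potential(s), mV.
#' @param v_half Half-activation voltage, mV.
#' @param k Slope factor, mV.
#' @return Open probability in `[0, 1]`.
#' @export
boltzmann <- function(v, v_half, k) 1 / (1 + exp(-(v - v_half) / k))

#' Fit a Boltzmann function to normalized activation data
#'
#' @param v Voltages (mV).
#' @param p Normalized responses (e.g. I/Imax).
#' @return List of class `boltzmann_fit`: `v_half`, `k`, `residual_norm`.
#' @export
boltzmann_fit <- function(v, p) {
  if (length(v) < 4) stop("at least 4 voltages are required")
  v50 <- v[which.min(abs(p - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ 1 / (1 + exp(-(v - v_half) / k)),
                      start = list(v_half = v50, k = 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Boltzmann fit failed to converge: ",
                             conditionMessage(e),
                             " (starting values v_half=", v50, ", k=5)"))
  cf <- coef(fit)
  structure(list(v_half = unname(cf["v_half"]), k = unname(cf["k"]),
                 residual_norm = sqrt(sum(resid(fit)^2))),
            class = "boltzmann_fit")
}

#' Voltage dependence of activation from a sweep set
#'
#' Peak currents are normalized to the maximal magnitude (I/Imax) and fitted
#' with the Boltzmann function.
#'
#' @param s A [sweep_set()].
#' @return A [boltzmann_fit()] result with the normalized data attached as
#'   attribute `data`.
#' @export
activation_fit <- function(s) {
  pk <- peak_currents(s)
  imax <- pk$peak[which.max(abs(pk$peak))]
  p <- pk$peak / imax
  fit <- boltzmann_fit(pk$voltage, p)
  attr(fit, "data") <- data.frame(voltage = pk$voltage, i_norm = p)
  fit
}

#' Construct a gating-current record
#'
#' @param trace Current trace in pA (the On gating transient, recorded at the
#'   reversal potential so no ionic current flows).
#' @param dt Sampling interval, ms.
#' @param baseline_start,baseline_end Pre-step baseline window, ms.
#' @param step_start,step_end Voltage-step (integration) window, ms.
#' @return List of class `gating_record`.
#' @export
gating_record <- function(trace, dt, baseline_start, baseline_end,
                          step_start, step_end) {
  if (baseline_end > step_start)
    stop("baseline window must precede the step")
  structure(list(trace = trace, dt = dt, baseline_start = baseline_start,
                 baseline_end = baseline_end, step_start = step_start,
                 step_end = step_end),
            class = "gating_record")
}

#' Total gating charge from the On transient
#'
#' Subtracts the mean of the pre-step baseline window and integrates the
#' transient over the step window (trapezoidal rule); pA * ms = fC.
#'
#' @param g A [gating_record()].
#' @return Charge in fC.
#' @export
qon <- function(g) {
  t <- (seq_along(g$trace) - 1) * g$dt
  bl <- g$trace[t >= g$baseline_start & t <= g$baseline_end]
  if (length(bl) == 0) stop("empty baseline window")
  on <- t >= g$step_start & t <= g$step_end
  pracma::trapz(t[on], g$trace[on] - mean(bl))
}

#' Variance-mean points for stationary noise analysis
#'
#' Within the stationary window (final 50% of the step by default), the mean
#' and unbiased variance across repeated sweeps are computed per time point
#' and averaged over the window.
#'
#' @param s A [sweep_set()].
#' @param window Optional `c(start, end)` in ms overriding the default
#'   stationary window.
#' @param drift_correct If `TRUE`, remove a linear trend of the per-sweep
#'   window mean across sweep index before computing the variance (slow
#'   rundown correction); off by default.
#' @return data.frame with `voltage` (mV), `mean_i` (pA), `var_i` (pA^2) and
#'   `n_sweeps`.
#' @export
noise_points <- function(s, window = NULL, drift_correct = FALSE) {
  if (is.null(window))
    window <- c(s$step_start + (s$step_end - s$step_start) / 2, s$step_end)
  t <- (seq_len(nrow(s$sweeps[[1]])) - 1) * s$dt
  idx <- which(t >= window[1] & t <= window[2])
  rows <- lapply(seq_along(s$voltages), function(i) {
    m <- s$sweeps[[i]][idx, , drop = FALSE]
    if (ncol(m) < 2) stop("at least 2 sweeps per voltage are required")
    if (drift_correct) {
      sm <- colMeans(m)
      trend <- predict(lm(sm ~ seq_along(sm)))
      m <- sweep(m, 2, trend - mean(sm), "-")
    }
    data.frame(voltage = s$voltages[i], mean_i = mean(rowMeans(m)),
               var_i = mean(apply(m, 1, var)), n_sweeps = ncol(m))
  })
  do.call(rbind, rows)
}

#' Stationary noise analysis: channel number and unitary conductance
#'
#' Fits the linear variance-mean relationship
#' `sigma^2/(I*(Vm-Vrev)) = -(1/n) * I/(Vm-Vrev) + gamma`. The intercept is
#' the unitary conductance and the (negative) slope the reciprocal channel
#' count; the maximal open probability follows from
#' `Po_max = I_max / (n * i)` with `i = gamma * (V - Vrev)` at the voltage of
#' the largest-magnitude mean current.
#'
#' @param points Variance-mean table from [noise_points()].
#' @param v_rev Reversal potential, mV.
#' @return List of class `noise_analysis_result`: `n_channels`, `gamma_ps`,
#'   `po_max`, `i_max_pa`, `unitary_i_pa`, `slope`, `intercept`, `points`
#'   (with the fitted x/y columns), `fit` (the underlying `lm`).
#' @export
noise_fit <- function(points, v_rev) {
  if (nrow(points) < 3) stop("at least 3 voltages are required")
  if (any(points$voltage == v_rev))
    stop("Vm equals Vrev for some point; driving force vanishes")
  df <- points$voltage - v_rev
  x <- points$mean_i / df                       # nS
  y <- points$var_i / (points$mean_i * df)      # nS
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= 0)
    stop("channel count unresolvable: non-negative variance-mean slope")
  n <- -1 / slope
  gamma_ns <- intercept
  imax_idx <- which.max(abs(points$mean_i))
  i_max <- points$mean_i[imax_idx]
  i_unit <- gamma_ns * df[imax_idx]             # pA
  po_max <- i_max / (n * i_unit)
  pts <- points; pts$x <- x; pts$y <- y
  structure(list(n_channels = n, gamma_ps = 1000 * gamma_ns,
                 po_max = po_max, i_max_pa = i_max, unitary_i_pa = i_unit,
                 slope = slope, intercept = intercept, points = pts,
                 fit = fit),
            class = "noise_analysis_result")
}

#' @export
print.noise_analysis_result <- function(x, ...) {
  cat(sprintf("Stationary noise analysis: n = %.0f channels, gamma = %.2f pS, Po_max = %.3f\n",
              x$n_channels, x$gamma_ps, x$po_max))
  invisible(x)
}

#' Bootstrap t-test between two groups of per-cell estimates
#'
#' Resamples each group with replacement, forming the bootstrap distribution
#' of each group mean and of their difference. The two-sided p-value is
#' `2 * min(P(diff <= 0), P(diff >= 0))` with a `+1/(n_boot+1)` continuity
#' correction; group summaries are the mean and SD of the bootstrap
#' distributions.
#'
#' @param group_a,group_b Numeric vectors (>= 3 values each), one value per
#'   cell.
#' @param n_boot Number of bootstrap replicates (default 500,000).
#' @param seed Integer seed.
#' @return List of class `bootstrap_result`: `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `mean_diff`, `sd_diff`, `p_value`, `n_boot`.
#' @export
bootstrap_ttest <- function(group_a, group_b, n_boot = 500000, seed = 1) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("both groups need at least 3 values")
  if (var(group_a) == 0 && var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    return(structure(list(mean_a = mean(group_a), sd_a = 0,
                          mean_b = mean(group_b), sd_b = 0, mean_diff = 0,
                          sd_diff = 0, p_value = 1, n_boot = n_boot),
                     class = "bootstrap_result"))
  }
  with_local_seed(seed, {
    boot_mean <- function(x) {
      m <- matrix(sample(x, length(x) * n_boot, replace = TRUE),
                  nrow = n_boot)
      rowMeans(m)
    }
    ba <- boot_mean(group_a)
    bb <- boot_mean(group_b)
    d <- ba - bb
    p <- 2 * min((sum(d <= 0) + 1) / (n_boot + 1),
                 (sum(d >= 0) + 1) / (n_boot + 1))
    structure(list(mean_a = mean(ba), sd_a = sd(ba), mean_b = mean(bb),
                   sd_b = sd(bb), mean_diff = mean(d), sd_diff = sd(d),
                   p_value = min(p, 1), n_boot = n_boot),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (n=%d): A = %.4g +/- %.3g, B = %.4g +/- %.3g, diff = %.4g, p = %.4g\n",
              x$n_boot, x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$mean_diff,
              x$p_value))
  invisible(x)
}
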