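## Thermal stability from intrinsic fluorescence and F-actin cosedimentation
## statistics.
##
## Unfolding is tracked by the spectral center of mass (CM), the
## intensity-weighted mean emission wavelength, fitted with a two-state
## transition model with linearly sloping native and denatured baselines.

#' Spectral center of mass
#'
#' `CM = sum(F * lambda) / sum(F)` over an emission spectrum.
#'
#' @param wavelength Wavelengths, nm (strictly increasing).
#' @param intensity Fluorescence intensities (>= 0, not all zero).
#' @return Center of mass in nm.
#' @export
center_of_mass <- function(wavelength, intensity) {
  if (any(diff(wavelength) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(intensity < 0)) stop("negative intensities")
  tot <- sum(intensity)
  if (tot <= 0) stop("all-zero spectrum")
  sum(intensity * wavelength) / tot
}

#' Center-of-mass series from a long spectra table
#'
#' @param spectra data.frame with columns `temperature`, `wavelength`,
#'   `intensity`.
#' @return data.frame with `temperature` (degC) and `cm` (nm).
#' @export
cm_series <- function(spectra) {
  out <- do.call(rbind, lapply(split(spectra, spectra$temperature),
                               function(g) {
    g <- g[order(g$wavelength), ]
    data.frame(temperature = g$temperature[1],
               cm = center_of_mass(g$wavelength, g$intensity))
  }))
  out <- out[order(out$temperature), ]
  rownames(out) <- NULL
  out
}

#' Two-state unfolding model for the spectral center of mass
#'
#' `y = (a_n + b_n T) / (1 + exp(4 Tm (T - Tm) / (T dT))) +
#'      (a_d + b_d T) / (1 + exp(4 Tm (Tm - T) / (T dT)))`
#' with `T` and `Tm` in the working temperature unit (Kelvin by default; see
#' [melt_fit()]).
#'
#' @param t_u Temperature in the working unit.
#' @param tm_u Transition midpoint in the working unit.
#' @param delta_t Transition width.
#' @param alpha_n,beta_n,alpha_d,beta_d Baseline intercepts/slopes of the
#'   native and denatured states.
#' @return Modelled CM.
#' @export
melt_model <- function(t_u, tm_u, delta_t, alpha_n, beta_n, alpha_d, beta_d) {
  en <- exp(4 * tm_u * (t_u - tm_u) / (t_u * delta_t))
  ed <- exp(4 * tm_u * (tm_u - t_u) / (t_u * delta_t))
  (alpha_n + beta_n * t_u) / (1 + en) + (alpha_d + beta_d * t_u) / (1 + ed)
}

#' Fit the two-state unfolding transition
#'
#' Nonlinear least squares of the two-state model to a temperature/CM series.
#' Initialization: `Tm` at the maximum |dCM/dT|, baselines from linear fits
#' of the terminal quarters of the scan. By default the temperatures inside
#' the transition exponent are taken in Kelvin (the dimensionally consistent
#' reading); `kelvin = FALSE` uses Celsius throughout, exactly as the model
#' is usually printed.
#'
#' @param temperature Temperatures in degC (>= 8 points spanning both
#'   baselines).
#' @param cm Spectral center of mass, nm.
#' @param kelvin Work in Kelvin inside the model (default `TRUE`).
#' @return List of class `melt_fit`: `t_m` (degC), `delta_t`, baselines
#'   `alpha_n`, `beta_n`, `alpha_d`, `beta_d` (in the working unit),
#'   `residual_norm`, `kelvin`.
#' @export
melt_fit <- function(temperature, cm, kelvin = TRUE) {
  if (length(temperature) < 8) stop("at least 8 temperatures are required")
  off <- if (kelvin) 273.15 else 0
  tu <- temperature + off
  ## initial guesses
  dcm <- diff(cm) / diff(tu)
  tm0 <- tu[which.max(abs(dcm))]
  q <- max(3, floor(length(tu) / 4))
  nfit <- lm(cm[seq_len(q)] ~ tu[seq_len(q)])
  didx <- seq(length(tu) - q + 1, length(tu))
  dfit <- lm(cm[didx] ~ tu[didx])
  start <- list(tm_u = tm0, delta_t = 5,
                alpha_n = unname(coef(nfit)[1]), beta_n = unname(coef(nfit)[2]),
                alpha_d = unname(coef(dfit)[1]), beta_d = unname(coef(dfit)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cm ~ melt_model(tu, tm_u, delta_t, alpha_n, beta_n, alpha_d, beta_d),
      start = start,
      lower = c(min(tu), 1e-3, -Inf, -Inf, -Inf, -Inf),
      upper = c(max(tu), Inf, Inf, Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("melt fit failed to converge: ", conditionMessage(e),
           "; initial guesses were ",
           paste(names(start), signif(unlist(start), 4), sep = "=",
                 collapse = ", ")))
  cf <- as.list(coef(fit))
  structure(list(t_m = cf$tm_u - off, delta_t = cf$delta_t,
                 alpha_n = cf$alpha_n, beta_n = cf$beta_n,
                 alpha_d = cf$alpha_d, beta_d = cf$beta_d,
                 residual_norm = sqrt(sum(resid(fit)^2)), kelvin = kelvin),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state unfolding: Tm = %.2f degC, dT = %.2f\n",
              x$t_m, x$delta_t))
  invisible(x)
}

#' Bound fractions from a cosedimentation lanes table
#'
#' Per replicate, the bound fraction is `pellet / (supernatant + pellet)`.
#' Conditions are summarized (mean, SD, n), compared pairwise with Welch
#' two-tailed t-tests and, when the condition labels are numeric (e.g. a
#' NaCl series), a monotonic-trend report (Kendall rank correlation of
#' fraction against condition) is added.
#'
#' @param lanes data.frame with columns `condition`, `replicate`,
#'   `supernatant`, `pellet` (background-corrected densitometry units >= 0).
#' @return List with `fractions`, `summary`, `tests` and `trend` (or `NULL`).
#' @export
bound_fraction <- function(lanes) {
  need <- c("condition", "replicate", "supernatant", "pellet")
  missing <- setdiff(need, names(lanes))
  if (length(missing) > 0)
    stop("lanes table lacks column(s): ", paste(missing, collapse = ", "))
  tot <- lanes$supernatant + lanes$pellet
  bad <- which(tot <= 0)
  if (length(bad) > 0)
    stop("supernatant + pellet is zero for lane(s): ",
         paste(bad, collapse = ", "))
  if (any(lanes$supernatant < 0 | lanes$pellet < 0))
    stop("negative band intensities")
  fr <- data.frame(condition = lanes$condition, replicate = lanes$replicate,
                   fraction = lanes$pellet / tot, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(fr, fr$condition), function(g)
    data.frame(condition = g$condition[1], mean = mean(g$fraction),
               sd = sd(g$fraction), n = nrow(g), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  conds <- unique(fr$condition)
  tests <- NULL
  if (length(conds) > 1) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(p) {
      a <- fr$fraction[fr$condition == p[1]]
      b <- fr$fraction[fr$condition == p[2]]
      pv <- if (length(a) > 1 && length(b) > 1)
        t.test(a, b)$p.value else NA_real_
      data.frame(condition_a = p[1], condition_b = p[2], p_value = pv,
                 stringsAsFactors = FALSE)
    }))
  }
  trend <- NULL
  num <- suppressWarnings(as.numeric(fr$condition))
  if (!anyNA(num) && length(unique(num)) > 2) {
    ct <- suppressWarnings(stats::cor.test(num, fr$fraction,
                                           method = "kendall"))
    trend <- list(tau = unname(ct$estimate), p_value = ct$p.value)
  }
  list(fractions = fr, summary = summ, tests = tests, trend = trend)
}
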