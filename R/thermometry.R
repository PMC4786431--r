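#' Fit an Arrhenius resistance-temperature calibration
#'
#' The electrical resistance of a saline-filled glass microelectrode falls
#' with temperature following an Arrhenius law, so the reciprocal of the
#' absolute temperature is linear in the log of the resistance:
#' 1/T_K = a + b ln(R). Fitting this line to calibration pairs yields an
#' R-T transformation that converts resistance readings at the laser focus
#' into temperatures. Natural log is used; a change of log base is absorbed
#' into `b`, so the fit is base-invariant. Temperatures are kelvin
#' internally and Celsius at all interfaces.
#'
#' @param pairs data frame with columns `resistance` (MOhm) and
#'   `temperature` (deg C), or two numeric vectors via `resistance=` /
#'   `temperature=`.
#' @param resistance,temperature alternative vector interface.
#' @return an object of class `arrhenius_fit` with coefficients `a` (1/K)
#'   and `b` (1/K per ln MOhm), the fitted domain, and the residual s.d.
#'   of 1/T_K.
#' @seealso [resistance_to_temperature()], [simulate_calibration_data()]
#' @export
fit_arrhenius <- function(pairs = NULL, resistance = NULL,
                          temperature = NULL) {
  if (!is.null(pairs)) {
    stopifnot(is.data.frame(pairs),
              all(c("resistance", "temperature") %in% names(pairs)))
    resistance <- pairs$resistance
    temperature <- pairs$temperature
  }
  if (length(resistance) < 2L) stop("need at least 2 calibration pairs")
  if (any(resistance <= 0)) stop("resistances must be positive")
  if (diff(range(resistance)) < 1e-12)
    stop("degenerate calibration: constant resistance")
  inv_t <- 1 / (temperature + 273.15)
  ln_r <- log(resistance)
  fit <- stats::lm(inv_t ~ ln_r)
  res_sd <- if (length(resistance) > 2L) stats::sigma(fit) else 0
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 fit_domain = range(resistance), residual_sd = res_sd,
                 n = length(resistance), lm = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("<arrhenius_fit> 1/T_K = a + b ln(R)\n")
  cat(sprintf("  a = %.6g 1/K, b = %.6g 1/K per ln(MOhm)  (n = %d)\n",
              x$a, x$b, x$n))
  cat(sprintf("  domain: %.2f - %.2f MOhm, residual sd(1/T_K) = %.3g\n",
              x$fit_domain[1], x$fit_domain[2], x$residual_sd))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.arrhenius_fit <- function(object, resistance, ...)
  resistance_to_temperature(resistance, object)

#' @export
plot.arrhenius_fit <- function(x, y, ...) {
  d <- x$lm$model
  plot(d$ln_r, d$inv_t, xlab = "ln R (MOhm)", ylab = "1/T (1/K)", ...)
  graphics::abline(x$a, x$b, col = "red")
  invisible(x)
}

#' Convert electrode resistance to temperature
#'
#' Applies the fitted Arrhenius transformation T = 1/(a + b ln R) - 273.15.
#' Values outside the calibration domain are extrapolated with a warning.
#'
#' @param resistance resistance values (MOhm).
#' @param model an [fit_arrhenius()] result.
#' @return temperatures (deg C).
#' @export
resistance_to_temperature <- function(resistance, model) {
  stopifnot(inherits(model, "arrhenius_fit"))
  if (any(resistance <= 0)) stop("resistances must be positive")
  if (any(resistance < model$fit_domain[1] - 1e-9 |
            resistance > model$fit_domain[2] + 1e-9))
    warning("resistance outside the calibration domain; extrapolating")
  inv_t <- model$a + model$b * log(resistance)
  if (any(inv_t <= 0))
    stop("transformation undefined: a + b ln(R) <= 0")
  1 / inv_t - 273.15
}

#' Linear IR-laser power-to-temperature model
#'
#' At the laser focus the steady temperature is directly proportional to
#' the laser output power: T = ambient + slope * P. The calibrated slope is
#' 0.6 deg C per mW above a 25 deg C ambient, so a 30 mW output heats the
#' focus to about 43 deg C.
#'
#' @param ambient ambient temperature (deg C).
#' @param slope heating slope (deg C per mW of laser output).
#' @return an object of class `power_model`.
#' @export
power_model <- function(ambient = 25, slope = 0.6) {
  if (slope <= 0) stop("`slope` must be positive")
  structure(list(ambient = ambient, slope = slope), class = "power_model")
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf("<power_model> T = %.1f + %.2f * P (deg C, P in mW)\n",
              x$ambient, x$slope))
  invisible(x)
}

#' @rdname power_model
#' @param P laser output power (mW), non-negative.
#' @param model a [power_model()].
#' @return `power_to_temperature()`: focal temperature (deg C).
#' @export
power_to_temperature <- function(P, model = power_model()) {
  stopifnot(inherits(model, "power_model"))
  if (any(P < 0)) stop("power must be non-negative")
  model$ambient + model$slope * P
}

#' Simulate electrode-resistance calibration data
#'
#' Draws (resistance, temperature) calibration pairs satisfying the
#' Arrhenius relation 1/T_K = a + b ln(R) with Gaussian noise added on the
#' 1/T_K scale. The default coefficients describe an electrode of about
#' 7.5 MOhm at 25 deg C, and the default resistance range spans the
#' 20-55 deg C temperatures of focal heating experiments.
#'
#' @param a intercept (1/K).
#' @param b slope (1/K per ln MOhm).
#' @param n number of pairs, >= 2.
#' @param noise_sd noise s.d. on 1/T_K.
#' @param r_range resistance range sampled (MOhm).
#' @param seed integer seed.
#' @return data frame with columns `resistance` and `temperature` (deg C).
#' @export
simulate_calibration_data <- function(a = 2.306e-3, b = 5.2e-4, n = 20,
                                      noise_sd = 0, r_range = c(4.2, 8.3),
                                      seed = 1L) {
  if (b == 0) stop("`b` must be nonzero")
  if (n < 2L) stop("need n >= 2")
  set.seed(seed)
  r <- exp(seq(log(r_range[1]), log(r_range[2]), length.out = n))
  inv_t <- a + b * log(r) + stats::rnorm(n, sd = noise_sd)
  t_c <- 1 / inv_t - 273.15
  if (any(t_c < 20 | t_c > 55))
    warning("some simulated temperatures fall outside 20-55 deg C")
  data.frame(resistance = r, temperature = t_c)
}
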