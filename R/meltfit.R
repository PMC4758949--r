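# Thermal-shift melt curves: four-parameter sigmoid fit for the melting
# temperature.

#' Four-parameter thermal unfolding sigmoid
#'
#' y = LL + (UL - LL) / (1 + exp((Tm - T) / a)). LL and UL are the lower
#' and upper fluorescence plateaus, a the transition slope (degrees C) and
#' Tm the midpoint: at T = Tm the signal is (LL + UL)/2, and y -> UL as
#' T -> infinity (the unfolded, dye-bound state).
#'
#' @param T temperature (degrees C).
#' @param LL,UL lower/upper plateaus (signal units).
#' @param a transition slope (degrees C).
#' @param Tm melting temperature (degrees C).
#' @return signal values.
#' @export
melt_sigmoid <- function(T, LL, UL, a, Tm) {
  LL + (UL - LL) / (1 + exp((Tm - T) / a))
}

#' Fit the four-parameter melt sigmoid to a thermal-shift curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with starts taken from the
#' data: LL/UL from the signal extremes, Tm from the steepest-slope
#' temperature, a from a tenth of the temperature span. Flat traces (no
#' detectable transition) are rejected.
#'
#' @param curve data.frame with temperature_C (strictly increasing, >= 8
#'   points) and signal.
#' @return object of class `melt_fit`: LL, UL, a, Tm, residual norm and the
#'   fitted model.
#' @export
fit_melt_curve <- function(curve) {
  stopifnot(all(c("temperature_C", "signal") %in% names(curve)))
  T <- curve$temperature_C; y <- curve$signal
  if (length(T) < 8) stop("melt curve needs at least 8 points")
  if (any(diff(T) <= 0)) stop("temperatures must be strictly increasing")
  span <- diff(range(y))
  if (span == 0 || !any(abs(diff(y)) > 1e-3 * max(abs(y), 1)))
    stop("no transition detectable: melt signal is flat")
  # initialise from a lightly smoothed trace: Tm at the steepest slope,
  # a from the sigmoid's midpoint slope (UL - LL) / (4 * max |dy/dT|)
  k <- min(5, length(y))
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  slope <- diff(as.vector(ys)) / diff(T)
  imax <- which.max(abs(slope))
  Tm0 <- mean(T[imax + 0:1])
  a0 <- span / (4 * max(abs(slope)))
  a0 <- min(max(a0, 0.1), diff(range(T)) / 4)
  starts <- list(
    list(LL = min(y), UL = max(y), a = a0, Tm = Tm0),
    list(LL = min(y), UL = max(y), a = diff(range(T)) / 10,
         Tm = T[which.max(abs(diff(y) / diff(T)))]))
  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(signal ~ melt_sigmoid(temperature_C, LL, UL, a, Tm),
                        data = data.frame(temperature_C = T, signal = y),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("melt fit did not converge (best start: Tm=", signif(Tm0, 4),
         ", a=", signif(a0, 3), ")", call. = FALSE)
  p <- as.list(coef(fit))
  if (p$a < 0) {  # mirrored solution; renormalise to UL > LL
    p <- list(LL = p$UL, UL = p$LL, a = -p$a, Tm = p$Tm)
  }
  structure(list(LL = p$LL, UL = p$UL, a = p$a, Tm = p$Tm,
                 residual_norm = sqrt(sum(resid(fit)^2)),
                 fit = fit),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: Tm = %.2f C, a = %.3f C, LL = %.3g, UL = %.3g, |r| = %.3g\n",
              x$Tm, x$a, x$LL, x$UL, x$residual_norm))
  invisible(x)
}
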