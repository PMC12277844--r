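#' Naka-Rushton intensity-response function
#'
#' Saturating hyperbolic curve
#' `R(I) = Rmin + (Rmax - Rmin) * I^n / (I^n + I50^n)` relating peak firing
#' rate to flash intensity. At `I = I50` the predicted response is exactly
#' `(Rmin + Rmax) / 2`.
#'
#' @param I intensity, R*/rod/s (vectorized).
#' @param Rmin,Rmax lowest and largest peak firing rates, spikes/s.
#' @param I50 half-saturation intensity, R*/rod/s.
#' @param n Hill exponent (dimensionless, > 0).
#' @return predicted peak firing rates, spikes/s.
#' @examples
#' naka_rushton(10, Rmin = 0, Rmax = 20, I50 = 10, n = 1) # == 10
#' @export
naka_rushton <- function(I, Rmin, Rmax, I50, n) {
  # compute on the log-intensity scale for numerical range safety
  r <- exp(n * (log(I) - log(I50)))
  Rmin + (Rmax - Rmin) * r / (r + 1)
}

ir_sse <- function(intensity, peak, Rmin, Rmax, I50, n) {
  sum((peak - naka_rushton(intensity, Rmin, Rmax, I50, n))^2)
}

#' Fit the Naka-Rushton intensity-response curve
#'
#' `Rmin` and `Rmax` are fixed to the lowest and largest observed corrected
#' peak rates; `I50` and `n` are then chosen to minimize the squared error
#' between observed and predicted peaks. The minimization runs a log-spaced
#' grid search over `I50` in `[min(I)/10, max(I)*10]` and `n` in
#' `[0.1, 10]`, followed by Nelder-Mead refinement from the best grid node
#' (on log-parameters, so positivity is preserved).
#'
#' @param points data frame with columns `intensity` (R*/rod/s) and
#'   `corrected_peak` (spikes/s, 0 for subthreshold responses), or an object
#'   with those columns. At least 3 points with at least 2 distinct peaks.
#' @param grid_size number of grid nodes per parameter.
#' @param n_range range of the Hill exponent searched.
#' @return object of class `ir_fit`: list with `Rmin`, `Rmax`, `I50`, `n`,
#'   `sse` and `degenerate` (TRUE when all peaks are equal, in which case
#'   `I50` and `n` are `NA` and the fit is the constant curve).
#' @examples
#' I <- c(0.83, 1.49, 4.32, 15.32, 49.38, 95.23)
#' pts <- data.frame(intensity = I,
#'                   corrected_peak = naka_rushton(I, 0, 20, 10, 1))
#' fit_intensity_response(pts)
#' @export
fit_intensity_response <- function(points, grid_size = 60,
                                   n_range = c(0.1, 10)) {
  points <- as.data.frame(points)
  if (!all(c("intensity", "corrected_peak") %in% names(points)))
    stopf("'points' needs columns 'intensity' and 'corrected_peak'")
  I <- points$intensity; peak <- points$corrected_peak
  if (length(I) < 3L)
    stopf("at least 3 intensity-response points are required")
  if (any(I <= 0)) stopf("intensities must be positive")
  if (any(peak < 0)) stopf("corrected peaks must be >= 0")
  Rmin <- min(peak); Rmax <- max(peak)
  if (length(unique(peak)) < 2L) {
    return(structure(list(Rmin = Rmin, Rmax = Rmax, I50 = NA_real_,
                          n = NA_real_, sse = 0, degenerate = TRUE),
                     class = "ir_fit"))
  }
  i50_grid <- exp(seq(log(min(I) / 10), log(max(I) * 10),
                      length.out = grid_size))
  n_grid <- exp(seq(log(n_range[1]), log(n_range[2]), length.out = grid_size))
  nodes <- expand.grid(I50 = i50_grid, n = n_grid)
  # I^n / (I^n + I50^n) = logistic(n * (log I - log I50)): one matrix pass
  z <- sweep(outer(log(I), log(nodes$I50), "-"), 2L, nodes$n, "*")
  resid <- peak - (Rmin + (Rmax - Rmin) * stats::plogis(z))
  sse_grid <- colSums(resid^2)
  best <- which.min(sse_grid)
  start <- log(c(nodes$I50[best], nodes$n[best]))
  obj <- function(par) ir_sse(I, peak, Rmin, Rmax, exp(par[1]), exp(par[2]))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  structure(list(Rmin = Rmin, Rmax = Rmax,
                 I50 = exp(opt$par[1]), n = exp(opt$par[2]),
                 sse = opt$value, degenerate = FALSE),
            class = "ir_fit")
}

#' @export
print.ir_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("Naka-Rushton fit (degenerate): constant %g spikes/s\n", x$Rmin))
  } else {
    cat(sprintf(
      "Naka-Rushton fit: Rmin = %.3g, Rmax = %.3g spikes/s, I50 = %.4g R*/rod/s, n = %.3g (sse %.3g)\n",
      x$Rmin, x$Rmax, x$I50, x$n, x$sse))
  }
  invisible(x)
}

#' Predicted peak rates from a fitted intensity-response curve
#'
#' @param object an `ir_fit`.
#' @param intensity intensities to predict at, R*/rod/s.
#' @param ... unused.
#' @return predicted corrected peak firing rates, spikes/s.
#' @export
predict.ir_fit <- function(object, intensity, ...) {
  if (isTRUE(object$degenerate))
    return(rep(object$Rmin, length(intensity)))
  naka_rushton(intensity, object$Rmin, object$Rmax, object$I50, object$n)
}
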