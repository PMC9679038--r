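#' Standard-additions quantification
#'
#' Recovers the initial analyte amount from a standard-additions series:
#' known increments `a_k` of the analyte are spiked into the sample and
#' the instrument response is regressed on them, `I = s (m0 + a)`. The
#' initial amount is the ratio intercept/slope, with a standard error
#' propagated to first order (delta method) from the regression covariance
#' of intercept and slope. The regression is ordinary (unweighted) least
#' squares.
#'
#' @param added_umol amounts added, umol: at least 3 values, monotone
#'   non-decreasing. By convention the first point is the unspiked sample
#'   (added amount 0); shifting all additions by a constant shifts the
#'   estimate by its negative.
#' @param intensity instrument response (arbitrary units), same length.
#' @param bootstrap_se also compute a residual-bootstrap standard error
#'   (default `FALSE`).
#' @param n_boot bootstrap replicates when `bootstrap_se = TRUE`.
#'
#' @return An object of class `standard_additions_fit`: a list with
#'   `m0_umol`, `se_umol`, `slope`, `intercept`, the `lm` fit, and
#'   optionally `se_boot_umol`.
#' @examples
#' standard_additions(c(0, 0.5, 1.0), c(10, 12, 14)) # m0 = 2.5 umol
#' @export
standard_additions <- function(added_umol, intensity,
                               bootstrap_se = FALSE, n_boot = 999) {
  stopifnot(is.numeric(added_umol), is.numeric(intensity))
  if (length(added_umol) != length(intensity))
    stop("added amounts and intensities must have equal length")
  if (length(added_umol) < 3)
    stop("at least 3 points are required")
  if (is.unsorted(added_umol))
    stop("added amounts must be monotone non-decreasing")
  fit <- stats::lm(intensity ~ added_umol)
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  if (!is.finite(b1) || b1 <= 0)
    stop("regression slope must be positive: signal must increase with additions")
  m0 <- b0 / b1
  # vcov warns on exactly collinear (noise-free) input; the zero SE is correct
  V <- suppressWarnings(stats::vcov(fit))
  grad <- c(1 / b1, -b0 / b1^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  out <- list(m0_umol = m0, se_umol = se, slope = b1, intercept = b0, fit = fit)
  if (bootstrap_se) {
    res <- stats::residuals(fit)
    fv <- stats::fitted(fit)
    boots <- replicate(n_boot, {
      ystar <- fv + sample(res, replace = TRUE)
      cf <- stats::coef(stats::lm(ystar ~ added_umol))
      if (cf[2] > 0) cf[1] / cf[2] else NA_real_
    })
    out$se_boot_umol <- stats::sd(boots, na.rm = TRUE)
  }
  structure(out, class = "standard_additions_fit")
}

#' @export
print.standard_additions_fit <- function(x, ...) {
  cat(sprintf("Standard additions: m0 = %.4g +/- %.3g umol (slope %.4g, intercept %.4g)\n",
              x$m0_umol, x$se_umol, x$slope, x$intercept))
  invisible(x)
}

#' Normalise an analyte amount per gram of hemoglobin
#'
#' @param m0_umol analyte amount, umol.
#' @param hb_g hemoglobin mass in the sample, g (strictly positive).
#'
#' @return Amount in umol per g Hb.
#' @export
normalize_per_hb <- function(m0_umol, hb_g) {
  stopifnot(is.numeric(m0_umol), is.numeric(hb_g))
  if (any(hb_g <= 0)) stop("hemoglobin mass must be strictly positive")
  m0_umol / hb_g
}
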