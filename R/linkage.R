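#' Two-state allosteric parameters for hemoglobin oxygen binding
#'
#' Parameter container for the oxygen equilibrium curve. Two modes are
#' supported: `"two_state"`, a concerted (MWC-type) two-state model in
#' which every tetramer is entirely in a high-affinity R or low-affinity T
#' quaternary state, and `"hill"`, the empirical Hill equation. The
#' two-state mode is what links oxygenation to GSH buffering: quaternary
#' state, not fractional saturation per se, determines how many GSH pockets
#' a tetramer exposes.
#'
#' The measured quantities in this field are oxygen saturation and P50;
#' the underlying binding constants are not observable from them alone, so
#' the defaults (`L = 1.7e5`, `c = 0.014`, and `KR` calibrated so that
#' half-saturation falls at `p50 = 26` mmHg) are conventional textbook-order
#' values for human hemoglobin, chosen here and fully configurable. They are
#' model plumbing, not measurements.
#'
#' @param mode `"two_state"` (default) or `"hill"`.
#' @param L allosteric constant: T/R population ratio at zero oxygen
#'   (two-state mode; must be positive).
#' @param c ratio of the R-state to T-state oxygen dissociation constants,
#'   in `(0, 1]` (two-state mode). At `c = 1` the states have equal
#'   affinity and the curve collapses to the non-cooperative hyperbola
#'   `a/(1+a)` for any `L`.
#' @param KR R-state oxygen dissociation constant, mmHg. If `NULL`
#'   (default) in two-state mode, it is calibrated so the curve passes
#'   through half-saturation at `p50`.
#' @param p50 half-saturation oxygen pressure, mmHg.
#' @param n_hill Hill coefficient (hill mode; at least 1).
#'
#' @return An object of class `mwc_params`.
#' @examples
#' pars <- mwc_params()
#' o2_saturation(pars$p50, pars) # 0.5
#' @export
mwc_params <- function(mode = c("two_state", "hill"),
                       L = 1.7e5, c = 0.014, KR = NULL,
                       p50 = 26, n_hill = 2.7) {
  mode <- match.arg(mode)
  stopifnot(L > 0, c > 0, c <= 1, p50 > 0, n_hill >= 1)
  out <- structure(
    list(mode = mode, L = L, c = c, KR = KR, p50 = p50, n_hill = n_hill),
    class = "mwc_params"
  )
  if (mode == "two_state") {
    if (is.null(KR)) {
      out$KR <- .calibrate_kr_value(L, c, p50)
    } else {
      stopifnot(KR > 0)
    }
  }
  out
}

#' @export
print.mwc_params <- function(x, ...) {
  if (x$mode == "two_state") {
    cat(sprintf(
      "Two-state O2 binding model: L = %g, c = %g, KR = %.4g mmHg (P50 = %.3g mmHg)\n",
      x$L, x$c, x$KR, x$p50))
  } else {
    cat(sprintf("Hill O2 binding model: P50 = %.3g mmHg, n = %.3g\n",
                x$p50, x$n_hill))
  }
  invisible(x)
}

#' State-resolved GSH binding parameters
#'
#' Describes the GSH "pockets" of hemoglobin in each quaternary state: the
#' oxygenated (R) tetramer carries `n_r` sites of dissociation constant
#' `kd_r`, the deoxygenated (T) tetramer `n_t` sites of `kd_t`. The
#' difference `n_r - n_t` is the releasable pool per tetramer. `phi` is the
#' mean fractional occupancy of the releasable pockets in circulating
#' cells; the stoichiometric release model scales with it.
#'
#' Defaults follow calorimetric estimates for the GSH:hemoglobin
#' interaction: four sites at about 2 uM on the oxy tetramer, two sites at
#' about 17 uM on the deoxy tetramer.
#'
#' @param n_r GSH sites per tetramer in the R (oxy) state (default 4).
#' @param kd_r R-state GSH dissociation constant, uM (default 2).
#' @param n_t GSH sites per tetramer in the T (deoxy) state (default 2).
#' @param kd_t T-state GSH dissociation constant, uM (default 17).
#' @param phi mean occupancy of the releasable pockets, in `[0, 1]`
#'   (default 0.17, the occupancy consistent with ~16.5% of the storage
#'   capacity being mobilised during deep deoxygenation).
#'
#' @return An object of class `gsh_linkage`.
#' @export
gsh_linkage <- function(n_r = 4, kd_r = 2, n_t = 2, kd_t = 17, phi = 0.17) {
  stopifnot(
    n_r == round(n_r), n_t == round(n_t), n_r >= n_t, n_t >= 0,
    kd_r > 0, kd_t > 0, phi >= 0, phi <= 1
  )
  structure(list(n_r = n_r, kd_r = kd_r, n_t = n_t, kd_t = kd_t, phi = phi),
            class = "gsh_linkage")
}

#' 2,3-bisphosphoglycerate binding parameters
#'
#' BPG is treated as a pure T-state effector occupying one central-cavity
#' site per tetramer, with no competition against GSH binding. Default
#' dissociation constants are the literature values 4.75 mM (oxy) and
#' 0.1 mM (deoxy).
#'
#' @param kd_oxy oxy-state BPG dissociation constant, mM.
#' @param kd_deoxy deoxy-state BPG dissociation constant, mM.
#'
#' @return An object of class `bpg_linkage`.
#' @export
bpg_linkage <- function(kd_oxy = 4.75, kd_deoxy = 0.1) {
  stopifnot(kd_oxy > 0, kd_deoxy > 0)
  structure(list(kd_oxy = kd_oxy, kd_deoxy = kd_deoxy), class = "bpg_linkage")
}

#' Oxygen saturation of hemoglobin
#'
#' Fractional saturation as a function of oxygen partial pressure. In
#' two-state mode, with `a = pO2/KR`,
#' \deqn{Y = \frac{a(1+a)^3 + Lca(1+ca)^3}{(1+a)^4 + L(1+ca)^4};}
#' in hill mode \eqn{Y = p^n / (p^n + P50^n)}.
#'
#' @param pO2 oxygen partial pressure, mmHg (non-negative; vectorised).
#' @param params an [mwc_params()] object.
#'
#' @return Fractional saturation in `[0, 1]`.
#' @export
o2_saturation <- function(pO2, params = mwc_params()) {
  stopifnot(inherits(params, "mwc_params"), is.numeric(pO2))
  if (any(pO2 < 0)) stop("pO2 must be non-negative")
  if (params$mode == "hill") {
    p_n <- pO2^params$n_hill
    return(p_n / (p_n + params$p50^params$n_hill))
  }
  a <- pO2 / params$KR
  ca <- params$c * a
  num <- a * (1 + a)^3 + params$L * ca * (1 + ca)^3
  den <- (1 + a)^4 + params$L * (1 + ca)^4
  num / den
}

#' Fraction of hemoglobin tetramers in the R quaternary state
#'
#' \deqn{f_R = \frac{(1+a)^4}{(1+a)^4 + L(1+ca)^4}, \quad a = pO2/KR.}
#' The T-state fraction is `1 - r_state_fraction(...)`.
#'
#' @inheritParams o2_saturation
#' @return R-state fraction in `[0, 1]`. Only defined for two-state mode.
#' @export
r_state_fraction <- function(pO2, params = mwc_params()) {
  stopifnot(inherits(params, "mwc_params"), is.numeric(pO2))
  if (params$mode != "two_state")
    stop("r_state_fraction is only defined for the two-state model")
  if (any(pO2 < 0)) stop("pO2 must be non-negative")
  a <- pO2 / params$KR
  ca <- params$c * a
  r4 <- (1 + a)^4
  r4 / (r4 + params$L * (1 + ca)^4)
}

#' Invert the oxygen equilibrium curve
#'
#' Finds the oxygen partial pressure at which the saturation equals `S`,
#' by bisection on the (strictly monotone) saturation curve.
#'
#' @param S target fractional saturation, strictly inside (0, 1);
#'   vectorised.
#' @param params an [mwc_params()] object.
#' @param tol absolute tolerance on the achieved saturation.
#'
#' @return Oxygen partial pressure(s), mmHg.
#' @export
saturation_to_pO2 <- function(S, params = mwc_params(), tol = 1e-9) {
  stopifnot(inherits(params, "mwc_params"), is.numeric(S))
  if (any(S <= 0 | S >= 1)) stop("saturation must lie strictly inside (0, 1)")
  vapply(S, function(s) {
    lo <- 0
    hi <- params$p50
    while (o2_saturation(hi, params) < s) hi <- hi * 2
    while (TRUE) {
      mid <- (lo + hi) / 2
      y <- o2_saturation(mid, params)
      if (abs(y - s) < tol || (hi - lo) < .Machine$double.eps * max(1, hi))
        return(mid)
      if (y < s) lo <- mid else hi <- mid
    }
  }, numeric(1))
}

# Root-solve KR so that the two-state curve is half-saturated at target_p50.
# Y is strictly increasing in a = p/KR, hence strictly decreasing in KR.
.calibrate_kr_value <- function(L, c, target_p50) {
  f <- function(kr) {
    pars <- structure(list(mode = "two_state", L = L, c = c, KR = kr,
                           p50 = target_p50, n_hill = 1), class = "mwc_params")
    o2_saturation(target_p50, pars) - 0.5
  }
  lo <- target_p50 * 1e-8
  hi <- target_p50 * 1e8
  if (f(lo) < 0 || f(hi) > 0) stop("KR calibration: no root in bracket")
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Calibrate the R-state oxygen dissociation constant to a target P50
#'
#' Returns a parameter set whose oxygen equilibrium curve passes through
#' half-saturation at `target_p50`. In hill mode `KR` is unused and the
#' P50 is simply set.
#'
#' @param params an [mwc_params()] object (its `L` and `c` are kept).
#' @param target_p50 desired half-saturation pressure, mmHg.
#'
#' @return An [mwc_params()] object with `KR` (two-state) or `p50` (hill)
#'   adjusted; `o2_saturation(target_p50, result)` is 0.5 within 1e-6.
#' @export
calibrate_KR <- function(params, target_p50) {
  stopifnot(inherits(params, "mwc_params"), target_p50 > 0)
  params$p50 <- target_p50
  if (params$mode == "two_state")
    params$KR <- .calibrate_kr_value(params$L, params$c, target_p50)
  params
}

# T-state fraction as a function of oxygen saturation, with saturating
# edge handling: SO2 <= 0 uses pO2 = 0; SO2 >= 1 uses the high-pO2 limit
# fT -> 0 (c < 1).
.t_state_at_saturation <- function(SO2, params) {
  vapply(SO2, function(s) {
    if (s >= 1) return(0)
    p <- if (s <= 0) 0 else saturation_to_pO2(s, params)
    1 - r_state_fraction(p, params)
  }, numeric(1))
}

#' GSH released stoichiometrically upon deoxygenation
#'
#' The stoichiometric release model: each tetramer that switches from the
#' R to the T quaternary state sheds its `n_r - n_t` releasable pockets,
#' liberating the GSH they held. At saturation `SO2` the released
#' concentration is
#' \deqn{released = \phi (n_r - n_t) \cdot Hb \cdot f_T(pO2(SO2)),}
#' monotone non-increasing in `SO2`.
#'
#' @param SO2 oxygen saturation as a fraction in `[0, 1]` (vectorised).
#' @param hb_mM hemoglobin tetramer concentration, mM (non-negative).
#' @param linkage a [gsh_linkage()] object.
#' @param params an [mwc_params()] object (two-state mode).
#'
#' @return Released GSH, mM.
#' @export
stoichiometric_release <- function(SO2, hb_mM,
                                   linkage = gsh_linkage(),
                                   params = mwc_params()) {
  stopifnot(inherits(linkage, "gsh_linkage"), is.numeric(SO2), is.numeric(hb_mM))
  if (any(hb_mM < 0)) stop("hemoglobin concentration must be non-negative")
  if (any(SO2 < 0 | SO2 > 1)) stop("SO2 must be a fraction in [0, 1]")
  fT <- .t_state_at_saturation(SO2, params)
  linkage$phi * (linkage$n_r - linkage$n_t) * hb_mM * fT
}

#' Predicted free cytosolic GSH as a function of oxygen saturation
#'
#' Baseline (fully oxygenated) free GSH plus the stoichiometric release at
#' the given saturation. Because the T-state fraction is sigmoidal in
#' oxygen pressure, the prediction is flat at high saturation and rises
#' steeply once saturation falls below roughly the half-saturation region.
#'
#' @inheritParams stoichiometric_release
#' @param baseline_mM free GSH at full oxygenation, mmol/L cell water.
#'
#' @return Predicted free GSH, mmol/L cell water.
#' @export
predicted_free_gsh <- function(SO2, baseline_mM, hb_mM,
                               linkage = gsh_linkage(),
                               params = mwc_params()) {
  stopifnot(baseline_mM >= 0)
  baseline_mM + stoichiometric_release(SO2, hb_mM, linkage, params)
}

#' Equilibrium free GSH under state-resolved mass balance
#'
#' The thermodynamically self-consistent alternative to
#' [stoichiometric_release()]: free GSH `g` solves the mass balance
#' \deqn{g + Hb\left[f_R \frac{n_r g}{g + K_{d,R}} +
#'   f_T \frac{n_t g}{g + K_{d,T}}\right] = g_{total}}
#' by bisection on `[0, g_total]`. The left side is strictly increasing in
#' `g`, so the root is unique.
#'
#' @param g_total_mM total (free + non-covalently bound) GSH, mM.
#' @param hb_mM hemoglobin tetramer concentration, mM.
#' @param SO2 oxygen saturation, fraction in `[0, 1]`.
#' @param linkage a [gsh_linkage()] object (its `kd_r`, `kd_t` are in uM
#'   and are converted internally).
#' @param params an [mwc_params()] object (two-state mode).
#'
#' @return Free GSH, mM; the mass-balance residual is below
#'   `1e-9 * g_total`.
#' @export
equilibrium_free_gsh <- function(g_total_mM, hb_mM, SO2,
                                 linkage = gsh_linkage(),
                                 params = mwc_params()) {
  stopifnot(inherits(linkage, "gsh_linkage"),
            length(g_total_mM) == 1L, length(hb_mM) == 1L, length(SO2) == 1L)
  if (g_total_mM < 0 || hb_mM < 0) stop("concentrations must be non-negative")
  if (g_total_mM == 0) return(0)
  if (hb_mM == 0) return(g_total_mM)
  fT <- .t_state_at_saturation(SO2, params)
  fR <- 1 - fT
  kdr <- linkage$kd_r / 1000 # uM -> mM
  kdt <- linkage$kd_t / 1000
  bal <- function(g) {
    bound <- hb_mM * (fR * linkage$n_r * g / (g + kdr) +
                        fT * linkage$n_t * g / (g + kdt))
    g + bound - g_total_mM
  }
  lo <- 0
  hi <- g_total_mM
  repeat {
    mid <- (lo + hi) / 2
    r <- bal(mid)
    if (abs(r) < 1e-9 * g_total_mM || (hi - lo) < .Machine$double.eps * g_total_mM)
      return(mid)
    if (r < 0) lo <- mid else hi <- mid
  }
}

#' P50 in the presence of GSH (and optionally BPG)
#'
#' GSH preferentially stabilises the R state (more sites, tighter binding),
#' while BPG stabilises the T state. Each ligand rescales the apparent
#' allosteric constant:
#' \deqn{L_{app} = L \cdot \frac{(1 + g/K_{d,T})^{n_t}}{(1 + g/K_{d,R})^{n_r}}
#'   \cdot \frac{1 + b/K_{d,deoxy}}{1 + b/K_{d,oxy}}}
#' (the BPG factor applies to its single central-cavity site). The P50 is
#' then recomputed from the modified curve. P50 is strictly decreasing in
#' GSH (left shift, higher affinity) and increasing in BPG (right shift).
#'
#' @param gsh_mM free GSH concentration, mM (non-negative).
#' @param linkage a [gsh_linkage()] object (`kd_r`, `kd_t` in uM).
#' @param params an [mwc_params()] object (two-state mode).
#' @param bpg optional [bpg_linkage()] object.
#' @param bpg_mM BPG concentration, mM (used only when `bpg` is supplied).
#'
#' @return The shifted P50, mmHg.
#' @export
p50_with_gsh <- function(gsh_mM, linkage = gsh_linkage(),
                         params = mwc_params(),
                         bpg = NULL, bpg_mM = 0) {
  stopifnot(inherits(params, "mwc_params"), gsh_mM >= 0)
  if (params$mode != "two_state")
    stop("p50_with_gsh requires the two-state model")
  kdr <- linkage$kd_r / 1000
  kdt <- linkage$kd_t / 1000
  L_app <- params$L * (1 + gsh_mM / kdt)^linkage$n_t /
    (1 + gsh_mM / kdr)^linkage$n_r
  if (!is.null(bpg)) {
    stopifnot(inherits(bpg, "bpg_linkage"), bpg_mM >= 0)
    L_app <- L_app * (1 + bpg_mM / bpg$kd_deoxy) / (1 + bpg_mM / bpg$kd_oxy)
  }
  shifted <- params
  shifted$L <- L_app
  saturation_to_pO2(0.5, shifted)
}

# Threshold-model design matrix fit at fixed (s_star, k): the response is
# flat at `a` above the threshold and a + b*(exp(k*(s_star - S)) - 1) below.
.threshold_ls <- function(so2, gsh, s_star, k) {
  x <- ifelse(so2 < s_star, expm1(k * (s_star - so2)), 0)
  if (all(abs(x) < 1e-12)) {
    a <- mean(gsh)
    return(list(a = a, b = 0, sse = sum((gsh - a)^2)))
  }
  fit <- stats::lm.fit(cbind(1, x), gsh)
  list(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]),
       sse = sum(fit$residuals^2))
}

#' Estimate the oxygen-saturation threshold for GSH release
#'
#' Fits a flat-then-exponential threshold model to (saturation, GSH)
#' points:
#' \deqn{g(S) = a \; (S \ge S^*), \qquad
#'   g(S) = a + b\,(e^{k (S^* - S)} - 1) \; (S < S^*),}
#' by exhaustive grid search over the threshold `S*` with a nested 1-D
#' optimisation over the rate `k` and linear least squares over `(a, b)`.
#' Whether any threshold exists at all is decided by an F-style
#' sum-of-squares ratio against the flat (constant) model; data compatible
#' with a flat line return a "no threshold" result rather than a number.
#'
#' @param so2 oxygen saturations as fractions in `[0, 1]` (at least 10
#'   points spanning the candidate range).
#' @param gsh GSH values (any consistent unit; the threshold location is
#'   scale-invariant).
#' @param grid candidate thresholds (default 0.05 to 0.95 in steps of 0.01).
#' @param k_range search interval for the exponential rate.
#' @param alpha significance level of the SSE-ratio test for the existence
#'   of a threshold.
#'
#' @return An object of class `threshold_fit`: a list with elements
#'   `threshold` (`NA` if none found), `threshold_found`, `a`, `b`, `k`,
#'   `sse`, `sse_flat`, `f_stat`, `p_value`, `n`.
#' @export
estimate_threshold <- function(so2, gsh,
                               grid = seq(0.05, 0.95, by = 0.01),
                               k_range = c(0.01, 30),
                               alpha = 0.05) {
  stopifnot(is.numeric(so2), is.numeric(gsh), length(so2) == length(gsh))
  n <- length(so2)
  if (n < 10) stop("at least 10 points are required")
  if (any(so2 < 0 | so2 > 1))
    stop("so2 must be fractions in [0, 1] (convert percent at input)")
  sse_flat <- sum((gsh - mean(gsh))^2)
  best <- list(sse = Inf)
  for (s_star in grid) {
    opt <- stats::optimize(function(k) .threshold_ls(so2, gsh, s_star, k)$sse,
                           interval = k_range)
    if (opt$objective < best$sse) {
      ls <- .threshold_ls(so2, gsh, s_star, opt$minimum)
      best <- list(s_star = s_star, k = opt$minimum,
                   a = ls$a, b = ls$b, sse = ls$sse)
    }
  }
  # F-style test: 3 extra parameters (threshold, rate, amplitude)
  df2 <- n - 4
  f_stat <- if (best$sse <= 0) Inf else
    ((sse_flat - best$sse) / 3) / (best$sse / df2)
  p_value <- stats::pf(f_stat, 3, df2, lower.tail = FALSE)
  found <- is.finite(f_stat) && p_value < alpha && best$b > 0 ||
    (is.infinite(f_stat) && best$b > 0)
  structure(
    list(threshold = if (found) best$s_star else NA_real_,
         threshold_found = found,
         a = best$a, b = best$b, k = best$k,
         sse = best$sse, sse_flat = sse_flat,
         f_stat = f_stat, p_value = p_value, n = n),
    class = "threshold_fit"
  )
}

#' @export
print.threshold_fit <- function(x, ...) {
  if (x$threshold_found) {
    cat(sprintf(
      "GSH release threshold: SO2* = %.2f (baseline %.3g, amplitude %.3g, rate %.3g)\n",
      x$threshold, x$a, x$b, x$k))
  } else {
    cat("No GSH release threshold detected (data compatible with a flat line)\n")
  }
  cat(sprintf("  SSE %.4g vs flat %.4g; F = %.3g, p = %.3g, n = %d\n",
              x$sse, x$sse_flat, x$f_stat, x$p_value, x$n))
  invisible(x)
}

#' Fit the pocket occupancy and oxygenated baseline from tonometry data
#'
#' The stoichiometric release model is linear in `(baseline, phi)`:
#' predicted GSH equals `baseline + phi * R(SO2)` with
#' `R(SO2) = (n_r - n_t) * Hb * f_T(SO2)`. Both parameters are estimated
#' by ordinary least squares; the occupancy is clipped to `[0, 1]`.
#'
#' @param so2 oxygen saturations as fractions in `[0, 1]` (at least 5
#'   points, including low saturations for identifiability).
#' @param gsh_mM measured free GSH, mmol/L cell water.
#' @param hb_mM hemoglobin tetramer concentration, mM.
#' @param linkage a [gsh_linkage()] object (its `phi` is ignored; the fit
#'   estimates it).
#' @param params an [mwc_params()] object (two-state mode).
#'
#' @return A list with `phi`, `baseline_mM`, `sse` and the fitted values.
#' @export
fit_phi <- function(so2, gsh_mM, hb_mM,
                    linkage = gsh_linkage(),
                    params = mwc_params()) {
  stopifnot(is.numeric(so2), is.numeric(gsh_mM), length(so2) == length(gsh_mM))
  if (length(so2) < 5) stop("at least 5 points are required")
  if (any(so2 < 0 | so2 > 1)) stop("so2 must be fractions in [0, 1]")
  release_unit <- (linkage$n_r - linkage$n_t) * hb_mM *
    .t_state_at_saturation(so2, params)
  if (stats::sd(so2) == 0 || stats::sd(release_unit) < 1e-12)
    stop("occupancy is not identifiable: saturations do not span a release range")
  fit <- stats::lm.fit(cbind(1, release_unit), gsh_mM)
  phi <- min(max(unname(fit$coefficients[2]), 0), 1)
  baseline <- unname(fit$coefficients[1])
  fitted <- baseline + phi * release_unit
  list(phi = phi, baseline_mM = baseline,
       sse = sum((gsh_mM - fitted)^2), fitted = fitted)
}
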