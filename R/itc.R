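# Gas constant, J / (mol K)
.R_GAS <- 8.31446261815324

#' Titration protocol for an isothermal titration calorimetry experiment
#'
#' Geometry and concentrations of a perfusion-cell titration: a ligand
#' solution in the syringe is injected stepwise into the sample cell
#' containing the macromolecule. Defaults describe a typical small-cell
#' instrument run: 19 injections of 2 uL of 4 mM ligand into 200 uL of
#' 85 uM protein at 25 degrees C, which carries the molar ratio past 8 and
#' covers the full isotherm for stoichiometries up to 4.
#'
#' @param cell_volume_uL active cell volume, uL.
#' @param injection_volumes_uL vector of injection volumes, uL (non-empty,
#'   all positive).
#' @param syringe_conc_mM ligand concentration in the syringe, mM.
#' @param cell_conc_uM macromolecule concentration in the cell, uM.
#' @param temperature_K experiment temperature, K.
#'
#' @return An object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume_uL = 200,
                         injection_volumes_uL = rep(2.0, 19),
                         syringe_conc_mM = 4.0,
                         cell_conc_uM = 85,
                         temperature_K = 298.15) {
  stopifnot(
    cell_volume_uL > 0, length(injection_volumes_uL) >= 1,
    all(injection_volumes_uL > 0), syringe_conc_mM > 0,
    cell_conc_uM > 0, temperature_K > 0
  )
  structure(
    list(cell_volume_uL = cell_volume_uL,
         injection_volumes_uL = injection_volumes_uL,
         syringe_conc_mM = syringe_conc_mM,
         cell_conc_uM = cell_conc_uM,
         temperature_K = temperature_K),
    class = "itc_protocol"
  )
}

#' Thermodynamic parameter set for one-site binding
#'
#' Holds the stoichiometry, association constant and enthalpy of a
#' one-set-of-sites interaction and completes the decomposition via the
#' identities `dG = -RT ln(Ka) = dH - TdS` and `Kd = 1/Ka`.
#'
#' @param n_sites binding stoichiometry N (sites per macromolecule, > 0).
#' @param ka association constant, 1/M (> 0).
#' @param dH_kJ_per_mol binding enthalpy, kJ/mol.
#' @param temperature_K temperature, K.
#'
#' @return An object of class `itc_thermo` with fields `n_sites`, `ka`,
#'   `kd` (M), `dH`, `dG`, `TdS` (all kJ/mol) and `temperature_K`.
#' @examples
#' itc_thermo(4, 5e5, -20) # Kd = 2 uM
#' @export
itc_thermo <- function(n_sites, ka, dH_kJ_per_mol, temperature_K = 298.15) {
  stopifnot(n_sites > 0, ka > 0, temperature_K > 0)
  dec <- thermo_decompose(ka, dH_kJ_per_mol, temperature_K)
  structure(
    list(n_sites = n_sites, ka = ka, kd = dec$kd,
         dH = dH_kJ_per_mol, dG = dec$dG, TdS = dec$TdS,
         temperature_K = temperature_K),
    class = "itc_thermo"
  )
}

#' @export
print.itc_thermo <- function(x, ...) {
  cat(sprintf("One-site binding: N = %.3g, Ka = %.4g 1/M (Kd = %.4g uM)\n",
              x$n_sites, x$ka, x$kd * 1e6))
  cat(sprintf("  dH = %.4g, dG = %.4g, TdS = %.4g kJ/mol at %.2f K\n",
              x$dH, x$dG, x$TdS, x$temperature_K))
  invisible(x)
}

#' Thermodynamic decomposition of a binding constant
#'
#' Applies `dG = -RT ln(Ka)`, `TdS = dH - dG`, `Kd = 1/Ka`.
#'
#' @param ka association constant, 1/M (> 0).
#' @param dH_kJ_per_mol binding enthalpy, kJ/mol.
#' @param temperature_K temperature, K.
#'
#' @return A list with `dG` and `TdS` in kJ/mol and `kd` in M.
#' @examples
#' thermo_decompose(5e5, -20) # dG about -32.5 kJ/mol
#' @export
thermo_decompose <- function(ka, dH_kJ_per_mol, temperature_K = 298.15) {
  if (any(ka <= 0)) stop("association constant must be strictly positive")
  stopifnot(temperature_K > 0)
  dG <- -.R_GAS * temperature_K * log(ka) / 1000
  list(dG = dG, TdS = dH_kJ_per_mol - dG, kd = 1 / ka)
}

# Post-injection cell concentrations under the standard perfusion-cell
# displacement convention: after cumulative injected volume dV,
#   M = M0 (1 - dV/2V0) / (1 + dV/2V0),  X = X0 (dV/V0) / (1 + dV/2V0).
.itc_concentrations <- function(protocol) {
  V0 <- protocol$cell_volume_uL * 1e-6       # L
  dV <- cumsum(protocol$injection_volumes_uL) * 1e-6
  M0 <- protocol$cell_conc_uM * 1e-6         # M
  X0 <- protocol$syringe_conc_mM * 1e-3      # M
  list(V0 = V0,
       M = M0 * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0)),
       X = X0 * (dV / V0) / (1 + dV / (2 * V0)))
}

#' Simulate a one-site titration trace
#'
#' Forward model of the injection heats under the one-set-of-sites
#' (Wiseman) isotherm with the standard perfusion-cell displacement
#' correction. With post-injection concentrations `M_i`, `X_i` (see
#' details), the cumulative heat after injection i is
#' \deqn{Q_i = \frac{N M_i \Delta H V_0}{2}
#'   \left[B_i - \sqrt{B_i^2 - 4X_i/(N M_i)}\right], \quad
#'   B_i = 1 + \frac{X_i}{N M_i} + \frac{1}{N K_a M_i},}
#' and the observed heat of injection i is
#' \eqn{\delta Q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i + Q_{i-1})/2}, the last
#' term accounting for liquid displaced out of the active volume.
#'
#' @param protocol an [itc_protocol()] object.
#' @param thermo an [itc_thermo()] object.
#'
#' @return A data frame with one row per injection: `injection`,
#'   `injection_volume_uL`, `molar_ratio` (cumulative ligand:macromolecule
#'   ratio in the cell) and `heat_uJ`.
#' @export
simulate_trace <- function(protocol, thermo) {
  stopifnot(inherits(protocol, "itc_protocol"), inherits(thermo, "itc_thermo"))
  conc <- .itc_concentrations(protocol)
  N <- thermo$n_sites
  Ka <- thermo$ka
  dH <- thermo$dH * 1000 # J/mol
  B <- 1 + conc$X / (N * conc$M) + 1 / (N * Ka * conc$M)
  disc <- B^2 - 4 * conc$X / (N * conc$M)
  if (any(disc < 0)) stop("internal error: negative discriminant in isotherm")
  Q <- (N * conc$M * dH * conc$V0 / 2) * (B - sqrt(disc)) # J, cumulative
  Qprev <- c(0, Q[-length(Q)])
  v <- protocol$injection_volumes_uL * 1e-6
  dQ <- Q - Qprev + (v / conc$V0) * (Q + Qprev) / 2
  data.frame(
    injection = seq_along(dQ),
    injection_volume_uL = protocol$injection_volumes_uL,
    molar_ratio = conc$X / conc$M,
    heat_uJ = dQ * 1e6
  )
}

#' Fit the one-set-of-sites model to a titration trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) over stoichiometry,
#' log10 association constant and enthalpy, with an optional constant
#' per-injection heat-of-dilution offset co-fitted by default. Starting
#' values follow common practice: the stoichiometry from the molar ratio
#' at half the total cumulative heat, the enthalpy from the first
#' injection, and Ka from 1e5 1/M, with a restart grid over
#' log10(Ka) in 3..8 if the first attempt stalls.
#'
#' @param trace a data frame as produced by [simulate_trace()] or
#'   [generate_itc()] (columns `heat_uJ` and `injection_volume_uL`; heats
#'   in uJ. Use [ucal_to_uJ()] first for traces recorded in ucal).
#' @param protocol the [itc_protocol()] describing the experiment.
#' @param exclude_first drop injection 1 from the fit (common practice for
#'   the first-injection artifact; default `FALSE`).
#' @param fit_dilution co-fit a constant per-injection offset (default
#'   `TRUE`).
#'
#' @return A list of class `itc_fit` with the recovered [itc_thermo()]
#'   object (`thermo`), `dilution_offset_uJ`, `sse`, `converged`, and the
#'   per-injection `fitted` data frame.
#' @export
fit_one_site <- function(trace, protocol,
                         exclude_first = FALSE, fit_dilution = TRUE) {
  stopifnot(is.data.frame(trace), inherits(protocol, "itc_protocol"),
            "heat_uJ" %in% names(trace))
  heats <- trace$heat_uJ
  n_inj <- length(heats)
  if (n_inj < 8) stop("at least 8 injections are required for a one-site fit")
  if (max(abs(heats)) < 1e-9)
    stop("all injection heats are zero: binding enthalpy is not identifiable")
  keep <- if (exclude_first) seq_len(n_inj)[-1] else seq_len(n_inj)

  conc <- .itc_concentrations(protocol)
  ratio <- conc$X / conc$M
  cumQ <- cumsum(heats)
  half_idx <- which.min(abs(abs(cumQ) - abs(cumQ[n_inj]) / 2))
  n0 <- max(ratio[half_idx], 0.1)
  moles_first <- protocol$injection_volumes_uL[1] * 1e-6 *
    protocol$syringe_conc_mM * 1e-3
  dH0 <- heats[1] * 1e-6 / moles_first / 1000 # kJ/mol
  if (!is.finite(dH0) || abs(dH0) < 1e-6) dH0 <- sign(sum(heats)) * 1

  flat_range <- diff(range(heats))
  if (flat_range < 0.01 * max(abs(heats)))
    warning("injection heats are nearly constant: trace may be saturated ",
            "from the start and the stoichiometry poorly identifiable")

  predict_heats <- function(par) {
    th <- structure(
      list(n_sites = exp(par[1]), ka = 10^par[2], kd = 10^(-par[2]),
           dH = par[3], dG = NA, TdS = NA,
           temperature_K = protocol$temperature_K),
      class = "itc_thermo"
    )
    pred <- simulate_trace(protocol, th)$heat_uJ
    if (fit_dilution) pred <- pred + par[4]
    pred
  }
  resid_fun <- function(par) heats[keep] - predict_heats(par)[keep]

  run_fit <- function(log10ka0) {
    start <- c(log(n0), log10ka0, dH0, if (fit_dilution) 0)
    out <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    list(par = out$par, sse = sum(out$fvec^2), info = out$info)
  }

  fits <- list(run_fit(5))
  scale <- sum(heats[keep]^2)
  best <- fits[[1]]
  if (is.null(best) || best$sse > 1e-12 * scale) {
    for (lk in 3:8) {
      f <- run_fit(lk)
      if (!is.null(f) && (is.null(best) || f$sse < best$sse)) best <- f
    }
  }
  if (is.null(best))
    stop("one-site fit failed to converge from every starting point")

  par <- best$par
  thermo <- itc_thermo(exp(par[1]), 10^par[2], par[3], protocol$temperature_K)
  fitted <- data.frame(
    injection = seq_len(n_inj),
    molar_ratio = ratio,
    heat_uJ = heats,
    fitted_uJ = predict_heats(par)
  )
  structure(
    list(thermo = thermo,
         dilution_offset_uJ = if (fit_dilution) par[4] else 0,
         sse = best$sse,
         converged = best$info %in% 1:3,
         fitted = fitted),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  print(x$thermo)
  cat(sprintf("  dilution offset %.3g uJ; SSE %.4g; converged: %s\n",
              x$dilution_offset_uJ, x$sse, x$converged))
  invisible(x)
}

#' Convert microcalories to microjoules
#'
#' Heats are carried in joules internally; traces recorded in ucal can be
#' converted at input with 1 cal = 4.184 J.
#'
#' @param x_ucal heat(s) in ucal.
#' @return Heat(s) in uJ.
#' @export
ucal_to_uJ <- function(x_ucal) x_ucal * 4.184
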