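# Shared fixtures, built in code.
default_comp <- rbc_composition()
default_params <- mwc_params()
default_linkage <- gsh_linkage()
hb_default_mM <- hb_mass_to_molar(default_comp$mchc_g_per_L, default_comp)

# Independent oracle for the one-site titration trace: the dilution
# bookkeeping is the shared convention, but the per-injection equilibrium
# is solved by bisection on the free-ligand mass balance instead of the
# closed-form isotherm.
oracle_trace_heats <- function(protocol, n_sites, ka, dH_kJ) {
  V0 <- protocol$cell_volume_uL * 1e-6
  dV <- cumsum(protocol$injection_volumes_uL) * 1e-6
  M <- protocol$cell_conc_uM * 1e-6 * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
  X <- protocol$syringe_conc_mM * 1e-3 * (dV / V0) / (1 + dV / (2 * V0))
  kd <- 1 / ka
  bound <- vapply(seq_along(M), function(i) {
    f <- function(x) x + n_sites * M[i] * x / (x + kd) - X[i]
    lo <- 0
    hi <- X[i]
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    X[i] - (lo + hi) / 2
  }, numeric(1))
  Q <- V0 * dH_kJ * 1000 * bound
  Qprev <- c(0, Q[-length(Q)])
  v <- protocol$injection_volumes_uL * 1e-6
  (Q - Qprev + (v / V0) * (Q + Qprev) / 2) * 1e6
}

# Flat-then-exponential threshold curve used by the recovery studies.
threshold_curve <- function(so2, a = 2.5, b = 0.412, k = 5, s_star = 0.5) {
  ifelse(so2 >= s_star, a, a + b * expm1(k * (s_star - so2)))
}
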