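#' Half-cell redox potential of the GSH/GSSG couple
#'
#' Computes the glutathione half-cell potential from the Nernst form fixed
#' at 25 degrees C and pH 7.0:
#'
#' \deqn{E_{hc}(mV) = -240 - (59.1/2) \log_{10}([GSH]^2 / [GSSG])}
#'
#' with both concentrations in mol/L. The squared GSH term makes the log
#' argument dimensionful; the mol/L convention is part of the definition
#' and is not generalised here (nor is the temperature/pH dependence).
#' More negative values indicate a more reducing cytosol.
#'
#' @param gsh_M reduced glutathione concentration, mol/L (strictly
#'   positive; vectorised).
#' @param gssg_M oxidised glutathione concentration, mol/L (strictly
#'   positive; vectorised).
#'
#' @return Half-cell potential in mV.
#' @examples
#' half_cell_potential(2e-3, 1e-4) # about -199 mV
#' @export
half_cell_potential <- function(gsh_M, gssg_M) {
  stopifnot(is.numeric(gsh_M), is.numeric(gssg_M))
  if (any(gsh_M <= 0) || any(gssg_M <= 0))
    stop("GSH and GSSG concentrations must be strictly positive (log undefined)")
  -240 - (59.1 / 2) * log10(gsh_M^2 / gssg_M)
}

#' Add a half-cell potential column to a per-sample table
#'
#' Converts the per-gram-hemoglobin GSH and GSSG columns of a sample table
#' into cell-water molarities and appends the GSH/GSSG half-cell potential
#' as an `ehc_mV` column.
#'
#' @param table a data frame with columns `gsh_umol_per_gHb` and
#'   `gssg_umol_per_gHb`.
#' @param comp an [rbc_composition()] object used for the unit conversion.
#'
#' @return The input data frame with an added `ehc_mV` column.
#' @export
add_ehc <- function(table, comp = rbc_composition()) {
  stopifnot(is.data.frame(table))
  need <- c("gsh_umol_per_gHb", "gssg_umol_per_gHb")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("table lacks columns: ", paste(missing, collapse = ", "))
  gsh_M <- per_gHb_to_cellwater(table$gsh_umol_per_gHb, comp) / 1000
  gssg_M <- per_gHb_to_cellwater(table$gssg_umol_per_gHb, comp) / 1000
  table$ehc_mV <- half_cell_potential(gsh_M, gssg_M)
  table
}
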