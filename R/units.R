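#' Unit conversions for alcohol concentrations
#'
#' %BAC data arrive in g/dL while the transport model works in mol/m^3;
#' conversion uses the molar mass of ethanol, 46.068 g/mol
#' (1 g/dL = 10^4 g/m^3 = 10^4 / 46.068 mol/m^3).
#'
#' @param x Non-negative concentration values.
#' @return Converted values, same length as `x`.
#' @examples
#' bac_gdl_to_mol_m3(0.1)  # a typical %BAC peak, ~21.7 mol/m^3
#' @export
bac_gdl_to_mol_m3 <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  x * 1e4 / ethanol_molar_mass
}

#' @rdname bac_gdl_to_mol_m3
#' @export
mol_m3_to_bac_gdl <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  x * ethanol_molar_mass / 1e4
}

#' Molar mass of ethanol (g/mol)
#' @export
ethanol_molar_mass <- 46.068

#' Convert transcutaneous to blood alcohol concentration
#'
#' Blood alcohol concentration is proportional to the transcutaneous
#' concentration measured at the skin surface: BAC = 0.71 x TrAC, both in
#' g/L. The factor is an empirical whole-body constant.
#'
#' @param trac Transcutaneous alcohol concentration, g/L (non-negative).
#' @param factor Proportionality constant, default 0.71.
#' @return Blood alcohol concentration, g/L.
#' @examples
#' trac_to_bac(1)  # 0.71 g/L
#' @export
trac_to_bac <- function(trac, factor = 0.71) {
  stopifnot(is.numeric(trac))
  if (any(trac < 0, na.rm = TRUE)) stop("TrAC must be non-negative")
  factor * trac
}
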