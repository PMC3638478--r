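# Diameter- and haematocrit-dependent apparent blood viscosity
# (Fahraeus-Lindqvist effect), after the empirical fits of Pries and
# co-workers. Diameters in micrometres.

pries_c_exponent <- function(d) {
  s <- 1 / (1 + 1e-11 * d^12)
  (0.8 + exp(-0.075 * d)) * (s - 1) + s
}

#' Relative apparent viscosity of blood in a microvessel
#'
#' Empirical apparent viscosity relative to plasma as a function of lumen
#' diameter and discharge haematocrit. Two published parameterizations
#' are available: the in-vitro glass-tube fit
#' `eta*_0.45 = 220 exp(-1.3 d) + 3.2 - 2.44 exp(-0.06 d^0.645)`
#' and the in-vivo fit (which absorbs the endothelial surface layer)
#' `eta*_0.45 = 6 exp(-0.085 d) + 3.2 - 2.44 exp(-0.06 d^0.645)`.
#' Both share the haematocrit dependence
#' `eta = 1 + (eta*_0.45 - 1) * ((1-H)^C - 1) / ((1-0.45)^C - 1)`.
#' At H = 0 the relative viscosity is exactly 1 (pure plasma).
#'
#' @param diameter Vessel diameter in um (vectorized).
#' @param haematocrit Discharge haematocrit in `[0, 1)`.
#' @param law `"in_vivo"` (default) or `"in_vitro"` (glass-tube fit).
#' @return Relative apparent viscosity (dimensionless, >= 1 for H > 0 in
#'   the capillary range for the in-vivo law).
#' @export
pries_relative_viscosity <- function(diameter, haematocrit = 0.45,
                                     law = c("in_vivo", "in_vitro")) {
  law <- match.arg(law)
  if (any(diameter <= 0))
    abort_capres("diameter must be positive", "capres_validation_error")
  if (haematocrit < 0 || haematocrit >= 1)
    abort_capres("haematocrit must be in [0, 1)", "capres_validation_error")
  eta45 <- switch(law,
    in_vitro = 220 * exp(-1.3 * diameter) + 3.2 -
      2.44 * exp(-0.06 * diameter^0.645),
    in_vivo = 6 * exp(-0.085 * diameter) + 3.2 -
      2.44 * exp(-0.06 * diameter^0.645)
  )
  C <- pries_c_exponent(diameter)
  1 + (eta45 - 1) * ((1 - haematocrit)^C - 1) / ((1 - 0.45)^C - 1)
}

#' Apparent blood viscosity in a microvessel
#'
#' @inheritParams pries_relative_viscosity
#' @param plasma_viscosity Plasma viscosity in mPa s (default 1.2).
#' @return Apparent viscosity in mPa s.
#' @export
apparent_viscosity <- function(diameter, haematocrit = 0.45,
                               plasma_viscosity = 1.2,
                               law = c("in_vivo", "in_vitro")) {
  plasma_viscosity * pries_relative_viscosity(diameter, haematocrit, law)
}
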