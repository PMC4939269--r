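# Physical and equilibrium constants used throughout the package.

# Faraday constant (C per mol electrons)
.FARADAY <- 96485.33212

# Converts (cm^2 s^-1) * (uM mm^-1) to umol m^-2 day^-1:
# 1e-4 m^2 s^-1 per cm^2 s^-1, 1e6 umol m^-4 per (uM mm^-1), 86400 s per day.
.FLUX_UNIT_FACTOR <- 8.64e6

#' Carbonate equilibrium constants
#'
#' Bundle of the carbonic-acid dissociation constants and the water ion
#' product used for carbonate speciation and alkalinity.  Defaults are
#' standard freshwater values at 20 degrees C (pK1 = 6.38, pK2 = 10.38,
#' pKw = 14.17); concentrations are treated as activities (dilute
#' groundwater assumption, no ionic-strength correction).
#'
#' @param pK1 First dissociation constant of carbonic acid, -log10 scale.
#' @param pK2 Second dissociation constant, -log10 scale.
#' @param pKw Water ion product, -log10 scale.
#' @param temperature Temperature in degrees C the constants refer to.
#' @param source_tag Free-text provenance note.
#' @return An object of class `carbonate_constants`.
#' @examples
#' carbonate_constants()
#' @export
carbonate_constants <- function(pK1 = 6.38, pK2 = 10.38, pKw = 14.17,
                                temperature = 20,
                                source_tag = "freshwater defaults, 20 C") {
  K1 <- 10^(-pK1); K2 <- 10^(-pK2); Kw <- 10^(-pKw)
  stopifnot(K1 > K2, K2 > 0, Kw > 0)
  structure(list(K1 = K1, K2 = K2, Kw = Kw,
                 pK1 = pK1, pK2 = pK2, pKw = pKw,
                 temperature = temperature, source_tag = source_tag),
            class = "carbonate_constants")
}

#' Physical constants: diffusivities and electrochemical conversions
#'
#' Molecular diffusion coefficients at the 20 degrees C reference
#' temperature (cm^2 s^-1) for the species whose porewater fluxes the
#' package computes, together with the electrochemical conversion factors:
#' the inverse Faraday constant (mol e- s^-1 A^-1), the cathodic
#' stoichiometry of four protons consumed per O2 reduced, the eight
#' electrons released per sulfide oxidized fully to sulfate, and the
#' average intracellular ATP content per cell used to convert ATP
#' concentrations to cell densities.
#'
#' The HS- diffusivity is not part of the pinned five-species table used
#' by the flux calculations; it is supplied (standard literature value at
#' 20 degrees C) for the sulfide transport step of the geobattery
#' simulator.
#'
#' @param diffusivities Named numeric vector of D0 at 20 C in cm^2 s^-1.
#' @param faraday_inverse Conversion factor, mol e- s^-1 A^-1.
#' @param protons_per_O2 Protons consumed per O2 molecule reduced.
#' @param electrons_per_sulfate Electrons released per sulfide oxidized to
#'   sulfate.
#' @param atp_per_cell Average ATP per cell, nmol.
#' @return An object of class `physical_constants`.
#' @examples
#' physical_constants()$diffusivities[["O2"]]  # 2.06e-5 cm^2/s
#' @export
physical_constants <- function(diffusivities = c(O2  = 2.06e-5,
                                                 HCO3 = 1.16e-5,
                                                 CO3  = 0.94e-5,
                                                 OH   = 5.51e-5,
                                                 H    = 9.14e-5,
                                                 H2S  = 1.73e-5),
                               faraday_inverse = 1.036e-5,
                               protons_per_O2 = 4,
                               electrons_per_sulfate = 8,
                               atp_per_cell = 1.75e-10) {
  stopifnot(all(diffusivities > 0), faraday_inverse > 0,
            protons_per_O2 == 4, electrons_per_sulfate == 8,
            atp_per_cell > 0)
  structure(list(diffusivities = diffusivities,
                 faraday_inverse = faraday_inverse,
                 protons_per_O2 = protons_per_O2,
                 electrons_per_sulfate = electrons_per_sulfate,
                 atp_per_cell = atp_per_cell,
                 reference_temperature = 20),
            class = "physical_constants")
}

#' Diffusion coefficient at a given temperature
#'
#' Returns the molecular diffusion coefficient of a species at the
#' requested temperature.  At the 20 degrees C reference the pinned table
#' value is returned exactly; at other temperatures the reference value is
#' scaled linearly in absolute temperature (the linear-in-T reading of the
#' Stokes-Einstein relation), i.e. `D(T) = D_ref * T[K] / T_ref[K]`.
#'
#' @param species Species name (one of `names(constants$diffusivities)`),
#'   ignored when `reference` is supplied.
#' @param temperature Temperature in degrees C (0-40).
#' @param constants A [physical_constants()] object.
#' @param reference Optional `c(D_ref, T_ref)` pair overriding the
#'   built-in table (D in cm^2 s^-1, T in degrees C).
#' @return Diffusion coefficient in cm^2 s^-1.
#' @examples
#' diffusivity_at_temperature("O2", 20)   # 2.06e-5
#' diffusivity_at_temperature("H", 20)    # 9.14e-5
#' @export
diffusivity_at_temperature <- function(species, temperature = 20,
                                       constants = physical_constants(),
                                       reference = NULL) {
  if (!is.finite(temperature) || temperature < 0 || temperature > 40)
    stop("temperature must be within 0-40 C, got ", temperature)
  if (is.null(reference)) {
    if (!species %in% names(constants$diffusivities))
      stop("no tabulated diffusivity for species '", species,
           "' and no reference pair given")
    D_ref <- constants$diffusivities[[species]]
    T_ref <- constants$reference_temperature
  } else {
    stopifnot(length(reference) == 2, all(is.finite(reference)))
    D_ref <- reference[[1]]
    T_ref <- reference[[2]]
  }
  D_ref * (temperature + 273.15) / (T_ref + 273.15)
}
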