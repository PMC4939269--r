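# Carbonate-system speciation and alkalinity at constant DIC.
#
# The porewater is treated as a two-acid carbonate system: given pH and
# total dissolved inorganic carbon (DIC = CO2* + HCO3- + CO3^2-), the
# ionization fractions follow from the dissociation constants, and
# alkalinity is the standard charge-equivalent sum
#   TA = [HCO3-] + 2 [CO3^2-] + [OH-] - [H+].
# CO2* (dissolved CO2 + H2CO3) carries no charge and does not contribute.

#' Carbonate speciation at fixed pH and DIC
#'
#' Distributes total dissolved inorganic carbon over CO2*, HCO3- and
#' CO3^2- using the closed-form ionization fractions, and reports [OH-]
#' and [H+] from the water ion product.
#'
#' @param pH Porewater pH (0 < pH < 14).
#' @param dic Total dissolved inorganic carbon, uM.
#' @param constants A [carbonate_constants()] object.
#' @return List of class `speciation_result` with components `co2_star`,
#'   `hco3`, `co3`, `oh`, `h`, all in uM.  The carbon species sum to
#'   `dic` to machine precision.
#' @examples
#' sp <- carbonate_speciation(7.0, 5500)
#' sp$hco3  # ~4434 uM (alpha1 ~ 0.806)
#' @export
carbonate_speciation <- function(pH, dic, constants = carbonate_constants()) {
  if (any(!is.finite(pH)) || any(pH <= 0) || any(pH >= 14))
    stop("pH out of (0, 14): ", paste(pH[pH <= 0 | pH >= 14], collapse = ", "))
  if (any(dic < 0)) stop("dic must be >= 0")
  h_molar <- 10^(-pH)                       # mol/L
  K1 <- constants$K1; K2 <- constants$K2; Kw <- constants$Kw
  # ionization fractions alpha0 (CO2*), alpha1 (HCO3-), alpha2 (CO3^2-)
  denom <- h_molar^2 + h_molar * K1 + K1 * K2
  a0 <- h_molar^2 / denom
  a1 <- h_molar * K1 / denom
  a2 <- K1 * K2 / denom
  structure(list(co2_star = a0 * dic,
                 hco3     = a1 * dic,
                 co3      = a2 * dic,
                 oh       = Kw / h_molar * 1e6,   # uM
                 h        = h_molar * 1e6),       # uM
            class = "speciation_result")
}

#' Alkalinity from pH at constant DIC
#'
#' Computes total alkalinity [HCO3-] + 2[CO3^2-] + [OH-] - [H+] in
#' charge-equivalent uM, from carbonate speciation at the given pH and
#' DIC.  May be negative at very low pH.  Strictly increasing in pH at
#' fixed DIC, which makes it invertible (see [ph_from_alkalinity()]).
#'
#' @inheritParams carbonate_speciation
#' @return Alkalinity in uM charge equivalents.
#' @examples
#' alkalinity_from_ph(7.0, 5500)  # ~4438 uM
#' @export
alkalinity_from_ph <- function(pH, dic, constants = carbonate_constants()) {
  sp <- carbonate_speciation(pH, dic, constants)
  sp$hco3 + 2 * sp$co3 + sp$oh - sp$h
}

#' Invert alkalinity to pH at constant DIC
#'
#' Finds the pH at which [alkalinity_from_ph()] equals the target value,
#' by bisection on the (strictly monotone) alkalinity-pH relation.
#'
#' @param alkalinity Target alkalinity, uM charge equivalents (may be a
#'   vector).
#' @param dic Dissolved inorganic carbon, uM.
#' @param constants A [carbonate_constants()] object.
#' @param interval pH search interval.
#' @param tol Absolute pH tolerance of the bisection.
#' @return pH value(s).
#' @export
ph_from_alkalinity <- function(alkalinity, dic,
                               constants = carbonate_constants(),
                               interval = c(2, 12), tol = 1e-10) {
  vapply(alkalinity, function(a) {
    f <- function(p) alkalinity_from_ph(p, dic, constants) - a
    lo <- interval[1]; hi <- interval[2]
    if (f(lo) > 0 || f(hi) < 0)
      stop("alkalinity ", a, " uM not attainable for pH in [",
           lo, ", ", hi, "] at DIC ", dic, " uM")
    stats::uniroot(f, c(lo, hi), tol = tol)$root
  }, numeric(1))
}
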