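# LDET diagnostics: oxygen penetration depth, diffusive oxygen uptake,
# pH extrema, suboxic zone geometry, cathodic proton consumption, current
# density, cathodic oxygen consumption, sulfate recycling, and ATP-based
# cell densities.

# linear interpolation of the first downward crossing below `threshold`
# that stays below at the next measured point; returns NA if none.
.first_crossing_below <- function(depths, values, threshold) {
  n <- length(values)
  for (i in seq_len(n - 1)) {
    if (values[i] >= threshold && values[i + 1] < threshold) {
      # require it to stay below at the following measured point too,
      # when one exists
      if (i + 2 <= n && values[i + 2] >= threshold) next
      if (values[i] == threshold) return(depths[i])
      return(depths[i] + (depths[i + 1] - depths[i]) *
               (values[i] - threshold) / (values[i] - values[i + 1]))
    }
  }
  NA_real_
}

#' Oxygen penetration depth
#'
#' Shallowest in-sediment depth at which linearly interpolated O2 first
#' falls below the detection threshold and stays below at the next
#' measured point.  A profile entirely below threshold gives 0; a profile
#' never below threshold returns the bottom depth with qc flag
#' `"not_reached"`.
#'
#' @param o2 An O2 [depth_profile()] (uM).
#' @param threshold Detection threshold, uM (default 0.3).
#' @return Depth in mm with attribute `qc_flags` (character vector).
#' @examples
#' p <- depth_profile(c(0, 4, 8), c(280, 140, 0), "O2")
#' oxygen_penetration_depth(p)  # ~7.99 mm
#' @export
oxygen_penetration_depth <- function(o2, threshold = 0.3) {
  sel <- o2$depths >= 0
  if (!any(sel)) stop("O2 profile has no in-sediment (depth >= 0) points")
  d <- o2$depths[sel]; v <- o2$values[sel]
  if (v[1] < threshold) return(structure(0, qc_flags = character()))
  opd <- .first_crossing_below(d, v, threshold)
  if (is.na(opd))
    return(structure(max(d), qc_flags = "not_reached"))
  structure(opd, qc_flags = character())
}

#' Diffusive oxygen uptake
#'
#' Downward diffusive O2 flux into the sediment from the near-surface
#' gradient, porosity applied.  The default fitting window spans the top
#' `min(2 mm, OPD/8)` of the sediment (widened to at least 3 points),
#' where the profile is closest to linear; fluxes computed deeper into a
#' consumption-bearing profile understate the surface gradient.
#'
#' @param o2 An O2 [depth_profile()].
#' @param core A [sediment_core()].
#' @param window Optional explicit window `c(min, max)` mm; `NULL` for
#'   the automatic near-surface window.
#' @param in_sediment Apply porosity (default `TRUE`); set `FALSE` to
#'   treat the window as a diffusive-boundary-layer gradient.
#' @param constants A [physical_constants()] object.
#' @return A `flux_estimate` (see [diffusive_flux()]); positive values
#'   are uptake into the sediment.
#' @export
diffusive_oxygen_uptake <- function(o2, core, window = NULL,
                                    in_sediment = TRUE,
                                    constants = physical_constants()) {
  if (is.null(window)) {
    opd <- oxygen_penetration_depth(o2)
    top <- min(2, max(as.numeric(opd) / 8, 1e-9))
    d_in <- o2$depths[o2$depths >= 0]
    if (length(d_in) < 3) stop("need >= 3 in-sediment O2 points")
    top <- max(top, d_in[3])        # ensure at least 3 points
    window <- c(0, top)
  }
  g <- fit_linear_gradient(o2, window)
  diffusive_flux(g, "O2", core, in_sediment = in_sediment,
                 constants = constants)
}

#' Locate the oxic pH maximum and deeper pH minimum
#'
#' The LDET signature is a pH maximum inside the oxic zone (cathodic
#' proton consumption) and a pH minimum below it in the sulfidic zone
#' (anodic proton release).  A moving-average smoother (default 3
#' points) is applied before locating the extrema; the reported values
#' are the unsmoothed measurements at the located depths.  Ties break
#' toward the shallower depth.  A pH profile with its maximum at the
#' shallowest point (no interior maximum) raises qc flag
#' `"no_LDET_signature"`.
#'
#' @param ph A pH [depth_profile()].
#' @param opd Oxygen penetration depth, mm.
#' @param opd_tolerance Depth slack (mm) allowed beyond the OPD when
#'   searching for the oxic maximum (default 2).
#' @param smooth Moving-average window in points (odd; 1 disables).
#' @return List with `ph_max = c(depth, pH)`, `ph_min = c(depth, pH)`
#'   and `qc_flags`.
#' @export
detect_ph_extrema <- function(ph, opd, opd_tolerance = 2, smooth = 3) {
  d <- ph$depths; v <- ph$values
  vs <- if (smooth > 1 && length(v) >= smooth) {
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(v, k, sides = 2)
    ifelse(is.na(sm), v, as.numeric(sm))
  } else v
  qc <- character()
  oxic <- which(d <= as.numeric(opd) + opd_tolerance)
  if (!length(oxic)) oxic <- seq_along(d)
  i_max <- oxic[which.max(vs[oxic])]          # which.max breaks ties low
  if (i_max == 1) qc <- c(qc, "no_LDET_signature")
  below <- which(d > d[i_max])
  if (length(below)) {
    i_min <- below[which.min(vs[below])]
  } else {
    i_min <- length(d); qc <- c(qc, "no_points_below_ph_max")
  }
  list(ph_max = c(depth = d[i_max], pH = v[i_max]),
       ph_min = c(depth = d[i_min], pH = v[i_min]),
       qc_flags = qc)
}

#' Bounds of the suboxic zone
#'
#' The suboxic zone is the depth interval with neither detectable O2 nor
#' detectable sulfide: top = oxygen penetration depth, bottom =
#' shallowest depth where interpolated sulfide exceeds its threshold.
#' When the sulfide profile is coarse (sliced cores), the bottom carries
#' an uncertainty half-interval equal to the local slice width, since
#' coarse sampling can only underestimate the zone width.
#'
#' @param o2 An O2 [depth_profile()].
#' @param h2s A sulfide [depth_profile()] (total dissolved sulfide, uM).
#' @param o2_threshold O2 detection threshold, uM.
#' @param h2s_threshold Sulfide detection threshold, uM (default 1).
#' @return List with `top`, `bottom`, `width` (mm),
#'   `bottom_uncertainty` (mm half-interval) and `qc_flags`.
#' @export
suboxic_zone_bounds <- function(o2, h2s, o2_threshold = 0.3,
                                h2s_threshold = 1) {
  top <- as.numeric(oxygen_penetration_depth(o2, o2_threshold))
  qc <- character()
  d <- h2s$depths; v <- h2s$values
  if (all(v <= h2s_threshold)) {
    return(list(top = top, bottom = NA_real_, width = NA_real_,
                bottom_uncertainty = NA_real_,
                qc_flags = "no_sulfide_detected"))
  }
  if (v[1] > h2s_threshold) {
    bottom <- top; qc <- c(qc, "overlap")
  } else {
    i <- which(v > h2s_threshold)[1]
    bottom <- d[i - 1] + (d[i] - d[i - 1]) *
      (h2s_threshold - v[i - 1]) / (v[i] - v[i - 1])
    if (bottom < top) { bottom <- top; qc <- c(qc, "overlap") }
  }
  # local sampling interval around the sulfide appearance depth
  i_near <- which.min(abs(d - bottom))
  gaps <- diff(d)
  local_gap <- if (i_near == 1) gaps[1] else gaps[max(i_near - 1, 1)]
  list(top = top, bottom = bottom, width = bottom - top,
       bottom_uncertainty = local_gap / 2, qc_flags = qc)
}

#' Alkalinity profile from a pH profile at constant DIC
#'
#' Pointwise [alkalinity_from_ph()] at every pH measurement depth,
#' assuming DIC is constant with depth (the buffering assumption under
#' which alkalinity fluxes are computed).
#'
#' @param ph A pH [depth_profile()].
#' @param core A [sediment_core()] supplying `dic`.
#' @param constants A [carbonate_constants()] object.
#' @return An alkalinity [depth_profile()] (uM charge equivalents).
#' @export
alkalinity_profile <- function(ph, core, constants = carbonate_constants()) {
  alk <- vapply(ph$values, alkalinity_from_ph, numeric(1),
                dic = core$dic, constants = constants)
  depth_profile(ph$depths, alk, "alkalinity",
                resolution_note = paste0("derived from pH at DIC ",
                                         core$dic, " uM"))
}

# species-resolved alkalinity flux over one window of a pH profile:
# each alkalinity-carrying species (HCO3- x1, CO3^2- x2, OH- x1, H+ x-1)
# is speciated at the local pH and constant DIC, its own OLS gradient is
# fitted, and its diffusive flux taken with its own diffusivity.
.alkalinity_flux_window <- function(ph, core, window,
                                    carb = carbonate_constants(),
                                    phys = physical_constants()) {
  weights <- c(hco3 = 1, co3 = 2, oh = 1, h = -1)
  species_names <- c(hco3 = "HCO3", co3 = "CO3", oh = "OH", h = "H")
  sel <- ph$depths >= window[1] & ph$depths <= window[2]
  if (sum(sel) < 2)
    stop("alkalinity flux window [", window[1], ", ", window[2],
         "] mm contains ", sum(sel), " point(s); need >= 2")
  total <- 0
  for (sp in names(weights)) {
    conc <- vapply(ph$values, function(p)
      carbonate_speciation(p, core$dic, carb)[[sp]], numeric(1))
    prof <- depth_profile(ph$depths, conc, "other")
    g <- fit_linear_gradient(prof, window)
    fx <- diffusive_flux(g, species_names[[sp]], core, in_sediment = TRUE,
                         constants = phys)
    total <- total + weights[[sp]] * fx$flux
  }
  total   # umol charge-equivalents m^-2 day^-1, positive downward
}

#' Cathodic proton consumption from convergent alkalinity fluxes
#'
#' Cathodic O2 reduction consumes protons and hence produces alkalinity
#' at the oxic pH maximum; at steady state that production equals the
#' alkalinity transported away from the maximum in both directions.  CPC
#' is computed as the sum of the species-resolved alkalinity fluxes
#' above and below the pH maximum, both taken in the direction away from
#' it: `CPC = J_below - J_above` with fluxes positive downward.  Each
#' species flux is `phi * D0(species) * d[species]/dx` with speciation at
#' the local pH and constant DIC.
#'
#' Default windows: from the sediment surface to the pH maximum (above)
#' and from the pH maximum to OPD + 5 mm (below).  If either component
#' points toward rather than away from the maximum the result is clipped
#' at 0 and flagged.
#'
#' @param ph A pH [depth_profile()] (CPC is computed from pH via
#'   speciation, not from a pre-computed alkalinity profile, so each
#'   species can carry its own diffusivity).
#' @param ph_max_depth Depth of the oxic pH maximum, mm; must lie
#'   strictly inside the profile range.
#' @param core A [sediment_core()].
#' @param opd Oxygen penetration depth, mm (sets the default lower
#'   window).
#' @param windows Optional list `list(above = c(..), below = c(..))`
#'   overriding the defaults.
#' @param carb,phys Constants objects.
#' @return CPC in umol H+ m^-2 day^-1 (>= 0), with attributes `windows`,
#'   `components` (the two signed fluxes) and `qc_flags`.
#' @export
cathodic_proton_consumption <- function(ph, ph_max_depth, core, opd = NULL,
                                        windows = NULL,
                                        carb = carbonate_constants(),
                                        phys = physical_constants()) {
  rng <- range(ph$depths)
  if (ph_max_depth <= rng[1] || ph_max_depth >= rng[2])
    stop("ph_max_depth ", ph_max_depth,
         " mm is not strictly inside the pH profile range")
  if (is.null(windows)) {
    lower_end <- if (!is.null(opd)) min(as.numeric(opd) + 5, rng[2]) else rng[2]
    windows <- list(above = c(max(0, rng[1]), ph_max_depth),
                    below = c(ph_max_depth, lower_end))
  }
  j_above <- .alkalinity_flux_window(ph, core, windows$above, carb, phys)
  j_below <- .alkalinity_flux_window(ph, core, windows$below, carb, phys)
  qc <- character()
  # divergence from the maximum: upward (negative) above, downward
  # (positive) below
  if (j_above > 0) qc <- c(qc, "above_component_not_divergent")
  if (j_below < 0) qc <- c(qc, "below_component_not_divergent")
  cpc <- max(j_below - j_above, 0)
  structure(cpc, windows = windows,
            components = c(above = j_above, below = j_below),
            qc_flags = qc)
}

#' Electric current density from cathodic proton consumption
#'
#' One electron is consumed per proton at the cathode (O2 + 4H+ + 4e- ->
#' 2H2O), so CPC converted to mol e- m^-2 s^-1 and divided by the
#' inverse-Faraday conversion factor (1.036e-5 mol e- s^-1 A^-1) gives
#' the current density.
#'
#' @param cpc Cathodic proton consumption, umol H+ m^-2 day^-1 (>= 0).
#' @param constants A [physical_constants()] object.
#' @return Current density in mA m^-2.
#' @examples
#' current_density_from_cpc(1360)  # ~1.5 mA m^-2
#' @export
current_density_from_cpc <- function(cpc, constants = physical_constants()) {
  if (any(cpc < 0)) stop("cpc must be >= 0")
  mol_e_per_m2_s <- cpc * 1e-6 / 86400
  1000 * mol_e_per_m2_s / constants$faraday_inverse
}

#' Cathodic oxygen consumption from CPC
#'
#' Four protons are consumed per O2 molecule reduced, so
#' `COC = CPC * 0.25`.
#'
#' @param cpc Cathodic proton consumption, umol H+ m^-2 day^-1 (>= 0).
#' @return COC in umol O2 m^-2 day^-1.
#' @examples
#' cathodic_oxygen_consumption(1360)  # 340
#' @export
cathodic_oxygen_consumption <- function(cpc) {
  if (any(cpc < 0)) stop("cpc must be >= 0")
  cpc * 0.25
}

#' Theoretical sulfate recycling from cathodic oxygen consumption
#'
#' Each O2 reduced at the cathode accepts 4 electrons; complete anodic
#' oxidation of sulfide to sulfate releases 8 electrons per sulfide, so
#' the sulfate regenerated per O2 is 4/8 = 1/2:
#' `recycling = COC * 4 / electrons_per_sulfate`.
#'
#' @param coc Cathodic oxygen consumption, umol O2 m^-2 day^-1 (>= 0).
#' @param constants A [physical_constants()] object; override
#'   `electrons_per_sulfate` for partial oxidation products by passing a
#'   modified constants list.
#' @param electrons_per_sulfate Electrons per sulfur oxidized (default
#'   from `constants`; 8 for full oxidation to sulfate, 2 for S0).
#' @return Sulfate recycling in umol SO4^2- m^-2 day^-1.
#' @examples
#' sulfate_recycling_rate(340)  # 170
#' @export
sulfate_recycling_rate <- function(coc, constants = physical_constants(),
                                   electrons_per_sulfate =
                                     constants$electrons_per_sulfate) {
  if (any(coc < 0)) stop("coc must be >= 0")
  coc * 4 / electrons_per_sulfate
}

#' Cell density from intracellular ATP
#'
#' Intracellular ATP = total ATP - extracellular ATP; cell numbers follow
#' from the average cell quota of 1.75e-10 nmol ATP per cell.  For
#' sediment samples no extracellular correction is applied (pass 0).
#'
#' @param total_atp Total ATP, nmol per ml (or per g for sediment).
#' @param extracellular_atp Extracellular ATP in the same units (0 for
#'   sediment samples).
#' @param constants A [physical_constants()] object.
#' @return Cells per ml (or per g).
#' @examples
#' cells_from_atp(5.25e-4)  # 3e6 cells/ml
#' @export
cells_from_atp <- function(total_atp, extracellular_atp = 0,
                           constants = physical_constants()) {
  if (any(extracellular_atp < 0)) stop("extracellular ATP must be >= 0")
  if (any(extracellular_atp > total_atp))
    stop("extracellular ATP exceeds total ATP")
  (total_atp - extracellular_atp) / constants$atp_per_cell
}
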