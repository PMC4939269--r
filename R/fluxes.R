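# Gradient fitting and diffusive fluxes (Fick's first law with porosity).
#
# Flux sign convention: positive downward (into the sediment).  With
# depth x positive downward, J = -phi * D0 * dC/dx, so an analyte
# decreasing with depth (negative slope) gives a positive downward flux.

#' Fit a linear concentration gradient over a depth window
#'
#' Ordinary least squares line through all profile points inside the
#' closed window; the slope is the dC/dx term of the flux calculation.
#'
#' @param profile A [depth_profile()].
#' @param window Numeric pair `c(depth_min, depth_max)` in mm.
#' @return An object of class `gradient_fit` with `slope` (uM/mm),
#'   `intercept` (uM at depth 0), `window`, `n_points` and `rmse`.
#' @examples
#' p <- depth_profile(c(0, 4, 8), c(280, 140, 0), "O2")
#' fit_linear_gradient(p, c(0, 8))$slope  # -35
#' @export
fit_linear_gradient <- function(profile, window) {
  stopifnot(length(window) == 2, all(is.finite(window)))
  window <- sort(window)
  sel <- profile$depths >= window[1] & profile$depths <= window[2]
  if (sum(sel) < 2)
    stop("gradient window [", window[1], ", ", window[2],
         "] mm contains ", sum(sel), " point(s); need >= 2")
  x <- profile$depths[sel]; y <- profile$values[sel]
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 window = window, n_points = sum(sel),
                 rmse = sqrt(mean(fit$residuals^2))),
            class = "gradient_fit")
}

#' Diffusive flux from a fitted gradient
#'
#' Fick's first law for porewater: `J = -phi * D0 * dC/dx` inside the
#' sediment (porosity applied), or `J = -D0 * dC/dx` in the overlying
#' water / diffusive boundary layer.  The unit factor 8.64e6 converts
#' `(cm^2 s^-1) * (uM mm^-1)` to `umol m^-2 day^-1`.
#'
#' @param gradient A [fit_linear_gradient()] result.
#' @param species Species name with a tabulated diffusivity (see
#'   [physical_constants()]).
#' @param core A [sediment_core()] supplying porosity and temperature.
#' @param in_sediment Apply porosity? (`TRUE` for in-sediment windows.)
#' @param constants A [physical_constants()] object.
#' @return An object of class `flux_estimate` with `flux` in
#'   umol m^-2 day^-1 (positive downward), the gradient, and the
#'   diffusivity used.
#' @examples
#' p <- depth_profile(c(0, 4, 8), c(280, 140, 0), "O2")
#' core <- sediment_core(list(O2 = p), porosity = 0.34)
#' g <- fit_linear_gradient(p, c(0, 8))
#' diffusive_flux(g, "O2", core)$flux  # ~2118 umol O2 m^-2 day^-1 downward
#' @export
diffusive_flux <- function(gradient, species, core, in_sediment = TRUE,
                           constants = physical_constants()) {
  D0 <- diffusivity_at_temperature(species, core$temperature, constants)
  phi <- if (in_sediment) core$porosity else 1
  flux <- -.FLUX_UNIT_FACTOR * phi * D0 * gradient$slope
  structure(list(species = species, flux = flux, gradient = gradient,
                 porosity_applied = in_sediment, D0 = D0),
            class = "flux_estimate")
}
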