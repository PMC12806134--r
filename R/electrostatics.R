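# Transmembrane electrostatic potential by double integration of the
# charge density along the membrane normal.

#' Electrostatic potential profile from a charge density
#'
#' Solves the 1-D Poisson equation by double cumulative trapezoid
#' integration of the charge density from the lower box edge, with
#' `psi = 0` and `dpsi/dz = 0` there:
#' `psi(z) = -(1/eps0) int int rho_q`. Charges are explicit, so the
#' relative permittivity is 1. No periodic dipole correction is applied:
#' the reported quantity downstream is a region *difference*, for which the
#' correction cancels in symmetric setups (documented approximation).
#'
#' @param charge_density a charge-weighted [density_profile()] on a uniform
#'   grid (e/nm^3)
#' @return an object of class `"potential_profile"`: data.frame with `z`
#'   (nm), `rho` (e/nm^3) and `psi` (mV); attribute `reference`
#' @export
potential_profile <- function(charge_density) {
  if (!inherits(charge_density, "density_profile") ||
      attr(charge_density, "weight") != "charge")
    stop("potential_profile() needs a charge-weighted density profile")
  z <- charge_density$z
  dzs <- diff(z)
  if (max(abs(dzs - dzs[1L])) > 1e-9) stop("non-uniform grid")
  rho <- charge_density$density
  efield <- pracma::cumtrapz(z, rho)             # e/nm^2 (up to 1/eps0)
  psi <- -.POTENTIAL_MV * pracma::cumtrapz(z, as.numeric(efield))
  out <- data.frame(z = z, rho = rho, psi = as.numeric(psi))
  structure(out, class = c("potential_profile", "data.frame"),
            reference = "psi = 0, dpsi/dz = 0 at the lower box edge")
}

#' Interior / exterior region bounds
#'
#' Regions are defined by `|z|`: the interior is `|z| < interior`, the
#' exterior `|z| > exterior`. Defaults follow the double-bilayer
#' two-compartment convention (interior 3 nm, exterior 11 nm); override for
#' smaller boxes.
#'
#' @param interior interior `|z|` bound, nm
#' @param exterior exterior `|z|` bound, nm (must exceed `interior`)
#' @return an object of class `"region_spec"`
#' @export
region_spec <- function(interior = 3, exterior = 11) {
  if (!(interior < exterior))
    stop("interior bound must be smaller than the exterior bound")
  structure(list(interior = interior, exterior = exterior),
            class = "region_spec")
}

#' Potential difference between exterior and interior regions
#'
#' `delta_psi = mean psi over the exterior minus mean psi over the
#' interior`; positive when the exterior potential is higher. The result is
#' reference-free (any constant offset of `psi` cancels).
#'
#' @param profile a [potential_profile()]
#' @param regions a [region_spec()]
#' @return potential difference, mV
#' @export
region_potential_difference <- function(profile, regions = region_spec()) {
  if (!inherits(regions, "region_spec")) regions <- do.call(region_spec, as.list(regions))
  int_mask <- abs(profile$z) < regions$interior
  ext_mask <- abs(profile$z) > regions$exterior
  if (sum(int_mask) < 3L) stop("interior region contains fewer than 3 grid points")
  if (sum(ext_mask) < 3L) stop("exterior region contains fewer than 3 grid points")
  mean(profile$psi[ext_mask]) - mean(profile$psi[int_mask])
}
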