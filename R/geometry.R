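#' Cylindrical geometry of a peri-synaptic astrocyte projection
#'
#' The projection (PAP) is idealized as a cylinder whose axis runs from the
#' membrane contacting the post-synaptic density (the alpha face, the IP3
#' source) to the Ca2+ stores (the beta face). Defaults are the model values:
#' length 1000 nm (measured PSD-to-store distance) and diameter 100 nm (upper
#' limit of reported PAP thickness). Because diffusion is treated in one
#' dimension along the axis, the cross-sectional shape is immaterial; only
#' the volume and axial length enter the analysis.
#'
#' @param length_nm Cylinder length L in nanometres.
#' @param diameter_nm Cylinder diameter D in nanometres.
#' @return An object of class `papm_geometry`.
#' @export
#' @examples
#' geom <- papm_geometry()
#' cylinder_volume(geom)$litres
papm_geometry <- function(length_nm = 1000, diameter_nm = 100) {
  check_positive(length_nm, "length_nm")
  check_positive(diameter_nm, "diameter_nm")
  structure(
    list(length_nm = length_nm, diameter_nm = diameter_nm),
    class = "papm_geometry"
  )
}

#' @export
print.papm_geometry <- function(x, ...) {
  v <- cylinder_volume(x)
  cat(sprintf(
    "PAP cylinder: L = %g nm, D = %g nm, V = %.4e L\n",
    x$length_nm, x$diameter_nm, v$litres
  ))
  invisible(x)
}

#' Physical constants of the diffusion model
#'
#' @param dab_um2_s Cytosolic diffusion coefficient of IP3 in um^2/s. Default
#'   300, the classical estimate; a disputed alternative of 10 um^2/s slows
#'   every time scale 30-fold but leaves the dimensionless solution unchanged.
#' @param degradation_horizon_s Earliest reported time for IP3 degradation to
#'   become relevant, in seconds (default 0.8). The synthesis model assumes no
#'   removal and is only trusted below this horizon.
#' @param avogadro Avogadro constant in 1/mol (exact SI value).
#' @return An object of class `papm_constants`.
#' @export
papm_constants <- function(dab_um2_s = 300, degradation_horizon_s = 0.8,
                           avogadro = 6.02214076e23) {
  check_positive(dab_um2_s, "dab_um2_s")
  check_positive(degradation_horizon_s, "degradation_horizon_s")
  check_positive(avogadro, "avogadro")
  structure(
    list(
      dab_um2_s = dab_um2_s,
      degradation_horizon_s = degradation_horizon_s,
      avogadro = avogadro
    ),
    class = "papm_constants"
  )
}

#' Internal volume of the projection cylinder
#'
#' V = pi * D^2 * L / 4, returned both in cubic metres and litres. For the
#' default geometry this is 7.8539e-21 m^3 = 7.8539e-18 L, i.e. about eight
#' zeptolitres -- the volume scale at which micromolar concentrations
#' correspond to single-digit molecule numbers.
#'
#' @param geom A [papm_geometry()].
#' @return A list with elements `m3` and `litres`.
#' @export
cylinder_volume <- function(geom = papm_geometry()) {
  stopifnot(inherits(geom, "papm_geometry"))
  v_nm3 <- pi * geom$diameter_nm^2 * geom$length_nm / 4
  m3 <- v_nm3 * 1e-27 # 1 nm^3 = 1e-27 m^3
  list(m3 = m3, litres = m3 * 1e3)
}

#' Convert molar concentration to an expected molecule count
#'
#' `n = conc * volume * N_A`. The result is real-valued: whether and how to
#' round to whole molecules is the caller's policy (see
#' [allocate_molecules()] and [round_count()]).
#'
#' @param conc_molar Concentration in mol/L (vectorized).
#' @param volume_l Volume in litres.
#' @param avogadro Avogadro constant in 1/mol.
#' @return Expected number of molecules (real-valued).
#' @export
#' @examples
#' v <- cylinder_volume()$litres
#' concentration_to_molecules(1e-6, v) # ~4.73 molecules at 1 uM
concentration_to_molecules <- function(conc_molar, volume_l,
                                       avogadro = 6.02214076e23) {
  check_nonnegative(conc_molar, "conc_molar")
  check_positive(volume_l, "volume_l")
  conc_molar * volume_l * avogadro
}

#' Convert a molecule count to molar concentration
#'
#' Exact inverse of [concentration_to_molecules()]. For the default
#' projection volume, one molecule corresponds to about 0.21 uM, which is why
#' sub-0.2 uM concentrations in this compartment mean "no molecule at all".
#'
#' @param n Number of molecules (need not be an integer).
#' @param volume_l Volume in litres.
#' @param avogadro Avogadro constant in 1/mol.
#' @return Concentration in mol/L.
#' @export
molecules_to_concentration <- function(n, volume_l,
                                       avogadro = 6.02214076e23) {
  check_nonnegative(n, "n")
  check_positive(volume_l, "volume_l")
  n / (volume_l * avogadro)
}

#' Concentration-to-molecule conversion table for the projection volume
#'
#' Tabulates how many molecules a set of molar concentrations corresponds to
#' in the cylinder volume (1 M down to 1 nM by default, spanning 4.73e6 down
#' to 4.73e-3 molecules for the default geometry).
#'
#' @param concentrations_molar Concentrations in mol/L.
#' @param geom A [papm_geometry()].
#' @param avogadro Avogadro constant in 1/mol.
#' @return A data frame with columns `concentration_molar` and `molecules`.
#' @export
conversion_table <- function(concentrations_molar = c(1, 1e-3, 1e-6, 1e-9),
                             geom = papm_geometry(),
                             avogadro = 6.02214076e23) {
  v <- cylinder_volume(geom)$litres
  data.frame(
    concentration_molar = concentrations_molar,
    molecules = concentration_to_molecules(concentrations_molar, v, avogadro)
  )
}
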