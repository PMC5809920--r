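#' IP3 receptor geometry at the Ca2+ store face
#'
#' Back-of-envelope parameters for how many IP3 receptor (IP3R) channels can
#' physically face the projection, and how much IP3 their activation needs.
#' The receptor footprint in the membrane plane is ~380 nm^2 (from the
#' cryo-EM structure, PDB 3jav); the store membrane area available is taken
#' as the projection cross-section pi*D^2/4, computed from the geometry
#' (~7854 nm^2 for D = 100 nm). Since other proteins -- notably ryanodine
#' receptors -- share that face, only a fraction (default one half) is
#' assumed available to IP3R. A tetrameric IP3R requires four bound IP3 to
#' gate.
#'
#' @param ip3r_footprint_nm2 Membrane-plane area of one IP3R, nm^2.
#' @param geometry A [papm_geometry()]; sets the cross-section.
#' @param sharing_fraction Fraction of the store face available to IP3R,
#'   in (0, 1].
#' @param ip3_per_receptor IP3 molecules needed to activate one receptor.
#' @return An object of class `papm_receptor_params` with the derived
#'   `cross_section_nm2`.
#' @export
#' @examples
#' p <- receptor_params()
#' max_ip3r(p)            # 20
#' effective_ip3r(p)      # 10
#' ip3_to_activate_pool(p) # 40
receptor_params <- function(ip3r_footprint_nm2 = 380,
                            geometry = papm_geometry(),
                            sharing_fraction = 0.5,
                            ip3_per_receptor = 4) {
  check_positive(ip3r_footprint_nm2, "ip3r_footprint_nm2")
  check_positive(ip3_per_receptor, "ip3_per_receptor")
  if (!is.numeric(sharing_fraction) || length(sharing_fraction) != 1L ||
      sharing_fraction <= 0 || sharing_fraction > 1) {
    stop_invalid("sharing_fraction must lie in (0, 1]")
  }
  structure(
    list(
      ip3r_footprint_nm2 = ip3r_footprint_nm2,
      cross_section_nm2 = pi * geometry$diameter_nm^2 / 4,
      sharing_fraction = sharing_fraction,
      ip3_per_receptor = ip3_per_receptor
    ),
    class = "papm_receptor_params"
  )
}

#' Receptor capacity and activation estimates
#'
#' `max_ip3r()` is the packing bound `floor(cross_section / footprint)`;
#' `effective_ip3r()` discounts it by the sharing fraction; and
#' `ip3_to_activate_pool()` is the IP3 needed to activate every effective
#' receptor (`effective * ip3_per_receptor`). With defaults: 20, 10 and 40.
#'
#' @param params A [receptor_params()].
#' @return Integer count.
#' @export
max_ip3r <- function(params = receptor_params()) {
  stopifnot(inherits(params, "papm_receptor_params"))
  floor(params$cross_section_nm2 / params$ip3r_footprint_nm2)
}

#' @rdname max_ip3r
#' @export
effective_ip3r <- function(params = receptor_params()) {
  floor(max_ip3r(params) * params$sharing_fraction)
}

#' @rdname max_ip3r
#' @export
ip3_to_activate_pool <- function(params = receptor_params()) {
  effective_ip3r(params) * params$ip3_per_receptor
}

#' Annotate a molecule table with receptor-activation thresholds
#'
#' Appends to an [ip3_table()] result two logical columns: whether the
#' near-store count reaches the single-receptor requirement
#' (`ip3_per_receptor`, default 4) and whether it reaches the full-pool
#' requirement ([ip3_to_activate_pool()], default 40).
#'
#' @param tbl Output of [ip3_table()].
#' @param params A [receptor_params()].
#' @return `tbl` with extra columns `near_beta_ge_4` and `near_beta_ge_pool`.
#' @export
receptor_thresholds <- function(tbl = ip3_table(), params = receptor_params()) {
  stopifnot(is.data.frame(tbl), "near_beta" %in% names(tbl))
  tbl$near_beta_ge_4 <- tbl$near_beta >= params$ip3_per_receptor
  tbl$near_beta_ge_pool <- tbl$near_beta >= ip3_to_activate_pool(params)
  tbl
}
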