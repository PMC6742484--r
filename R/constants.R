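#' Geometric and physical constants of the lattice model
#'
#' All geometric constants of the simulation live here, in nanometres.
#' The tubulin dimer footprint (8 nm axial repeat, ~5 nm tangential,
#' ~4.5 nm radial) and the canonical 13-protofilament B-lattice with a
#' 3-start helix are the field's standard values; the exact polygonal
#' shapes are this package's own approximations of the cryo-EM envelope.
#'
#' @format A named list:
#' \describe{
#'   \item{n_protofilaments}{13, the canonical protofilament number.}
#'   \item{lattice_radius}{Radius from the microtubule axis to dimer
#'     centres, nm.}
#'   \item{axial_repeat}{Axial dimer repeat, nm.}
#'   \item{helical_rise}{Rise per protofilament step of the 3-start
#'     helix, nm (12 nm per turn / 13 protofilaments).}
#'   \item{dimer_axial}{Axial extent of the dimer solid, nm.  Slightly
#'     shorter than the 8 nm repeat so that consecutive dimers in a
#'     protofilament do not touch.}
#'   \item{dimer_tangential}{Tangential (lateral) extent, nm.}
#'   \item{dimer_radial}{Radial extent, nm.}
#'   \item{dimer_chamfer}{Chamfer cut on the four axial edges, nm.}
#'   \item{anchor_axial, anchor_tangential, anchor_radial}{Body-frame
#'     coordinates (absolute values) of the pocket contact anchors: the
#'     mid-height of the four corner edges of the dimer.}
#'   \item{binder_bottom_halfwidth, binder_bottom_z, binder_top_halfwidth,
#'     binder_top_z}{Frustum dimensions of the binder solid, nm.}
#'   \item{binder_anchor_drop}{Distance from the binder centre to the
#'     plane of its pocket anchors along the binding axis, nm.}
#' }
#' @export
mt_constants <- function() {
  list(
    n_protofilaments  = 13L,
    lattice_radius    = 12.5,
    axial_repeat      = 8.0,
    helical_rise      = 12.0 / 13.0,
    dimer_axial       = 7.6,
    dimer_tangential  = 5.0,
    dimer_radial      = 4.5,
    dimer_chamfer     = 0.8,
    anchor_axial      = 3.8,
    anchor_tangential = 2.5,
    anchor_radial     = 0.0,
    binder_bottom_halfwidth = 0.45,
    binder_bottom_z   = -1.9,
    binder_top_halfwidth    = 1.1,
    binder_top_z      = 0.9,
    binder_anchor_drop = 2.1
  )
}

# Boltzmann constant, J/K
.kB <- 1.380649e-23
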