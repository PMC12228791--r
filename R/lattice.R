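#' Helical lattice of a microtubule
#'
#' Describes the pseudo-helical geometry of an N-protofilament microtubule:
#' the per-subunit twist and rise relating adjacent protofilaments, and the
#' monomer/dimer axial repeats that distinguish the two alpha/beta-tubulin
#' registers. Defaults are the standard 3-start B-lattice values for a
#' 13-protofilament microtubule (rise 9.46 A per subunit, twist -360/13 deg,
#' 82 A dimer repeat).
#'
#' @param n_pf protofilament count (>= 1).
#' @param twist_per_subunit degrees of rotation about the helical axis
#'   between laterally adjacent subunits; default \code{-360/n_pf}.
#' @param rise_per_subunit axial rise (Angstrom) between laterally adjacent
#'   subunits.
#' @param dimer_repeat axial length (Angstrom) of one alpha/beta-tubulin
#'   dimer; the monomer repeat is half of it.
#' @param monomer_repeat axial length (Angstrom) of one tubulin monomer;
#'   must equal \code{dimer_repeat/2} within 0.1 A.
#' @return object of class \code{helical_lattice}.
#' @examples
#' lat <- helical_lattice(13)
#' length(enumerate_seam_references(lat))  # 26
#' @export
helical_lattice <- function(n_pf,
                            twist_per_subunit = -360 / n_pf,
                            rise_per_subunit = 9.46,
                            dimer_repeat = 82,
                            monomer_repeat = dimer_repeat / 2) {
  if (!is.numeric(n_pf) || length(n_pf) != 1 || n_pf < 1 || n_pf != round(n_pf))
    stop("n_pf must be a positive integer")
  if (abs(dimer_repeat - 2 * monomer_repeat) > 0.1)
    stop("dimer_repeat must equal 2 * monomer_repeat within 0.1 A")
  structure(
    list(n_pf = as.integer(n_pf),
         twist_per_subunit = twist_per_subunit,
         rise_per_subunit = rise_per_subunit,
         monomer_repeat = monomer_repeat,
         dimer_repeat = dimer_repeat),
    class = "helical_lattice")
}

#' @export
print.helical_lattice <- function(x, ...) {
  cat(sprintf(
    "helical_lattice: %d pf, twist %.3f deg, rise %.3f A, dimer repeat %.1f A\n",
    x$n_pf, x$twist_per_subunit, x$rise_per_subunit, x$dimer_repeat))
  invisible(x)
}

#' Enumerate seam/register reference hypotheses
#'
#' A B-lattice microtubule with N protofilaments has a single seam, so a
#' filament's azimuthal assignment is ambiguous among N seam positions, each
#' further ambiguous by a one-monomer (~41 A) axial translation swapping the
#' alpha/beta register: 2N hypotheses in total (26 for a 13-protofilament
#' microtubule). Hypothesis k in [0, N) applies the k-th lattice rotation
#' \code{k * twist_per_subunit} with axial offset \code{k * rise_per_subunit};
#' hypothesis k + N is its counterpart translated one monomer along the
#' helical axis.
#'
#' @param lattice a [helical_lattice()].
#' @return list of \code{seam_hypothesis} objects, each with fields
#'   \code{index}, \code{delta_phi} (degrees), \code{delta_z} (Angstrom) and
#'   \code{description}.
#' @export
enumerate_seam_references <- function(lattice) {
  stopifnot(inherits(lattice, "helical_lattice"))
  n <- lattice$n_pf
  hyps <- vector("list", 2L * n)
  for (k in seq_len(n) - 1L) {
    dphi <- wrap_angle(k * lattice$twist_per_subunit)
    dz <- k * lattice$rise_per_subunit
    hyps[[k + 1L]] <- structure(
      list(index = k, delta_phi = dphi, delta_z = dz,
           description = sprintf("seam position %d, alpha/beta register 0", k)),
      class = "seam_hypothesis")
    hyps[[k + 1L + n]] <- structure(
      list(index = k + n, delta_phi = dphi,
           delta_z = dz + lattice$monomer_repeat,
           description = sprintf("seam position %d, alpha/beta register 1", k)),
      class = "seam_hypothesis")
  }
  hyps
}

#' @export
print.seam_hypothesis <- function(x, ...) {
  cat(sprintf("seam_hypothesis %d: dphi=%.3f deg, dz=%.2f A (%s)\n",
              x$index, x$delta_phi, x$delta_z, x$description))
  invisible(x)
}
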