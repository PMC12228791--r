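## Pose algebra: a particle pose maps reference-frame coordinates r to
## image coordinates x = A(rot,tilt,psi) r + t with t = (origin_x,
## origin_y, 0).  Lattice symmetry operators (rotation about the helical z
## axis plus axial translation) compose on the right, in the reference
## frame.

#' Compose a pose with a helical-axis rotation and axial translation
#'
#' Right-composition of a Relion pose with the reference-frame operator
#' "rotate \code{delta_phi} about z, translate \code{delta_z} along z".
#' Because the Euler convention is ZYZ, the rotation folds into rot; the
#' translation projects into the in-plane origins through the pose matrix.
#'
#' @param rot,tilt,psi Euler angles (degrees).
#' @param origin_x,origin_y in-plane shifts (Angstrom).
#' @param delta_phi rotation about the helical axis (degrees).
#' @param delta_z axial translation (Angstrom).
#' @return named vector \code{c(rot, tilt, psi, origin_x, origin_y)}.
#' @export
compose_pose <- function(rot, tilt, psi, origin_x, origin_y,
                         delta_phi = 0, delta_z = 0) {
  a <- euler_to_matrix(rot, tilt, psi)
  tz <- a %*% c(0, 0, delta_z)
  c(rot = wrap_angle(rot + delta_phi), tilt = tilt, psi = psi,
    origin_x = origin_x + tz[1], origin_y = origin_y + tz[2])
}

#' Symmetry-expand a filament table over the protofilament lattice
#'
#' Replicates each segment's pose by every lattice symmetry operator so that
#' each asymmetric unit (one tubulin dimer plus bound motor) can be treated
#' independently: the j-th copy composes the pose with rotation
#' \code{j * twist_per_subunit} about the helical axis and axial offset
#' \code{j * rise_per_subunit}. Output has \code{n_pf} times the input rows,
#' with a \code{subunit_index} column (j = 0 is the untouched original) and
#' a \code{parent_row} column linking back to the input.
#'
#' @param table a [filament_table()] with seam register assigned.
#' @param lattice a [helical_lattice()].
#' @return expanded [filament_table()]-like data.frame (segment indices are
#'   no longer unique per filament, so the result is a plain data.frame).
#' @export
symmetry_expand <- function(table, lattice) {
  stopifnot(inherits(table, "filament_table"),
            inherits(lattice, "helical_lattice"))
  n_pf <- lattice$n_pf
  out <- vector("list", n_pf)
  base <- as.data.frame(table)
  for (j in seq_len(n_pf) - 1L) {
    blk <- base
    blk$subunit_index <- j
    blk$parent_row <- seq_len(nrow(base))
    if (j > 0L) {
      for (i in seq_len(nrow(blk))) {
        pose <- compose_pose(base$rot[i], base$tilt[i], base$psi[i],
                             base$origin_x[i], base$origin_y[i],
                             delta_phi = j * lattice$twist_per_subunit,
                             delta_z = j * lattice$rise_per_subunit)
        blk$rot[i] <- pose["rot"]
        blk$origin_x[i] <- pose["origin_x"]
        blk$origin_y[i] <- pose["origin_y"]
      }
    }
    out[[j + 1L]] <- blk
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Re-centre extraction origins on a focused sub-particle
#'
#' Shifts each row's in-plane origin by the projection of the rotated
#' \code{focus_offset} (a fixed reference-frame vector, e.g. the
#' kinesin-tubulin interface of the asymmetric unit), so that re-extraction
#' boxes centre on the focus. The axial (projection-direction) component of
#' the rotated offset does not alter the in-plane origins. The operation is
#' exactly invertible with \code{invert = TRUE}.
#'
#' @param table data.frame with full pose columns (as from
#'   [symmetry_expand()]).
#' @param focus_offset numeric 3-vector (Angstrom) in the reference frame.
#' @param invert logical; undo a previous re-centring.
#' @return the table with updated \code{origin_x}, \code{origin_y}.
#' @export
subparticle_coords <- function(table, focus_offset, invert = FALSE) {
  stopifnot(length(focus_offset) == 3)
  sgn <- if (invert) -1 else 1
  for (i in seq_len(nrow(table))) {
    a <- euler_to_matrix(table$rot[i], table$tilt[i], table$psi[i])
    v <- a %*% focus_offset
    table$origin_x[i] <- table$origin_x[i] + sgn * v[1]
    table$origin_y[i] <- table$origin_y[i] + sgn * v[2]
  }
  table
}
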