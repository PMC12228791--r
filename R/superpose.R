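## Rigid-body superposition (Kabsch) and the comparison statistics built on
## it: global and per-residue RMSD, Calpha displacements in a chosen
## alignment frame, and the decomposition of inter-head rotations.

#' Kabsch least-squares rotation for paired coordinate sets
#' @param p,q n x 3 matrices (mobile, reference), already paired row-wise.
#' @return list(rotation, translation): x_ref ~ R x_mob + t.
#' @noRd
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv <- svd(t(pc) %*% qc)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = r, translation = as.numeric(cq - r %*% cp))
}

#' Match atoms between two models by (chain, resno, atom)
#' @noRd
match_atoms <- function(mobile, reference, selection, atoms, chain_map = NULL) {
  im <- select_atoms(mobile, selection, atoms)
  ir <- select_atoms(reference, selection, atoms)
  am <- mobile$atoms[im, ]; ar <- reference$atoms[ir, ]
  cm <- am$chain
  if (!is.null(chain_map)) cm <- ifelse(cm %in% names(chain_map),
                                        unlist(chain_map)[cm], cm)
  km <- paste(cm, am$resno, am$atom)
  kr <- paste(ar$chain, ar$resno, ar$atom)
  hit <- match(km, kr)
  keep <- !is.na(hit)
  if (!is.null(selection) && !any(keep))
    stop("selection matched no atom pairs between the models")
  list(mobile_idx = im[keep], reference_idx = ir[hit[keep]],
       unmatched = km[!keep])
}

#' Superpose a mobile model onto a reference
#'
#' Least-squares optimal rigid superposition (Kabsch) of the mobile model
#' onto the reference, restricted to a named selection and atom subset
#' (default Calpha). Atoms are paired by (chain, residue number, atom name);
#' mismatched residue names are tolerated (chimeric constructs share
#' numbering). The global RMSD is computed over the matched scoring set
#' after applying the fitted transform.
#'
#' @param mobile,reference [structure_model()] objects.
#' @param selection alignment selection (see [select_atoms()]); NULL uses
#'   all residues.
#' @param atoms atom subset for alignment and scoring, default "CA".
#' @param score_selection selection over which the global RMSD is scored;
#'   default the alignment selection itself. Use NULL to score all matched
#'   atoms.
#' @param chain_map optional named list mapping mobile chain ids to
#'   reference chain ids.
#' @return object of class \code{superposition_result}: list with
#'   \code{rotation} (3x3, det +1), \code{translation}, \code{selection},
#'   \code{rmsd_global}, \code{rmsd_per_residue}, \code{rotation_angle}
#'   (degrees), \code{rotation_axis}, \code{n_atoms}.
#' @export
superpose <- function(mobile, reference, selection = NULL, atoms = "CA",
                      score_selection = selection, chain_map = NULL) {
  mm <- match_atoms(mobile, reference, selection, atoms, chain_map)
  p <- as.matrix(mobile$atoms[mm$mobile_idx, c("x", "y", "z")])
  q <- as.matrix(reference$atoms[mm$reference_idx, c("x", "y", "z")])
  if (nrow(p) < 3) stop("fewer than 3 paired atoms; superposition underdetermined")
  sing <- svd(sweep(p, 2, colMeans(p)))$d
  if (sing[2] < 1e-6) stop("paired atoms are collinear; superposition underdetermined")
  fit <- kabsch(p, q)
  moved <- transform_model(mobile, fit$rotation, fit$translation)
  sm <- match_atoms(moved, reference, score_selection, atoms, chain_map)
  ps <- as.matrix(moved$atoms[sm$mobile_idx, c("x", "y", "z")])
  qs <- as.matrix(reference$atoms[sm$reference_idx, c("x", "y", "z")])
  dev2 <- rowSums((ps - qs)^2)
  res_key <- paste(reference$atoms$chain[sm$reference_idx],
                   reference$atoms$resno[sm$reference_idx])
  per_res <- sqrt(tapply(dev2, res_key, mean))
  aa <- rotation_angle_axis(fit$rotation)
  structure(
    list(rotation = fit$rotation, translation = fit$translation,
         selection = selection, atoms = atoms,
         rmsd_global = sqrt(mean(dev2)),
         rmsd_per_residue = per_res,
         rotation_angle = aa$angle, rotation_axis = aa$axis,
         axis_defined = aa$axis_defined,
         n_atoms = nrow(p)),
    class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf(
    "superposition over %d atoms (%s): rmsd %.3f A, rotation %.2f deg\n",
    x$n_atoms, if (is.null(x$selection)) "all residues" else
      paste(deparse(x$selection), collapse = ""), x$rmsd_global,
    x$rotation_angle))
  invisible(x)
}

#' Per-residue deviation map after a fitted superposition
#'
#' Applies an already-fitted rigid transform to the mobile model and reports
#' the per-residue RMS deviation over the chosen atom subset. When the
#' scoring sets coincide, the global RMSD is the quadratic mean of the
#' per-residue values weighted by atoms per residue.
#'
#' @param sup a \code{superposition_result}.
#' @param mobile,reference the models the superposition was fitted on.
#' @param selection residues to report; NULL for all matched.
#' @param atoms atom subset, default "CA".
#' @return named numeric vector, names "chain resno".
#' @export
per_residue_rmsd <- function(sup, mobile, reference, selection = NULL,
                             atoms = "CA") {
  moved <- transform_model(mobile, sup$rotation, sup$translation)
  mm <- match_atoms(moved, reference, selection, atoms)
  p <- as.matrix(moved$atoms[mm$mobile_idx, c("x", "y", "z")])
  q <- as.matrix(reference$atoms[mm$reference_idx, c("x", "y", "z")])
  dev2 <- rowSums((p - q)^2)
  res_key <- paste(reference$atoms$chain[mm$reference_idx],
                   reference$atoms$resno[mm$reference_idx])
  out <- tapply(dev2, res_key, mean)
  sqrt(out[unique(res_key)])
}

#' Calpha displacement of a residue in a chosen alignment frame
#'
#' Superposes the mobile model onto the reference using only the frame
#' selection (e.g. the P-loop / helix alpha-2a frame), then reports the
#' Euclidean distance between the residue's Calpha positions. This is the
#' statistic behind statements like "D231 is displaced by ~3 A relative to
#' the P-loop and helix alpha-2a".
#'
#' @param mobile,reference [structure_model()] objects.
#' @param residue residue number.
#' @param frame alignment selection, default the P-loop + helix alpha-2a
#'   frame \code{"PLOOP_A2A"}.
#' @param chain optional chain id of the residue.
#' @param atom atom name, default "CA".
#' @return displacement in Angstrom.
#' @export
ca_displacement <- function(mobile, reference, residue, frame = "PLOOP_A2A",
                            chain = NULL, atom = "CA") {
  sup <- superpose(mobile, reference, selection = frame)
  moved <- transform_model(mobile, sup$rotation, sup$translation)
  sel <- if (is.null(chain)) list(resno = residue) else
    list(chain = chain, resno = residue)
  im <- select_atoms(moved, sel, atom)
  ir <- select_atoms(reference, sel, atom)
  if (length(im) != 1 || length(ir) != 1)
    stop("residue ", residue, " ", atom, " not uniquely present in both models")
  sqrt(sum((as.numeric(moved$atoms[im, c("x", "y", "z")]) -
            as.numeric(reference$atoms[ir, c("x", "y", "z")]))^2))
}

#' Inter-head rotation between two motor dimers
#'
#' Aligns the anchor heads (e.g. the MT-bound heads) of two two-headed
#' complexes, then fits the residual rigid transform mapping the distal
#' head of A onto the distal head of B and decomposes it into a rotation
#' angle (from the matrix trace) and axis. Near-zero rotations carry an
#' undefined-axis flag.
#'
#' @param complexA,complexB [structure_model()] objects containing both
#'   heads.
#' @param anchor selection for the anchor head (e.g.
#'   \code{list(chain = "A")}).
#' @param distal selection for the distal head.
#' @param atoms atom subset, default "CA".
#' @return list with \code{angle} (degrees), \code{axis}, \code{axis_defined}
#'   and the two underlying \code{superposition_result}s.
#' @export
rotation_between_heads <- function(complexA, complexB, anchor, distal,
                                   atoms = "CA") {
  sup_anchor <- superpose(complexA, complexB, selection = anchor,
                          atoms = atoms)
  aligned <- transform_model(complexA, sup_anchor$rotation,
                             sup_anchor$translation)
  sup_distal <- superpose(aligned, complexB, selection = distal,
                          atoms = atoms)
  list(angle = sup_distal$rotation_angle,
       axis = sup_distal$rotation_axis,
       axis_defined = sup_distal$axis_defined,
       anchor_fit = sup_anchor, distal_fit = sup_distal)
}
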