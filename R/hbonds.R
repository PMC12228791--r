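## Hydrogen-bond network extraction from H-free (cryo-EM) models: a
## donor/acceptor typing table for the standard amino acids plus ADP, a
## heavy-atom geometric criterion, and set-diffing of networks between
## nucleotide states.

.aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

## donor atom -> antecedent heavy atom (for the heavy-atom angle criterion)
.donor_table <- list(
  backbone = c(N = "CA"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  CYS = c(SG = "CB"), ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  LYS = c(NZ = "CE"), TRP = c(NE1 = "CD1"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"),
  ADP = c(N6 = "C6", "O2'" = "C2'", "O3'" = "C3'")
)

.acceptor_table <- list(
  backbone = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD",
  ADP = c("O1A", "O2A", "O3A", "O1B", "O2B", "O3B", "O4'", "O5'",
          "O2'", "O3'", "N1", "N3", "N7")
)

.charged_pos <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))
.charged_neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                     ADP = c("O1A", "O2A", "O3A", "O1B", "O2B", "O3B"))

.residue_tag <- function(resname, resno, chain, multi_chain) {
  code <- if (resname %in% names(.aa1)) .aa1[[resname]] else resname
  tag <- sprintf("%s%d", code, resno)
  if (multi_chain) paste0(chain, "/", tag) else tag
}

#' Extract the hydrogen-bond network of a model
#'
#' Enumerates donor-acceptor pairs between distinct residues using a
#' built-in chemistry table (standard amino acids, backbone, ADP). Because
#' cryo-EM models carry no hydrogens, the default geometric criterion is
#' heavy-atom: donor-acceptor distance <= \code{d_max} and
#' antecedent-donor-acceptor angle >= \code{angle_min}; donors with no
#' resolvable antecedent fall back to the distance criterion. Salt-bridge
#' pairs (Lys/Arg/His vs Asp/Glu/phosphate) are reported with the distance
#' criterion only when \code{salt_bridge_distance_only} is TRUE. Residues
#' with unknown chemistry are skipped with a warning.
#'
#' @param model a [structure_model()].
#' @param d_max maximum donor-acceptor distance (Angstrom), default 3.5.
#' @param angle_min minimum heavy-atom angle at the donor (degrees),
#'   default 90 (use ~120 when explicit hydrogens are present and treated
#'   as antecedents).
#' @param salt_bridge_distance_only logical, see above.
#' @return object of class \code{hbond_network}: data.frame of edges with
#'   donor/acceptor identifiers, \code{distance}, \code{angle} (NA when not
#'   evaluated) and a residue-pair \code{label}.
#' @export
hbond_network <- function(model, d_max = 3.5, angle_min = 90,
                          salt_bridge_distance_only = TRUE) {
  at <- model$atoms
  multi_chain <- length(unique(at$chain)) > 1
  known <- unique(c(names(.aa1), "ADP"))
  unk <- setdiff(unique(at$resname), known)
  if (length(unk))
    warning("unknown residue chemistry, skipped: ",
            paste(unk, collapse = ", "))
  is_aa <- at$resname %in% names(.aa1)

  donors <- list()
  for (i in which(at$resname %in% known)) {
    rn <- at$resname[i]; an <- at$atom[i]
    ante <- NA_character_
    hit <- FALSE
    if (is_aa[i] && an == "N" && rn != "PRO") { ante <- "CA"; hit <- TRUE }
    sc <- .donor_table[[rn]]
    if (!hit && !is.null(sc) && an %in% names(sc)) { ante <- sc[[an]]; hit <- TRUE }
    if (hit) donors[[length(donors) + 1L]] <- c(i = i, ante = ante)
  }
  acc_idx <- integer(0)
  for (i in which(at$resname %in% known)) {
    rn <- at$resname[i]; an <- at$atom[i]
    ok <- (is_aa[i] && an %in% .acceptor_table$backbone) ||
      an %in% .acceptor_table[[rn]]
    if (isTRUE(ok)) acc_idx <- c(acc_idx, i)
  }

  xyz <- as.matrix(at[, c("x", "y", "z")])
  edges <- list()
  for (d in donors) {
    di <- as.integer(d[["i"]])
    # antecedent atom within the donor's residue
    ai <- which(at$chain == at$chain[di] & at$resno == at$resno[di] &
                at$atom == d[["ante"]])
    for (aj in acc_idx) {
      if (at$chain[aj] == at$chain[di] && at$resno[aj] == at$resno[di]) next
      dist <- sqrt(sum((xyz[di, ] - xyz[aj, ])^2))
      if (dist > d_max || dist < 1e-6) next
      salt <- salt_bridge_distance_only &&
        at$atom[di] %in% .charged_pos[[at$resname[di]]] &&
        at$atom[aj] %in% .charged_neg[[at$resname[aj]]]
      ang <- NA_real_
      if (!salt && length(ai) == 1) {
        v1 <- xyz[ai, ] - xyz[di, ]
        v2 <- xyz[aj, ] - xyz[di, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        if (ang < angle_min) next
      }
      t1 <- .residue_tag(at$resname[di], at$resno[di], at$chain[di], multi_chain)
      t2 <- .residue_tag(at$resname[aj], at$resno[aj], at$chain[aj], multi_chain)
      lab <- if (at$resno[di] <= at$resno[aj]) paste0(t1, "-", t2) else
        paste0(t2, "-", t1)
      edges[[length(edges) + 1L]] <- data.frame(
        donor_chain = at$chain[di], donor_resno = at$resno[di],
        donor_res = at$resname[di], donor_atom = at$atom[di],
        acceptor_chain = at$chain[aj], acceptor_resno = at$resno[aj],
        acceptor_res = at$resname[aj], acceptor_atom = at$atom[aj],
        distance = dist, angle = ang, salt_bridge = salt, label = lab,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(donor_chain = character(0), donor_resno = integer(0),
               donor_res = character(0), donor_atom = character(0),
               acceptor_chain = character(0), acceptor_resno = integer(0),
               acceptor_res = character(0), acceptor_atom = character(0),
               distance = numeric(0), angle = numeric(0),
               salt_bridge = logical(0), label = character(0))
  class(out) <- c("hbond_network", "data.frame")
  out
}

#' Difference between two hydrogen-bond networks
#'
#' Set difference keyed by residue-pair labels: edges present in \code{netA}
#' but not \code{netB} are "lost", the converse "gained". This is the
#' rewiring statistic behind nucleotide-pocket remodeling comparisons
#' (e.g. loss of the T92-D231 contact and gain of D231-R190 / D231-K91 on
#' microtubule binding).
#'
#' @param netA,netB \code{hbond_network} objects from residue-matched
#'   models.
#' @return list with character vectors \code{lost} and \code{gained}
#'   (unique residue-pair labels).
#' @export
network_diff <- function(netA, netB) {
  a <- unique(netA$label); b <- unique(netB$label)
  list(lost = setdiff(a, b), gained = setdiff(b, a))
}
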