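#' Atomic structure model
#'
#' A light container for an atomic model: one row per atom with chain,
#' residue number/name, atom name, element and coordinates (Angstrom), plus
#' a set of named residue-range selections (P-loop, helix alpha-2a, loop 9,
#' ...). Selections are residue-number sets, optionally chain-qualified,
#' and are configurable because residue numbering differs between kinesin
#' species.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}.
#' @param selections named list; each element either an integer vector of
#'   residue numbers or a list \code{list(chain=, resno=)}.
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, selections = default_motor_selections()) {
  req <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing <- setdiff(req, names(atoms))
  if (length(missing))
    stop("structure_model atoms missing columns: ",
         paste(missing, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom) records: ",
         key[anyDuplicated(key)][1])
  structure(list(atoms = as.data.frame(atoms), selections = selections),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Default named selections for the Kif5b motor domain
#'
#' Residue ranges (human Kif5b numbering) for the structural elements used
#' in alignment frames and comparisons. The P-loop (Walker A, G85-T92) plus
#' helix alpha-2a through residue 100 form the default nucleotide-holding
#' alignment frame. Ranges are package defaults, not literature constants,
#' and can be overridden per model.
#'
#' @return named list of integer residue vectors.
#' @export
default_motor_selections <- function() {
  list(
    P_LOOP      = 85:92,
    HELIX_A2A   = 93:100,
    PLOOP_A2A   = 85:100,   # standard alignment frame
    LOOP9       = 190:204,  # switch I region
    LOOP11      = 232:245,  # switch II region
    HELIX_A4    = 246:270,
    NECK_LINKER = 325:338,
    CORE_SHEET  = c(77:84, 130:140, 215:230)
  )
}

#' Resolve a selection to atom row indices
#'
#' @param model a [structure_model()].
#' @param selection NULL (all atoms), a character selection name, an
#'   integer vector of residue numbers, or \code{list(chain=, resno=)}.
#' @param atoms atom-name filter (e.g. "CA"); NULL keeps all atom names.
#' @return integer vector of row indices into \code{model$atoms}.
#' @export
select_atoms <- function(model, selection = NULL, atoms = "CA") {
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(selection)) {
    if (is.character(selection) && length(selection) == 1) {
      if (!selection %in% names(model$selections))
        stop("unknown selection: ", selection)
      selection <- model$selections[[selection]]
    }
    if (is.list(selection)) {
      if (!is.null(selection$chain)) keep <- keep & at$chain %in% selection$chain
      if (!is.null(selection$resno)) keep <- keep & at$resno %in% selection$resno
    } else {
      keep <- keep & at$resno %in% selection
    }
  }
  if (!is.null(atoms)) keep <- keep & at$atom %in% atoms
  which(keep)
}

#' Read a PDB file into a structure_model
#'
#' Fixed-column parser for ATOM/HETATM records (first MODEL only).
#' Alternate locations other than '' or 'A' are dropped.
#'
#' @param path path to a PDB file.
#' @param selections passed to [structure_model()].
#' @return a [structure_model()].
#' @export
read_pdb <- function(path, selections = default_motor_selections()) {
  lines <- readLines(path, warn = FALSE)
  end1 <- which(startsWith(lines, "ENDMDL"))
  if (length(end1)) lines <- lines[seq_len(end1[1] - 1L)]
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  alt <- trimws(substr(rec, 17, 17))
  rec <- rec[alt %in% c("", "A")]
  elem <- trimws(substr(rec, 77, 78))
  name <- trimws(substr(rec, 13, 16))
  fallback <- gsub("[0-9']", "", name)
  elem[elem == ""] <- substr(fallback[elem == ""], 1, 1)
  atoms <- data.frame(
    chain = trimws(substr(rec, 22, 22)),
    resno = as.integer(substr(rec, 23, 26)),
    resname = trimws(substr(rec, 18, 20)),
    atom = name,
    element = toupper(elem),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    stringsAsFactors = FALSE)
  structure_model(atoms, selections)
}

#' Read an mmCIF atom_site table into a structure_model
#'
#' Minimal reader for the \code{_atom_site} loop of a coordinate mmCIF.
#' Uses auth chain/residue numbering (as deposited). First model only.
#'
#' @param path path to an mmCIF file.
#' @param selections passed to [structure_model()].
#' @return a [structure_model()].
#' @export
read_mmcif <- function(path, selections = default_motor_selections()) {
  lines <- readLines(path, warn = FALSE)
  hdr_i <- grep("^_atom_site\\.", lines)
  if (!length(hdr_i)) stop("no _atom_site loop in ", path)
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_i]))
  body <- lines[(max(hdr_i) + 1L):length(lines)]
  stop_i <- which(startsWith(body, "#") | startsWith(body, "loop_") |
                  startsWith(body, "_"))
  if (length(stop_i)) body <- body[seq_len(stop_i[1] - 1L)]
  fields <- strsplit(trimws(body), "[ \t]+")
  fields <- fields[lengths(fields) == length(cols)]
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  get <- function(nm, alt = NULL) {
    if (nm %in% cols) m[, nm] else if (!is.null(alt) && alt %in% cols)
      m[, alt] else stop("mmCIF missing _atom_site.", nm)
  }
  grp <- get("group_PDB")
  keep <- grp %in% c("ATOM", "HETATM")
  if ("pdbx_PDB_model_num" %in% cols) {
    mdl <- m[, "pdbx_PDB_model_num"]
    keep <- keep & mdl == mdl[keep][1]
  }
  if ("label_alt_id" %in% cols)
    keep <- keep & m[, "label_alt_id"] %in% c(".", "?", "A")
  atoms <- data.frame(
    chain = get("auth_asym_id", "label_asym_id")[keep],
    resno = as.integer(get("auth_seq_id", "label_seq_id")[keep]),
    resname = get("auth_comp_id", "label_comp_id")[keep],
    atom = gsub('"', "", get("auth_atom_id", "label_atom_id")[keep]),
    element = toupper(get("type_symbol")[keep]),
    x = as.numeric(get("Cartn_x")[keep]),
    y = as.numeric(get("Cartn_y")[keep]),
    z = as.numeric(get("Cartn_z")[keep]),
    stringsAsFactors = FALSE)
  structure_model(atoms, selections)
}

#' Apply a rigid transform to a structure model
#'
#' @param model a [structure_model()].
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric 3-vector (Angstrom).
#' @return the transformed [structure_model()].
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(rotation), 2, translation, `+`)
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  model
}
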