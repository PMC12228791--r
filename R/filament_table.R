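#' Per-segment filament metadata table
#'
#' The central container of the consensus stage: one row per boxed filament
#' segment, with the Relion pose parameterisation (ZYZ Euler angles
#' rot/tilt/psi in degrees, in-plane origin shifts in Angstrom) plus the 3D
#' class assigned to the segment. Angles are normalised to [-180, 180);
#' segment indices must be strictly increasing within each filament.
#'
#' @param df data.frame with columns \code{filament_id}, \code{segment_index},
#'   \code{rot}, \code{tilt}, \code{psi}, \code{origin_x}, \code{origin_y},
#'   \code{class_id}; an optional \code{signal} column carries a per-row
#'   scalar for segment averaging. Extra columns are preserved.
#' @return the validated data.frame with class \code{filament_table}.
#' @export
filament_table <- function(df) {
  req <- c("filament_id", "segment_index", "rot", "tilt", "psi",
           "origin_x", "origin_y", "class_id")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("filament_table missing columns: ", paste(missing, collapse = ", "))
  if (any(is.na(df$filament_id)))
    stop("every row needs a filament_id")
  for (a in c("rot", "tilt", "psi")) df[[a]] <- wrap_angle(df[[a]])
  for (fid in unique(df$filament_id)) {
    s <- df$segment_index[df$filament_id == fid]
    if (any(diff(s) <= 0))
      stop("segment_index not strictly increasing within filament ", fid)
  }
  class(df) <- c("filament_table", "data.frame")
  df
}

#' Split a filament table by filament, preserving row order
#' @noRd
split_filaments <- function(table) {
  split(seq_len(nrow(table)), table$filament_id)
}

#' Modal-class tie rule: most frequent value, ties to the smallest
#' @noRd
modal_value <- function(x) {
  tab <- table(x)
  winners <- names(tab)[tab == max(tab)]
  v <- suppressWarnings(as.numeric(winners))
  if (!anyNA(v)) min(v) else min(winners)
}
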