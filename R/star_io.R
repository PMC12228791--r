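## Minimal STAR (Relion particle dialect) reader/writer. Only the loop_
## table layout used by Relion particle metadata is supported; unknown
## columns round-trip untouched.

#' Read a STAR file
#'
#' Parses the named \code{data_} block (default: the first block containing
#' a \code{loop_}) of a Relion-dialect STAR file into a data.frame. Columns
#' whose values all parse as numbers become numeric.
#'
#' @param path path to a STAR file.
#' @param block name of the data block (without the \code{data_} prefix),
#'   or NULL for the first loop block.
#' @return data.frame with one column per \code{_rln...} tag (leading
#'   underscore stripped).
#' @export
read_star <- function(path, block = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (startsWith(lines[i], "data_")) {
      bname <- sub("^data_", "", lines[i])
      j <- i + 1L
      while (j <= n && !startsWith(lines[j], "loop_") &&
             !startsWith(lines[j], "data_")) j <- j + 1L
      if (j <= n && startsWith(lines[j], "loop_") &&
          (is.null(block) || identical(bname, block))) {
        k <- j + 1L
        cols <- character(0)
        while (k <= n && startsWith(lines[k], "_")) {
          cols <- c(cols, sub("^_", "", strsplit(lines[k], "[ \t]+")[[1]][1]))
          k <- k + 1L
        }
        rows <- list()
        while (k <= n && nzchar(lines[k]) && !startsWith(lines[k], "data_")) {
          fields <- strsplit(lines[k], "[ \t]+")[[1]]
          if (length(fields) != length(cols))
            stop(sprintf("STAR row has %d fields, expected %d (line %d)",
                         length(fields), length(cols), k))
          rows[[length(rows) + 1L]] <- fields
          k <- k + 1L
        }
        m <- do.call(rbind, rows)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- cols
        for (cn in cols) {
          v <- suppressWarnings(as.numeric(df[[cn]]))
          if (!anyNA(v)) df[[cn]] <- v
        }
        return(df)
      }
      i <- j
    } else i <- i + 1L
  }
  stop("no matching loop_ data block found in ", path)
}

#' Write a data.frame as a STAR loop block
#'
#' @param df data.frame; column names are written as \code{_name} tags.
#' @param path output path.
#' @param block data block name (written as \code{data_<block>}).
#' @export
write_star <- function(df, path, block = "particles") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, digits = 12, scientific = FALSE)
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  writeLines("", con)
  invisible(path)
}

## column map between internal filament-table names and Relion tags
.star_map <- c(
  filament_id   = "rlnHelicalTubeID",
  segment_index = "rlnSegmentIndex",
  rot           = "rlnAngleRot",
  tilt          = "rlnAngleTilt",
  psi           = "rlnAnglePsi",
  origin_x      = "rlnOriginXAngst",
  origin_y      = "rlnOriginYAngst",
  class_id      = "rlnClassNumber",
  signal        = "mtSignalValue"
)

#' Write a filament table as a Relion particle STAR file
#'
#' @param table a [filament_table()].
#' @param path output path.
#' @export
write_filament_star <- function(table, path) {
  df <- as.data.frame(table)
  idx <- match(names(df), names(.star_map))
  names(df)[!is.na(idx)] <- .star_map[idx[!is.na(idx)]]
  write_star(df, path, block = "particles")
}

#' Read a filament table from a Relion particle STAR file
#'
#' @param path path to a STAR file with the Relion helical particle columns
#'   (rlnHelicalTubeID, rlnAngleRot/Tilt/Psi, rlnOriginXAngst/YAngst,
#'   rlnClassNumber).
#' @return a [filament_table()].
#' @export
read_filament_star <- function(path) {
  df <- read_star(path)
  rev_map <- stats::setNames(names(.star_map), .star_map)
  idx <- match(names(df), names(rev_map))
  names(df)[!is.na(idx)] <- rev_map[idx[!is.na(idx)]]
  if (!"segment_index" %in% names(df)) {
    df <- df[order(df$filament_id), , drop = FALSE]
    df$segment_index <- stats::ave(seq_len(nrow(df)), df$filament_id,
                                   FUN = seq_along)
  }
  filament_table(df)
}
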