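## Per-filament consensus operations: the "modified MiRP" bookkeeping that
## turns noisy per-segment cryo-EM metadata into coherent per-filament
## assignments.

#' Assign the modal 3D class of each filament to all its segments
#'
#' Each microtubule is given the most frequent class among its segments and
#' that class overwrites every row of the filament. Ties break toward the
#' smallest class id.
#'
#' @param table a [filament_table()] with per-segment \code{class_id} votes.
#' @return list with \code{assignments} (named vector filament_id -> class)
#'   and \code{table} (the input with the vote applied to all rows).
#' @export
modal_class_vote <- function(table) {
  stopifnot(inherits(table, "filament_table"))
  if (any(is.na(table$class_id)))
    stop("filament with missing class votes")
  groups <- split_filaments(table)
  assignments <- vapply(groups, function(idx) modal_value(table$class_id[idx]),
                        numeric(1))
  for (fid in names(groups))
    table$class_id[groups[[fid]]] <- assignments[[fid]]
  list(assignments = assignments, table = table)
}

## centred window indices, symmetric half-width shrink: keeps any locally
## linear series a fixed point of the moving mean, including at filament ends
.sym_window <- function(i, n, half) {
  h <- min(half, i - 1L, n - i)
  (i - h):(i + h)
}

.trunc_window <- function(i, n, half) {
  max(1L, i - half):min(n, i + half)
}

.smooth_column <- function(x, window, threshold, circular) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  med <- vapply(seq_len(n), function(i) {
    w <- x[.trunc_window(i, n, half)]
    if (circular) circular_median(w) else stats::median(w)
  }, numeric(1))
  dev <- if (circular) circular_distance(x, med) else abs(x - med)
  x[dev > threshold] <- med[dev > threshold]
  out <- vapply(seq_len(n), function(i) {
    w <- x[.sym_window(i, n, half)]
    if (circular) circular_mean(w) else mean(w)
  }, numeric(1))
  out
}

#' Smooth in-plane angles and origin shifts along each filament
#'
#' Implements the per-filament smoothing of rough psi angles and x/y
#' translations between adjacent segments. Per filament and per column,
#' values deviating from a running (circular for psi, plain for shifts)
#' median by more than \code{outlier_threshold} are replaced by that median;
#' the cleaned series is then replaced by a centred moving circular-mean /
#' mean of width \code{window}. The moving-mean window shrinks symmetrically
#' at filament ends, so locally linear drifts are exact fixed points.
#'
#' @param table a [filament_table()].
#' @param window odd window width in segments (>= 3).
#' @param outlier_threshold outlier cutoff: degrees for psi, Angstrom for
#'   shifts. Default 8 corrects a single misaligned segment in an otherwise
#'   smooth filament.
#' @return the smoothed [filament_table()].
#' @export
smooth_inplane <- function(table, window = 5, outlier_threshold = 8) {
  stopifnot(inherits(table, "filament_table"))
  if (window < 3 || window %% 2 == 0)
    stop("window must be odd and >= 3")
  for (idx in split_filaments(table)) {
    table$psi[idx] <- .smooth_column(table$psi[idx], window,
                                     outlier_threshold, circular = TRUE)
    table$origin_x[idx] <- .smooth_column(table$origin_x[idx], window,
                                          outlier_threshold, circular = FALSE)
    table$origin_y[idx] <- .smooth_column(table$origin_y[idx], window,
                                          outlier_threshold, circular = FALSE)
  }
  table
}

#' Assign each filament's circular-median phi angle to all its segments
#'
#' The rot (phi) angle about the helical axis should be common to a
#' filament; each filament's rows receive the circular median of its phi
#' values (the value minimising summed circular distance; ties to the
#' smaller angle).
#'
#' @param table a [filament_table()].
#' @return [filament_table()] with per-filament constant \code{rot}.
#' @export
assign_phi_median <- function(table) {
  stopifnot(inherits(table, "filament_table"))
  for (idx in split_filaments(table))
    table$rot[idx] <- circular_median(table$rot[idx])
  table
}

#' Average each segment's signal with its adjacent partners
#'
#' Emulates the "segment average" used to boost signal before register
#' classification: each segment's \code{signal} becomes the mean over the
#' consecutive run of \code{partners + 1} segments containing it, centred
#' with the extra partner on the high-index side and shifted inward at
#' filament ends. Filaments shorter than \code{partners + 1} average over
#' all available segments.
#'
#' @param table a [filament_table()] with a \code{signal} column.
#' @param partners number of adjacent partners (default 7).
#' @return [filament_table()] with averaged \code{signal}.
#' @export
segment_average <- function(table, partners = 7) {
  stopifnot(inherits(table, "filament_table"))
  if (!"signal" %in% names(table))
    stop("segment_average needs a 'signal' column")
  for (idx in split_filaments(table)) {
    x <- table$signal[idx]
    n <- length(x)
    w <- min(partners + 1L, n)
    lead <- (w - 1L) %/% 2L  # partners before the segment; extra goes after
    out <- vapply(seq_len(n), function(i) {
      start <- min(max(1L, i - lead), n - w + 1L)
      mean(x[start:(start + w - 1L)])
    }, numeric(1))
    table$signal[idx] <- out
  }
  table
}

#' Assign the modal seam/register hypothesis to each filament
#'
#' Per-segment register votes over the 2N seam/register classes are reduced
#' to the filament mode (ties to the smallest index); the winning
#' hypothesis' transform is then applied to every row: \code{delta_phi} is
#' added to rot and the axial offset \code{delta_z}, expressed in the
#' reference frame, is projected through each row's pose into the in-plane
#' origins.
#'
#' @param table a [filament_table()] whose \code{class_id} column holds
#'   register votes in \code{[0, 2 n_pf)}.
#' @param lattice a [helical_lattice()].
#' @return list with \code{assignments} (named list filament_id ->
#'   \code{seam_hypothesis}) and \code{table} (poses updated, plus a
#'   \code{register} column).
#' @export
assign_seam_register <- function(table, lattice) {
  stopifnot(inherits(table, "filament_table"),
            inherits(lattice, "helical_lattice"))
  hyps <- enumerate_seam_references(lattice)
  n_classes <- length(hyps)
  if (any(table$class_id < 0 | table$class_id >= n_classes))
    stop("register vote outside [0, ", n_classes, ")")
  groups <- split_filaments(table)
  assignments <- list()
  table$register <- NA_real_
  for (fid in names(groups)) {
    idx <- groups[[fid]]
    k <- modal_value(table$class_id[idx])
    hyp <- hyps[[k + 1L]]
    assignments[[fid]] <- hyp
    table$register[idx] <- k
    for (i in idx) {
      pose <- compose_pose(table$rot[i], table$tilt[i], table$psi[i],
                           table$origin_x[i], table$origin_y[i],
                           delta_phi = hyp$delta_phi, delta_z = hyp$delta_z)
      table$rot[i] <- pose["rot"]
      table$origin_x[i] <- pose["origin_x"]
      table$origin_y[i] <- pose["origin_y"]
    }
  }
  list(assignments = assignments, table = table)
}

#' Occupancy statistics over motor-state classes
#'
#' Counts and fractions of asymmetric units per motor-state label (e.g.
#' one-headed, two-headed, undecorated).
#'
#' @param labels character or factor vector, one label per asymmetric unit,
#'   or a named numeric vector of pre-tabulated counts.
#' @return object of class \code{occupancy_report}: list with \code{counts},
#'   \code{fractions} (summing to 1) and \code{n}.
#' @export
occupancy_stats <- function(labels) {
  if (length(labels) == 0) stop("no labeled units")
  counts <- if (is.numeric(labels) && !is.null(names(labels))) {
    labels
  } else {
    tab <- table(as.character(labels))
    stats::setNames(as.numeric(tab), names(tab))
  }
  n <- sum(counts)
  if (n <= 0) stop("no labeled units")
  structure(list(counts = counts, fractions = counts / n, n = n),
            class = "occupancy_report")
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat(sprintf("occupancy over %d units:\n", x$n))
  for (s in names(x$counts))
    cat(sprintf("  %-12s %6d  (%.1f%%)\n", s, x$counts[[s]],
                100 * x$fractions[[s]]))
  invisible(x)
}
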