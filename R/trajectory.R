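## Trajectory containers and MD observables: monitored pair distances,
## ligand RMSD after core alignment, fluctuation statistics, 2D densities,
## adaptive restart-frame selection, release detection, ion coordination
## and the protocol time ledger.

#' Toy trajectory container
#'
#' Coordinates for a set of atoms over time: an atom table plus a
#' frames x atoms x 3 coordinate array. This is the neutral coordinate
#' stream the observables operate on; engine-native binary formats are an
#' adapter concern, not part of the core model.
#'
#' @param atoms data.frame with at least \code{atom}, \code{resno}; optional
#'   \code{chain}, \code{resname}, \code{element}.
#' @param coords numeric array \code{[n_frames, n_atoms, 3]} (Angstrom).
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @return object of class \code{toy_trajectory}.
#' @export
toy_trajectory <- function(atoms, coords, times = seq_len(dim(coords)[1])) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == nrow(atoms),
            length(times) == dim(coords)[1])
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(atoms = as.data.frame(atoms), coords = coords,
                 times = as.numeric(times)),
            class = "toy_trajectory")
}

#' Time-indexed observable series for one replica
#'
#' @param times frame times (ns), strictly increasing.
#' @param distances numeric matrix (frames x pairs) of monitored distances
#'   (Angstrom), with column names; may have zero columns.
#' @param ligand_rmsd optional numeric vector of ligand RMSD per frame.
#' @param replica,level identifiers for bookkeeping across the adaptive
#'   protocol.
#' @return object of class \code{trajectory_series}.
#' @export
trajectory_series <- function(times, distances = NULL, ligand_rmsd = NULL,
                              replica = 1L, level = 1L) {
  n <- length(times)
  if (n < 1) stop("empty series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(distances)) distances <- matrix(numeric(0), nrow = n, ncol = 0)
  distances <- as.matrix(distances)
  if (nrow(distances) != n) stop("distances length mismatch")
  if (!is.null(ligand_rmsd) && length(ligand_rmsd) != n)
    stop("ligand_rmsd length mismatch")
  structure(list(times = as.numeric(times), distances = distances,
                 ligand_rmsd = ligand_rmsd, replica = replica, level = level),
            class = "trajectory_series")
}

#' Monitored atom-pair specifiers
#'
#' @param pairs data.frame with columns \code{label}, \code{a_resno},
#'   \code{a_atom}, \code{b_resno}, \code{b_atom}.
#' @return the validated data.frame, class \code{monitored_pairs}.
#' @export
monitored_pairs <- function(pairs) {
  req <- c("label", "a_resno", "a_atom", "b_resno", "b_atom")
  if (!all(req %in% names(pairs)))
    stop("monitored_pairs needs columns: ", paste(req, collapse = ", "))
  class(pairs) <- c("monitored_pairs", "data.frame")
  pairs
}

#' Default ADP-stability pair set
#'
#' The distances used to monitor ADP stability in the nucleotide pocket:
#' the ADP beta-phosphorus against P-loop residues T87, S88, S89, K91, plus
#' a fifth pair for which two presets exist in the literature record:
#' E199 against S88 (\code{variant = "S88"}) or against S98
#' (\code{variant = "S98"}). Residue-side atoms default to Calpha, the ADP
#' side to the PB atom; both are configurable after construction.
#'
#' @param variant which fifth pair to use, \code{"S88"} or \code{"S98"}.
#' @param adp_resno residue number of ADP in the topology.
#' @return a [monitored_pairs()] data.frame.
#' @export
default_monitored_pairs <- function(variant = c("S88", "S98"),
                                    adp_resno = 500L) {
  variant <- match.arg(variant)
  fifth <- if (variant == "S88") 88L else 98L
  monitored_pairs(data.frame(
    label = c("bP-T87", "bP-S88", "bP-S89", "bP-K91",
              sprintf("E199-S%d", fifth)),
    a_resno = c(rep(adp_resno, 4L), 199L),
    a_atom = c(rep("PB", 4L), "CA"),
    b_resno = c(87L, 88L, 89L, 91L, fifth),
    b_atom = "CA",
    stringsAsFactors = FALSE))
}

.resolve_atom <- function(traj, resno, atom, what) {
  i <- which(traj$atoms$resno == resno & traj$atoms$atom == atom)
  if (length(i) != 1)
    stop("cannot resolve ", what, ": residue ", resno, " atom ", atom,
         " (", length(i), " matches)")
  i
}

#' Per-frame distances for monitored atom pairs
#'
#' @param traj a [toy_trajectory()].
#' @param pairs a [monitored_pairs()] specifier.
#' @param replica,level passed through to the result.
#' @return a [trajectory_series()] with one distance column per pair.
#' @export
pair_distance_series <- function(traj, pairs, replica = 1L, level = 1L) {
  stopifnot(inherits(traj, "toy_trajectory"))
  d <- sapply(seq_len(nrow(pairs)), function(k) {
    ia <- .resolve_atom(traj, pairs$a_resno[k], pairs$a_atom[k],
                        paste("pair", pairs$label[k]))
    ib <- .resolve_atom(traj, pairs$b_resno[k], pairs$b_atom[k],
                        paste("pair", pairs$label[k]))
    sqrt(rowSums((traj$coords[, ia, , drop = TRUE] -
                  traj$coords[, ib, , drop = TRUE])^2))
  })
  d <- matrix(d, nrow = dim(traj$coords)[1])
  colnames(d) <- pairs$label
  trajectory_series(traj$times, d, replica = replica, level = level)
}

#' Fluctuation statistics of monitored distances across replicas
#'
#' Per-replica standard deviation of each monitored distance, the mean
#' across replicas and its standard error (the SD of the per-replica SDs
#' divided by sqrt of the replica count).
#'
#' @param series_list list of [trajectory_series()] objects sharing pair
#'   columns.
#' @return list with \code{per_replica} (replica x pair SD matrix),
#'   \code{mean} and \code{sem} (per pair; \code{sem} is NA with a single
#'   replica).
#' @export
distance_fluctuation_sd <- function(series_list) {
  if (inherits(series_list, "trajectory_series"))
    series_list <- list(series_list)
  if (!length(series_list)) stop("need at least one replica")
  sds <- t(vapply(series_list, function(s) {
    if (length(s$times) < 2) stop("single-frame series has no fluctuation")
    apply(s$distances, 2, stats::sd)
  }, numeric(ncol(series_list[[1]]$distances))))
  if (ncol(series_list[[1]]$distances) == 1)
    sds <- matrix(sds, ncol = 1,
                  dimnames = list(NULL, colnames(series_list[[1]]$distances)))
  n <- nrow(sds)
  list(per_replica = sds,
       mean = colMeans(sds),
       sem = if (n > 1) apply(sds, 2, stats::sd) / sqrt(n) else
         stats::setNames(rep(NA_real_, ncol(sds)), colnames(sds)))
}

#' Ligand RMSD series after core Calpha alignment
#'
#' For every frame, superposes the alignment set (default the motor-core
#' Calpha atoms of residues 75-95) onto the same atoms in the reference
#' frame, applies that rigid transform to the whole frame, and reports the
#' RMSD of the ligand atoms against their reference positions. No ligand
#' fitting is performed, so genuine ligand motion relative to the core is
#' retained while global rigid motion cancels exactly.
#'
#' @param traj a [toy_trajectory()].
#' @param ligand_resno residue number of the ligand.
#' @param align_resno residues whose Calpha atoms define the alignment,
#'   default \code{75:95}.
#' @param reference_frame frame index used as reference, default 1.
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
ligand_rmsd_series <- function(traj, ligand_resno, align_resno = 75:95,
                               reference_frame = 1L) {
  at <- traj$atoms
  ai <- which(at$resno %in% align_resno & at$atom == "CA")
  li <- which(at$resno %in% ligand_resno)
  if (length(ai) < 3) stop("missing alignment atoms (need >= 3 Calpha)")
  if (!length(li)) stop("ligand atoms not found")
  nf <- dim(traj$coords)[1]
  ref_align <- matrix(traj$coords[reference_frame, ai, ], ncol = 3)
  ref_lig <- matrix(traj$coords[reference_frame, li, ], ncol = 3)
  vapply(seq_len(nf), function(f) {
    p <- matrix(traj$coords[f, ai, ], ncol = 3)
    fit <- kabsch(p, ref_align)
    lig <- sweep(matrix(traj$coords[f, li, ], ncol = 3) %*% t(fit$rotation),
                 2, fit$translation, `+`)
    sqrt(mean(rowSums((lig - ref_lig)^2)))
  }, numeric(1))
}

#' Normalised 2D histogram of two reaction coordinates
#'
#' @param x,y numeric vectors of equal length (e.g. ligand RMSD and a
#'   monitored distance).
#' @param bins number of bins per axis, default 50.
#' @return list with \code{density} (bins x bins matrix summing to 1),
#'   \code{x_breaks}, \code{y_breaks}.
#' @export
density2d <- function(x, y, bins = 50) {
  if (!length(x) || length(x) != length(y)) stop("x and y must be equal, non-empty")
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  xb <- seq(pad(range(x))[1], pad(range(x))[2], length.out = bins + 1L)
  yb <- seq(pad(range(y))[1], pad(range(y))[2], length.out = bins + 1L)
  ix <- pmin(findInterval(x, xb, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(y, yb, rightmost.closed = TRUE), bins)
  h <- matrix(0, bins, bins)
  for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
  list(density = h / length(x), x_breaks = xb, y_breaks = yb)
}

#' Combined progress score for adaptive restart seeding
#'
#' Score per frame = z-score of the ligand RMSD plus the mean over pairs of
#' the z-score of |d(t) - d(0)| (deviation from the starting distances).
#' Constant observables contribute zero. z-scoring makes Angstrom-scale
#' observables commensurate; affine rescaling of any single observable does
#' not change the score ordering.
#'
#' @param series a [trajectory_series()] with \code{ligand_rmsd} and/or
#'   distance columns.
#' @return numeric score per frame.
#' @export
restart_score <- function(series) {
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  }
  score <- rep(0, length(series$times))
  if (!is.null(series$ligand_rmsd)) score <- score + zs(series$ligand_rmsd)
  if (ncol(series$distances) > 0) {
    dev <- abs(sweep(series$distances, 2, series$distances[1, ]))
    score <- score + rowMeans(apply(dev, 2, zs))
  }
  score
}

#' Select restart frames for the next protocol level
#'
#' Returns the indices of the k frames with the highest combined progress
#' score ([restart_score()]); ties break toward the earlier frame. k = 2
#' reproduces the Level-1 to Level-2 seeding of the adaptive protocol,
#' k = 7 on the pooled Level-2 set the Level-2 to Level-3 seeding.
#'
#' @param series a [trajectory_series()].
#' @param k number of frames to select.
#' @return integer frame indices, in decreasing score order.
#' @export
select_restart_frames <- function(series, k) {
  n <- length(series$times)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds number of frames")
  score <- restart_score(series)
  ord <- order(-score, seq_len(n))
  ord[seq_len(k)]
}

#' Detect a ligand release event
#'
#' A release is the first frame at which the ligand RMSD exceeds
#' \code{threshold} for at least \code{dwell} consecutive frames and never
#' afterwards returns below \code{threshold/2} (a committed, not transient,
#' excursion). Returns \code{NA_integer_} when no release occurs.
#'
#' @param series a [trajectory_series()] with a \code{ligand_rmsd} series.
#' @param threshold RMSD threshold (Angstrom), default 20.
#' @param dwell minimum consecutive frames above threshold, default 100.
#' @return integer frame index of the release, or \code{NA_integer_}.
#' @export
detect_release <- function(series, threshold = 20, dwell = 100) {
  x <- series$ligand_rmsd
  if (is.null(x)) stop("series has no ligand_rmsd")
  n <- length(x)
  if (!is.finite(threshold)) return(NA_integer_)
  above <- x > threshold
  sufmin <- rev(cummin(rev(x)))          # min of x[i..n]
  runlen <- integer(n)                   # length of the above-run starting at i
  for (i in n:1)
    runlen[i] <- if (above[i]) (if (i < n) runlen[i + 1L] else 0L) + 1L else 0L
  ok <- which(runlen >= dwell & sufmin > threshold / 2)
  if (length(ok)) ok[1] else NA_integer_
}

#' Count compensatory ions coordinating a site
#'
#' Per-frame count of ion atoms within \code{cutoff} of any site atom, and
#' the mean over frames (the statistic behind "three compensatory sodium
#' ions on average").
#'
#' @param traj a [toy_trajectory()].
#' @param ion_sel,site_sel logical/integer atom row selectors into
#'   \code{traj$atoms} (e.g. \code{which(traj$atoms$element == "NA")}).
#' @param cutoff coordination cutoff (Angstrom).
#' @return list with \code{counts} (per frame) and \code{mean}.
#' @export
ion_coordination_count <- function(traj, ion_sel, site_sel, cutoff) {
  nf <- dim(traj$coords)[1]
  ion_sel <- if (is.logical(ion_sel)) which(ion_sel) else as.integer(ion_sel)
  site_sel <- if (is.logical(site_sel)) which(site_sel) else as.integer(site_sel)
  counts <- vapply(seq_len(nf), function(f) {
    if (!length(ion_sel) || !length(site_sel) || cutoff <= 0) return(0L)
    ions <- matrix(traj$coords[f, ion_sel, ], ncol = 3)
    site <- matrix(traj$coords[f, site_sel, ], ncol = 3)
    sum(vapply(seq_len(nrow(ions)), function(i) {
      any(rowSums(sweep(site, 2, ions[i, ])^2) <= cutoff^2)
    }, logical(1)))
  }, integer(1))
  list(counts = counts, mean = mean(counts))
}

#' Adaptive-protocol plan
#'
#' One row per protocol level: how many seed frames, how many replicas per
#' seed, how long each replica runs.
#'
#' @param levels data.frame with columns \code{n_seed_frames},
#'   \code{replicas_per_seed}, \code{replica_length_ns}.
#' @return validated data.frame, class \code{protocol_plan}.
#' @export
protocol_plan <- function(levels) {
  req <- c("n_seed_frames", "replicas_per_seed", "replica_length_ns")
  if (!all(req %in% names(levels)))
    stop("protocol_plan needs columns: ", paste(req, collapse = ", "))
  if (any(levels$n_seed_frames < 0) || any(levels$replicas_per_seed < 0))
    stop("counts must be >= 0")
  if (any(levels$replica_length_ns <= 0))
    stop("replica lengths must be > 0")
  class(levels) <- c("protocol_plan", "data.frame")
  levels
}

#' The three-level adaptive seeding plan
#'
#' Level 1: one starting structure, three replicas of 1000 ns. Level 2: two
#' selected frames, five replicas of 150 ns each. Level 3: seven selected
#' frames, five replicas of 150 ns each. Totals 9.75 microseconds.
#'
#' @return a [protocol_plan()].
#' @export
adaptive_seeding_plan <- function() {
  protocol_plan(data.frame(
    level = 1:3,
    n_seed_frames = c(1L, 2L, 7L),
    replicas_per_seed = c(3L, 5L, 5L),
    replica_length_ns = c(1000, 150, 150)))
}

#' Simulation-time ledger for a protocol plan
#'
#' @param plan a [protocol_plan()].
#' @return list with \code{total_us} (microseconds) and \code{per_level}
#'   (the plan with an added \code{time_us} column).
#' @export
sim_time_ledger <- function(plan) {
  stopifnot(inherits(plan, "protocol_plan"))
  t_ns <- plan$n_seed_frames * plan$replicas_per_seed * plan$replica_length_ns
  per <- as.data.frame(plan)
  per$time_us <- t_ns / 1000
  list(total_us = sum(t_ns) / 1000, per_level = per)
}
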