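## Synthetic-data generators with known ground truth: filament metadata
## tables, toy structure pairs, and Langevin ligand-escape trajectories.
## Everything downstream is testable against what these record.

#' Specification for a synthetic filament metadata table
#'
#' Describes the stated world of a simulated cryo-EM filament dataset:
#' smoothly bending filaments (quadratic orientation drift), additive
#' Gaussian angular/shift noise, a fraction of misaligned outlier segments,
#' and per-segment register votes drawn from a row-stochastic confusion
#' matrix over the 2N seam/register classes of the lattice.
#'
#' @param n_filaments number of microtubules.
#' @param segments_per_filament segments per microtubule (>= 1).
#' @param lattice a [helical_lattice()].
#' @param angle_noise_sd Gaussian noise SD on angles (degrees).
#' @param shift_noise_sd Gaussian noise SD on origin shifts (Angstrom).
#' @param outlier_fraction fraction of segments misaligned, in [0, 1].
#' @param outlier_magnitude half-width of the uniform outlier perturbation
#'   (degrees for angles, Angstrom for shifts); outliers replace, not add
#'   to, the Gaussian noise.
#' @param class_confusion row-stochastic 2N x 2N matrix: row r is the vote
#'   distribution of a filament whose true register is r-1. Default:
#'   identity (perfect classification).
#' @param true_registers optional integer vector (length n_filaments) of
#'   true register indices in [0, 2N); drawn uniformly when NULL.
#' @param seed integer RNG seed.
#' @return validated list of class \code{filament_sim_spec}.
#' @export
filament_sim_spec <- function(n_filaments, segments_per_filament, lattice,
                              angle_noise_sd = 0, shift_noise_sd = 0,
                              outlier_fraction = 0, outlier_magnitude = 0,
                              class_confusion = NULL, true_registers = NULL,
                              seed = 1L) {
  stopifnot(inherits(lattice, "helical_lattice"))
  if (segments_per_filament < 1) stop("segments_per_filament must be >= 1")
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stop("outlier_fraction must be in [0, 1]")
  n_classes <- 2L * lattice$n_pf
  if (is.null(class_confusion)) class_confusion <- diag(n_classes)
  class_confusion <- as.matrix(class_confusion)
  if (!all(dim(class_confusion) == n_classes))
    stop("class_confusion must be ", n_classes, " x ", n_classes)
  if (any(class_confusion < 0) ||
      any(abs(rowSums(class_confusion) - 1) > 1e-9))
    stop("class_confusion rows must be non-negative and sum to 1 (1e-9)")
  if (!is.null(true_registers)) {
    if (length(true_registers) != n_filaments ||
        any(true_registers < 0 | true_registers >= n_classes))
      stop("true_registers must be length n_filaments, values in [0, 2N)")
  }
  structure(list(n_filaments = as.integer(n_filaments),
                 segments_per_filament = as.integer(segments_per_filament),
                 lattice = lattice, angle_noise_sd = angle_noise_sd,
                 shift_noise_sd = shift_noise_sd,
                 outlier_fraction = outlier_fraction,
                 outlier_magnitude = outlier_magnitude,
                 class_confusion = class_confusion,
                 true_registers = true_registers, seed = as.integer(seed)),
            class = "filament_sim_spec")
}

## quadratic drift: value(s) = a0 + a1 s + a2 s^2, coefficients drawn once
## per filament from ranges emulating slowly bending microtubules
.draw_drift <- function(s, a0_range, a1_range, a2_range) {
  a0 <- stats::runif(1, a0_range[1], a0_range[2])
  a1 <- stats::runif(1, a1_range[1], a1_range[2])
  a2 <- stats::runif(1, a2_range[1], a2_range[2])
  a0 + a1 * s + a2 * s^2
}

#' Generate a synthetic filament table with ground truth
#'
#' True psi/phi and origin shifts vary as per-filament quadratics in the
#' segment index; observations add Gaussian noise, with an
#' \code{outlier_fraction} of rows replaced by uniform perturbations of
#' half-width \code{outlier_magnitude} (modelling alignment to a wrong
#' lattice site). Register votes are i.i.d. draws from the confusion row of
#' the filament's true register. Fixed seed gives identical output.
#'
#' @param spec a [filament_sim_spec()].
#' @return list with \code{table} (a [filament_table()], votes in
#'   \code{class_id}) and \code{truth} (list: \code{table} of true values,
#'   \code{true_registers} named by filament id).
#' @export
make_filament_table <- function(spec) {
  stopifnot(inherits(spec, "filament_sim_spec"))
  set.seed(spec$seed)
  n_classes <- 2L * spec$lattice$n_pf
  regs <- if (is.null(spec$true_registers))
    sample.int(n_classes, spec$n_filaments, replace = TRUE) - 1L
  else as.integer(spec$true_registers)
  rows <- truth_rows <- vector("list", spec$n_filaments)
  for (f in seq_len(spec$n_filaments)) {
    s <- seq_len(spec$segments_per_filament)
    true_psi <- wrap_angle(.draw_drift(s, c(-180, 180), c(-1, 1), c(-0.02, 0.02)))
    true_phi <- wrap_angle(.draw_drift(s, c(-180, 180), c(-0.5, 0.5), c(-0.01, 0.01)))
    true_x <- .draw_drift(s, c(-20, 20), c(-1, 1), c(-0.05, 0.05))
    true_y <- .draw_drift(s, c(-20, 20), c(-1, 1), c(-0.05, 0.05))
    n <- length(s)
    noise <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
    psi <- true_psi + noise(spec$angle_noise_sd)
    phi <- true_phi + noise(spec$angle_noise_sd)
    ox <- true_x + noise(spec$shift_noise_sd)
    oy <- true_y + noise(spec$shift_noise_sd)
    out_rows <- stats::runif(n) < spec$outlier_fraction
    if (any(out_rows)) {
      m <- sum(out_rows); w <- spec$outlier_magnitude
      psi[out_rows] <- true_psi[out_rows] + stats::runif(m, -w, w)
      phi[out_rows] <- true_phi[out_rows] + stats::runif(m, -w, w)
      ox[out_rows] <- true_x[out_rows] + stats::runif(m, -w, w)
      oy[out_rows] <- true_y[out_rows] + stats::runif(m, -w, w)
    }
    votes <- sample.int(n_classes, n, replace = TRUE,
                        prob = spec$class_confusion[regs[f] + 1L, ]) - 1L
    rows[[f]] <- data.frame(
      filament_id = f, segment_index = s,
      rot = wrap_angle(phi), tilt = 90, psi = wrap_angle(psi),
      origin_x = ox, origin_y = oy, class_id = votes)
    truth_rows[[f]] <- data.frame(
      filament_id = f, segment_index = s,
      rot = true_phi, tilt = 90, psi = true_psi,
      origin_x = true_x, origin_y = true_y, class_id = regs[f])
  }
  table <- filament_table(do.call(rbind, rows))
  truth <- list(table = do.call(rbind, truth_rows),
                true_registers = stats::setNames(regs, seq_len(spec$n_filaments)))
  list(table = table, truth = truth)
}

#' Write a synthetic filament dataset to disk
#'
#' The observed table goes to a Relion-dialect STAR file; the ground truth
#' to a JSON sidecar next to it.
#'
#' @param sim result of [make_filament_table()].
#' @param star_path output STAR path; the sidecar is
#'   \code{<star_path>.truth.json}.
#' @return invisibly, the two paths.
#' @export
write_filament_sim <- function(sim, star_path) {
  write_filament_star(sim$table, star_path)
  truth_path <- paste0(star_path, ".truth.json")
  jsonlite::write_json(
    list(true_registers = as.list(sim$truth$true_registers),
         table = sim$truth$table),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(star = star_path, truth = truth_path))
}

#' Construct a toy structure pair with known transform and displacements
#'
#' Builds a random non-collinear Calpha cloud (the reference), applies the
#' inverse of a stated rigid transform to obtain the mobile model, and
#' additionally moves selected residues by stated vectors *after* the rigid
#' transform, so that superposition on the undisplaced set recovers the
#' displacement magnitudes exactly.
#'
#' @param n_residues number of residues (>= 3).
#' @param rotation_angle true rotation angle (degrees) about a random axis.
#' @param displaced named list/vector: residue number -> displacement
#'   magnitude (Angstrom) applied along a recorded random direction.
#' @param translation true translation 3-vector, default zero.
#' @param seed RNG seed.
#' @return list of class \code{toy_structure_pair}: \code{reference},
#'   \code{mobile} ([structure_model()]s), \code{true_rotation},
#'   \code{true_translation}, \code{displaced} (data.frame resno,
#'   magnitude, dx, dy, dz).
#' @export
make_toy_structure_pair <- function(n_residues, rotation_angle = 0,
                                    displaced = list(),
                                    translation = c(0, 0, 0), seed = 1L) {
  if (n_residues < 3) stop("n_residues must be >= 3 (superposition underdetermined)")
  set.seed(seed)
  repeat {
    xyz <- matrix(stats::rnorm(3 * n_residues, sd = 10), ncol = 3)
    if (svd(sweep(xyz, 2, colMeans(xyz)))$d[2] > 1e-3) break
  }
  ref_atoms <- data.frame(
    chain = "A", resno = seq_len(n_residues), resname = "ALA", atom = "CA",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  reference <- structure_model(ref_atoms, selections = list())
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- rotation_angle * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  # mobile = R^-1 (reference - t); then T(mobile) = reference exactly
  mob_xyz <- sweep(xyz, 2, translation) %*% R  # == t(R^-1 %*% t(...))
  disp_df <- data.frame(resno = integer(0), magnitude = numeric(0),
                        dx = numeric(0), dy = numeric(0), dz = numeric(0))
  if (length(displaced)) {
    resnos <- as.integer(names(displaced))
    if (any(is.na(resnos)) || any(!resnos %in% seq_len(n_residues)))
      stop("displaced names must be valid residue numbers")
    for (k in seq_along(resnos)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      v <- unlist(displaced[k]) * u
      # displacement applied after the rigid transform: shift the mobile
      # atom by R^-1 v so that T(mobile) = reference + v
      mob_xyz[resnos[k], ] <- mob_xyz[resnos[k], ] + as.numeric(v %*% R)
      disp_df <- rbind(disp_df, data.frame(
        resno = resnos[k], magnitude = unlist(displaced[k]),
        dx = v[1], dy = v[2], dz = v[3]))
    }
  }
  mob_atoms <- ref_atoms
  mob_atoms$x <- mob_xyz[, 1]; mob_atoms$y <- mob_xyz[, 2]
  mob_atoms$z <- mob_xyz[, 3]
  structure(list(reference = reference,
                 mobile = structure_model(mob_atoms, selections = list()),
                 true_rotation = R, true_translation = translation,
                 displaced = disp_df),
            class = "toy_structure_pair")
}

#' Specification for a synthetic ligand-escape trajectory
#'
#' A ligand particle diffuses (overdamped Langevin) in a flat-bottomed
#' harmonic well of stated depth; an outward radial bias models the driving
#' force toward release. With zero bias the distance series is stationary
#' (bound ligand); when the bias exceeds the maximal restoring force the
#' particle escapes and the distance grows without bound.
#'
#' @param well_depth well depth in kT units, default 8.
#' @param noise_scale dimensionless thermal noise scale (> 0), default 1.
#' @param n_frames number of frames (>= 2), default 5000.
#' @param timestep integration step in ns-equivalents, default 0.05.
#' @param escape_bias outward radial drift (dimensionless), default 0.
#' @param well_width radius (Angstrom) at which the well flattens,
#'   default 10.
#' @param seed RNG seed.
#' @return validated list of class \code{escape_trajectory_spec}.
#' @export
escape_trajectory_spec <- function(well_depth = 8, noise_scale = 1,
                                   n_frames = 5000, timestep = 0.05,
                                   escape_bias = 0, well_width = 10,
                                   seed = 1L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (noise_scale <= 0) stop("noise scale must be > 0")
  if (well_depth <= 0 || well_width <= 0 || timestep <= 0)
    stop("well_depth, well_width and timestep must be > 0")
  structure(list(well_depth = well_depth, noise_scale = noise_scale,
                 n_frames = as.integer(n_frames), timestep = timestep,
                 escape_bias = escape_bias, well_width = well_width,
                 seed = as.integer(seed)),
            class = "escape_trajectory_spec")
}

#' Simulate a ligand-in-well escape trajectory
#'
#' Euler-Maruyama integration of the overdamped Langevin equation in 3D:
#' restoring force \code{-k r} inside the well (spring constant
#' \code{k = 2 well_depth / well_width^2}), capped at \code{k well_width}
#' outside, plus the outward \code{escape_bias}; thermal kicks of scale
#' \code{sqrt(2 noise_scale^2 dt)}. Escape is deterministic in drift once
#' \code{escape_bias > k * well_width}. The ligand starts at the well
#' centre; the reported \code{ligand_rmsd} is its distance from the start.
#'
#' @param spec an [escape_trajectory_spec()].
#' @return a [trajectory_series()] with one distance column
#'   (\code{"ligand_site"}) and a \code{ligand_rmsd} series; the 3D path is
#'   attached as attribute \code{"coords"}.
#' @export
make_escape_trajectory <- function(spec) {
  stopifnot(inherits(spec, "escape_trajectory_spec"))
  set.seed(spec$seed)
  k <- 2 * spec$well_depth / spec$well_width^2
  dt <- spec$timestep
  sig <- sqrt(2 * spec$noise_scale^2 * dt)
  x <- matrix(0, spec$n_frames, 3)
  pos <- c(0, 0, 0)
  for (i in 2:spec$n_frames) {
    r <- sqrt(sum(pos^2))
    drift <- if (r < 1e-12) c(0, 0, 0) else {
      u <- pos / r
      (-min(k * r, k * spec$well_width) + spec$escape_bias) * u
    }
    pos <- pos + drift * dt + sig * stats::rnorm(3)
    x[i, ] <- pos
  }
  dist <- sqrt(rowSums(x^2))
  ts <- trajectory_series(times = seq_len(spec$n_frames) * dt,
                          distances = matrix(dist, ncol = 1,
                                             dimnames = list(NULL, "ligand_site")),
                          ligand_rmsd = dist)
  attr(ts, "coords") <- x
  ts
}

#' Write a trajectory series as CSV (and optional XYZ path)
#'
#' @param series a [trajectory_series()].
#' @param csv_path output CSV (frame, time, one column per observable).
#' @param xyz_path optional XYZ output of the attached 3D path.
#' @return invisibly, the CSV path.
#' @export
write_trajectory_csv <- function(series, csv_path, xyz_path = NULL) {
  df <- data.frame(frame = seq_along(series$times), time_ns = series$times)
  if (ncol(series$distances)) df <- cbind(df, series$distances)
  if (!is.null(series$ligand_rmsd)) df$ligand_rmsd <- series$ligand_rmsd
  utils::write.csv(df, csv_path, row.names = FALSE)
  coords <- attr(series, "coords")
  if (!is.null(xyz_path) && !is.null(coords)) {
    con <- file(xyz_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(coords))) {
      writeLines(c("1", sprintf("frame %d", i),
                   sprintf("L %.6f %.6f %.6f", coords[i, 1], coords[i, 2],
                           coords[i, 3])), con)
    }
  }
  invisible(csv_path)
}
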