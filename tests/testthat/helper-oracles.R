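# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (Kabsch/SVD, pose composition) so that agreement
# is evidence, not tautology.

# Horn's quaternion method for optimal rigid superposition: returns the
# minimal RMSD mapping p onto q (n x 3 matrices, paired rows).
quaternion_rmsd <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  M <- t(pc) %*% qc
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(pc^2) + sum(qc^2) - 2 * lam) / nrow(p)
  sqrt(max(0, msd))
}

# 4x4 homogeneous transform of a Relion pose: x = A r + t
pose_homogeneous <- function(rot, tilt, psi, ox, oy) {
  H <- diag(4)
  H[1:3, 1:3] <- euler_to_matrix(rot, tilt, psi)
  H[1:3, 4] <- c(ox, oy, 0)
  H
}

# helical symmetry operator as homogeneous matrix (reference frame)
sym_homogeneous <- function(delta_phi, delta_z) {
  r <- delta_phi * pi / 180
  H <- diag(4)
  H[1:2, 1:2] <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  H[3, 4] <- delta_z
  H
}

# brute-force mode with smallest-value tie rule
brute_mode <- function(x) {
  counts <- vapply(sort(unique(x)), function(v) sum(x == v), numeric(1))
  sort(unique(x))[which.max(counts)]  # which.max takes first = smallest value
}

# mean circular error (degrees) between two angle vectors
mean_circ_error <- function(a, b) mean(circular_distance(a, b))

# small all-CA filament-free structure helpers
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1-2*(y^2+z^2), 2*(x*y+w*z),   2*(x*z-w*y),
           2*(x*y-w*z),   1-2*(x^2+z^2), 2*(y*z+w*x),
           2*(x*z+w*y),   2*(y*z-w*x),   1-2*(x^2+y^2)), 3, 3)
}

axis_rotation <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
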