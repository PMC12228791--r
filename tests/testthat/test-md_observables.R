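# hand-built trajectory fixtures -----------------------------------------

mk_traj <- function(coord_list, atoms) {
  # coord_list: list of n_atoms x 3 matrices, one per frame
  nf <- length(coord_list)
  arr <- array(0, dim = c(nf, nrow(atoms), 3))
  for (f in seq_len(nf)) arr[f, , ] <- coord_list[[f]]
  toy_trajectory(atoms, arr)
}

pocket_atoms <- data.frame(
  chain = "A",
  resno = c(75:95, 199, 500),
  atom = c(rep("CA", 22), "PB"),
  resname = c(rep("GLY", 22), "ADP"),
  element = c(rep("C", 22), "P"))

test_that("pair distances match hand geometry and permute with pair order", {
  atoms <- data.frame(chain = "A", resno = c(87, 500), atom = c("CA", "PB"),
                      resname = c("THR", "ADP"), element = c("C", "P"))
  f1 <- rbind(c(0, 0, 0), c(3, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(3, 4, 0))
  traj <- mk_traj(list(f1, f2), atoms)
  pairs <- monitored_pairs(data.frame(
    label = "bP-T87", a_resno = 500, a_atom = "PB",
    b_resno = 87, b_atom = "CA"))
  s <- pair_distance_series(traj, pairs)
  expect_equal(unname(s$distances[, 1]), c(3, 5))

  # static frames: constant distance
  static <- mk_traj(list(f1, f1, f1), atoms)
  expect_equal(unname(pair_distance_series(static, pairs)$distances[, 1]),
               rep(3, 3))

  # permuting pairs permutes columns only
  two <- monitored_pairs(data.frame(
    label = c("p1", "p2"),
    a_resno = c(500, 87), a_atom = c("PB", "CA"),
    b_resno = c(87, 500), b_atom = c("CA", "PB")))
  rev2 <- two[2:1, ]
  d1 <- pair_distance_series(traj, two)$distances
  d2 <- pair_distance_series(traj, rev2)$distances
  expect_equal(d1[, c("p2", "p1")], d2[, c("p2", "p1")])

  missing <- monitored_pairs(data.frame(
    label = "bad", a_resno = 1, a_atom = "XX", b_resno = 87, b_atom = "CA"))
  expect_error(pair_distance_series(traj, missing), "bad")
})

test_that("fluctuation statistics: closed forms and sampling oracle", {
  const <- trajectory_series(1:100, matrix(2, 100, 1,
                                           dimnames = list(NULL, "d")))
  fl <- distance_fluctuation_sd(list(const))
  expect_equal(unname(fl$mean), 0)

  # i.i.d. Gaussian sigma = 0.5, 10^4 frames
  set.seed(31)
  g <- trajectory_series(1:10000,
                         matrix(10 + rnorm(10000, sd = 0.5), ncol = 1,
                                dimnames = list(NULL, "d")))
  expect_lt(abs(distance_fluctuation_sd(list(g))$mean - 0.5), 0.02)

  # two replicas with SDs 1 and 3: mean 2, sem 1
  mk_sd <- function(target) {
    x <- rep(c(-1, 1), 50) * target  # sample sd = target * sqrt(100/99)
    trajectory_series(1:100, matrix(x * sqrt(99 / 100), ncol = 1,
                                    dimnames = list(NULL, "d")))
  }
  fl2 <- distance_fluctuation_sd(list(mk_sd(1), mk_sd(3)))
  expect_equal(unname(fl2$mean), 2, tolerance = 1e-9)
  expect_equal(unname(fl2$sem), 1, tolerance = 1e-9)

  single <- trajectory_series(1, matrix(1, 1, 1, dimnames = list(NULL, "d")))
  expect_error(distance_fluctuation_sd(list(single)), "single-frame")
})

test_that("ligand RMSD is zero for the reference, invariant to rigid motion,
           and recovers constructed displacements", {
  set.seed(32)
  n_at <- nrow(pocket_atoms)
  base <- matrix(rnorm(3 * n_at, sd = 6), ncol = 3)
  lig <- which(pocket_atoms$resno == 500)

  # frame 2 = rigid motion of everything; frame 3 = rigid motion plus a
  # genuine 2 A ligand shift applied before the motion
  R <- random_rotation(); t <- c(4, -7, 2)
  f2 <- sweep(base %*% t(R), 2, t, `+`)
  shift <- c(2, 0, 0)
  base3 <- base; base3[lig, ] <- base3[lig, ] + rep(shift, each = length(lig))
  f3 <- sweep(base3 %*% t(R), 2, t, `+`)
  traj <- mk_traj(list(base, f2, f3), pocket_atoms)

  r <- ligand_rmsd_series(traj, ligand_resno = 500, align_resno = 75:95)
  expect_lt(r[1], 1e-12)
  expect_lt(r[2], 1e-9)               # global motion cancels exactly
  expect_equal(r[3], 2.0, tolerance = 1e-6)

  expect_error(ligand_rmsd_series(traj, ligand_resno = 999), "ligand")
  few <- pocket_atoms[c(1, 2, 23), ]
  expect_error(
    ligand_rmsd_series(mk_traj(list(base[c(1, 2, 23), ]), few), 500),
    "alignment")
})

test_that("density2d is a normalised counting histogram", {
  one <- density2d(1, 2, bins = 5)
  expect_equal(sum(one$density), 1)
  expect_equal(sum(one$density == 1), 1)

  # uniform grid: equal masses
  g <- expand.grid(x = seq(0.5, 9.5, 1), y = seq(0.5, 9.5, 1))
  h <- density2d(g$x, g$y, bins = 10)
  expect_true(all(abs(h$density - 0.01) < 1e-12))

  set.seed(33)
  rnd <- density2d(rnorm(500), rnorm(500), bins = 7)
  expect_equal(sum(rnd$density), 1, tolerance = 1e-12)
  expect_error(density2d(numeric(0), numeric(0)), "non-empty")
})

test_that("restart-frame selection: monotone case, ties, exhaustive oracle", {
  # monotone increasing RMSD and deviations: top-2 are the last two frames
  up <- trajectory_series(1:50,
                          matrix(seq(10, 20, length.out = 50), ncol = 1,
                                 dimnames = list(NULL, "d")),
                          ligand_rmsd = seq(0, 5, length.out = 50))
  expect_setequal(select_restart_frames(up, 2), c(49, 50))

  # constant series: tie rule picks the earliest frames
  flat <- trajectory_series(1:20, matrix(3, 20, 1,
                                         dimnames = list(NULL, "d")),
                            ligand_rmsd = rep(1, 20))
  expect_equal(select_restart_frames(flat, 2), c(1, 2))

  expect_error(select_restart_frames(flat, 21), "exceeds")
  expect_error(select_restart_frames(flat, 0), ">= 1")

  # random series agree with brute-force argmax of the documented score
  set.seed(34)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    d <- matrix(rnorm(3 * n, sd = 2) + 10, ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    s <- trajectory_series(seq_len(n), d, ligand_rmsd = abs(rnorm(n)))
    z <- function(v) if (sd(v) < 1e-12) 0 * v else (v - mean(v)) / sd(v)
    dev <- abs(sweep(d, 2, d[1, ]))
    score <- z(s$ligand_rmsd) + rowMeans(apply(dev, 2, z))
    k <- sample(1:5, 1)
    got <- select_restart_frames(s, k)
    ord <- order(-score, seq_len(n))
    expect_equal(got, ord[seq_len(k)])
    # selected frames always score above the trajectory mean (enrichment)
    expect_gt(mean(score[got]), mean(score) - 1e-12)
  }
})

test_that("selection is invariant to affine rescaling of one observable", {
  set.seed(35)
  n <- 40
  d <- matrix(rnorm(2 * n) + 8, ncol = 2, dimnames = list(NULL, c("a", "b")))
  s1 <- trajectory_series(seq_len(n), d, ligand_rmsd = abs(rnorm(n)))
  d2 <- d; d2[, 1] <- 5.5 * d2[, 1] + 3
  s2 <- trajectory_series(seq_len(n), d2, ligand_rmsd = s1$ligand_rmsd)
  expect_equal(select_restart_frames(s1, 5), select_restart_frames(s2, 5))
})

test_that("release detection: bounded none, forced finite, threshold Inf none", {
  bound <- make_escape_trajectory(
    escape_trajectory_spec(n_frames = 10000, escape_bias = 0, seed = 2L))
  expect_identical(detect_release(bound, 20, 100), NA_integer_)
  expect_identical(detect_release(bound, Inf, 1), NA_integer_)

  esc <- make_escape_trajectory(
    escape_trajectory_spec(n_frames = 3000, escape_bias = 6, seed = 3L))
  f <- detect_release(esc, threshold = 15, dwell = 50)
  expect_false(is.na(f))
  # fires only after the constructed crossing
  expect_true(all(esc$ligand_rmsd[f:(f + 49)] > 15))
  expect_true(all(esc$ligand_rmsd[f:length(esc$ligand_rmsd)] > 7.5))
  if (f > 1) expect_false(all(esc$ligand_rmsd[(f - 1):(f + 48)] > 15) &&
                          all(esc$ligand_rmsd[(f - 1):length(esc$ligand_rmsd)] > 7.5))
})

test_that("higher escape bias gives stochastically earlier release (20 seeds)", {
  med_release <- function(bias) {
    frames <- vapply(1:20, function(s) {
      tr <- make_escape_trajectory(
        escape_trajectory_spec(n_frames = 3000, escape_bias = bias, seed = s))
      f <- detect_release(tr, threshold = 15, dwell = 50)
      if (is.na(f)) 3000L else f
    }, integer(1))
    median(frames)
  }
  m <- c(med_release(3), med_release(5), med_release(8))
  expect_true(all(diff(m) < 0))
})

test_that("ion coordination counts constructed geometries", {
  atoms <- data.frame(chain = "A", resno = c(1, 2, 3, 4, 5),
                      atom = c("O1", "NA", "NA", "NA", "NA"),
                      resname = c("SITE", rep("NA", 4)),
                      element = c("O", rep("NA", 4)))
  # three ions within 4 A of the site atom at origin, one far away
  f1 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(0, 0, 3.9), c(20, 0, 0))
  traj <- mk_traj(list(f1, f1), atoms)
  ions <- which(atoms$element == "NA")
  site <- which(atoms$resname == "SITE")
  res <- ion_coordination_count(traj, ions, site, cutoff = 4)
  expect_equal(res$counts, c(3L, 3L))
  expect_equal(res$mean, 3)
  expect_equal(ion_coordination_count(traj, ions, site, cutoff = 0)$mean, 0)
  expect_equal(ion_coordination_count(traj, integer(0), site, 4)$mean, 0)
})

test_that("simulation-time ledger sums the adaptive plan", {
  led <- sim_time_ledger(adaptive_seeding_plan())
  expect_equal(led$total_us, 9.75)
  expect_equal(led$per_level$time_us, c(3, 1.5, 5.25))

  empty <- protocol_plan(data.frame(n_seed_frames = integer(0),
                                    replicas_per_seed = integer(0),
                                    replica_length_ns = numeric(0)))
  expect_equal(sim_time_ledger(empty)$total_us, 0)

  set.seed(36)
  for (i in 1:10) {
    lv <- data.frame(n_seed_frames = sample(0:5, 3, TRUE),
                     replicas_per_seed = sample(0:6, 3, TRUE),
                     replica_length_ns = runif(3, 1, 500))
    got <- sim_time_ledger(protocol_plan(lv))$total_us
    brute <- 0
    for (r in 1:3) brute <- brute +
      lv$n_seed_frames[r] * lv$replicas_per_seed[r] * lv$replica_length_ns[r]
    expect_equal(got, brute / 1000, tolerance = 1e-12)
  }
  expect_error(protocol_plan(data.frame(n_seed_frames = -1,
                                        replicas_per_seed = 1,
                                        replica_length_ns = 10)), ">= 0")
})

test_that("trajectory CSV writer round-trips observables", {
  tr <- make_escape_trajectory(
    escape_trajectory_spec(n_frames = 50, seed = 4L))
  csv <- tempfile(fileext = ".csv"); xyz <- tempfile(fileext = ".xyz")
  write_trajectory_csv(tr, csv, xyz)
  back <- read.csv(csv)
  expect_equal(back$ligand_site, unname(tr$distances[, 1]), tolerance = 1e-6)
  expect_equal(nrow(back), 50)
  expect_equal(length(readLines(xyz)), 150)
  unlink(c(csv, xyz))
})
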