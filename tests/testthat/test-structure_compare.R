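test_that("superposition recovers identity and pure rotations", {
  pair <- make_toy_structure_pair(15, rotation_angle = 0, seed = 1L)
  sup <- superpose(pair$mobile, pair$reference)
  expect_lt(sup$rmsd_global, 1e-9)
  expect_lt(sup$rotation_angle, 1e-4)

  rot90 <- make_toy_structure_pair(15, rotation_angle = 90, seed = 2L)
  sup90 <- superpose(rot90$mobile, rot90$reference)
  expect_lt(sup90$rmsd_global, 1e-9)
  expect_equal(sup90$rotation_angle, 90, tolerance = 1e-6)
  expect_equal(det(sup90$rotation), 1, tolerance = 1e-9)
})

test_that("superposition RMSD equals the quaternion oracle on random clouds", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    p <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
    q <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
    atoms <- function(m) data.frame(chain = "A", resno = seq_len(n),
                                    resname = "GLY", atom = "CA",
                                    element = "C",
                                    x = m[, 1], y = m[, 2], z = m[, 3])
    sup <- superpose(structure_model(atoms(p), list()),
                     structure_model(atoms(q), list()))
    expect_equal(sup$rmsd_global, quaternion_rmsd(p, q), tolerance = 1e-9)
  }
})

test_that("superposition is invariant to rigid pre-transforms of the mobile", {
  set.seed(5)
  base <- make_toy_structure_pair(20, rotation_angle = 30,
                                  displaced = list(`7` = 2.5), seed = 6L)
  ref_rmsd <- superpose(base$mobile, base$reference)$rmsd_global
  for (i in 1:100) {
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    moved <- transform_model(base$mobile, R, t)
    expect_equal(superpose(moved, base$reference)$rmsd_global, ref_rmsd,
                 tolerance = 1e-9)
  }
})

test_that("rotation angles add for rotations about a shared axis", {
  set.seed(6)
  for (i in 1:20) {
    ax <- rnorm(3)
    a <- runif(1, 5, 85); b <- runif(1, 5, 85)
    R12 <- axis_rotation(ax, a) %*% axis_rotation(ax, b)
    expect_equal(rotation_angle_axis(R12)$angle, a + b, tolerance = 1e-6)
  }
})

test_that("degenerate superpositions error out", {
  n <- 5
  line <- data.frame(chain = "A", resno = 1:n, resname = "GLY", atom = "CA",
                     element = "C", x = 1:n, y = 2 * (1:n), z = -(1:n))
  lm <- structure_model(line, list())
  expect_error(superpose(lm, lm), "collinear")
  pair <- make_toy_structure_pair(10, seed = 1L)
  small <- pair$mobile
  small$atoms <- small$atoms[1:2, ]
  expect_error(superpose(small, pair$reference), "fewer than 3")
  expect_error(superpose(pair$mobile, pair$reference,
                         selection = list(resno = 900:905)),
               "no atom pairs")
})

test_that("per-residue RMSD localises constructed displacements", {
  pair <- make_toy_structure_pair(30, rotation_angle = 25,
                                  displaced = list(`12` = 3.0), seed = 7L)
  # align on the undisplaced residues
  frame <- setdiff(1:30, 12)
  sup <- superpose(pair$mobile, pair$reference, selection = frame)
  per <- per_residue_rmsd(sup, pair$mobile, pair$reference)
  expect_equal(unname(per[["A 12"]]), 3.0, tolerance = 1e-6)
  others <- per[names(per) != "A 12"]
  expect_lt(max(others), 1e-6)

  # identity case: all zeros
  same <- make_toy_structure_pair(10, seed = 8L)
  sup0 <- superpose(same$mobile, same$reference)
  expect_lt(max(per_residue_rmsd(sup0, same$mobile, same$reference)), 1e-9)
})

test_that("global RMSD is the quadratic mean of per-residue values", {
  set.seed(9)
  n <- 12
  mk <- function(m) structure_model(
    data.frame(chain = "A", resno = seq_len(n), resname = "GLY", atom = "CA",
               element = "C", x = m[, 1], y = m[, 2], z = m[, 3]), list())
  p <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
  q <- p + matrix(rnorm(3 * n, sd = 1), ncol = 3)
  sup <- superpose(mk(p), mk(q))
  per <- per_residue_rmsd(sup, mk(p), mk(q))
  expect_equal(sqrt(mean(per^2)), sup$rmsd_global, tolerance = 1e-9)
})

test_that("Calpha displacement recovers constructed ground truth", {
  pair <- make_toy_structure_pair(30, rotation_angle = 40,
                                  displaced = list(`12` = 3.0), seed = 10L)
  frame <- setdiff(1:30, 12)
  d <- ca_displacement(pair$mobile, pair$reference, residue = 12,
                       frame = list(resno = frame))
  expect_equal(d, 3.0, tolerance = 1e-6)

  same <- make_toy_structure_pair(10, seed = 11L)
  expect_lt(ca_displacement(same$mobile, same$reference, residue = 5,
                            frame = list(resno = 1:10)), 1e-9)
  expect_error(ca_displacement(same$mobile, same$reference, residue = 99,
                               frame = list(resno = 1:10)), "residue")
})

test_that("inter-head rotation decomposition recovers a constructed 25 deg", {
  set.seed(12)
  # build a two-headed complex: chains A (anchor) and B (distal)
  mk_head <- function(chain, centre) {
    m <- matrix(rnorm(3 * 20, sd = 6), ncol = 3)
    data.frame(chain = chain, resno = 1:20, resname = "GLY", atom = "CA",
               element = "C", x = m[, 1] + centre[1], y = m[, 2] + centre[2],
               z = m[, 3] + centre[3])
  }
  A <- rbind(mk_head("A", c(0, 0, 0)), mk_head("B", c(40, 0, 0)))
  cA <- structure_model(A, list())
  # complex B: same anchor, distal head rotated 25 deg about a known axis
  # through its centroid
  ax <- c(0.3, -0.5, 0.8)
  R <- axis_rotation(ax, 25)
  B <- A
  bi <- B$chain == "B"
  xyz <- as.matrix(B[bi, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz2 <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr, `+`)
  B[bi, c("x", "y", "z")] <- xyz2
  cB <- structure_model(B, list())
  res <- rotation_between_heads(cA, cB, anchor = list(chain = "A"),
                                distal = list(chain = "B"))
  expect_equal(res$angle, 25, tolerance = 0.01)
  expect_true(res$axis_defined)
  expect_gt(abs(sum(res$axis * ax / sqrt(sum(ax^2)))), 0.999)

  ident <- rotation_between_heads(cA, cA, anchor = list(chain = "A"),
                                  distal = list(chain = "B"))
  expect_lt(ident$angle, 1e-4)
  expect_false(ident$axis_defined)
})

test_that("hydrogen-bond detection follows the geometric criteria", {
  # SER OG donor (antecedent CB) against an ASP OD1 acceptor at 2.8 A and
  # a 160 degree heavy-atom angle
  place_acceptor <- function(d, ang_deg) {
    # donor at origin, antecedent along +x; acceptor in the xy plane
    th <- ang_deg * pi / 180
    c(d * cos(th), d * sin(th), 0)
  }
  acc <- place_acceptor(2.8, 160)
  atoms <- data.frame(
    chain = "A",
    resno = c(10, 10, 20),
    resname = c("SER", "SER", "ASP"),
    atom = c("CB", "OG", "OD1"),
    element = c("C", "O", "O"),
    x = c(1.5, 0, acc[1]), y = c(0, 0, acc[2]), z = 0)
  net <- hbond_network(structure_model(atoms, list()))
  expect_equal(nrow(net), 1)
  expect_equal(net$label, "S10-D20")
  expect_equal(net$distance, 2.8, tolerance = 1e-9)
  expect_equal(net$angle, 160, tolerance = 1e-6)

  # too far: no edge
  far <- atoms; far[3, c("x", "y")] <- place_acceptor(4.5, 160)[1:2]
  expect_equal(nrow(hbond_network(structure_model(far, list()))), 0)

  # angle below the heavy-atom minimum: no edge
  bent <- atoms; bent[3, c("x", "y")] <- place_acceptor(2.8, 60)[1:2]
  expect_equal(nrow(hbond_network(structure_model(bent, list()))), 0)

  # empty model
  empty <- structure_model(atoms[0, ], list())
  expect_equal(nrow(hbond_network(empty)), 0)

  # unknown chemistry warns and skips
  odd <- atoms; odd$resname[3] <- "XYZ"
  expect_warning(net2 <- hbond_network(structure_model(odd, list())),
                 "unknown residue")
  expect_equal(nrow(net2), 0)
})

test_that("all reported H-bond edges respect the distance bound (subset check)", {
  set.seed(14)
  n <- 12
  atoms <- data.frame(
    chain = "A", resno = rep(1:n, each = 2),
    resname = rep(c("SER", "ASP"), n),
    atom = rep(c("OG", "OD1"), n),
    element = "O",
    x = rnorm(2 * n, sd = 4), y = rnorm(2 * n, sd = 4), z = rnorm(2 * n, sd = 4))
  atoms$resname <- ifelse(atoms$atom == "OG", "SER", "ASP")
  # give each SER its CB antecedent
  cb <- atoms[atoms$atom == "OG", ]
  cb$atom <- "CB"; cb$element <- "C"
  cb[, c("x", "y", "z")] <- cb[, c("x", "y", "z")] + 1.5
  model <- structure_model(rbind(atoms, cb), list())
  net <- hbond_network(model, d_max = 3.5)
  if (nrow(net)) expect_true(all(net$distance <= 3.5))
  # every edge is among the exhaustive set of close pairs
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  D <- as.matrix(dist(xyz))
  for (k in seq_len(nrow(net))) {
    i <- which(model$atoms$resno == net$donor_resno[k] &
               model$atoms$atom == net$donor_atom[k])
    j <- which(model$atoms$resno == net$acceptor_resno[k] &
               model$atoms$atom == net$acceptor_atom[k])
    expect_lte(D[i, j], 3.5)
  }
})

test_that("network diff is an exact set difference on labels", {
  mk_net <- function(labels) {
    df <- data.frame(label = labels)
    class(df) <- c("hbond_network", "data.frame")
    df
  }
  a <- mk_net(c("T92-D231", "R14-E236", "K91-E199"))
  expect_equal(network_diff(a, a), list(lost = character(0),
                                        gained = character(0)))
  b <- mk_net(c("R14-E236", "K91-E199", "D231-R190"))
  d <- network_diff(a, b)
  expect_equal(d$lost, "T92-D231")
  expect_equal(d$gained, "D231-R190")

  # brute-force set algebra on random label universes
  set.seed(15)
  for (i in 1:20) {
    u <- sprintf("P%d-Q%d", 1:30, 31:60)
    la <- sample(u, sample(5:20, 1))
    lb <- sample(u, sample(5:20, 1))
    d <- network_diff(mk_net(la), mk_net(lb))
    expect_setequal(d$lost, la[!la %in% lb])
    expect_setequal(d$gained, lb[!lb %in% la])
  }
})

test_that("PDB and mmCIF readers parse coordinates and identifiers", {
  pdb <- c(
    "HEADER    TEST",
    "ATOM      1  N   SER A  10       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  SER A  10       2.000   2.000   3.000  1.00 10.00           C",
    "ATOM      3  OG  SER A  10       2.500   3.100   3.000  1.00 10.00           O",
    "HETATM    4  PB  ADP A 500       9.000   8.000   7.000  1.00 10.00           P",
    "END")
  pf <- tempfile(fileext = ".pdb")
  writeLines(pdb, pf)
  m <- read_pdb(pf)
  expect_equal(nrow(m$atoms), 4)
  expect_equal(m$atoms$x[1], 1.0)
  expect_equal(m$atoms$atom[4], "PB")
  expect_equal(m$atoms$resno[4], 500)
  expect_equal(m$atoms$element[4], "P")
  expect_equal(select_atoms(m, list(resno = 10), atoms = "CA"), 2L)

  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "ATOM 1 N N SER A 10 1.000 2.000 3.000",
    "ATOM 2 C CA SER A 10 2.000 2.000 3.000",
    "#")
  cf <- tempfile(fileext = ".cif")
  writeLines(cif, cf)
  mc <- read_mmcif(cf)
  expect_equal(nrow(mc$atoms), 2)
  expect_equal(mc$atoms$y[2], 2.0)
  expect_equal(mc$atoms$chain, c("A", "A"))
  unlink(c(pf, cf))
})
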