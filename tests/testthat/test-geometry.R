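test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(structure_from_xyz(matrix(c(3, 4, 5),
                                                            ncol = 3))), 0)
  two <- structure_from_xyz(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(radius_of_gyration(two), 5)
  # uniform ball: Rg = sqrt(3/5) R
  set.seed(11)
  ball <- ball_cloud(1e5, 30)
  expect_equal(radius_of_gyration(structure_from_xyz(ball)),
               sqrt(3 / 5) * 30, tolerance = 0.01)
  # weighted version reduces to the weighted centroid second moment
  w <- c(1, 3)
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0))
  ctr <- 3
  expect_equal(radius_of_gyration(structure_from_xyz(xyz), weights = w),
               sqrt((1 * 9 + 3 * 1) / 4))
  expect_error(radius_of_gyration(structure_from_xyz(xyz), weights = c(1, -1)),
               "positive")
})

test_that("superposition recovers known transforms and matches an SVD oracle", {
  ab <- fx_antibody()
  self <- superpose(ab, ab)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-9)

  tr <- axis_rotation(c(1, -2, 0.5), 63, center = c(10, 0, -4))
  moved <- apply_transform(ab, tr)
  sp <- superpose(moved, ab)
  expect_lt(sp$rmsd, 1e-8)
  comp <- compose_transforms(tr, sp$transform)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-8)
  expect_lt(max(abs(comp$translation)), 1e-8)

  # perturbed case against bio3d's independent Kabsch implementation
  skip_if_not_installed("bio3d")
  set.seed(21)
  a <- ball_cloud(200, 15)
  b <- apply_transform(a, axis_rotation(c(1, 1, 1), 40)) +
    matrix(rnorm(600, 0, 0.1), ncol = 3)
  ours <- superpose(a, b)
  theirs <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
  oracle_rmsd <- sqrt(mean(rowSums((matrix(theirs, ncol = 3,
                                           byrow = TRUE) - b)^2)))
  expect_equal(ours$rmsd, oracle_rmsd, tolerance = 1e-9)
})

test_that("superposition is invariant to pre-rotation and rejects degeneracy", {
  set.seed(31)
  a <- ball_cloud(50, 10)
  b <- ball_cloud(50, 10)
  r1 <- superpose(a, b)$rmsd
  a2 <- apply_transform(a, axis_rotation(c(0, 1, 0), 111))
  expect_equal(superpose(a2, b)$rmsd, r1, tolerance = 1e-9)

  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate|collinear")
  expect_error(superpose(a[1:2, ], b[1:2, ]), ">= 3")
})

test_that("minimum pair distance equals an exhaustive double-loop oracle", {
  set.seed(41)
  a <- ball_cloud(300, 20)
  b <- sweep(ball_cloud(200, 20), 2, c(-45, 0, 0))
  d <- min_pair_distance(a, b)
  expect_equal(d, brute_min_dist(a, b), tolerance = 1e-9)
  expect_equal(d, min_pair_distance(b, a), tolerance = 1e-9)  # symmetry

  one <- matrix(c(0, 0, 0), ncol = 3)
  two <- matrix(c(7.99, 0, 0), ncol = 3)
  expect_equal(min_pair_distance(one, two), 7.99)
  expect_error(min_pair_distance(matrix(numeric(0), ncol = 3), a),
               "non-empty")
})

test_that("three-point angle covers boundary and random cases", {
  expect_equal(three_point_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(three_point_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(51)
  for (i in 1:20) {
    p1 <- rnorm(3); v <- rnorm(3); p2 <- rnorm(3)
    oracle <- acos(sum((p1 - v) * (p2 - v)) /
                   (sqrt(sum((p1 - v)^2)) * sqrt(sum((p2 - v)^2)))) * 180 / pi
    expect_equal(three_point_angle(p1, v, p2), oracle, tolerance = 1e-9)
  }
  expect_error(three_point_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
})

test_that("torsion rotation matches a Rodrigues oracle on a toy peptide", {
  # 5-residue ideal backbone built by the hinge generator
  ab <- fx_antibody()
  pep <- extract_structure(ab, label_indices(ab, "hinge1"))
  pep$info <- list()
  resno <- sort(unique(pep$atoms$resno))
  r <- resno[3]

  same <- apply_torsion(pep, "A", r, "phi", 0)
  expect_identical(coords(same), coords(pep))
  full <- apply_torsion(pep, "A", r, "phi", 360)
  expect_lt(max(abs(coords(full) - coords(pep))), 1e-9)

  rot <- apply_torsion(pep, "A", r, "psi", 30)
  # independent axis-angle (Rodrigues) rotation of the downstream atoms
  xyz <- coords(pep)
  ca <- which(pep$atoms$resno == r & pep$atoms$elety == "CA")
  cc <- which(pep$atoms$resno == r & pep$atoms$elety == "C")
  k <- xyz[ca, ] - xyz[cc, ]
  k <- k / sqrt(sum(k^2))
  th <- 30 * pi / 180
  down <- which(seq_len(nrow(xyz)) > cc)
  oracle <- xyz
  for (i in down) {
    v <- xyz[i, ] - xyz[ca, ]
    kxv <- c(k[2] * v[3] - k[3] * v[2], k[3] * v[1] - k[1] * v[3],
             k[1] * v[2] - k[2] * v[1])
    oracle[i, ] <- xyz[ca, ] + v * cos(th) + kxv * sin(th) +
      k * sum(k * v) * (1 - cos(th))
  }
  expect_lt(max(abs(coords(rot) - oracle)), 1e-9)

  # measured dihedral changes by +30 (mod 360)
  d0 <- measure_dihedral(pep, "A", r, "psi")
  d1 <- measure_dihedral(rot, "A", r, "psi")
  wrapped <- ((d1 - d0 - 30 + 180) %% 360) - 180
  expect_equal(wrapped, 0, tolerance = 1e-9)

  # upstream atoms untouched; pairwise distances preserved within each side
  up <- which(seq_len(nrow(xyz)) <= cc)
  expect_identical(coords(rot)[up, ], xyz[up, ])
  dd0 <- dist(xyz[down, ]); dd1 <- dist(coords(rot)[down, ])
  expect_lt(max(abs(dd0 - dd1)), 1e-9)

  expect_error(apply_torsion(pep, "A", resno[1], "phi", 10), "backbone")
})

test_that("rigid transforms compose and invert exactly", {
  tr <- axis_rotation(c(2, -1, 4), 97, center = c(1, 2, 3))
  inv <- invert_transform(tr)
  set.seed(61)
  x <- ball_cloud(30, 5)
  expect_lt(max(abs(apply_transform(apply_transform(x, tr), inv) - x)), 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
})
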