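test_that("atom_distance matches elementary cases and the norm oracle", {
  co <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(atom_distance(co, 1, 2), 5)
  expect_equal(atom_distance(rbind(c(1, 2, 3), c(1, 2, 3)), 1, 2), 0)
  set.seed(11)
  for (k in 1:50) {
    co <- matrix(rnorm(6, sd = 10), 2, 3)
    expect_equal(atom_distance(co, 1, 2), sqrt(sum((co[1, ] - co[2, ])^2)))
  }
  co_bad <- rbind(c(NaN, 0, 0), c(1, 1, 1))
  expect_error(atom_distance(co_bad, 1, 2), "non-finite")
})

test_that("min_group_distance matches brute force and breaks ties by index", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0))
  r <- min_group_distance(co, 1, 2)
  expect_equal(r$distance, 1)
  # constructed known minimum
  co <- rbind(c(0, 0, 0), c(10, 0, 0), c(2.41, 0, 0), c(8, 8, 8))
  r <- min_group_distance(co, c(1, 2), c(3, 4))
  expect_equal(r$distance, 2.41)
  expect_equal(c(r$index_a, r$index_b), c(1, 3))
  # tie: two pairs at the same distance -> lower-index pair
  co <- rbind(c(0, 0, 0), c(0, 5, 0), c(2, 0, 0), c(2, 5, 0))
  r <- min_group_distance(co, c(2, 1), c(4, 3))
  expect_equal(r$distance, 2)
  expect_equal(c(r$index_a, r$index_b), c(1, 3))
  set.seed(21)
  for (k in 1:200) {
    co <- matrix(rnorm(30, sd = 5), 10, 3)
    ga <- sample(10, 4); gb <- sample(10, 4)
    expect_equal(min_group_distance(co, ga, gb)$distance,
                 oracle_min_distance(co, ga, gb), tolerance = 1e-12)
  }
  expect_error(min_group_distance(co, integer(0), 1), "non-empty")
})

test_that("plane_angle keeps orientation, is symmetric, matches the oracle", {
  # two triples in one plane, normals parallel
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
              c(3, 0, 0), c(4, 0, 0), c(4, 1, 0))
  expect_equal(plane_angle(co, 1:3, 4:6), 0, tolerance = 1e-9)
  # perpendicular planes
  co2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
               c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  expect_equal(plane_angle(co2, 1:3, 4:6), 90, tolerance = 1e-9)
  # reversing one triple's turn direction must show up above 90 (no folding)
  co3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
               c(3, 0, 0), c(4, 0, 0), c(4, -1, 0))
  expect_equal(plane_angle(co3, 1:3, 4:6), 180, tolerance = 1e-9)
  set.seed(31)
  for (k in 1:200) {
    co <- matrix(rnorm(18, sd = 3), 6, 3)
    a <- plane_angle(co, 1:3, 4:6)
    expect_equal(a, oracle_plane_angle(co, 1:3, 4:6), tolerance = 1e-9)
    expect_equal(a, plane_angle(co, 4:6, 1:3), tolerance = 1e-12)
  }
  co_lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), co2[4:6, ])
  expect_error(plane_angle(co_lin, 1:3, 4:6), "collinear")
})

test_that("dihedral_angle follows the cis=0 convention and flips under reflection", {
  # planar cis (butadiene-like) and trans fragments
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(dihedral_angle(cis, 1, 2, 3, 4), 0, tolerance = 1e-9)
  trans <- rbind(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(abs(dihedral_angle(trans, 1, 2, 3, 4)), 180, tolerance = 1e-9)
  # hand-derived sign case: far substituent rotated +90 about the bond
  quarter <- rbind(c(1, 0, -0.5), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1.5))
  expect_equal(dihedral_angle(quarter, 1, 2, 3, 4), 90, tolerance = 1e-9)
  set.seed(41)
  for (k in 1:200) {
    co <- matrix(rnorm(12, sd = 2), 4, 3)
    d <- tryCatch(dihedral_angle(co, 1, 2, 3, 4), error = function(e) NULL)
    if (is.null(d)) next
    expect_equal(d, oracle_dihedral(co, 1, 2, 3, 4), tolerance = 1e-9)
    # mirror reflection flips the sign
    mir <- co; mir[, 3] <- -mir[, 3]
    expect_equal(dihedral_angle(mir, 1, 2, 3, 4), -d, tolerance = 1e-9)
    # atom-order reversal preserves the value under the convention
    expect_equal(dihedral_angle(co, 4, 3, 2, 1), d, tolerance = 1e-9)
  }
})

test_that("superpose_rmsd is exact on rigid motions and matches oracles", {
  set.seed(51)
  a <- matrix(rnorm(30, sd = 4), 10, 3)
  fit <- superpose_rmsd(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  for (k in 1:20) {
    b <- rigid_transform(a)
    expect_lt(superpose_rmsd(a, b)$rmsd, 1e-9)
  }
  # against the independent superposition in bio3d
  for (k in 1:10) {
    b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
    ours <- superpose_rmsd(a, b)$rmsd
    fitted <- bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b)),
                             fixed.inds = 1:30, mobile.inds = 1:30)
    ref <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                a)^2)))
    expect_equal(ours, ref, tolerance = 1e-6)
  }
  # rotation is proper
  b <- rigid_transform(a)
  expect_equal(det(superpose_rmsd(a, b)$rotation), 1, tolerance = 1e-9)
  expect_error(superpose_rmsd(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("rmsd_series is zero for static input and steps at events", {
  base <- matrix(rnorm(60, sd = 5), 20, 3)
  static <- toy_trajectory(list(base, base, base))
  expect_equal(rmsd_series(static)$value, c(0, 0, 0), tolerance = 1e-12)
  # a structural step shows as an RMSD step
  moved <- base
  moved[1:10, ] <- moved[1:10, ] + 3
  traj <- toy_trajectory(list(base, base, moved, moved))
  v <- rmsd_series(traj)$value
  expect_lt(v[2], 1e-9)
  expect_gt(v[3], 1)
  expect_equal(v[3], v[4], tolerance = 1e-9)
})

test_that("noise-driven RMSD matches the Gaussian expectation at large n", {
  set.seed(61)
  n <- 500
  sigma <- 0.1
  base <- matrix(rnorm(3 * n, sd = 10), n, 3)
  frames <- c(list(base), lapply(1:60, function(i) {
    base + matrix(rnorm(3 * n, sd = sigma), n, 3)
  }))
  v <- rmsd_series(toy_trajectory(frames))$value[-1]
  expect_equal(mean(v), sigma * sqrt(3), tolerance = 0.1)
})

test_that("geometric centres and principal axes recover constructions", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  co <- rbind(cube, sweep(cube, 2, c(42.3, 0, 0), "+"))
  expect_equal(geometric_center_distance(co, 1:8, 9:16), 42.3, tolerance = 1e-12)
  expect_equal(geometric_center_distance(co, 1:8, 1:8), 0)
  set.seed(71)
  for (k in 1:20) {
    co <- matrix(rnorm(60, sd = 5), 20, 3)
    d <- sqrt(sum((colMeans(co[1:10, ]) - colMeans(co[11:20, ]))^2))
    expect_equal(geometric_center_distance(co, 1:10, 11:20), d, tolerance = 1e-12)
  }
  # collinear and orthogonal rods
  rodx <- cbind(seq(-5, 5, length.out = 50), rnorm(50, sd = 0.05), rnorm(50, sd = 0.05))
  rody <- cbind(rnorm(50, sd = 0.05), seq(-5, 5, length.out = 50), rnorm(50, sd = 0.05))
  co <- rbind(rodx, sweep(rodx, 2, c(20, 0, 0), "+"))
  expect_lt(principal_axis_angle(co, 1:50, 51:100), 2)
  co <- rbind(rodx, sweep(rody, 2, c(20, 0, 0), "+"))
  expect_gt(principal_axis_angle(co, 1:50, 51:100), 88)
  # exactly degenerate: a square has two equal leading eigenvalues
  square <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 0.1), c(0, 0, -0.1))
  degen <- rbind(square, sweep(rodx, 2, c(30, 0, 0), "+"))
  expect_error(principal_axis_angle(degen, 1:6, 7:56), "ambiguous")
})

test_that("frame descriptors are invariant under rigid motion", {
  set.seed(81)
  for (k in 1:25) {
    co <- matrix(rnorm(30, sd = 4), 10, 3)
    tr <- rigid_transform(co)
    expect_equal(atom_distance(tr, 1, 2), atom_distance(co, 1, 2),
                 tolerance = 1e-9)
    expect_equal(min_group_distance(tr, 1:4, 5:8)$distance,
                 min_group_distance(co, 1:4, 5:8)$distance, tolerance = 1e-9)
    expect_equal(plane_angle(tr, 1:3, 4:6), plane_angle(co, 1:3, 4:6),
                 tolerance = 1e-7)
    expect_equal(dihedral_angle(tr, 1, 2, 3, 4), dihedral_angle(co, 1, 2, 3, 4),
                 tolerance = 1e-7)
    expect_equal(geometric_center_distance(tr, 1:5, 6:10),
                 geometric_center_distance(co, 1:5, 6:10), tolerance = 1e-9)
  }
  # principal-axis angle also survives reflection (axes are unsigned)
  rodx <- cbind(seq(-5, 5, length.out = 50), rnorm(50, sd = 0.1), rnorm(50, sd = 0.1))
  co <- rbind(rodx, sweep(rodx %*% diag(c(1, -1, 1)), 2, c(0, 30, 0), "+"))
  ang <- principal_axis_angle(co, 1:50, 51:100)
  mir <- co %*% diag(c(1, 1, -1))
  expect_equal(principal_axis_angle(mir, 1:50, 51:100), ang, tolerance = 1e-9)
})
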