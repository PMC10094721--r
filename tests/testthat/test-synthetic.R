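test_that("polyene fragment classifies as built", {
  frag <- build_polyene_fragment()
  for (b in c(4, 7, 10, 13, 16, 19)) {
    bc <- bond_config(frag$coords, frag$carbons[paste0("C", c(b, b + 1))],
                      frag$carbons[paste0("C", c(b - 1, b + 2))])
    expect_equal(bc$config, "Z")
  }
  # one bond built E classifies E, the rest stay Z
  cfg <- setNames(rep("Z", 6), c("C4-C5", "C7-C8", "C10-C11", "C13-C14",
                                 "C16-C17", "C19-C20"))
  cfg["C13-C14"] <- "E"
  frag_e <- build_polyene_fragment(cfg)
  for (b in c(4, 7, 10, 13, 16, 19)) {
    bc <- bond_config(frag_e$coords, frag_e$carbons[paste0("C", c(b, b + 1))],
                      frag_e$carbons[paste0("C", c(b - 1, b + 2))])
    expect_equal(bc$config, if (b == 13) "E" else "Z")
  }
  expect_error(build_polyene_fragment(c("C2-C9" = "Z")), "bond key")
  # mirror reflection: identical Z/E labels, flipped pro-R/pro-S labels
  mir <- frag$coords %*% diag(c(-1, 1, 1))
  bc <- bond_config(mir, frag$carbons[c("C10", "C11")],
                    frag$carbons[c("C9", "C12")])
  expect_equal(bc$config, "Z")
  lab <- prochiral_labels(frag$coords, frag$carbons[["C12"]],
                          frag$carbons[c("C11", "C13")], frag$hydrogens[["C12"]])
  lab_m <- prochiral_labels(mir, frag$carbons[["C12"]],
                            frag$carbons[c("C11", "C13")], frag$hydrogens[["C12"]])
  expect_false(lab[[1]] == lab_m[[1]])
  # bond geometry uses the documented ideal constants
  expect_equal(atom_distance(frag$coords, frag$carbons[["C4"]],
                             frag$carbons[["C5"]]), 1.33, tolerance = 1e-9)
  expect_equal(atom_distance(frag$coords, frag$carbons[["C5"]],
                             frag$carbons[["C6"]]), 1.50, tolerance = 1e-9)
  expect_equal(atom_distance(frag$coords, frag$carbons[["C12"]],
                             frag$hydrogens[["C12"]][1]), 1.09, tolerance = 1e-9)
})

test_that("place_cofactor hits feasible targets and reports residuals", {
  frag <- build_polyene_fragment()
  h12 <- frag$hydrogens[["C12"]][1]
  placed <- place_cofactor(frag$coords, frag$topology,
                           setNames(3.0, as.character(h12)))
  expect_equal(unname(placed$achieved), 3.0, tolerance = 1e-6)
  expect_lt(placed$residual, 1e-6)
  expect_equal(unname(atom_distance(placed$coords, placed$cofactor[["O_hydroxide"]],
                                    h12)), 3.0, tolerance = 1e-6)
  # the observed mean distances used as simultaneous targets: least-squares
  # placement stays within 0.2 A of each
  hm <- loxtraj:::hydrogen_label_map(frag)
  targets <- setNames(c(2.99, 3.44, 4.49),
                      as.character(hm[c("H12proS", "H9proR", "H15proS")]))
  placed3 <- place_cofactor(frag$coords, frag$topology, targets)
  expect_true(all(abs(placed3$achieved - targets) < 0.2))
  expect_error(place_cofactor(frag$coords, frag$topology,
                              setNames(0, as.character(h12))), "positive")
})

test_that("o2 candidate positions sit exactly on the sphere", {
  frag <- build_polyene_fragment()
  c14 <- frag$carbons[["C14"]]
  pos <- o2_candidate_positions(frag$coords, c14, 3.0)
  expect_equal(nrow(pos), 12)
  d <- sqrt(rowSums(sweep(pos, 2, frag$coords[c14, ])^2))
  expect_true(all(abs(d - 3.0) < 1e-9))
  axes_only <- rbind(diag(3), -diag(3))
  pos6 <- o2_candidate_positions(frag$coords, c14, 3.0, directions = axes_only)
  expect_equal(nrow(pos6), 6)
  expect_error(o2_candidate_positions(frag$coords, c14, 3.0,
                                      directions = matrix(0, 0, 3)), "non-empty")
  expect_error(o2_candidate_positions(frag$coords, c14, -1), "positive")
})

test_that("two-domain clouds recover their construction exactly", {
  set.seed(151)
  cl <- build_two_domain_cloud(42.3, 38.2, n_points = 500, aspect = 10)
  expect_equal(geometric_center_distance(cl$coords, cl$set_a, cl$set_b),
               42.3, tolerance = 1e-9)
  expect_equal(principal_axis_angle(cl$coords, cl$set_a, cl$set_b),
               38.2, tolerance = 1e-6)
  # parallel and orthogonal rods
  cl0 <- build_two_domain_cloud(30, 0, n_points = 200, aspect = 10)
  expect_lt(principal_axis_angle(cl0$coords, cl0$set_a, cl0$set_b), 1e-6)
  cl90 <- build_two_domain_cloud(30, 90, n_points = 200, aspect = 10)
  expect_equal(principal_axis_angle(cl90$coords, cl90$set_a, cl90$set_b),
               90, tolerance = 1e-6)
  expect_error(build_two_domain_cloud(30, 45, aspect = 1), "aspect")
  expect_error(build_two_domain_cloud(30, 45, n_points = 3), "4 points")
})

test_that("torsion_for_plane_angle inverts the angle map", {
  for (target in c(65, 80, 95, 110)) {
    tau <- torsion_for_plane_angle(target)
    frag <- build_polyene_fragment(torsions = setNames(tau, "C12-C13"))
    expect_equal(plane_angle(frag$coords, frag$carbons[paste0("C", 10:12)],
                             frag$carbons[paste0("C", 12:14)]),
                 target, tolerance = 1e-4)
  }
  expect_error(torsion_for_plane_angle(30), "reachable")
})

test_that("trajectories are deterministic and exact at zero noise", {
  sp <- synthetic_spec(n_frames = 6, seed = 42, noise_sigma = 0,
                       domains = list(center_distance = 42.3, axis_angle = 38.2,
                                      n_points = 60, aspect = 10, scale = 1.5),
                       events = list())
  s1 <- suppressWarnings(make_trajectory(sp))
  s2 <- suppressWarnings(make_trajectory(sp))
  expect_identical(s1$trajectory$frames, s2$trajectory$frames)
  expect_identical(s1$ground_truth, s2$ground_truth)
  # zero noise: analyses reproduce ground truth exactly
  gt <- s1$ground_truth
  cs <- s1$selection$substrate_carbons
  pa <- plane_angle_series(s1$trajectory, unname(cs[c("C10", "C11", "C12")]),
                           unname(cs[c("C12", "C13", "C14")]))
  expect_equal(pa$value, gt$plane_angle_C12, tolerance = 1e-9)
  dm <- domain_motion_series(
    s1$trajectory,
    domain_atoms(s1$selection, s1$trajectory$topology, "PLAT"),
    domain_atoms(s1$selection, s1$trajectory$topology, "CAT"))
  expect_equal(dm$value[dm$name == "domain_center_distance"],
               gt$center_distance, tolerance = 1e-9)
  expect_equal(dm$value[dm$name == "domain_axis_angle"],
               gt$axis_angle, tolerance = 1e-6)
})

test_that("scheduled events step the domain parameters", {
  sp <- synthetic_spec(n_frames = 10, seed = 8, noise_sigma = 0,
                       cofactor = NULL,
                       domains = list(center_distance = 42.3, axis_angle = 38.2,
                                      n_points = 60, aspect = 10, scale = 1.5),
                       events = list(
                         list(frame = 7, parameter = "center_distance", value = 47.2),
                         list(frame = 7, parameter = "axis_angle", value = 58.8)
                       ))
  s <- make_trajectory(sp)
  gt <- s$ground_truth
  expect_equal(gt$center_distance, c(rep(42.3, 6), rep(47.2, 4)))
  expect_equal(gt$axis_angle, c(rep(38.2, 6), rep(58.8, 4)))
  dm <- domain_motion_series(
    s$trajectory, domain_atoms(s$selection, s$trajectory$topology, "PLAT"),
    domain_atoms(s$selection, s$trajectory$topology, "CAT"))
  expect_equal(dm$value[dm$name == "domain_center_distance"], gt$center_distance,
               tolerance = 1e-9)
  expect_error(synthetic_spec(n_frames = 5, events = list(
    list(frame = 9, parameter = "center_distance", value = 1))), "outside")
  expect_error(synthetic_spec(n_frames = 5, events = list(
    list(frame = 2, parameter = "wobble", value = 1))), "unknown event")
})

test_that("recovery error scales with the noise level", {
  errs <- vapply(c(0.05, 0.1, 0.2), function(sg) {
    s <- suppressWarnings(make_trajectory(synthetic_spec(
      n_frames = 30, seed = 17, noise_sigma = sg, domains = NULL,
      cofactor = NULL, events = list()
    )))
    cs <- s$selection$substrate_carbons
    pa <- plane_angle_series(s$trajectory, unname(cs[c("C10", "C11", "C12")]),
                             unname(cs[c("C12", "C13", "C14")]))
    sqrt(mean((pa$value - s$ground_truth$plane_angle_C12)^2))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[3] / errs[1], 8)  # roughly proportional to sigma
  expect_gt(errs[3] / errs[1], 2)
})

test_that("radical-stage trajectories carry their label ground truth", {
  s <- make_trajectory(synthetic_spec(
    n_frames = 10, seed = 23, noise_sigma = 0, stage = "radical",
    plane_angle_targets = list(C12 = c(62, 85)), cofactor = NULL,
    domains = NULL, events = list()
  ))
  expect_true(all(s$ground_truth$pentadienyl_label == "ZE"))
  rep <- stereo_report(s$trajectory, s$selection)
  lab <- rep$label[rep$feature == "C10_C14"]
  expect_equal(lab, s$ground_truth$pentadienyl_label)
  # planar span at zero noise
  expect_true(all(rep$planarity[rep$feature == "C10_C14"] < 1e-9))
})
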