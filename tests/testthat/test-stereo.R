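# Stereochemistry from coordinates.  The chirality convention is anchored
# by a hand-assigned worked example: a bromochlorofluoromethane-like
# centre built so that, viewed from the side opposite the lowest-priority
# substituent, the s1 -> s2 -> s3 sweep is clockwise, i.e. R.

chfclbr_R <- function() {
  h <- 0.5
  rbind(c(0, 0, 0),                 # centre
        c(0, 1, h),                 # s1 (Br): top of the view from +z
        c(cos(-pi / 6), sin(-pi / 6), h),   # s2 (Cl): lower right
        c(cos(-5 * pi / 6), sin(-5 * pi / 6), h),  # s3 (F): lower left
        c(0, 0, -1))                # s4 (H), opposite the other three
}

test_that("center_chirality reproduces the hand-assigned worked example", {
  co <- chfclbr_R()
  r <- center_chirality(co, 1, c(2, 3, 4, 5))
  expect_equal(r$config, "R")
  expect_lt(r$signed_volume, 0)
  # mirroring flips the assignment
  mir <- co %*% diag(c(1, 1, -1))
  expect_equal(center_chirality(mir, 1, c(2, 3, 4, 5))$config, "S")
  # rigid motion preserves it
  set.seed(91)
  for (k in 1:20) {
    expect_equal(center_chirality(rigid_transform(co), 1, c(2, 3, 4, 5))$config, "R")
  }
  # planar centre is degenerate
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, -1, 0), c(1, 1, 0))
  expect_error(center_chirality(flat, 1, c(2, 3, 4, 5)), "degenerate")
})

test_that("bond_config classifies Z/E with the 90-degree threshold", {
  make_torsion <- function(phi) {
    rbind(c(1, 0, -0.5), c(0, 0, 0), c(0, 0, 1),
          c(cos(phi * pi / 180), sin(phi * pi / 180), 1.5))
  }
  expect_equal(bond_config(make_torsion(0), c(2, 3), c(1, 4))$config, "Z")
  expect_equal(bond_config(make_torsion(180), c(2, 3), c(1, 4))$config, "E")
  expect_equal(bond_config(make_torsion(89.9), c(2, 3), c(1, 4))$config, "Z")
  expect_equal(bond_config(make_torsion(90.1), c(2, 3), c(1, 4))$config, "E")
})

test_that("pentadienyl_label reads the two letters and scores planarity", {
  # planar span built Z about the first formal bond, E about the second
  frag <- build_polyene_fragment(torsions = c("C11-C12" = 180, "C12-C13" = 180))
  span <- frag$carbons[paste0("C", 10:14)]
  flanks <- frag$carbons[c("C9", "C15")]
  lab <- pentadienyl_label(frag$coords, span, flanks)
  expect_equal(lab$label, "ZE")
  expect_equal(lab$planarity, 0, tolerance = 1e-9)
  # ZZ construction
  frag2 <- build_polyene_fragment(torsions = c("C11-C12" = 180, "C12-C13" = 0))
  lab2 <- pentadienyl_label(frag2$coords, frag2$carbons[paste0("C", 10:14)],
                            frag2$carbons[c("C9", "C15")])
  expect_equal(lab2$label, "ZZ")
  expect_equal(lab2$planarity, 0, tolerance = 1e-9)
  expect_error(pentadienyl_label(frag$coords, span[1:4], flanks), "five")
})

test_that("prochiral labels are opposite, swap with the hydrogens, flip on mirror", {
  # worked methylene example on tetrahedral vertices: with priorities
  # Chigh(1,1,1) > Clow(1,-1,-1), the hydrogen at (-1,1,-1) was assigned
  # pro-S by hand via the signed-volume rule
  co <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  lab <- prochiral_labels(co, 1, c(2, 3), c(4, 5))
  expect_equal(unname(lab), c("pro-S", "pro-R"))
  # swapping the two hydrogens' coordinates swaps the labels
  co_swap <- co[c(1, 2, 3, 5, 4), ]
  expect_equal(unname(prochiral_labels(co_swap, 1, c(2, 3), c(4, 5))),
               c("pro-R", "pro-S"))
  # mirroring flips every label
  mir <- co %*% diag(c(-1, 1, 1))
  expect_equal(unname(prochiral_labels(mir, 1, c(2, 3), c(4, 5))),
               c("pro-R", "pro-S"))
  # the two hydrogens always receive opposite labels on methylene-like
  # centres (jittered tetrahedra under random rigid motion)
  set.seed(101)
  template <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1),
                    c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  n_ok <- 0
  for (k in 1:1000) {
    co <- rigid_transform(template + matrix(rnorm(15, sd = 0.04), 5, 3))
    lab <- tryCatch(suppressWarnings(prochiral_labels(co, 1, c(2, 3), c(4, 5))),
                    error = function(e) NULL)
    if (is.null(lab)) next
    expect_false(lab[[1]] == lab[[2]])
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 900)
})

test_that("prochiral assignment on the generator's DHA fragment matches CIP", {
  # frozen from an independent CIP engine run on these exact coordinates
  # (deuterium-substitution check): first placed H is pro-S at C12 and
  # C15, pro-R at C9, under the verified neighbour priorities
  frag <- build_polyene_fragment()
  lab12 <- prochiral_labels(frag$coords, frag$carbons[["C12"]],
                            frag$carbons[c("C11", "C13")],
                            frag$hydrogens[["C12"]])
  expect_equal(unname(lab12), c("pro-S", "pro-R"))
  lab9 <- prochiral_labels(frag$coords, frag$carbons[["C9"]],
                           frag$carbons[c("C10", "C8")],
                           frag$hydrogens[["C9"]])
  expect_equal(unname(lab9), c("pro-R", "pro-S"))
  lab15 <- prochiral_labels(frag$coords, frag$carbons[["C15"]],
                            frag$carbons[c("C14", "C16")],
                            frag$hydrogens[["C15"]])
  expect_equal(unname(lab15), c("pro-S", "pro-R"))
})

test_that("face_classification separates the two plane sides", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  co <- rbind(sq, c(0.5, 0.5, 2), c(0.5, 0.5, -1.5))
  r <- face_classification(co, 1:4, 5, 6)
  expect_equal(r$face, "antarafacial")
  co_same <- rbind(sq, c(0.5, 0.5, 2), c(0.2, 0.8, 1))
  expect_equal(face_classification(co_same, 1:4, 5, 6)$face, "suprafacial")
  # reflecting the probe through the plane swaps the classification
  co_ref <- co
  co_ref[5, 3] <- -co_ref[5, 3]
  expect_equal(face_classification(co_ref, 1:4, 5, 6)$face, "suprafacial")
  # in-plane probe is rejected
  co_in <- rbind(sq, c(0.5, 0.5, 0), c(0.5, 0.5, 1))
  expect_error(face_classification(co_in, 1:4, 5, 6), "face undefined")
})

test_that("Z/E labels survive reflection while chirality flips", {
  frag <- build_polyene_fragment()
  mir <- frag$coords %*% diag(c(1, -1, 1))
  for (b in c(4, 7, 10, 13, 16, 19)) {
    bond <- frag$carbons[paste0("C", c(b, b + 1))]
    subs <- frag$carbons[paste0("C", c(b - 1, b + 2))]
    expect_equal(bond_config(mir, bond, subs)$config,
                 bond_config(frag$coords, bond, subs)$config)
  }
  lab <- prochiral_labels(frag$coords, frag$carbons[["C12"]],
                          frag$carbons[c("C11", "C13")], frag$hydrogens[["C12"]])
  lab_m <- prochiral_labels(mir, frag$carbons[["C12"]],
                            frag$carbons[c("C11", "C13")], frag$hydrogens[["C12"]])
  expect_false(lab_m[[1]] == lab[[1]])
  expect_false(lab_m[[2]] == lab[[2]])
})

test_that("antarafacial peroxyl construction classifies S; its reflection R", {
  ad <- build_peroxyl_adduct("antarafacial")
  fc <- face_classification(ad$coords, ad$span, ad$o_attacking, ad$o_reference)
  expect_equal(fc$face, "antarafacial")
  ch <- center_chirality(ad$coords, ad$carbons[["C14"]], ad$priorities)
  expect_equal(ch$config, "S")
  # moving the oxygen to the cofactor side (reflecting its plane side)
  # gives the suprafacial approach and the opposite chirality
  ads <- build_peroxyl_adduct("suprafacial")
  fcs <- face_classification(ads$coords, ads$span, ads$o_attacking, ads$o_reference)
  expect_equal(fcs$face, "suprafacial")
  expect_equal(center_chirality(ads$coords, ads$carbons[["C14"]],
                                ads$priorities)$config, "R")
  # a whole-frame mirror flips chirality but not the relative face
  mir <- ad$coords %*% diag(c(1, 1, -1))
  expect_equal(center_chirality(mir, ad$carbons[["C14"]], ad$priorities)$config, "R")
  expect_equal(face_classification(mir, ad$span, ad$o_attacking,
                                   ad$o_reference)$face, "antarafacial")
})
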