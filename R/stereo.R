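# Stereochemical labels from 3-D coordinates.  No general CIP engine is
# implemented: substituent priorities are declared per centre in the
# selection config, which is all the DHA/lipoxygenase analyses need.

#' Z/E configuration of a double bond
#'
#' The configuration is read from the `Ch-Ci-Cj-Ck` torsion, where `Ch` is
#' the chain substituent on `Ci` and `Ck` the one on `Cj`.  Absolute
#' torsion at or below 90 degrees classifies Z (cis), above 90 E (trans);
#' the tie at exactly 90 is measure-zero and assigned Z.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param bond Length-2 index vector `(Ci, Cj)`.
#' @param substituents Length-2 index vector `(Ch, Ck)`: chain substituent
#'   of `Ci`, then of `Cj`.
#' @return List with `config` (`"Z"` or `"E"`) and `dihedral` (degrees).
#' @export
bond_config <- function(coords, bond, substituents) {
  dih <- dihedral_angle(coords, substituents[1], bond[1], bond[2], substituents[2])
  list(config = if (abs(dih) <= 90) "Z" else "E", dihedral = dih)
}

#' Least-squares plane through a set of atoms
#'
#' @param coords `n x 3` coordinate matrix.
#' @param set Atom indices (>= 3, non-collinear).
#' @return List with `centroid`, unit `normal`, and `max_deviation`
#'   (angstrom): the largest absolute out-of-plane distance among the set.
#' @export
lsq_plane <- function(coords, set) {
  check_indices(coords, set)
  x <- coords[set, , drop = FALSE]
  centroid <- colMeans(x)
  x0 <- sweep(x, 2, centroid)
  e <- eigen(crossprod(x0), symmetric = TRUE)
  if (e$values[2] < 1e-12) abort("collinear atoms: plane undefined")
  normal <- e$vectors[, 3]
  list(centroid = centroid, normal = normal,
       max_deviation = max(abs(x0 %*% normal)))
}

#' Two-letter stereochemistry label of a pentadienyl radical span
#'
#' For a five-carbon span `Ca..Ca+4` the first letter is the Z/E
#' configuration about `(Ca, Ca+1)` with substituents `(Ca-1, Ca+2)`, the
#' second about `(Ca+2, Ca+3)` with substituents `(Ca+1, Ca+4)`.  For the
#' C10-C14 span of DHA this produces the labels that become the 10Z/10E and
#' 12Z/12E assignments of the final hydroperoxide.  A planarity score (the
#' maximum out-of-plane deviation from the least-squares plane through the
#' five span carbons, in angstrom) is reported alongside; a delocalised
#' radical should score near zero.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param span Length-5 index vector `Ca..Ca+4`, consecutive chain carbons.
#' @param flanks Length-2 index vector `(Ca-1, Ca+5)`.
#' @return List with `label` (e.g. `"ZE"`), `first`, `second` (each a
#'   [bond_config()] result) and `planarity` (angstrom).
#' @export
pentadienyl_label <- function(coords, span, flanks) {
  if (length(span) != 5) abort("span must list exactly five carbons")
  first <- bond_config(coords, span[1:2], c(flanks[1], span[3]))
  second <- bond_config(coords, span[3:4], c(span[2], span[5]))
  plane <- lsq_plane(coords, span)
  list(label = paste0(first$config, second$config),
       first = first, second = second, planarity = plane$max_deviation)
}

#' R/S configuration at a tetrahedral centre with declared priorities
#'
#' With unit vectors `u1, u2, u3` from the centre to the three
#' highest-priority substituents (descending priority), the signed volume
#' `t = (u1 x u2) . u3` decides the configuration: `t < 0` is R, `t > 0`
#' is S.  The convention is anchored by a hand-assigned worked example in
#' the test-suite (a bromochlorofluoromethane-like centre).  The lowest
#' priority substituent `s4` is used only to validate that it lies on the
#' opposite side of the `s1 s2 s3` plane from their mean direction.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param center Index of the stereocentre.
#' @param priorities Length-4 index vector, substituents in descending
#'   priority `(s1, s2, s3, s4)`.
#' @return List with `config` (`"R"` or `"S"`) and `signed_volume`.
#' @export
center_chirality <- function(coords, center, priorities) {
  if (length(priorities) != 4) abort("exactly four substituents required")
  check_indices(coords, c(center, priorities))
  u <- lapply(priorities, function(s) {
    v <- coords[s, ] - coords[center, ]
    nv <- vnorm(v)
    if (nv < 1e-9) abort("substituent coincides with the centre")
    v / nv
  })
  t <- sum(cross3(u[[1]], u[[2]]) * u[[3]])
  if (abs(t) < 1e-6) abort("degenerate (near-planar) stereocentre")
  # s4 should point away from the mean of s1..s3
  if (sum(u[[4]] * (u[[1]] + u[[2]] + u[[3]])) > 0) {
    warn("lowest-priority substituent is not opposite the other three")
  }
  list(config = if (t < 0) "R" else "S", signed_volume = t)
}

#' Pro-R/pro-S labels for the two hydrogens of a prochiral methylene
#'
#' Each hydrogen is assessed by promoting it above its geminal partner:
#' priorities are `Chigh > Clow > H_assessed > H_other`, and the
#' [center_chirality()] rule then yields R (label pro-R) or S (pro-S).
#' The two hydrogens always receive opposite labels.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param center Index of the methylene carbon.
#' @param neighbor_priority Length-2 index vector `(Chigh, Clow)`: the two
#'   chain neighbours in descending priority.  For the bis-allylic
#'   methylenes of DHA the verified orders are C11 > C13 (at C12),
#'   C10 > C8 (at C9) and C14 > C16 (at C15); the winner is decided deep
#'   in the CIP digraph and is not simply the carboxyl-side branch.
#' @param hydrogens Length-2 index vector of the two attached hydrogens.
#' @return Named character vector mapping each hydrogen index (as name) to
#'   `"pro-R"` or `"pro-S"`.
#' @export
prochiral_labels <- function(coords, center, neighbor_priority, hydrogens) {
  if (length(hydrogens) != 2) abort("a methylene has exactly two hydrogens")
  lab <- vapply(1:2, function(k) {
    res <- center_chirality(
      coords, center,
      c(neighbor_priority, hydrogens[k], hydrogens[-k])
    )
    if (res$config == "R") "pro-R" else "pro-S"
  }, character(1))
  setNames(lab, as.character(hydrogens))
}

#' Suprafacial/antarafacial classification of an oxygen approach
#'
#' A least-squares plane is fitted through the pentadienyl span carbons;
#' `side(x) = sign((x - centroid) . n)` places the probe (the attacking or
#' peroxyl oxygen) and the reference (the cofactor hydroxide oxygen) on a
#' side each.  Same side is suprafacial, opposite sides antarafacial.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param plane_atoms Indices of the span carbons (>= 3, non-collinear).
#' @param probe Index of the probe atom.
#' @param reference Index of the reference atom.
#' @return List with `face` (`"suprafacial"` or `"antarafacial"`),
#'   `probe_side`, `reference_side` (signed distances, angstrom).
#' @export
face_classification <- function(coords, plane_atoms, probe, reference) {
  check_indices(coords, c(plane_atoms, probe, reference))
  plane <- lsq_plane(coords, plane_atoms)
  side <- function(i) sum((coords[i, ] - plane$centroid) * plane$normal)
  ps <- side(probe); rs <- side(reference)
  if (abs(ps) < 1e-6 || abs(rs) < 1e-6) {
    abort("probe or reference lies in the span plane: face undefined")
  }
  list(face = if (sign(ps) == sign(rs)) "suprafacial" else "antarafacial",
       probe_side = ps, reference_side = rs)
}

#' Full per-frame stereochemistry report for a trajectory
#'
#' Applies [bond_config()] to every declared double bond and
#' [pentadienyl_label()] to every declared span, per frame.
#'
#' @param trajectory A [lox_trajectory()].
#' @param selection A [selection_config()] with `double_bonds` (and
#'   optionally `stereo` spans) declared.
#' @return A tibble with columns `frame_id`, `feature` (bond or span
#'   name), `kind` (`"bond"` or `"pentadienyl"`), `label`, `dihedral`,
#'   `planarity`.
#' @export
stereo_report <- function(trajectory, selection) {
  rows <- purrr::map2_dfr(trajectory$frames, trajectory$frame_ids, function(f, id) {
    bonds <- purrr::map_dfr(selection$double_bonds, function(b) {
      bc <- bond_config(f, b$bond, b$substituents)
      tibble(frame_id = id, feature = b$name, kind = "bond",
             label = bc$config, dihedral = bc$dihedral, planarity = NA_real_)
    })
    spans <- purrr::map_dfr(selection$stereo$spans, function(s) {
      pl <- pentadienyl_label(f, s$span, s$flanks)
      tibble(frame_id = id, feature = s$name, kind = "pentadienyl",
             label = pl$label, dihedral = pl$second$dihedral,
             planarity = pl$planarity)
    })
    dplyr::bind_rows(bonds, spans)
  })
  rows
}
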