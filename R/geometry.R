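# Frame-level descriptors.  All functions take an n x 3 coordinate matrix
# (angstroms) and 1-based atom indices; trajectory-level wrappers return
# lox_series tibbles.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

check_indices <- function(coords, idx) {
  if (any(idx < 1 | idx > nrow(coords))) {
    abort(paste0("atom index out of range 1..", nrow(coords)))
  }
  if (!all(is.finite(coords[idx, , drop = FALSE]))) {
    abort("non-finite coordinates at requested atoms")
  }
}

#' Euclidean distance between two atoms
#'
#' @param coords `n x 3` coordinate matrix (angstrom).
#' @param i,j Atom indices (1-based).
#' @return Distance in angstrom.
#' @export
atom_distance <- function(coords, i, j) {
  check_indices(coords, c(i, j))
  vnorm(coords[i, ] - coords[j, ])
}

#' Minimum pairwise distance between two atom groups
#'
#' Ties are broken towards the lowest `(index_a, index_b)` pair.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param group_a,group_b Non-empty integer index vectors.
#' @return A list with `distance` (angstrom), `index_a`, `index_b`.
#' @export
min_group_distance <- function(coords, group_a, group_b) {
  if (length(group_a) < 1 || length(group_b) < 1) {
    abort("both groups must be non-empty")
  }
  check_indices(coords, c(group_a, group_b))
  # sort first so the tie rule is index-based, not position-based
  group_a <- sort(group_a)
  group_b <- sort(group_b)
  a <- coords[group_a, , drop = FALSE]
  b <- coords[group_b, , drop = FALSE]
  # direct differences (no Gram-matrix cancellation); groups are small
  d2 <- t(vapply(seq_along(group_a), function(i) {
    rowSums(sweep(b, 2, a[i, ])^2)
  }, numeric(length(group_b))))
  d2 <- matrix(d2, nrow = length(group_a))
  flat <- which(d2 == min(d2))
  # ties: lowest index_a, then lowest index_b
  ia <- (flat - 1L) %% nrow(d2) + 1L
  ib <- (flat - 1L) %/% nrow(d2) + 1L
  pick <- order(ia, ib)[1]
  list(distance = sqrt(min(d2)),
       index_a = group_a[ia[pick]],
       index_b = group_b[ib[pick]])
}

plane_normal <- function(coords, triple) {
  a <- coords[triple[1], ]; b <- coords[triple[2], ]; c <- coords[triple[3], ]
  n <- cross3(b - a, c - b)
  nn <- vnorm(n)
  if (nn < 1e-9) abort("collinear atom triple: plane undefined")
  n / nn
}

#' Angle between two oriented planes
#'
#' Each plane is given by an ordered atom triple `(a, b, c)`; its normal is
#' `(b - a) x (c - b)`, so atom order fixes the orientation.  The angle is
#' reported in `[0, 180]` degrees and is deliberately not folded to
#' `[0, 90]`: configurations on either side of 90 degrees are
#' distinguished, which is what the stereochemistry criterion for the
#' pentadienyl planes requires.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param triple_a,triple_b Ordered length-3 index vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
plane_angle <- function(coords, triple_a, triple_b) {
  check_indices(coords, c(triple_a, triple_b))
  n1 <- plane_normal(coords, triple_a)
  n2 <- plane_normal(coords, triple_b)
  acos(max(-1, min(1, sum(n1 * n2)))) * 180 / pi
}

#' Dihedral (torsion) angle
#'
#' IUPAC sign convention: cis = 0, trans = 180; value in `(-180, 180]`.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param i,j,k,l Atom indices along the torsion.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(coords, i, j, k, l) {
  check_indices(coords, c(i, j, k, l))
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  if (vnorm(c12) < 1e-9 || vnorm(c23) < 1e-9) {
    abort("degenerate dihedral: three consecutive atoms are collinear")
  }
  ang <- atan2(sum(b2 * cross3(c12, c23)) / vnorm(b2), sum(c12 * c23)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of `coords_b` onto `coords_a` over a
#' selection, via singular value decomposition of the covariance matrix
#' with the proper-rotation (det = +1) correction.
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices with identical atom
#'   ordering.
#' @param selection Indices used for fitting (>= 3, non-degenerate);
#'   default all atoms.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the fitted coordinates are `coords_b %*% rotation + translation`), and
#'   `rmsd` (angstrom, over the selection after fitting).
#' @export
superpose_rmsd <- function(coords_a, coords_b, selection = NULL) {
  selection <- selection %||% seq_len(nrow(coords_a))
  if (length(selection) < 3) abort("superposition needs at least 3 atoms")
  check_indices(coords_a, selection)
  check_indices(coords_b, selection)
  a <- coords_a[selection, , drop = FALSE]
  b <- coords_b[selection, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(b0, a0))           # maximise tr(R' B' A)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- b0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - a0)^2)))
  list(rotation = rot, translation = as.numeric(ca - cb %*% rot), rmsd = rmsd)
}

#' Per-frame RMSD series relative to a reference frame
#'
#' @param trajectory A [lox_trajectory()].
#' @param selection Atom indices used for both fitting and the RMSD.
#' @param reference Frame position used as reference (default 1).
#' @param name Series label.
#' @return A [lox_series()] in angstrom; the reference frame maps to 0.
#' @export
rmsd_series <- function(trajectory, selection = NULL, reference = 1,
                        name = "rmsd") {
  ref <- frame_coords(trajectory, reference)
  vals <- vapply(seq_len(n_frames(trajectory)), function(k) {
    tryCatch(
      superpose_rmsd(ref, frame_coords(trajectory, k), selection)$rmsd,
      error = function(e) abort(paste0("frame ", trajectory$frame_ids[k],
                                       ": ", conditionMessage(e)))
    )
  }, numeric(1))
  lox_series(name, trajectory$frame_ids, vals, "angstrom")
}

#' Distance between the geometric centres of two atom sets
#'
#' Unweighted centroids (no mass weighting).
#'
#' @param coords `n x 3` coordinate matrix.
#' @param set_a,set_b Non-empty index vectors.
#' @return Distance in angstrom.
#' @export
geometric_center_distance <- function(coords, set_a, set_b) {
  if (length(set_a) < 1 || length(set_b) < 1) abort("atom sets must be non-empty")
  check_indices(coords, c(set_a, set_b))
  vnorm(colMeans(coords[set_a, , drop = FALSE]) -
          colMeans(coords[set_b, , drop = FALSE]))
}

#' Gyration tensor of an atom set
#'
#' Unweighted centred second-moment matrix `t(X0) %*% X0 / n`.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param set Atom indices (>= 4).
#' @return A symmetric 3 x 3 matrix.
#' @export
gyration_tensor <- function(coords, set) {
  if (length(set) < 4) abort("gyration tensor needs >= 4 points")
  check_indices(coords, set)
  x <- coords[set, , drop = FALSE]
  x0 <- sweep(x, 2, colMeans(x))
  crossprod(x0) / nrow(x0)
}

principal_axis <- function(coords, set) {
  e <- eigen(gyration_tensor(coords, set), symmetric = TRUE)
  gap <- (e$values[1] - e$values[2]) / max(e$values[1], 1e-12)
  if (gap < 1e-6) abort("axis ambiguous: degenerate largest gyration eigenvalue")
  e$vectors[, 1]
}

#' Angle between the longest principal axes of two atom sets
#'
#' The axis of each set is the eigenvector of the largest eigenvalue of its
#' gyration tensor.  Axes are unsigned, so the angle is folded to
#' `[0, 90]` degrees.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param set_a,set_b Index vectors (each >= 4 non-coplanar points with a
#'   non-degenerate largest eigenvalue).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
principal_axis_angle <- function(coords, set_a, set_b) {
  u <- principal_axis(coords, set_a)
  v <- principal_axis(coords, set_b)
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}

#' Domain-motion series: centre separation and principal-axis angle
#'
#' @param trajectory A [lox_trajectory()].
#' @param set_a,set_b Atom index vectors for the two domains.
#' @return A [lox_series()] pair bound by row: `domain_center_distance`
#'   (angstrom) and `domain_axis_angle` (degree).
#' @export
domain_motion_series <- function(trajectory, set_a, set_b) {
  dist <- vapply(trajectory$frames, geometric_center_distance,
                 numeric(1), set_a = set_a, set_b = set_b)
  ang <- vapply(trajectory$frames, principal_axis_angle,
                numeric(1), set_a = set_a, set_b = set_b)
  dplyr::bind_rows(
    lox_series("domain_center_distance", trajectory$frame_ids, dist, "angstrom"),
    lox_series("domain_axis_angle", trajectory$frame_ids, ang, "degree")
  )
}

#' Per-frame distance series between two atoms
#'
#' @param trajectory A [lox_trajectory()].
#' @param i,j Atom indices.
#' @param name Series label.
#' @return A [lox_series()] in angstrom.
#' @export
distance_series <- function(trajectory, i, j, name = "distance") {
  vals <- vapply(trajectory$frames, atom_distance, numeric(1), i = i, j = j)
  lox_series(name, trajectory$frame_ids, vals, "angstrom")
}

#' Per-frame plane-angle series
#'
#' @param trajectory A [lox_trajectory()].
#' @param triple_a,triple_b Ordered atom triples (see [plane_angle()]).
#' @param name Series label.
#' @return A [lox_series()] in degrees.
#' @export
plane_angle_series <- function(trajectory, triple_a, triple_b,
                               name = "plane_angle") {
  vals <- vapply(trajectory$frames, plane_angle, numeric(1),
                 triple_a = triple_a, triple_b = triple_b)
  lox_series(name, trajectory$frame_ids, vals, "degree")
}
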