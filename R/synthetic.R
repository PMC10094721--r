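# Synthetic-structure generator: topology-correct geometry with recorded
# ground truth, so every analysis stage is testable without simulation
# software.  Idealised internal coordinates (documented constants, not
# force-field derived): C=C 1.33 A, C-C 1.50 A, C-H 1.09 A, C-O 1.25 A,
# sp2 angles 120 deg, sp3 angles 109.47 deg.

BOND_CC_DOUBLE <- 1.33
BOND_CC_SINGLE <- 1.50
BOND_CH <- 1.09
BOND_CO <- 1.25
ANGLE_SP2 <- 120
ANGLE_SP3 <- 109.47

# DHA double bonds, fatty-acid numbering from the carboxyl carbon
DHA_BONDS <- c("C4-C5", "C7-C8", "C10-C11", "C13-C14", "C16-C17", "C19-C20")

#' Place an atom from internal coordinates (NeRF)
#'
#' @param a,b,c Positions of the three preceding atoms.
#' @param r Bond length `c`-new (angstrom).
#' @param theta Bond angle `b`-`c`-new (degrees).
#' @param phi Torsion `a`-`b`-`c`-new (degrees).
#' @return Position of the new atom.
#' @keywords internal
place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- cross3(b - a, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

parse_bond_key <- function(key) {
  parts <- carbon_number(strsplit(key, "-", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts)) {
    abort(paste0("malformed bond key '", key, "' (expected e.g. 'C10-C11')"))
  }
  sort(parts)
}

#' Build an idealised polyene (DHA-like) fragment
#'
#' Constructs a 22-carbon fatty-acid chain with carboxylate oxygens,
#' prescribed Z/E configurations at each double bond, both methylene
#' hydrogens placed tetrahedrally, and single in-plane hydrogens at sp2
#' carbons.  The chain is generated from internal coordinates; torsions
#' about double bonds are 0 (Z) or 180 (E) degrees, single-bond torsions
#' default to an alternating +-120 degree skew and can be overridden per
#' bond (this is how the inter-plane-angle regimes of a trajectory are
#' steered).
#'
#' @param bond_configs Named character vector mapping bond keys
#'   (`"C4-C5"`, ...) to `"Z"` or `"E"`.  Default: the six cis bonds of
#'   DHA, all `"Z"`.
#' @param torsions Optional named numeric vector of single-bond torsion
#'   overrides, keyed by bond (e.g. `c("C12-C13" = 150)` sets the
#'   C11-C12-C13-C14 dihedral).
#' @param n_carbons Chain length (default 22).
#' @return List with `coords` (matrix), `topology` (tibble), `carbons`
#'   (named index vector `C1`..), `hydrogens` (named list per carbon),
#'   `oxygens` (carboxylate indices), `ground_truth` (tibble of bond
#'   configurations).
#' @export
build_polyene_fragment <- function(bond_configs = setNames(rep("Z", 6), DHA_BONDS),
                                   torsions = NULL, n_carbons = 22) {
  bond_pairs <- lapply(names(bond_configs), parse_bond_key)
  if (any(vapply(bond_pairs, diff, numeric(1)) != 1)) {
    abort("unknown bond key: double bonds must join adjacent carbons")
  }
  bond_lo <- vapply(bond_pairs, `[`, numeric(1), 1)
  if (any(bond_lo < 2 | bond_lo + 1 > n_carbons)) {
    abort("unknown bond key: double bonds must lie within C2..Cn")
  }
  if (!all(bond_configs %in% c("Z", "E"))) abort("bond configs must be 'Z' or 'E'")
  sp2 <- sort(unique(c(bond_lo, bond_lo + 1)))

  is_double <- function(i) i %in% bond_lo          # bond (Ci, Ci+1)
  bond_len <- function(i) if (is_double(i)) BOND_CC_DOUBLE else BOND_CC_SINGLE
  angle_at <- function(i) if (i %in% sp2) ANGLE_SP2 else ANGLE_SP3

  torsion_about <- function(i) {                    # bond (Ci, Ci+1)
    key <- paste0("C", i, "-C", i + 1)
    if (is_double(i)) {
      if (bond_configs[[key]] == "Z") 0 else 180
    } else if (!is.null(torsions) && key %in% names(torsions)) {
      torsions[[key]]
    } else {
      if (i %% 2 == 0) 120 else -120               # default skew
    }
  }

  cpos <- matrix(NA_real_, n_carbons, 3)
  cpos[1, ] <- c(0, 0, 0)
  cpos[2, ] <- c(bond_len(1), 0, 0)
  cpos[3, ] <- place_atom(cpos[1, ] + c(0, 1, 0), cpos[1, ], cpos[2, ],
                          bond_len(2), angle_at(2), 90)
  for (i in 4:n_carbons) {
    cpos[i, ] <- place_atom(cpos[i - 3, ], cpos[i - 2, ], cpos[i - 1, ],
                            bond_len(i - 1), angle_at(i - 1),
                            torsion_about(i - 2))
  }

  atoms <- list()
  add_atom <- function(name, element, pos) {
    atoms[[length(atoms) + 1]] <<- list(name = name, element = element, pos = pos)
    length(atoms)
  }
  carbons <- vapply(seq_len(n_carbons), function(i) {
    add_atom(paste0("C", i), "C", cpos[i, ])
  }, integer(1))
  names(carbons) <- paste0("C", seq_len(n_carbons))

  # carboxylate oxygens on C1, sp2 in the C1-C2-C3 plane
  u21 <- cpos[1, ] - cpos[2, ]; u21 <- u21 / vnorm(u21)
  n_c1 <- cross3(cpos[2, ] - cpos[1, ], cpos[3, ] - cpos[2, ])
  n_c1 <- n_c1 / vnorm(n_c1)
  m_c1 <- cross3(n_c1, u21)
  o_dir1 <- cos(pi / 6) * u21 + sin(pi / 6) * m_c1
  o_dir2 <- cos(pi / 6) * u21 - sin(pi / 6) * m_c1
  oxygens <- c(add_atom("O1", "O", cpos[1, ] + BOND_CO * o_dir1),
               add_atom("O2", "O", cpos[1, ] + BOND_CO * o_dir2))

  hydrogens <- vector("list", n_carbons)
  names(hydrogens) <- names(carbons)
  for (i in 2:(n_carbons - 1)) {
    prev <- cpos[i - 1, ]; this <- cpos[i, ]; nxt <- cpos[i + 1, ]
    u_prev <- (prev - this) / vnorm(prev - this)
    u_next <- (nxt - this) / vnorm(nxt - this)
    bis <- -(u_prev + u_next)
    bis <- bis / vnorm(bis)
    if (i %in% sp2) {
      hydrogens[[i]] <- add_atom(paste0("H", i), "H", this + BOND_CH * bis)
    } else {
      perp <- cross3(u_prev, u_next)
      perp <- perp / vnorm(perp)
      half <- ANGLE_SP3 / 2 * pi / 180
      h1 <- this + BOND_CH * (cos(half) * bis + sin(half) * perp)
      h2 <- this + BOND_CH * (cos(half) * bis - sin(half) * perp)
      hydrogens[[i]] <- c(add_atom(paste0("H", i, "A"), "H", h1),
                          add_atom(paste0("H", i, "B"), "H", h2))
    }
  }
  # terminal methyl on Cn
  last <- n_carbons
  for (k in 1:3) {
    hpos <- place_atom(cpos[last - 2, ], cpos[last - 1, ], cpos[last, ],
                       BOND_CH, ANGLE_SP3, c(180, 60, -60)[k])
    hydrogens[[last]] <- c(hydrogens[[last]],
                           add_atom(paste0("H", last, LETTERS[k]), "H", hpos))
  }

  coords <- do.call(rbind, lapply(atoms, `[[`, "pos"))
  colnames(coords) <- c("x", "y", "z")
  topology <- tibble(
    serial = seq_along(atoms),
    name = vapply(atoms, `[[`, character(1), "name"),
    resid = "DHA", resno = 1L,
    element = vapply(atoms, `[[`, character(1), "element")
  )
  ground_truth <- tibble(bond = names(bond_configs),
                         config = unname(unlist(bond_configs)))
  list(coords = coords, topology = topology, carbons = carbons,
       hydrogens = hydrogens, oxygens = oxygens, ground_truth = ground_truth)
}

#' Solve a single-bond torsion for a target inter-plane angle
#'
#' Finds the torsion about the bond `(C_mid, C_mid+1)` (the second single
#' bond of a bis-allylic motif, e.g. C12-C13) that makes the angle between
#' the oriented planes `(C_mid-2, C_mid-1, C_mid)` and
#' `(C_mid, C_mid+1, C_mid+2)` equal to `target` degrees.  The angle is a
#' monotone function of the torsion on `[-180, -60]`, covering roughly
#' (60, 120) degrees of plane angle for the idealised geometry.
#'
#' @param target Target plane angle (degrees).
#' @param mid Bis-allylic methylene carbon number (default 12).
#' @param bond_configs As in [build_polyene_fragment()].
#' @return Torsion in degrees.
#' @export
torsion_for_plane_angle <- function(target, mid = 12,
                                    bond_configs = setNames(rep("Z", 6), DHA_BONDS)) {
  key <- paste0("C", mid, "-C", mid + 1)
  angle_of <- function(tau) {
    frag <- build_polyene_fragment(bond_configs, torsions = setNames(tau, key))
    plane_angle(frag$coords,
                frag$carbons[paste0("C", (mid - 2):mid)],
                frag$carbons[paste0("C", mid:(mid + 2))])
  }
  lo <- angle_of(-180); hi <- angle_of(-60)
  if (target <= min(lo, hi) || target >= max(lo, hi)) {
    abort(sprintf("target plane angle %.1f outside the reachable range (%.1f, %.1f)",
                  target, min(lo, hi), max(lo, hi)))
  }
  uniroot(function(tau) angle_of(tau) - target, c(-180, -60), tol = 1e-8)$root
}

#' Place a hydroxide cofactor at target hydrogen distances
#'
#' Places the hydroxide oxygen so the distance to each listed hydrogen
#' matches its target, by least squares when the targets over-determine
#' the position.  An iron atom (1.9 A from O) and the hydroxide hydrogen
#' (0.97 A) are added alongside.
#'
#' @param coords Coordinate matrix of the structure so far.
#' @param topology Matching topology tibble.
#' @param targets Named numeric vector: hydrogen atom index (as name,
#'   coercible to integer) to target distance (angstrom, > 0).
#' @return List with `coords` and `topology` extended by `FE`, `OH`, `HO`
#'   atoms (resid `COF`), `cofactor` (named indices), `residual` (root
#'   mean square distance error, angstrom) and `achieved` (named measured
#'   distances).
#' @export
place_cofactor <- function(coords, topology, targets) {
  if (length(targets) < 1) abort("at least one target distance is required")
  if (any(targets <= 0)) abort("target distance must be positive (coincident atoms)")
  h_idx <- as.integer(names(targets))
  check_indices(coords, h_idx)
  hp <- coords[h_idx, , drop = FALSE]
  centroid_all <- colMeans(coords)
  obj <- function(p) sum((sqrt(rowSums(sweep(hp, 2, p)^2)) - targets)^2)
  # multi-start: outward axis directions from the hydrogens' centroid
  hc <- colMeans(hp)
  away <- hc - centroid_all
  if (vnorm(away) < 1e-6) away <- c(0, 0, 1)
  away <- away / vnorm(away)
  starts <- rbind(hc + mean(targets) * away,
                  sweep(diag(3) * mean(targets), 2, hc, "+"),
                  sweep(-diag(3) * mean(targets), 2, hc, "+"))
  fits <- apply(starts, 1, function(s) {
    optim(s, obj, method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  o_pos <- best$par
  achieved <- sqrt(rowSums(sweep(hp, 2, o_pos)^2))
  residual <- sqrt(best$value / length(targets))
  if (residual > 0.2) {
    warn(sprintf("cofactor targets infeasible: rms placement residual %.3f A",
                 residual))
  }
  fe_dir <- o_pos - centroid_all
  fe_dir <- fe_dir / max(vnorm(fe_dir), 1e-9)
  fe_pos <- o_pos + 1.9 * fe_dir
  ho_perp <- cross3(fe_dir, c(0, 0, 1))
  if (vnorm(ho_perp) < 1e-6) ho_perp <- cross3(fe_dir, c(0, 1, 0))
  ho_pos <- o_pos + 0.97 * ho_perp / vnorm(ho_perp)

  n0 <- nrow(coords)
  coords <- rbind(coords, fe_pos, o_pos, ho_pos)
  rownames(coords) <- NULL
  topology <- dplyr::bind_rows(topology, tibble(
    serial = n0 + 1:3, name = c("FE", "OH", "HO"), resid = "COF",
    resno = max(topology$resno) + 1L, element = c("FE", "O", "H")
  ))
  list(coords = coords, topology = topology,
       cofactor = c(Fe = n0 + 1L, O_hydroxide = n0 + 2L, H_hydroxide = n0 + 3L),
       residual = residual,
       achieved = setNames(achieved, names(targets)))
}

#' Candidate O2 positions on a sphere around a carbon
#'
#' Positions at exactly `radius` from the centre atom along a configured
#' direction set.  The default set holds the six signed Cartesian axes and
#' the six in-plane bisectors of the xy, xz and yz planes (12 directions);
#' the sign convention of the bisectors is configurable because placement
#' protocols differ on whether both signs are explored.
#'
#' @param coords Coordinate matrix.
#' @param center_atom Index of the centre atom (C14 for the main DHA
#'   pathway).
#' @param radius Sphere radius in angstrom (> 0); 3.0 in the reference
#'   placement protocol.
#' @param directions Optional `k x 3` matrix of directions (rows need not
#'   be normalised).
#' @return A `k x 3` matrix of positions.
#' @export
o2_candidate_positions <- function(coords, center_atom, radius = 3.0,
                                   directions = NULL) {
  if (radius <= 0) abort("radius must be positive")
  if (is.null(directions)) {
    ax <- rbind(diag(3), -diag(3))
    bis <- rbind(c(1, 1, 0), c(-1, -1, 0), c(1, 0, 1),
                 c(-1, 0, -1), c(0, 1, 1), c(0, -1, -1))
    directions <- rbind(ax, bis)
  }
  if (!is.matrix(directions) || nrow(directions) == 0 || ncol(directions) != 3) {
    abort("directions must be a non-empty k x 3 matrix")
  }
  check_indices(coords, center_atom)
  unit <- directions / sqrt(rowSums(directions^2))
  sweep(unit * radius, 2, coords[center_atom, ], "+")
}

#' Two anisotropic Gaussian point clouds with exact centre distance and
#' axis angle
#'
#' Emulates a two-domain protein: each domain is a rod-like Gaussian cloud
#' whose longest gyration-tensor principal axis is placed exactly; cloud A
#' sits at the origin with axis x, cloud B at `center_distance` along x
#' with its axis rotated by `axis_angle` about z.  Sampled clouds are
#' re-centred and re-aligned so the constructed values are exact
#' (noiseless) ground truth.
#'
#' @param center_distance Centre-to-centre distance (angstrom).
#' @param axis_angle Angle between the two long axes (degrees, `[0, 180]`;
#'   recovered angles fold to `[0, 90]`).
#' @param n_points Points per domain (>= 4).
#' @param aspect Ratio of the long-axis standard deviation to the
#'   transverse one (> 1; 10 gives clearly rod-like domains).
#' @param scale Transverse standard deviation (angstrom, default 1.5).
#' @return List with `coords` (`2 n_points x 3`), `topology` (pseudo-atom
#'   tibble; domain A residues 1..110 style ranges, see `domain_ranges`),
#'   `set_a`, `set_b` (index vectors), `ground_truth` (tibble with the
#'   exact centre distance and axis angle).
#' @export
build_two_domain_cloud <- function(center_distance, axis_angle,
                                   n_points = 500, aspect = 10, scale = 1.5) {
  if (n_points < 4) abort("at least 4 points per domain are required")
  if (aspect <= 1) abort("aspect ratio must exceed 1 (axis ambiguous)")
  sample_rod <- function() {
    x <- cbind(rnorm(n_points, sd = aspect * scale),
               rnorm(n_points, sd = scale),
               rnorm(n_points, sd = scale))
    x <- sweep(x, 2, colMeans(x))
    e <- eigen(crossprod(x) / n_points, symmetric = TRUE)
    r <- e$vectors
    if (det(r) < 0) r[, 3] <- -r[, 3]
    x %*% r                                   # exact principal axes = e1,e2,e3
  }
  a <- sample_rod()
  b <- sample_rod()
  ang <- axis_angle * pi / 180
  rot_z <- rbind(c(cos(ang), -sin(ang), 0),
                 c(sin(ang), cos(ang), 0),
                 c(0, 0, 1))
  b <- b %*% t(rot_z)
  b <- sweep(b, 2, c(center_distance, 0, 0), "+")
  coords <- rbind(a, b)
  colnames(coords) <- c("x", "y", "z")
  topology <- tibble(
    serial = seq_len(2 * n_points),
    name = "CA", resid = "GLY",
    resno = c(rep_len(1:110, n_points), rep_len(111:600, n_points)),
    element = "C"
  )
  list(coords = coords, topology = topology,
       set_a = seq_len(n_points), set_b = n_points + seq_len(n_points),
       ground_truth = tibble(center_distance = center_distance,
                             axis_angle = min(axis_angle, 180 - axis_angle)))
}

#' Construct a peroxyl adduct with a declared addition face
#'
#' Builds the planar ZE pentadienyl radical (C10..C14 span), keeps the
#' cofactor hydroxide oxygen on the side from which the pro-S hydrogen of
#' C12 was abstracted, and adds the attacking oxygen at C14 on the
#' declared face (antarafacial = opposite the cofactor, the approach
#' observed for the main 14S pathway).  C14 is pyramidalised: its
#' hydrogen moves to the side opposite the added oxygen.
#'
#' @param face `"antarafacial"` or `"suprafacial"`.
#' @param o_distance C14-O distance for the added oxygen (angstrom,
#'   default 1.45, a formed C-O bond; use ~3 for a reactant-like
#'   approach).
#' @return List with `coords`, `topology`, `carbons`, `span` (C10..C14
#'   indices), `o_reference` (cofactor hydroxide O index), `o_attacking`,
#'   `o_outer` (second peroxyl O), `h14` (the C14 hydrogen), and
#'   `priorities`: the C14 substituents in descending priority
#'   (O > C13 > C15 > H).
#' @export
build_peroxyl_adduct <- function(face = c("antarafacial", "suprafacial"),
                                 o_distance = 1.45) {
  face <- match.arg(face)
  frag <- build_polyene_fragment(
    torsions = c("C11-C12" = 180, "C12-C13" = 180)  # planar ZE radical span
  )
  span <- frag$carbons[paste0("C", 10:14)]
  plane <- lsq_plane(frag$coords, span)
  nhat <- plane$normal
  # side of the abstracted pro-S hydrogen at C12 = the cofactor side
  labs <- prochiral_labels(frag$coords, frag$carbons[["C12"]],
                           frag$carbons[c("C11", "C13")],
                           frag$hydrogens[["C12"]])
  h_pros <- as.integer(names(labs)[labs == "pro-S"])
  s_ref <- sign(sum((frag$coords[h_pros, ] - plane$centroid) * nhat))
  s_add <- if (face == "antarafacial") -s_ref else s_ref

  c14 <- frag$coords[frag$carbons[["C14"]], ]
  o_att <- c14 + o_distance * s_add * nhat
  o_out <- o_att + 1.3 * (s_add * nhat + c(0.5, 0, 0)) /
    vnorm(s_add * nhat + c(0.5, 0, 0))
  # pyramidalise C14: its hydrogen moves opposite the added oxygen
  h14 <- frag$hydrogens[["C14"]][1]
  coords <- frag$coords
  coords[h14, ] <- c14 - BOND_CH * s_add * nhat
  o_ref <- frag$coords[frag$carbons[["C12"]], ] + 3.0 * s_ref * nhat

  n0 <- nrow(coords)
  coords <- rbind(coords, o_ref, o_att, o_out)
  rownames(coords) <- NULL
  topology <- dplyr::bind_rows(frag$topology, tibble(
    serial = n0 + 1:3, name = c("OH", "OA", "OB"),
    resid = c("COF", "PER", "PER"), resno = c(2L, 3L, 3L),
    element = "O"
  ))
  list(coords = coords, topology = topology, carbons = frag$carbons,
       span = span, o_reference = n0 + 1L, o_attacking = n0 + 2L,
       o_outer = n0 + 3L, h14 = h14,
       priorities = c(n0 + 2L, frag$carbons[["C13"]],
                      frag$carbons[["C15"]], h14))
}
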