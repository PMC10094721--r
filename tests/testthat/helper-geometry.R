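# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's own primitives: cross products come from pracma, rotations are
# built from quaternions, and minima are found by exhaustive search.

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

rigid_transform <- function(coords) {
  r <- random_rotation()
  t <- rnorm(3, sd = 20)
  sweep(coords %*% t(r), 2, t, "+")
}

# exhaustive pairwise minimum
oracle_min_distance <- function(coords, ga, gb) {
  best <- Inf
  for (i in ga) for (j in gb) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d < best) best <- d
  }
  best
}

oracle_plane_angle <- function(coords, ta, tb) {
  n1 <- pracma::cross(coords[ta[2], ] - coords[ta[1], ],
                      coords[ta[3], ] - coords[ta[2], ])
  n2 <- pracma::cross(coords[tb[2], ] - coords[tb[1], ],
                      coords[tb[3], ] - coords[tb[2], ])
  acos(max(-1, min(1, sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
}

# dihedral via projection of the outer substituent directions onto the
# plane perpendicular to the central bond; signed angle by right-hand rule
# about the bond (hand-checked against the convention: a far substituent
# rotated +90 degrees about the central bond axis gives +90)
oracle_dihedral <- function(coords, i, j, k, l) {
  b2 <- coords[k, ] - coords[j, ]
  b2 <- b2 / sqrt(sum(b2^2))
  v1 <- coords[i, ] - coords[j, ]
  v2 <- coords[l, ] - coords[k, ]
  p1 <- v1 - sum(v1 * b2) * b2
  p2 <- v2 - sum(v2 * b2) * b2
  atan2(sum(pracma::cross(p1, p2) * b2), sum(p1 * p2)) * 180 / pi
}

# brute-force rotation search for the optimal-superposition RMSD: coarse
# Euler grid followed by Nelder-Mead refinement of the best grid point
oracle_superpose_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    rz %*% ry %*% rx
  }
  f <- function(ang) sqrt(mean(rowSums((b0 %*% t(rot_euler(ang)) - a0)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  grid_half <- seq(0, pi, length.out = 7)
  best <- c(0, 0, 0); best_val <- f(best)
  for (az in grid) for (ay in grid_half) for (ax in grid) {
    v <- f(c(az, ay, ax))
    if (v < best_val) { best <- c(az, ay, ax); best_val <- v }
  }
  opt <- optim(best, f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  opt$value
}

# small helper: trajectory from a list of coordinate matrices and a minimal
# topology
toy_trajectory <- function(frames, element = "C") {
  n <- nrow(frames[[1]])
  topo <- tibble::tibble(serial = seq_len(n), name = paste0("X", seq_len(n)),
                         resid = "TOY", resno = 1L, element = element)
  lox_trajectory(topo, frames)
}
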