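# Precatalytic-structure statistics and reaction-coordinate descriptors.
# A frame is precatalytic for a candidate hydrogen when that hydrogen lies
# strictly within the threshold distance (default 4.0 A) of the cofactor
# hydroxide oxygen.

#' Candidate-hydrogen to cofactor-oxygen distance series
#'
#' For each candidate carbon (typically C9, C12, C15 of DHA) the distance
#' from each attached hydrogen to the hydroxide oxygen is reported, with
#' the hydrogen labelled pro-R/pro-S via [prochiral_labels()], plus a
#' per-carbon minimum ("closest H") series.
#'
#' @param trajectory A [lox_trajectory()].
#' @param selection A `lox_selection`; candidate methylenes must be
#'   declared under `stereo$methylenes` (with hydrogens enumerated or
#'   resolvable) and the cofactor `O_hydroxide` must be present.
#' @return A tibble of [lox_series()] rows; series names are e.g.
#'   `"H12proS"`, `"H12proR"`, `"H12_min"`.
#' @export
candidate_h_distances <- function(trajectory, selection) {
  o_idx <- selection$cofactor$O_hydroxide
  if (is.null(o_idx)) abort("cofactor O_hydroxide not declared")
  purrr::map_dfr(selection$stereo$methylenes, function(m) {
    hs <- m$hydrogens
    if (is.null(hs) || length(hs) != 2) {
      abort(paste0("candidate carbon ", m$name,
                   ": two attached hydrogens are required (resolve or declare them)"))
    }
    cnum <- carbon_number(m$name)
    per_frame <- purrr::map2_dfr(
      trajectory$frames, trajectory$frame_ids,
      function(f, id) {
        lab <- prochiral_labels(f, m$center, m$neighbor_priority, hs)
        tibble(
          frame_id = id,
          hydrogen = hs,
          label = sub("pro-", "pro", unname(lab[as.character(hs)])),
          value = vapply(hs, function(h) atom_distance(f, h, o_idx), numeric(1))
        )
      })
    labelled <- per_frame |>
      dplyr::mutate(name = paste0("H", cnum, sub("pro", "pro", .data$label)),
                    unit = "angstrom") |>
      dplyr::select("name", "frame_id", "value", "unit")
    min_series <- per_frame |>
      dplyr::summarise(value = min(.data$value), .by = "frame_id") |>
      dplyr::mutate(name = paste0("H", cnum, "_min"), unit = "angstrom") |>
      dplyr::select("name", "frame_id", "value", "unit")
    out <- dplyr::bind_rows(labelled, min_series)
    class(out) <- c("lox_series", class(out))
    out
  })
}

#' Precatalytic flags and fraction for a distance series
#'
#' Strict inequality: a frame is precatalytic when the distance is smaller
#' than the threshold; a value exactly at the threshold is not.
#'
#' @param series A [lox_series()] of distances (single series).
#' @param threshold Distance threshold in angstrom (default 4.0).
#' @return List with `flags` (tibble `frame_id`, `value`, `precatalytic`)
#'   and `fraction` (mean of the flags).
#' @export
precatalytic_stats <- function(series, threshold = 4.0) {
  if (nrow(series) == 0) abort("empty series")
  flags <- tibble(frame_id = series$frame_id, value = series$value,
                  precatalytic = series$value < threshold)
  list(flags = flags, fraction = mean(flags$precatalytic))
}

#' Precatalytic report over all candidate hydrogens
#'
#' @param trajectory A [lox_trajectory()].
#' @param selection A `lox_selection` (see [candidate_h_distances()]).
#' @param threshold Distance threshold in angstrom (default 4.0).
#' @return List with `series` (the labelled distance series tibble) and
#'   `fractions`: a tibble `name`, `fraction`, `n_frames` for every
#'   labelled and minimum series.
#' @export
precatalytic_report <- function(trajectory, selection, threshold = 4.0) {
  series <- candidate_h_distances(trajectory, selection)
  fractions <- series |>
    dplyr::summarise(fraction = mean(.data$value < threshold),
                     n_frames = dplyr::n(), .by = "name")
  list(series = series, fractions = fractions, threshold = threshold)
}

#' Hydrogen-abstraction reaction coordinate
#'
#' `d(Cx, Hx) - d(Hx, O_cofactor)`: negative in reactant-like geometries
#' (H still bound to carbon), positive in product-like ones.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param cx,hx,o_cofactor Atom indices of the carbon, the shifting
#'   hydrogen and the hydroxide oxygen.
#' @return Coordinate value in angstrom.
#' @export
abstraction_coordinate <- function(coords, cx, hx, o_cofactor) {
  atom_distance(coords, cx, hx) - atom_distance(coords, hx, o_cofactor)
}

#' Oxygen-addition reaction coordinate
#'
#' Distance from the attacking oxygen to the target carbon (C14 for the
#' main DHA pathway).
#'
#' @param coords `n x 3` coordinate matrix.
#' @param o_attacking,c_target Atom indices.
#' @return Distance in angstrom.
#' @export
addition_coordinate <- function(coords, o_attacking, c_target) {
  atom_distance(coords, o_attacking, c_target)
}

#' Carbon-chain rotation coordinate
#'
#' The C13-C14-C15-C16 dihedral used to follow the rotation of the peroxyl
#' radical's carbon chain.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param selection A `lox_selection` (supplies the carbon indices), or
#'   `NULL` if indices are given directly.
#' @param indices Optional length-4 index vector overriding the selection.
#' @return Dihedral in degrees, `(-180, 180]`.
#' @export
rotation_coordinate <- function(coords, selection = NULL, indices = NULL) {
  idx <- indices %||% unname(selection$substrate_carbons[c("C13", "C14", "C15", "C16")])
  dihedral_angle(coords, idx[1], idx[2], idx[3], idx[4])
}

#' Retro-hydrogen-abstraction reaction coordinate
#'
#' `d(H, O_water) - d(H, O_peroxyl_outer)`: the breaking water O-H bond
#' against the forming peroxyl O-H bond.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param h_water,o_water,o_peroxyl_outer Atom indices.
#' @return Coordinate value in angstrom.
#' @export
retro_coordinate <- function(coords, h_water, o_water, o_peroxyl_outer) {
  atom_distance(coords, h_water, o_water) -
    atom_distance(coords, h_water, o_peroxyl_outer)
}

#' Plane-angle regime flags and fraction
#'
#' Applies the stereochemistry criterion for the pentadienyl planes: a
#' frame is in the "E-prompting" regime when the angle between the two
#' oriented planes is strictly smaller than the threshold (default 90
#' degrees).
#'
#' @param trajectory A [lox_trajectory()].
#' @param triple_a,triple_b Ordered atom triples defining the two planes
#'   (for DHA: `(C10, C11, C12)`/`(C12, C13, C14)` and
#'   `(C7, C8, C9)`/`(C9, C10, C11)`).
#' @param threshold Angle threshold in degrees (default 90).
#' @param name Series label.
#' @return List with `series` (the plane-angle [lox_series()]), `flags`
#'   (logical, angle < threshold) and `fraction`.
#' @export
plane_angle_regime <- function(trajectory, triple_a, triple_b,
                               threshold = 90, name = "plane_angle") {
  series <- plane_angle_series(trajectory, triple_a, triple_b, name)
  flags <- series$value < threshold
  list(series = series, flags = flags, fraction = mean(flags))
}
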