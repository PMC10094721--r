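# Hydrogen-bond and pi-stacking contact distance series.  Both are
# minimum-pairwise-distance descriptors: the analyses report "closest atom"
# distances, with no angular criterion, matching how such interactions are
# traced along lipoxygenase-substrate trajectories.

contact_min_series <- function(trajectory, group_a, group_b, name) {
  if (length(group_a) < 1 || length(group_b) < 1) {
    abort(paste0("contact '", name, "': empty atom group"))
  }
  vals <- vapply(trajectory$frames, function(f) {
    min_group_distance(f, group_a, group_b)$distance
  }, numeric(1))
  lox_series(name, trajectory$frame_ids, vals, "angstrom")
}

#' Hydrogen-bond contact distance series
#'
#' Per-frame minimum distance between the substrate oxygens and the donor
#' hydrogens of a residue group (e.g. a carboxylate oxygen pair against the
#' guanidinium hydrogens of an active-site arginine).
#'
#' @param trajectory A [lox_trajectory()].
#' @param contact A resolved contact definition: list with `name`,
#'   `substrate_group`, `residue_group` (integer index vectors), as built
#'   by [selection_config()].
#' @return A [lox_series()] in angstrom.
#' @export
hbond_series <- function(trajectory, contact) {
  contact_min_series(trajectory, contact$substrate_group,
                     contact$residue_group, contact$name)
}

#' Pi-stacking contact distance series
#'
#' Per-frame minimum distance between the heavy atoms of an aromatic side
#' chain and the closer of a double bond's two carbons.
#'
#' @inheritParams hbond_series
#' @param contact List with `name`, `substrate_group` (the double bond's
#'   two carbons) and `residue_group` (ring/side-chain heavy atoms).
#' @return A [lox_series()] in angstrom.
#' @export
stacking_series <- function(trajectory, contact) {
  if (length(contact$substrate_group) != 2) {
    abort(paste0("stacking contact '", contact$name,
                 "': substrate group must be the bond's two carbons"))
  }
  contact_min_series(trajectory, contact$substrate_group,
                     contact$residue_group, contact$name)
}

#' All declared contact series of a selection
#'
#' @param trajectory A [lox_trajectory()].
#' @param selection A `lox_selection` with `contacts` declared.
#' @return Contact series bound by row (one [lox_series()] per contact).
#' @export
contact_series <- function(trajectory, selection) {
  purrr::map_dfr(selection$contacts, function(co) {
    contact_min_series(trajectory, co$substrate_group, co$residue_group, co$name)
  })
}
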