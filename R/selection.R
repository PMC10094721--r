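# Selection config: a semantic-role -> atom-index map.  Config files (YAML
# or JSON) use 1-based PDB serials; atom references inside stereo/contact
# declarations may also name substrate carbons ("C12"), cofactor roles
# ("O_hydroxide") or O2 roles ("O_attacking").

carbon_number <- function(nm) {
  suppressWarnings(as.integer(sub("^C", "", nm)))
}

#' Load and validate a selection config
#'
#' The config maps semantic roles to atom indices: `substrate_carbons`
#' (`C1`..`C22`, fatty-acid numbering from the carboxyl carbon),
#' `substrate_hydrogens` (optional; unlisted carbons are resolved later by
#' connectivity, see [resolve_hydrogens()]), `cofactor`
#' (`Fe`, `O_hydroxide`, `H_hydroxide`), optional `o2` (`O_attacking`,
#' `O_outer`), `contact_groups` (named atom-index sets), `domain_ranges`
#' (named residue ranges), `double_bonds` (each with `name`, `bond` = two
#' adjacent carbons, `substituents` = their chain substituents), optional
#' `stereo` (pentadienyl `spans`, prochiral `methylenes`, chirality
#' `centers` with declared priorities) and optional `contacts`.
#'
#' @param path Path to a YAML or JSON config file.
#' @param topology Topology tibble of the trajectory the config addresses
#'   (from a [lox_trajectory()]).
#' @return A validated `lox_selection` list.
#' @export
load_selection_config <- function(path, topology) {
  if (!file.exists(path)) abort(paste0("cannot read config: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  selection_config(raw, topology)
}

#' Build a selection config from a list
#'
#' Programmatic equivalent of [load_selection_config()]; the synthetic
#' generator uses it to describe its own output.
#'
#' @param raw Nested list with the schema of [load_selection_config()].
#' @param topology Topology tibble.
#' @return A validated `lox_selection` list.
#' @export
selection_config <- function(raw, topology) {
  n <- nrow(topology)
  check_serials <- function(idx, role) {
    idx <- as.integer(unlist(idx))
    bad <- idx[is.na(idx) | idx < 1 | idx > n]
    if (length(bad) > 0) {
      abort(paste0("selection role '", role, "' references atom index ",
                   paste(bad, collapse = ", "), " outside topology (1..", n, ")"))
    }
    idx
  }

  carbons <- vapply(raw$substrate_carbons, function(x) as.integer(x), integer(1))
  carbons <- setNames(check_serials(carbons, "substrate_carbons"),
                      names(raw$substrate_carbons))
  nums <- carbon_number(names(carbons))
  if (anyNA(nums)) abort("substrate carbon names must be C<number>")
  carbons <- carbons[order(nums)]
  if (!all(diff(sort(nums)) == 1)) {
    abort("substrate carbons must be consecutive along the chain (C1..Cn)")
  }

  resolve_atom <- function(ref, role) {
    if (is.numeric(ref)) return(check_serials(ref, role))
    ref <- as.character(ref)
    if (ref %in% names(carbons)) return(unname(carbons[[ref]]))
    if (!is.null(raw$cofactor[[ref]])) return(check_serials(raw$cofactor[[ref]], role))
    if (!is.null(raw$o2[[ref]])) return(check_serials(raw$o2[[ref]], role))
    abort(paste0("selection role '", role, "': unknown atom reference '", ref, "'"))
  }
  resolve_atoms <- function(refs, role) {
    vapply(as.list(refs), resolve_atom, integer(1), role = role)
  }

  hydrogens <- lapply(raw$substrate_hydrogens, check_serials,
                      role = "substrate_hydrogens")

  cofactor <- lapply(raw$cofactor, check_serials, role = "cofactor")
  o2 <- lapply(raw$o2, check_serials, role = "o2")
  contact_groups <- lapply(raw$contact_groups, check_serials,
                           role = "contact_groups")

  domain_ranges <- lapply(raw$domain_ranges, function(rng) {
    rng <- as.integer(unlist(rng))
    if (length(rng) != 2 || rng[1] > rng[2]) {
      abort("domain ranges must be [first_residue, last_residue]")
    }
    rng
  })

  double_bonds <- lapply(seq_along(raw$double_bonds), function(k) {
    b <- raw$double_bonds[[k]]
    bond_names <- as.character(unlist(b$bond))
    num <- carbon_number(bond_names)
    if (length(num) == 2 && !anyNA(num) && abs(num[2] - num[1]) != 1) {
      abort(paste0("double bond (", bond_names[1], ", ", bond_names[2],
                   ") is non-adjacent along the chain"))
    }
    list(name = b$name %||% paste0("delta", min(num)),
         bond = resolve_atoms(b$bond, "double_bonds"),
         substituents = resolve_atoms(b$substituents, "double_bonds"))
  })

  stereo <- list(
    spans = lapply(raw$stereo$spans, function(s) {
      list(name = s$name,
           span = resolve_atoms(s$span, "stereo$spans"),
           flanks = resolve_atoms(s$flanks, "stereo$spans"))
    }),
    methylenes = lapply(raw$stereo$methylenes, function(m) {
      list(name = m$name,
           center = resolve_atom(m$center, "stereo$methylenes"),
           neighbor_priority = resolve_atoms(m$neighbor_priority,
                                             "stereo$methylenes"),
           hydrogens = if (!is.null(m$hydrogens))
             check_serials(m$hydrogens, "stereo$methylenes"))
    }),
    centers = lapply(raw$stereo$centers, function(ct) {
      list(name = ct$name,
           center = resolve_atom(ct$center, "stereo$centers"),
           priorities = resolve_atoms(ct$priorities, "stereo$centers"))
    })
  )

  contacts <- lapply(raw$contacts, function(co) {
    resolve_group <- function(g, role) {
      if (is.character(g) && length(g) == 1 && g %in% names(contact_groups)) {
        return(contact_groups[[g]])
      }
      resolve_atoms(g, role)
    }
    list(name = co$name,
         substrate_group = resolve_group(co$substrate_group, "contacts"),
         residue_group = resolve_group(co$residue_group, "contacts"))
  })

  structure(
    list(substrate_carbons = carbons, substrate_hydrogens = hydrogens,
         cofactor = cofactor, o2 = o2, contact_groups = contact_groups,
         domain_ranges = domain_ranges, double_bonds = double_bonds,
         stereo = stereo, contacts = contacts),
    class = "lox_selection"
  )
}

#' @export
print.lox_selection <- function(x, ...) {
  cat("<lox_selection> ", length(x$substrate_carbons), " substrate carbons, ",
      length(x$double_bonds), " double bonds, ",
      length(x$contacts), " contacts\n", sep = "")
  invisible(x)
}

#' Resolve methylene hydrogens by connectivity
#'
#' Simulation-derived PDBs name hydrogens inconsistently, so hydrogens not
#' enumerated in the config are resolved geometrically: every atom with
#' element `H` within `cutoff` of the parent carbon is attached to it.
#'
#' @param selection A `lox_selection`.
#' @param coords One coordinate frame (`n x 3`).
#' @param topology Topology tibble with an `element` column.
#' @param carbons Character vector of carbon names to resolve; defaults to
#'   every substrate carbon not already listed under `substrate_hydrogens`.
#' @param cutoff Bonding cutoff in angstrom (default 1.2).
#' @return The selection with `substrate_hydrogens` completed.
#' @export
resolve_hydrogens <- function(selection, coords, topology,
                              carbons = NULL, cutoff = 1.2) {
  carbons <- carbons %||% setdiff(names(selection$substrate_carbons),
                                  names(selection$substrate_hydrogens))
  h_idx <- which(topology$element == "H")
  for (cn in carbons) {
    ci <- selection$substrate_carbons[[cn]]
    d <- sqrt(rowSums(sweep(coords[h_idx, , drop = FALSE], 2, coords[ci, ])^2))
    selection$substrate_hydrogens[[cn]] <- h_idx[d < cutoff]
  }
  selection
}

#' Atom indices of a named domain
#'
#' @param selection A `lox_selection`.
#' @param topology Topology tibble.
#' @param domain Name of a declared residue range.
#' @return Integer atom indices whose residue number falls in the range.
#' @export
domain_atoms <- function(selection, topology, domain) {
  rng <- selection$domain_ranges[[domain]]
  if (is.null(rng)) abort(paste0("unknown domain range: ", domain))
  which(topology$resno >= rng[1] & topology$resno <= rng[2])
}
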