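#' Trajectory container
#'
#' A `lox_trajectory` bundles a shared atom topology with an ordered set of
#' coordinate frames.  Coordinates are in angstroms.  All per-frame analyses
#' in the package take either a single coordinate matrix (one frame) or a
#' `lox_trajectory` (returning a per-frame series).
#'
#' @param topology Tibble with one row per atom and columns `serial`
#'   (integer, 1-based), `name` (atom name), `resid` (residue name),
#'   `resno` (residue number) and `element`.
#' @param frames List of numeric `n_atoms x 3` coordinate matrices.
#' @param frame_ids Integer vector of frame identifiers, strictly
#'   increasing; defaults to `seq_along(frames)`.
#' @param time_step Optional time per frame (ns); metadata only.
#'
#' @return A `lox_trajectory` object.
#' @export
lox_trajectory <- function(topology, frames, frame_ids = NULL, time_step = NULL) {
  topology <- as_tibble(topology)
  required <- c("serial", "name", "resid", "resno", "element")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols) > 0) {
    abort(paste0("topology lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!is.list(frames) || length(frames) < 1) {
    abort("a trajectory needs at least one frame")
  }
  n_atoms <- nrow(topology)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || ncol(f) != 3) {
      abort(paste0("frame ", k, " is not an n x 3 coordinate matrix"))
    }
    if (nrow(f) != n_atoms) {
      abort(paste0("frame ", k, " has ", nrow(f), " atoms; topology has ", n_atoms))
    }
    if (!all(is.finite(f))) {
      abort(paste0("frame ", k, " contains non-finite coordinates"))
    }
  }
  frame_ids <- as.integer(frame_ids %||% seq_along(frames))
  if (length(frame_ids) != length(frames) || any(diff(frame_ids) <= 0)) {
    abort("frame_ids must match the number of frames and be strictly increasing")
  }
  structure(
    list(topology = topology, frames = unname(frames),
         frame_ids = frame_ids, time_step = time_step),
    class = "lox_trajectory"
  )
}

#' @export
print.lox_trajectory <- function(x, ...) {
  cat("<lox_trajectory> ", n_frames(x), " frame(s), ", n_atoms(x), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param trajectory A `lox_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' @rdname n_frames
#' @export
n_atoms <- function(trajectory) nrow(trajectory$topology)

#' Extract one coordinate frame
#' @param trajectory A `lox_trajectory`.
#' @param i Frame position (1-based position in the frame list, not frame id).
#' @return An `n_atoms x 3` coordinate matrix.
#' @export
frame_coords <- function(trajectory, i) {
  if (i < 1 || i > n_frames(trajectory)) {
    abort(paste0("frame position ", i, " out of range 1..", n_frames(trajectory)))
  }
  trajectory$frames[[i]]
}

#' Tidy view of a trajectory
#'
#' @param x A `lox_trajectory`.
#' @param ... Ignored.
#' @return A tibble with one row per atom per frame: `frame_id`, `serial`,
#'   `name`, `resid`, `resno`, `element`, `x`, `y`, `z`.
#' @export
as_tibble.lox_trajectory <- function(x, ...) {
  purrr::map2_dfr(x$frames, x$frame_ids, function(f, id) {
    dplyr::mutate(x$topology, frame_id = id,
                  x = f[, 1], y = f[, 2], z = f[, 3], .before = 1)
  }) |>
    dplyr::relocate("frame_id", "serial", "name", "resid", "resno", "element")
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' One frame per `MODEL` record; a single-structure file yields a one-frame
#' trajectory.  Every model must contain the same number of atoms.
#'
#' @param path Path to a PDB file.
#' @return A [lox_trajectory()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read PDB file: ", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    # pre-scan: atom count per MODEL block must be constant
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(k) {
      sum(is_atom[bounds[k]:(bounds[k + 1] - 1L)])
    }, integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      abort(paste0("inconsistent atom count in model ", bad, ": ",
                   counts[bad], " atoms, expected ", counts[1]))
    }
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  topology <- tibble(
    serial  = seq_len(nrow(pdb$atom)),
    name    = trimws(pdb$atom$elety),
    resid   = trimws(pdb$atom$resid),
    resno   = as.integer(pdb$atom$resno),
    element = trimws(ifelse(is.na(pdb$atom$elesy), "", pdb$atom$elesy))
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    matrix(xyz[k, ], ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  })
  lox_trajectory(topology, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Companion writer used by the synthetic-structure generator (fixtures and
#' round-trip tests).  Coordinates are written at the PDB's fixed 1e-3 A
#' precision.
#'
#' @param trajectory A [lox_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(trajectory, path) {
  top <- trajectory$topology
  xyz <- do.call(rbind, lapply(trajectory$frames, function(f) as.vector(t(f))))
  pdb_line <- function(serial, name, resid, resno, x, y, z, element) {
    nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
    sprintf("ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, nm, resid, resno, x, y, z, element)
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  for (k in seq_len(nrow(xyz))) {
    writeLines(sprintf("MODEL     %4d", trajectory$frame_ids[k]), con)
    f <- trajectory$frames[[k]]
    writeLines(pdb_line(top$serial, top$name, top$resid, top$resno,
                        f[, 1], f[, 2], f[, 3], top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
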