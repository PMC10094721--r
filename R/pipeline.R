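# Config-driven end-to-end runs.  The package is the interface: these
# functions orchestrate the per-module analyses over a trajectory and
# write deterministic output sets.

#' Run a set of analyses over a trajectory
#'
#' Orchestrates the per-frame analyses: `rmsd`, `domains`, `contacts`,
#' `candidates` (hydrogen-cofactor distances), `precatalytic`,
#' `plane_regimes`, `stereo`.  Unknown analysis names are rejected before
#' any computation.  With an `out_dir`, every series is written as CSV
#' and every report as JSON, with a checksum manifest; reruns with
#' identical inputs are byte-identical.
#'
#' @param trajectory A [lox_trajectory()].
#' @param selection A `lox_selection`.
#' @param analyses Character subset of the analyses above (default all
#'   that the selection supports).
#' @param precat_threshold Precatalytic distance threshold (angstrom).
#' @param plane_threshold Plane-angle regime threshold (degrees).
#' @param rmsd_selection Atom indices for the RMSD series (default: all
#'   substrate carbons).
#' @param out_dir Optional output directory.
#' @return List with the computed `series` (tibble), `reports` (list) and
#'   `manifest` (tibble or `NULL`).
#' @export
run_analysis <- function(trajectory, selection,
                         analyses = c("rmsd", "domains", "contacts",
                                      "candidates", "precatalytic",
                                      "plane_regimes", "stereo"),
                         precat_threshold = 4.0, plane_threshold = 90,
                         rmsd_selection = NULL, out_dir = NULL) {
  known <- c("rmsd", "domains", "contacts", "candidates", "precatalytic",
             "plane_regimes", "stereo")
  bad <- setdiff(analyses, known)
  if (length(bad) > 0) {
    abort(paste0("unknown analysis: ", paste(bad, collapse = ", ")))
  }
  if (precat_threshold <= 0 || plane_threshold <= 0) {
    abort("thresholds must be positive")
  }
  series <- list()
  reports <- list()
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  if ("rmsd" %in% analyses) {
    sel <- rmsd_selection %||% unname(selection$substrate_carbons)
    series$rmsd <- run_stage("rmsd",
      rmsd_series(trajectory, sel, name = "substrate_rmsd"))
  }
  if ("domains" %in% analyses && length(selection$domain_ranges) >= 2) {
    nms <- names(selection$domain_ranges)[1:2]
    set_a <- domain_atoms(selection, trajectory$topology, nms[1])
    set_b <- domain_atoms(selection, trajectory$topology, nms[2])
    series$domains <- run_stage("domains",
      domain_motion_series(trajectory, set_a, set_b))
  }
  if ("contacts" %in% analyses && length(selection$contacts) > 0) {
    series$contacts <- run_stage("contacts",
      contact_series(trajectory, selection))
  }
  if ("candidates" %in% analyses && length(selection$stereo$methylenes) > 0) {
    series$candidates <- run_stage("candidates",
      candidate_h_distances(trajectory, selection))
  }
  if ("precatalytic" %in% analyses && length(selection$stereo$methylenes) > 0) {
    pre <- run_stage("precatalytic",
      precatalytic_report(trajectory, selection, precat_threshold))
    reports$precatalytic <- list(
      threshold = pre$threshold,
      fractions = pre$fractions
    )
    if (is.null(series$candidates)) series$candidates <- pre$series
  }
  if ("plane_regimes" %in% analyses) {
    regimes <- run_stage("plane_regimes", {
      cs <- selection$substrate_carbons
      lapply(list(C12 = c(10, 11, 12, 12, 13, 14),
                  C9 = c(7, 8, 9, 9, 10, 11)), function(idx) {
        plane_angle_regime(trajectory,
                           unname(cs[paste0("C", idx[1:3])]),
                           unname(cs[paste0("C", idx[4:6])]),
                           threshold = plane_threshold)
      })
    })
    series$plane_regimes <- dplyr::bind_rows(
      dplyr::mutate(regimes$C12$series, name = "plane_angle_C10C11C12_C12C13C14"),
      dplyr::mutate(regimes$C9$series, name = "plane_angle_C7C8C9_C9C10C11")
    )
    reports$plane_regimes <- list(
      threshold = plane_threshold,
      fraction_C12 = regimes$C12$fraction,
      fraction_C9 = regimes$C9$fraction
    )
  }
  if ("stereo" %in% analyses &&
      (length(selection$double_bonds) > 0 || length(selection$stereo$spans) > 0)) {
    reports$stereo <- run_stage("stereo", stereo_report(trajectory, selection))
  }

  all_series <- dplyr::bind_rows(series)
  manifest <- NULL
  if (!is.null(out_dir)) {
    manifest <- write_report(all_series, reports, out_dir)
  }
  list(series = all_series, reports = reports, manifest = manifest)
}

#' Generate a synthetic trajectory and write it with its ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory; receives `trajectory.pdb`
#'   (multi-model) and `ground_truth.json`.
#' @return The [make_trajectory()] result, invisibly.
#' @export
run_synth <- function(spec, out_dir) {
  synth <- make_trajectory(spec)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(paste0("cannot create directory: ", out_dir))
  write_multimodel_pdb(synth$trajectory, file.path(out_dir, "trajectory.pdb"))
  jsonlite::write_json(synth$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(synth)
}

#' Summarise a barrier table and write the summary
#'
#' @param table Path to a barrier CSV, a packaged table name (see
#'   [lox_table()]), or a barrier table tibble.
#' @param temperature Temperature in kelvin.
#' @param out_dir Optional output directory for `summary.json`.
#' @return A [barrier_table_summary()].
#' @export
run_barriers <- function(table, temperature = 300, out_dir = NULL) {
  printed <- NA_real_
  if (is.character(table)) {
    if (file.exists(table)) {
      records <- read_barrier_table(table)
    } else {
      printed <- published_average(table)
      records <- lox_table(table)
    }
  } else {
    records <- table
  }
  summary <- barrier_table_summary(records, temperature,
                                   printed_average = printed)
  if (!is.null(out_dir)) {
    write_report(reports = list(summary = list(
      n = summary$n, min_barrier = summary$min_barrier,
      mean_barrier = summary$mean_barrier,
      exp_avg_barrier = summary$exp_avg_barrier,
      mean_reaction = summary$mean_reaction,
      stereo_tally = as.list(summary$stereo_tally),
      temperature = summary$temperature,
      printed_average = summary$printed_average,
      discrepancy = summary$discrepancy
    )), out_dir = out_dir)
  }
  summary
}

#' Reference-table and construction self-checks
#'
#' Recomputes, from the packaged ensembles and small synthetic
#' constructions, the quantities the package is designed to reproduce:
#' the two abstraction exponential averages and their difference, the
#' stereo tallies of the three abstraction tables, the flagged
#' recomputation gap of the pigALOX15-mini-LOX ensemble, and the
#' plane-angle/pentadienyl-label and antarafacial/S construction
#' properties.
#'
#' @param seed Seed for the synthetic constructions.
#' @return Tibble with `check`, `value`, `expected`, `pass`.
#' @export
run_reference_checks <- function(seed = 1) {
  h12 <- lox_table("halox12_h12pros")
  h9 <- lox_table("halox12_h9pror")
  pig <- lox_table("pigalox15_h12pros")
  ea12 <- exponential_average(h12$dE_barrier)
  ea9 <- exponential_average(h9$dE_barrier)
  pig_sum <- barrier_table_summary(pig, printed_average = published_average("pigalox15_h12pros"))

  synth_ze <- make_trajectory(synthetic_spec(
    n_frames = 20, seed = seed, noise_sigma = 0, stage = "radical",
    plane_angle_targets = list(C12 = c(62, 85)),
    cofactor = NULL, domains = NULL, events = list()
  ))
  synth_zz <- make_trajectory(synthetic_spec(
    n_frames = 20, seed = seed + 1, noise_sigma = 0, stage = "radical",
    plane_angle_targets = list(C12 = c(95, 118)),
    cofactor = NULL, domains = NULL, events = list()
  ))
  label_share <- function(synth, lab) {
    rep <- stereo_report(synth$trajectory, synth$selection)
    rep <- rep[rep$feature == "C10_C14", ]
    mean(rep$label == lab)
  }
  adduct <- build_peroxyl_adduct("antarafacial")
  fc <- face_classification(adduct$coords, adduct$span,
                            adduct$o_attacking, adduct$o_reference)
  ch <- center_chirality(adduct$coords, adduct$carbons[["C14"]],
                         adduct$priorities)

  checks <- tibble(
    check = c("exp_avg_H12proS", "exp_avg_H9proR", "exp_avg_difference",
              "tally_ZE_H12proS", "tally_ZZ_H9proR", "tally_ZZ_pig",
              "pig_recomputation_flagged",
              "label_ZE_share_low_angle", "label_ZZ_share_high_angle",
              "antarafacial_construction", "chirality_S_construction"),
    value = c(ea12, ea9, ea9 - ea12,
              sum(h12$stereo == "ZE"), sum(h9$stereo == "ZZ"),
              sum(pig$stereo == "ZZ"),
              as.numeric(isTRUE(pig_sum$discrepancy)),
              label_share(synth_ze, "ZE"), label_share(synth_zz, "ZZ"),
              as.numeric(fc$face == "antarafacial"),
              as.numeric(ch$config == "S")),
    expected = c(17.1, 23.9, 6.8, 10, 10, 10, 1, 1, 1, 1, 1)
  )
  checks$pass <- abs(checks$value - checks$expected) <=
    c(0.05, 0.05, 0.1, 0, 0, 0, 0, 0, 0, 0, 0)
  checks
}
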