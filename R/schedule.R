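#' Constrained reaction-coordinate interpolation schedule
#'
#' The reaction coordinate is the distance between the nucleophilic serine
#' O-gamma and the substrate carbonyl carbon. A barrier profile is mapped by
#' optimizing the structure at a series of frames in which that distance is
#' held fixed at d_i = d_ini - i * (d_ini - d_fin) / n, for frame index
#' i = 0..n: frame 0 is the enzyme-substrate (ES) complex and frame n the
#' tetrahedral intermediate (TI).
#'
#' @param d_ini Coordinate distance in the ES complex, in Angstrom.
#' @param d_fin Coordinate distance in the TI, in Angstrom.
#' @param n_segments Number of equal interpolation steps (default 10,
#'   giving 11 frames).
#' @return An object of class `interpolation_schedule`.
#' @examples
#' sched <- interpolation_schedule(d_ini = 3.0, d_fin = 1.5)
#' frame_distance(sched, 4)
#' @export
interpolation_schedule <- function(d_ini, d_fin, n_segments = 10L) {
  stopifnot(is.numeric(d_ini), is.numeric(d_fin), length(d_ini) == 1, length(d_fin) == 1)
  n_segments <- as.integer(n_segments)
  if (!is.finite(d_ini) || d_ini <= 0 || !is.finite(d_fin) || d_fin <= 0) {
    abort("Distances must be positive and finite (Angstrom).")
  }
  if (is.na(n_segments) || n_segments < 1) {
    abort("`n_segments` must be an integer >= 1.")
  }
  structure(
    list(d_ini = as.numeric(d_ini), d_fin = as.numeric(d_fin), n_segments = n_segments),
    class = "interpolation_schedule"
  )
}

#' @export
print.interpolation_schedule <- function(x, ...) {
  cat(sprintf(
    "Interpolation schedule: %.3f -> %.3f Angstrom over %d segments (%d frames)\n",
    x$d_ini, x$d_fin, x$n_segments, x$n_segments + 1L
  ))
  invisible(x)
}

#' Fixed coordinate distance at one interpolation frame
#'
#' @param schedule An [interpolation_schedule()].
#' @param i Frame index (vector allowed), each in `0:n_segments`.
#' @return Distance(s) in Angstrom: `d_ini - i * (d_ini - d_fin) / n_segments`.
#' @export
frame_distance <- function(schedule, i) {
  stopifnot(inherits(schedule, "interpolation_schedule"))
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 0) || any(i > schedule$n_segments)) {
    abort(sprintf("Frame index must lie in 0..%d.", schedule$n_segments))
  }
  schedule$d_ini - i * (schedule$d_ini - schedule$d_fin) / schedule$n_segments
}

#' Full frame-by-frame distance table
#'
#' @param schedule An [interpolation_schedule()].
#' @return A tibble with columns `frame` (0..n_segments) and `distance`
#'   (Angstrom); monotone from `d_ini` to `d_fin`.
#' @export
schedule_distances <- function(schedule) {
  stopifnot(inherits(schedule, "interpolation_schedule"))
  frames <- 0:schedule$n_segments
  tibble::tibble(frame = frames, distance = frame_distance(schedule, frames))
}

#' Optimization constraints carried to the energy backend
#'
#' Alongside the fixed coordinate distance, each frame optimization keeps a
#' set of surface residues frozen (they otherwise rearrange their hydrogen
#' bonding during optimization and corrupt the barrier shape), applies a
#' gradient convergence criterion and a locality cutoff for the
#' linear-scaling wavefunction.
#'
#' @param fixed_residues Residue identifiers kept frozen; default
#'   `c("S50", "P133", "Q156", "L277", "P280")`.
#' @param coordinate_atoms Length-2 character vector naming the two atoms
#'   whose distance is constrained; default serine O-gamma and substrate
#'   carbonyl carbon.
#' @param gradient_criterion Convergence criterion in kcal/(mol*Angstrom);
#'   default 0.5.
#' @param locality_cutoff NDDO interaction cutoff in Angstrom; default 15.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(fixed_residues = c("S50", "P133", "Q156", "L277", "P280"),
                           coordinate_atoms = c("OG:S105", "C20:substrate"),
                           gradient_criterion = 0.5,
                           locality_cutoff = 15) {
  stopifnot(length(coordinate_atoms) == 2)
  if (coordinate_atoms[[1]] == coordinate_atoms[[2]]) {
    abort("The two coordinate atoms must be distinct.")
  }
  if (!is.numeric(gradient_criterion) || gradient_criterion <= 0) {
    abort("`gradient_criterion` must be positive.")
  }
  structure(
    list(
      fixed_residues = as.character(fixed_residues),
      coordinate_atoms = as.character(coordinate_atoms),
      gradient_criterion = as.numeric(gradient_criterion),
      locality_cutoff = as.numeric(locality_cutoff)
    ),
    class = "constraint_set"
  )
}

#' Render a backend job description for one frame
#'
#' Produces a backend-agnostic, deterministic job record for the external
#' energy program: the mutant identity, the frame's fixed coordinate
#' distance, the frozen residues, gradient criterion and locality cutoff.
#' Serialize with [write_jobs_json()].
#'
#' @param schedule An [interpolation_schedule()].
#' @param constraints A [constraint_set()].
#' @param i Frame index in `0:n_segments`.
#' @param mutant Mutant identifier string (canonicalized).
#' @return A named list (class `backend_job`).
#' @export
render_job <- function(schedule, constraints, i, mutant) {
  stopifnot(inherits(schedule, "interpolation_schedule"), inherits(constraints, "constraint_set"))
  i <- as.integer(i)
  structure(
    list(
      mutant = canonical_mutant(mutant),
      frame = i,
      distance_angstrom = frame_distance(schedule, i),
      coordinate_atoms = constraints$coordinate_atoms,
      fixed_residues = constraints$fixed_residues,
      gradient_criterion_kcal_mol_angstrom = constraints$gradient_criterion,
      locality_cutoff_angstrom = constraints$locality_cutoff
    ),
    class = "backend_job"
  )
}

#' Serialize backend jobs to JSON
#'
#' @param jobs A single `backend_job` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly. Two renders of the same inputs are
#'   byte-identical.
#' @export
write_jobs_json <- function(jobs, path) {
  if (inherits(jobs, "backend_job")) jobs <- list(jobs)
  payload <- purrr::map(jobs, unclass)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a semi-empirical input deck for one job (optional adapter)
#'
#' A minimal keyword-block renderer for a MOPAC-style program: method,
#' locality cutoff, gradient criterion, frozen residues and the fixed
#' coordinate distance. The core pipeline never requires this adapter; it
#' exists so rendered jobs can be handed to a real backend.
#'
#' @param job A `backend_job` from [render_job()].
#' @param method Semi-empirical Hamiltonian keyword (default `"PM6"`).
#' @return Character vector of deck lines.
#' @export
render_backend_deck <- function(job, method = "PM6") {
  stopifnot(inherits(job, "backend_job"))
  c(
    sprintf(
      "%s MOZYME CUTOFF=%g GNORM=%g", method,
      job$locality_cutoff_angstrom, job$gradient_criterion_kcal_mol_angstrom
    ),
    sprintf("MUTANT %s FRAME %d", job$mutant, job$frame),
    sprintf(
      "FIX DISTANCE %s %s %.6f", job$coordinate_atoms[[1]],
      job$coordinate_atoms[[2]], job$distance_angstrom
    ),
    sprintf("FREEZE RESIDUE %s", job$fixed_residues)
  )
}

#' Parse the final energy from backend text output (optional adapter)
#'
#' Scans output lines for the documented pattern
#' `FINAL HEAT OF FORMATION = <number> KCAL/MOL` and returns the last match.
#'
#' @param lines Character vector of backend output lines.
#' @return Energy in kcal/mol (length 1), or an error if no line matches.
#' @export
parse_backend_energy <- function(lines) {
  m <- stringr::str_match(
    lines, "FINAL HEAT OF FORMATION\\s*=\\s*(-?[0-9]+\\.?[0-9]*)\\s*KCAL/MOL"
  )
  hits <- m[!is.na(m[, 2]), 2]
  if (length(hits) == 0) {
    abort("No 'FINAL HEAT OF FORMATION = ... KCAL/MOL' line found in output.")
  }
  as.numeric(hits[[length(hits)]])
}
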