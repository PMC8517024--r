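# Time integration: velocity-Verlet core with a BAOAB-split Langevin
# thermostat (friction gamma, reduced temperature T).  gamma = 0, T = 0
# gives plain NVE velocity Verlet; the production regime for cellular
# mechanics is overdamped (gamma of order 1-10, small T).

#' Simulation parameters
#'
#' @param dt timestep (reduced time; default 0.002).
#' @param n_steps number of integration steps.
#' @param damping Langevin friction coefficient gamma (`>= 0`; 0 = NVE).
#' @param temperature reduced temperature (0 = deterministic dynamics).
#' @param seed RNG seed for the thermostat noise (integer).
#' @param record_every steps between recorded trajectory frames.
#' @param record_frames store full per-frame bead positions (set `FALSE`
#'   for long runs where only energies / probe forces are needed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.002, n_steps = 1000L, damping = 2,
                       temperature = 0.01, seed = 1L,
                       record_every = 10L, record_frames = TRUE) {
  stopifnot(dt > 0, n_steps >= 1, damping >= 0, temperature >= 0,
            record_every >= 1)
  structure(list(dt = dt, n_steps = as.integer(n_steps), damping = damping,
                 temperature = temperature, seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 record_frames = isTRUE(record_frames)),
            class = "sim_config")
}

run_md_raw <- function(config, table, sim, anchors = NULL, t0 = 0) {
  m <- pair_rule_matrices(table)
  if (is.null(anchors)) anchors <- empty_anchors()
  cpp_run_md(config$positions, config$velocities, as.integer(config$type),
             as.integer(config$cell_id),
             bonds_matrix(table), angles_matrix(table),
             m$same, m$cross, anchors,
             sim$dt, sim$n_steps, sim$damping, sim$temperature,
             sim$seed, sim$record_every, sim$record_frames, t0)
}

#' Advance a bead configuration by one timestep
#'
#' One velocity-Verlet update with Langevin friction/noise when
#' `damping > 0` and `temperature > 0`; deterministic for a fixed seed.
#'
#' @param state a `bead_config`.
#' @param table an `interaction_table`.
#' @param sim a [sim_config()] (its `n_steps` is ignored; one step is taken).
#' @return The updated `bead_config`.
#' @export
md_step <- function(state, table, sim) {
  sim$n_steps <- 1L
  sim$record_every <- 1L
  sim$record_frames <- FALSE
  out <- run_md_raw(state, table, sim)
  state$positions <- out$pos
  state$velocities <- out$vel
  state
}

#' Run a molecular-dynamics trajectory
#'
#' Iterates [md_step()] efficiently in compiled code, recording frames,
#' kinetic and potential energies every `record_every` steps.  Identical
#' seeds and configurations yield bitwise-identical trajectories.
#'
#' @param state a `bead_config` (see [build_cell()]).
#' @param table an `interaction_table`.
#' @param sim a [sim_config()].
#' @param anchors optional matrix of moving harmonic anchors (one row per
#'   anchor: bead index, kx, ky, x0, y0, vx, vy); used internally by the
#'   virtual AFM and the pull assay.
#' @return An object of class `trajectory`: list with `times`, `kinetic`,
#'   `potential`, `frames` (a `n_beads x 2 x n_frames` array when
#'   recorded), `final` (the final `bead_config`), anchor forces and
#'   positions per frame, and the `sim` metadata.
#' @export
run_md <- function(state, table, sim, anchors = NULL) {
  out <- run_md_raw(state, table, sim, anchors)
  final <- state
  final$positions <- out$pos
  final$velocities <- out$vel
  structure(list(times = out$times, kinetic = out$kinetic,
                 potential = out$potential,
                 frames = out$frames,
                 anchor_fx = out$anchor_fx, anchor_fy = out$anchor_fy,
                 anchor_x = out$anchor_x, anchor_y = out$anchor_y,
                 final = final, sim = sim),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " frames, t = ",
      signif(x$times[1], 4), " .. ", signif(x$times[length(x$times)], 4),
      "; final E_kin = ", signif(x$kinetic[length(x$kinetic)], 4),
      ", E_pot = ", signif(x$potential[length(x$potential)], 4), "\n", sep = "")
  invisible(x)
}

#' Write a trajectory as extended-XYZ text plus a CSV energy log
#'
#' @param traj a `trajectory` recorded with `record_frames = TRUE`.
#' @param xyz_path output path for the extended-XYZ file (columns: type,
#'   x, y; one block per frame).
#' @param energy_path optional path for a per-frame CSV energy log.
#' @param state the `bead_config` the trajectory was started from (for the
#'   bead type labels).
#' @return `xyz_path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, xyz_path, state, energy_path = NULL) {
  if (is.null(traj$frames)) stop("trajectory has no recorded frames")
  n <- dim(traj$frames)[1]
  con <- file(xyz_path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.10g", traj$times[f]), con)
    writeLines(sprintf("%d %.10g %.10g", state$type,
                       traj$frames[, 1, f], traj$frames[, 2, f]), con)
  }
  if (!is.null(energy_path))
    utils::write.csv(data.frame(time = traj$times, kinetic = traj$kinetic,
                                potential = traj$potential),
                     energy_path, row.names = FALSE)
  invisible(xyz_path)
}
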