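# Scenario sweeps: cortical contractility (vary eps03 at fixed eps00)
# versus cell-cell adhesion (vary eps00 at fixed eps03), each probed by
# virtual AFM indentation; and the colony cohesion assay that ramps a
# pulling spring on one cell until it detaches.

#' Specify a parameter sweep over contractility or adhesion
#'
#' @param scenario `"vary_eps03_fixed_eps00"` or
#'   `"vary_eps00_fixed_eps03"`.
#' @param values `>= 3` strictly increasing levels of the varied attraction
#'   energy.
#' @param fixed_value the held parameter's value.
#' @param seeds integer seeds (`>= 1` of them), one replicate per seed.
#' @param geometry,springs,tip,sim component configurations.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(scenario = c("vary_eps03_fixed_eps00",
                                    "vary_eps00_fixed_eps03"),
                       values = c(0.5, 1, 2) * 2, fixed_value = 1,
                       seeds = 1:3,
                       geometry = geometry_config(),
                       springs = spring_constants(),
                       tip = tip_config(), sim = sim_config()) {
  scenario <- match.arg(scenario)
  stopifnot(length(values) >= 3, all(diff(values) > 0) || length(unique(values)) == 1,
            length(seeds) >= 1)
  structure(list(scenario = scenario, values = values,
                 fixed_value = fixed_value, seeds = as.integer(seeds),
                 geometry = geometry, springs = springs, tip = tip,
                 sim = sim),
            class = "sweep_spec")
}

#' Run an attraction-energy sweep probed by virtual AFM
#'
#' One indentation per (level, seed) with all other parameters held fixed.
#' For each curve the post-contact stiffness proxy and the force at the
#' reference travel (midway between contact and maximal travel) are
#' recorded; per-run failures (e.g. membrane rupture) are flagged in the
#' row, not fatal to the sweep.
#'
#' @param spec a [sweep_spec()].
#' @return An object of class `sweep_result`: a data frame with one row
#'   per (level, seed) -- columns `scenario`, `level`, `seed`,
#'   `stiffness_proxy`, `force_at_reference_travel`, `rupture_flag` -- with
#'   a `summary` attribute of per-level mean and sd and the full spec as
#'   provenance.
#' @export
run_sweep <- function(spec) {
  rows <- list()
  for (lv in spec$values) for (sd in spec$seeds) {
    eps03 <- if (spec$scenario == "vary_eps03_fixed_eps00") lv else spec$fixed_value
    eps00 <- if (spec$scenario == "vary_eps00_fixed_eps03") lv else spec$fixed_value
    model <- build_cell(spec$geometry, spec$springs,
                        eps00 = eps00, eps03 = eps03)
    sim <- spec$sim
    sim$seed <- sd
    res <- tryCatch({
      curve <- run_indentation(model, spec$tip, sim)
      contact <- detect_contact(curve)
      t_ref <- min(contact + 0.5 * spec$tip$max_travel, max(curve$travel))
      # mid-indentation force: local average around the reference depth
      # (single samples carry bead-scale stick-slip noise)
      w <- 0.125 * spec$tip$max_travel
      sel <- curve$travel >= t_ref - w & curve$travel <= t_ref + w
      list(sp = stiffness_proxy(curve),
           fr = mean(curve$force[sel]),
           rupture = isTRUE(attr(curve, "ruptured")))
    }, error = function(e) list(sp = NA_real_, fr = NA_real_, rupture = TRUE))
    rows[[length(rows) + 1]] <- data.frame(
      scenario = spec$scenario, level = lv, seed = sd,
      stiffness_proxy = res$sp, force_at_reference_travel = res$fr,
      rupture_flag = res$rupture, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$level), function(d) data.frame(
    level = d$level[1],
    mean_force = mean(d$force_at_reference_travel, na.rm = TRUE),
    sd_force = stats::sd(d$force_at_reference_travel),
    mean_stiffness = mean(d$stiffness_proxy, na.rm = TRUE),
    sd_stiffness = stats::sd(d$stiffness_proxy))))
  summ <- summ[order(summ$level), ]
  rownames(summ) <- NULL
  structure(out, class = c("sweep_result", "data.frame"),
            summary = summ, spec = spec)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", attr(x, "spec")$scenario, ", ",
      length(unique(x$level)), " levels x ", length(unique(x$seed)),
      " seeds\n", sep = "")
  print(attr(x, "summary"))
  invisible(x)
}

#' Compare the force response of two sweep scenarios
#'
#' Computes each scenario's dynamic range of the mean force readout
#' (max mean - min mean over levels) and their ratio; the scenarios must
#' span the same multiplicative parameter range.
#'
#' @param a,b `sweep_result` objects.
#' @return A list with `range_a`, `range_b`, `ratio` (`range_a / range_b`)
#'   and `dominant` (`"a"`, `"b"`, or `"tie"`).
#' @export
compare_scenarios <- function(a, b) {
  span <- function(x) {
    v <- sort(unique(x$level)); v / v[1]
  }
  if (!isTRUE(all.equal(span(a), span(b))))
    stop("sweeps span different relative parameter ranges")
  rng <- function(x) {
    s <- attr(x, "summary")
    max(s$mean_force) - min(s$mean_force)
  }
  ra <- rng(a); rb <- rng(b)
  list(range_a = ra, range_b = rb, ratio = ra / rb,
       dominant = if (isTRUE(all.equal(ra, rb))) "tie" else
         if (ra > rb) "a" else "b")
}

#' Specify a colony pull-out assay
#'
#' @param target `"edge"` or `"center"`: which cell to pull.
#' @param pull_spring stiffness of the pulling spring (`> 0`).
#' @param ramp_rate outward speed of the pull anchor (`> 0`).
#' @param detach_displacement centroid displacement (in cell diameters)
#'   at which the cell counts as detached (default 1).
#' @param n_grab number of membrane beads (nearest the pull direction) the
#'   spring is distributed over.
#' @param seeds integer replicate seeds.
#' @param sim a [sim_config()].
#' @return An object of class `pull_spec`.
#' @export
pull_spec <- function(target = c("edge", "center"), pull_spring = 5,
                      ramp_rate = 0.1, detach_displacement = 1,
                      n_grab = 9L, seeds = 1:3, sim = sim_config()) {
  target <- match.arg(target)
  stopifnot(pull_spring > 0, ramp_rate > 0, detach_displacement > 0,
            n_grab >= 1)
  structure(list(target = target, pull_spring = pull_spring,
                 ramp_rate = ramp_rate,
                 detach_displacement = detach_displacement,
                 n_grab = as.integer(n_grab), seeds = as.integer(seeds),
                 sim = sim),
            class = "pull_spec")
}

#' Pull a cell out of a colony and record the pull-out force
#'
#' A pulling spring, distributed over the target cell's membrane beads
#' nearest the outward pull direction, is ramped away from the colony at
#' constant speed.  The pull-out force is the maximum total spring force
#' recorded before the cell's centroid has moved one detachment distance
#' from its initial position; runs that never detach within the allotted
#' travel are flagged censored.
#'
#' The reported force is corrected for the steady viscous drag of towing a
#' free cell through the Langevin bath (`damping * n_beads * ramp_rate`),
#' so that with no adhesion the pull-out force is zero up to thermal noise.
#'
#' @param colony a `cell_model` from [build_colony()].
#' @param spec a [pull_spec()].
#' @param max_travel_diameters maximal anchor travel, in cell diameters.
#' @param equil_steps colony pre-equilibration steps before the ramp
#'   (default 6000): the cells contract to their contractile steady state
#'   and compact into mutual adhesive contact.
#' @return A data frame with one row per seed: `target`, `cell_id`,
#'   `seed`, `pullout_force` (drag-corrected), `detached`, `censored`.
#' @export
run_pull_assay <- function(colony, spec = pull_spec(),
                           max_travel_diameters = 2, equil_steps = 6000L) {
  cells <- colony$cells
  if (spec$target == "center" && !any(cells$role == "center"))
    stop("colony has no center cell")
  cid <- cells$cell_id[cells$role == spec$target][1]
  cfg0 <- colony$config
  sel_cell <- cfg0$cell_id == cid
  mem <- which(sel_cell & cfg0$type == 0L)
  cell_centre <- c(cells$cx[cid], cells$cy[cid])
  colony_centre <- colMeans(cells[, c("cx", "cy")])
  dirv <- cell_centre - colony_centre
  if (sqrt(sum(dirv^2)) < 1e-9) dirv <- c(1, 0)  # pulling the central cell
  dirv <- dirv / sqrt(sum(dirv^2))
  # membrane beads facing the pull direction
  proj <- as.vector(cfg0$positions[mem, , drop = FALSE] %*% dirv)
  grab <- mem[order(proj, decreasing = TRUE)][seq_len(min(spec$n_grab, length(mem)))]
  k_each <- spec$pull_spring / length(grab)
  diam <- 2 * colony$R_cell
  detach_d <- spec$detach_displacement * diam
  max_travel <- max_travel_diameters * diam

  n_cell_beads <- sum(sel_cell)
  rows <- list()
  for (sd in spec$seeds) {
    sim <- spec$sim
    sim$seed <- sd
    sim$record_frames <- FALSE
    cfg <- cfg0
    if (equil_steps > 0) {
      sim_eq <- sim
      sim_eq$n_steps <- as.integer(equil_steps)
      sim_eq$seed <- sim$seed + 32452843L
      eq <- run_md_raw(cfg, colony$table, sim_eq)
      cfg$positions <- eq$pos
      cfg$velocities <- eq$vel
    }
    anchors <- cbind(grab, k_each, k_each,
                     cfg$positions[grab, 1], cfg$positions[grab, 2],
                     spec$ramp_rate * dirv[1], spec$ramp_rate * dirv[2])
    drag <- sim$damping * n_cell_beads * spec$ramp_rate
    n_steps <- ceiling(max_travel / (spec$ramp_rate * sim$dt))
    n_chunks <- 24L
    chunk <- ceiling(n_steps / n_chunks)
    t_now <- 0
    fmax <- 0
    detached <- FALSE
    start_centroid <- colMeans(cfg$positions[sel_cell, , drop = FALSE])
    for (ck in seq_len(n_chunks)) {
      sim_ck <- sim
      sim_ck$n_steps <- min(chunk, n_steps - (ck - 1L) * chunk)
      if (sim_ck$n_steps <= 0) break
      sim_ck$seed <- sim$seed + 104729L * (ck - 1L)
      out <- run_md_raw(cfg, colony$table, sim_ck, anchors, t0 = t_now)
      ftot <- sqrt(rowSums(out$anchor_fx)^2 + rowSums(out$anchor_fy)^2)
      cfg$positions <- out$pos
      cfg$velocities <- out$vel
      t_now <- t_now + sim_ck$n_steps * sim$dt  # true final time, not last frame
      centroid <- colMeans(cfg$positions[sel_cell, , drop = FALSE])
      disp <- sqrt(sum((centroid - start_centroid)^2))
      if (disp >= detach_d) {
        # only force up to the detachment event counts
        fmax <- max(fmax, max(ftot))
        detached <- TRUE
        break
      }
      fmax <- max(fmax, max(ftot))
    }
    rows[[length(rows) + 1]] <- data.frame(
      target = spec$target, cell_id = cid, seed = sd,
      pullout_force = max(fmax - drag, 0), detached = detached,
      censored = !detached, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
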