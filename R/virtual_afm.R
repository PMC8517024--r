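# Virtual AFM: a probe bead (type 7) clamped to a moving apparatus by two
# orthogonal springs (kx, ky).  The apparatus advances toward the cell at
# constant velocity; the reported force is the spring deformation projected
# on the approach direction.  The same module carries the Hertz/Sneddon
# contact-mechanics fit used for experimental force-indentation curves.

#' AFM tip parameters
#'
#' @param kx,ky spring constants clamping the tip bead to the moving
#'   apparatus, in x and y (`> 0`).
#' @param radius tip interaction radius; the tip--membrane WCA equilibrium
#'   distance is `radius + 0.5` (tip radius plus membrane bead radius).
#' @param velocity constant approach speed of the apparatus (`> 0`,
#'   reduced units); keep small enough to stay quasi-static.
#' @param approach_direction unit 2D vector pointing from the tip toward
#'   the cell.
#' @param start_gap initial clearance between tip surface and membrane.
#' @param max_travel total apparatus displacement.
#' @return An object of class `tip_config`.
#' @export
tip_config <- function(kx = 5, ky = 5, radius = 2, velocity = 0.1,
                       approach_direction = c(-1, 0), start_gap = 1,
                       max_travel = 8) {
  stopifnot(kx > 0, ky > 0, radius > 0, velocity > 0, start_gap >= 0,
            max_travel > 0)
  v <- approach_direction / sqrt(sum(approach_direction^2))
  structure(list(kx = kx, ky = ky, radius = radius, velocity = velocity,
                 approach_direction = v, start_gap = start_gap,
                 max_travel = max_travel),
            class = "tip_config")
}

#' Run a virtual AFM indentation
#'
#' Appends the tip bead (type 7, purely repulsive WCA against all cell
#' beads), couples it to an apparatus anchor moving at the tip's constant
#' velocity along the approach direction, integrates the damped dynamics,
#' and records the restoring spring force projected on the approach
#' direction as a function of apparatus travel.
#'
#' If a FENE bond overextends (membrane rupture) the curve is truncated at
#' the rupture point and flagged.
#'
#' @param model a `cell_model` from [build_cell()] (or [build_colony()]).
#' @param tip a [tip_config()].
#' @param sim a [sim_config()]; its `n_steps` is ignored (derived from
#'   `max_travel / (velocity * dt)`), `record_every` sets the curve's
#'   sampling.
#' @param target_cell cell whose membrane is approached (default 1).
#' @param equil_steps pre-equilibration steps with the apparatus held
#'   still (default 4000), letting the cortex contract to its steady
#'   state before the approach begins.
#' @return An object of class `fd_curve`: data frame columns `travel`,
#'   `force`, with metadata attributes (`tip`, `sim`, `seed`, `ruptured`).
#' @export
run_indentation <- function(model, tip = tip_config(), sim = sim_config(),
                            target_cell = 1L, equil_steps = 4000L) {
  cfg <- model$config
  table <- model$table
  dirv <- tip$approach_direction
  sel <- cfg$cell_id == target_cell & cfg$type == 0L
  centre <- colMeans(cfg$positions[sel, , drop = FALSE])
  # membrane point nearest the incoming tip
  proj <- as.vector(cfg$positions[sel, , drop = FALSE] %*% dirv)
  surface <- cfg$positions[sel, , drop = FALSE][which.min(proj), ]
  sigma07 <- tip$radius + 0.5
  tip_pos <- surface - (sigma07 + tip$start_gap) * dirv

  cfg$positions <- rbind(cfg$positions, tip_pos)
  cfg$velocities <- rbind(cfg$velocities, tip$velocity * dirv)
  cfg$type <- c(cfg$type, 7L)
  cfg$cell_id <- c(cfg$cell_id, 0L)
  tip_idx <- length(cfg$type)

  pr <- table$pair_rules
  if (is.null(pr$scope)) pr$scope <- "any"
  for (tt in c(0L, 1L, 3L))
    pr <- rbind(pr, data.frame(type_i = tt, type_j = 7L, potential = "WCA",
                               epsilon = 1, sigma = sigma07, cutoff = sigma07,
                               scope = "any"))
  table$pair_rules <- pr

  anchors <- matrix(c(tip_idx, tip$kx, tip$ky, tip_pos[1], tip_pos[2],
                      tip$velocity * dirv[1], tip$velocity * dirv[2]),
                    nrow = 1)

  if (equil_steps > 0) {
    cfg$velocities[tip_idx, ] <- 0
    hold <- anchors
    hold[1, 6:7] <- 0
    sim_eq <- sim
    sim_eq$n_steps <- as.integer(equil_steps)
    sim_eq$record_frames <- FALSE
    sim_eq$seed <- sim$seed + 15485863L
    eq <- run_md_raw(cfg, table, sim_eq, hold)
    cfg$positions <- eq$pos
    cfg$velocities <- eq$vel
    cfg$velocities[tip_idx, ] <- tip$velocity * dirv
  }

  n_steps <- ceiling(tip$max_travel / (tip$velocity * sim$dt))
  n_chunks <- 16L
  chunk <- ceiling(n_steps / n_chunks)
  sim$record_frames <- FALSE
  travel <- numeric(0); force <- numeric(0)
  ruptured <- FALSE
  t_now <- 0
  for (ck in seq_len(n_chunks)) {
    sim_ck <- sim
    sim_ck$n_steps <- min(chunk, n_steps - (ck - 1L) * chunk)
    if (sim_ck$n_steps <= 0) break
    sim_ck$seed <- sim$seed + 7919L * (ck - 1L)
    out <- tryCatch(run_md_raw(cfg, table, sim_ck, anchors, t0 = t_now),
                    error = function(e) e)
    if (inherits(out, "error")) {
      ruptured <- TRUE
      break
    }
    keep <- if (ck == 1L) TRUE else -1L  # drop duplicated first frame
    tt <- out$times
    ff <- out$anchor_fx[, 1] * dirv[1] + out$anchor_fy[, 1] * dirv[2]
    if (ck > 1L) { tt <- tt[-1]; ff <- ff[-1] }
    travel <- c(travel, tip$velocity * tt)
    force <- c(force, ff)
    cfg$positions <- out$pos
    cfg$velocities <- out$vel
    t_now <- t_now + sim_ck$n_steps * sim$dt  # true final time, not last frame
  }
  # spring elongation along the approach direction: positive once the
  # membrane resists the advancing tip
  curve <- data.frame(travel = travel, force = force)
  structure(curve, class = c("fd_curve", "data.frame"),
            tip = tip, sim = sim, seed = sim$seed, ruptured = ruptured)
}

#' Detect the contact point of a force--distance curve
#'
#' First sample whose force exceeds a fraction of the maximum recorded
#' force (default 1%).
#'
#' @param curve an `fd_curve` (or data frame with `travel`, `force`).
#' @param threshold_frac force threshold as a fraction of the maximum.
#' @return The contact travel value.
#' @export
detect_contact <- function(curve, threshold_frac = 0.01) {
  thr <- threshold_frac * max(curve$force)
  idx <- which(curve$force > thr)
  if (!length(idx)) stop("no contact detected")
  curve$travel[idx[1]]
}

#' Stiffness proxy: post-contact slope of a force--distance curve
#'
#' Least-squares slope of force versus travel over a post-contact window.
#'
#' @inheritParams detect_contact
#' @param window travel interval `c(lo, hi)`; default the central half of
#'   the post-contact range.
#' @return Slope (force per distance).
#' @export
stiffness_proxy <- function(curve, window = NULL, threshold_frac = 0.01) {
  contact <- detect_contact(curve, threshold_frac)
  tmax <- max(curve$travel)
  if (is.null(window))
    window <- contact + c(0.25, 0.75) * (tmax - contact)
  if (window[1] < contact)
    stop("stiffness window precedes detected contact point")
  sel <- curve$travel >= window[1] & curve$travel <= window[2]
  if (sum(sel) < 2) stop("stiffness window contains fewer than 2 samples")
  unname(stats::coef(stats::lm(force ~ travel, data = curve[sel, ]))[2])
}

#' Force at a given travel, by linear interpolation
#'
#' @inheritParams detect_contact
#' @param travel apparatus displacement at which to read the force.
#' @return Interpolated force.
#' @export
force_at <- function(curve, travel) {
  stats::approx(curve$travel, curve$force, xout = travel, rule = 2)$y
}

hertz_prefactor <- function(model_form) {
  switch(model_form, cone = 2 / pi, pyramid = 0.7453,
         stop("unknown model_form"))
}

#' Fit the Hertz--Sneddon contact model to a force--indentation curve
#'
#' Fits \deqn{F(\delta) = C \frac{E}{1-\nu^2} \tan(\alpha)\,\delta^2,
#'   \qquad \delta = travel - contact,}
#' jointly estimating the elastic modulus `E` and the contact point, where
#' \eqn{\alpha} is the probe half-opening angle and \eqn{\nu} the sample
#' Poisson ratio.  `C = 2/pi` for a conical (Sneddon) indenter, the
#' default; `C = 0.7453` for a four-sided pyramid.
#'
#' Units follow the curve: with travel in micrometres and force in
#' nanonewtons the fitted modulus is in kilopascals.
#'
#' @param curve a force--indentation curve (data frame with `travel`,
#'   `force`), in physical units, with at least 20 post-contact samples.
#' @param half_angle probe tip half-opening angle in degrees (default 9).
#' @param poisson sample Poisson ratio (default 0.45; must be in (0, 0.5]).
#' @param model_form `"cone"` or `"pyramid"`.
#' @return An object of class `hertz_fit` with components `modulus`,
#'   `contact_point`, `half_angle`, `poisson`, `model_form` and the
#'   underlying nonlinear-least-squares fit; supports [print()], [coef()],
#'   [predict()], [plot()] and [residuals()].
#' @export
fit_hertz <- function(curve, half_angle = 9, poisson = 0.45,
                      model_form = c("cone", "pyramid")) {
  model_form <- match.arg(model_form)
  stopifnot(poisson > 0, poisson <= 0.5)
  C <- hertz_prefactor(model_form)
  K <- C * tan(half_angle * pi / 180) / (1 - poisson^2)
  c0 <- tryCatch(detect_contact(curve), error = function(e) min(curve$travel))
  if (sum(curve$travel > c0) < 20)
    stop("need at least 20 post-contact samples to fit")
  post <- curve[curve$travel > c0, ]
  E0 <- stats::median(post$force / pmax(post$travel - c0, 1e-12)^2) / K
  dat <- data.frame(t = curve$travel, f = curve$force)
  fit <- minpack.lm::nlsLM(
    f ~ K * E * pmax(t - t0, 0)^2, data = dat,
    start = list(E = max(E0, .Machine$double.eps), t0 = c0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv && fit$convInfo$stopCode %in% c(0, 5))
    stop("Hertz fit failed to converge; residual sum of squares = ",
         signif(sum(stats::residuals(fit)^2), 4))
  est <- stats::coef(fit)
  structure(list(modulus = unname(est["E"]),
                 contact_point = unname(est["t0"]),
                 half_angle = half_angle, poisson = poisson,
                 model_form = model_form, prefactor = C,
                 fit = fit, curve = curve),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("Hertz-Sneddon fit (", x$model_form, " indenter, half-angle ",
      x$half_angle, " deg, nu = ", x$poisson, ")\n", sep = "")
  cat("  elastic modulus E: ", signif(x$modulus, 5),
      "\n  contact point:     ", signif(x$contact_point, 5), "\n", sep = "")
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(modulus = object$modulus, contact_point = object$contact_point)
}

#' @export
predict.hertz_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$curve$travel else newdata$travel
  K <- object$prefactor * tan(object$half_angle * pi / 180) /
    (1 - object$poisson^2)
  K * object$modulus * pmax(t - object$contact_point, 0)^2
}

#' @export
residuals.hertz_fit <- function(object, ...) {
  object$curve$force - predict(object)
}

#' @export
plot.hertz_fit <- function(x, ...) {
  graphics::plot(x$curve$travel, x$curve$force, pch = 16, cex = 0.5,
                 xlab = "travel", ylab = "force", ...)
  ord <- order(x$curve$travel)
  graphics::lines(x$curve$travel[ord], predict(x)[ord], col = 2, lwd = 2)
  graphics::abline(v = x$contact_point, lty = 3)
  invisible(x)
}

#' Filter out-of-range elastic moduli
#'
#' Removes modulus values above `max_modulus` (default 20 kPa, the
#' substrate-effect cutoff for cultures with exposed dish areas: very large
#' apparent moduli are direct dish indentations, not cells).
#'
#' @param values vector of fitted moduli (finite, positive).
#' @param max_modulus retention threshold; values `<= max_modulus` are kept
#'   in their original order.
#' @return A list with `values` (the retained moduli) and `n_removed`.
#' @export
filter_moduli <- function(values, max_modulus = 20) {
  stopifnot(all(is.finite(values)), all(values > 0) || !length(values))
  keep <- values <= max_modulus
  list(values = values[keep], n_removed = sum(!keep))
}

#' Write / read a force--distance curve as CSV with a JSON sidecar
#'
#' @param curve an `fd_curve`.
#' @param path CSV output path (two columns: travel, force); metadata goes
#'   to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(travel = curve$travel, force = curve$force),
                   path, row.names = FALSE)
  meta <- list(tip = unclass(attr(curve, "tip")),
               sim = unclass(attr(curve, "sim")),
               seed = attr(curve, "seed"),
               ruptured = isTRUE(attr(curve, "ruptured")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  curve <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  structure(curve, class = c("fd_curve", "data.frame"),
            tip = meta$tip, sim = meta$sim, seed = meta$seed,
            ruptured = isTRUE(meta$ruptured))
}
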