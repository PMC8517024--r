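# The short indentation runs here use the reduced-resolution desk cell;
# the full-size sweeps live in the acceptance suite.

desk_tip <- function(...) tip_config(velocity = 0.2, max_travel = 3, ...)
desk_sim <- function(seed = 1) sim_config(seed = seed, record_every = 20)

test_that("no force is recorded before contact (deterministic at T = 0)", {
  m <- build_cell(desk_geometry())
  tip <- tip_config(velocity = 0.2, start_gap = 3, max_travel = 1.5)
  sim <- sim_config(temperature = 0, seed = 1, record_every = 20)
  cu <- run_indentation(m, tip, sim, equil_steps = 1000)
  expect_true(all(cu$travel <= 1.5 + 1e-9))
  expect_lt(max(abs(cu$force)), 1e-9)
})

test_that("identical seed and configuration give identical curves", {
  m <- build_cell(desk_geometry())
  c1 <- run_indentation(m, desk_tip(), desk_sim(5), equil_steps = 500)
  c2 <- run_indentation(m, desk_tip(), desk_sim(5), equil_steps = 500)
  expect_identical(c1$force, c2$force)
  c3 <- run_indentation(m, desk_tip(), desk_sim(6), equil_steps = 500)
  expect_false(identical(c1$force, c3$force))
})

test_that("post-contact indentation force resists the approach", {
  m <- build_cell(desk_geometry())
  tip <- tip_config(velocity = 0.2, start_gap = 0.5, max_travel = 4)
  cu <- run_indentation(m, tip, desk_sim(2), equil_steps = 2000)
  ct <- detect_contact(cu)
  post <- cu$force[cu$travel > ct + 0.5]
  expect_gt(mean(post), 0)
  expect_gt(force_at(cu, max(cu$travel)), 0)
})

test_that("stiffness proxy recovers exact slopes and scales linearly", {
  curve <- data.frame(travel = seq(0, 1, 0.01))
  curve$force <- 3.7 * curve$travel
  expect_equal(stiffness_proxy(curve), 3.7, tolerance = 1e-12)
  curve2 <- curve; curve2$force <- 5 * curve$force
  expect_equal(stiffness_proxy(curve2), 5 * 3.7, tolerance = 1e-12)
  expect_error(stiffness_proxy(curve, window = c(-1, 0.5)), "precedes")
})

test_that("the quasi-static probe measures the contact law, not its own spring", {
  # rigid wall: a vertical line of immobilized beads.  At quasi-static
  # equilibrium the force at a given tip position is the contact force
  # alone, so it must not depend on the clamp stiffness (kx, ky) or on
  # the approach velocity.
  wall_curve <- function(k, v) {
    nw <- 15
    wall <- cbind(rep(0, nw), seq(-7, 7, length.out = nw))
    tipp <- c(4.5, 0)
    cfg <- structure(list(positions = rbind(wall, tipp),
                          velocities = rbind(matrix(0, nw, 2), c(-v, 0)),
                          type = c(rep(0L, nw), 7L),
                          cell_id = c(rep(1L, nw), 0L)),
                     class = "bead_config")
    tab <- structure(list(
      bonds = NULL, angles = NULL,
      pair_rules = data.frame(type_i = 0L, type_j = 7L, potential = "WCA",
                              epsilon = 1, sigma = 2.5, cutoff = 2.5),
      eps00 = 0, eps03 = 0), class = "interaction_table")
    anchors <- rbind(cbind(seq_len(nw), 500, 500, wall[, 1], wall[, 2], 0, 0),
                     c(nw + 1, k, k, tipp[1], tipp[2], -v, 0))
    sim <- sim_config(dt = 0.002, n_steps = ceiling(2.8 / (v * 0.002)),
                      damping = 2, temperature = 0, seed = 1,
                      record_every = 20, record_frames = TRUE)
    tr <- run_md(cfg, tab, sim, anchors = anchors)
    # force as a function of tip position (not apparatus travel)
    data.frame(tip_x = tr$frames[nw + 1, 1, ], force = -tr$anchor_fx[, nw + 1])
  }
  f_of_x <- function(cu, grid) approx(rev(cu$tip_x), rev(cu$force), xout = grid)$y
  c_soft <- wall_curve(k = 5, v = 0.05)
  c_stiff <- wall_curve(k = 10, v = 0.05)
  c_slow <- wall_curve(k = 5, v = 0.025)
  grid <- seq(2.37, 2.47, 0.02)  # shallow contact (WCA onset at x = 2.5)
  ref <- f_of_x(c_soft, grid)
  expect_lt(max(abs(f_of_x(c_stiff, grid) - ref)) / max(ref), 0.05)
  expect_lt(max(abs(f_of_x(c_slow, grid) - ref)) / max(ref), 0.05)
})

test_that("Hertz fit recovers the planted modulus", {
  # noiseless cone-form curve at the wild-type stiffness scale
  fx <- make_sneddon_curve(E = 2.2, contact_point = 0.4, seed = 1)
  fit <- fit_hertz(fx$curve)
  expect_equal(fit$modulus, 2.2, tolerance = 0.01)
  expect_equal(fit$contact_point, 0.4, tolerance = 0.02)
  # doubling the force doubles the fitted modulus
  c2 <- fx$curve; c2$force <- 2 * c2$force
  expect_equal(fit_hertz(c2)$modulus, 2 * fit$modulus, tolerance = 1e-6)
  # pyramid form is self-consistent
  fp <- make_sneddon_curve(E = 5.9, model_form = "pyramid", seed = 2)
  expect_equal(fit_hertz(fp$curve, model_form = "pyramid")$modulus, 5.9,
               tolerance = 0.01)
  # fitted-curve methods
  expect_equal(unname(coef(fit)["modulus"]), fit$modulus)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("Hertz fit is robust to multiplicative noise", {
  set.seed(99)
  err <- replicate(50, {
    fx <- make_sneddon_curve(E = 2.2, contact_point = 0.4,
                             noise = list(kind = "multiplicative", sd = 0.02),
                             seed = sample.int(1e6, 1))
    abs(fit_hertz(fx$curve)$modulus - 2.2) / 2.2
  })
  expect_lt(median(err), 0.05)
})

test_that("the 20 kPa substrate-effect filter keeps order and reports removals", {
  r <- filter_moduli(c(4.0, 25.0, 5.9))
  expect_equal(r$values, c(4.0, 5.9))
  expect_equal(r$n_removed, 1)
  expect_equal(filter_moduli(numeric(0))$values, numeric(0))
  v <- c(3, 19.9, 20)
  expect_equal(filter_moduli(v)$values, v)
})

test_that("force-distance curves round-trip through CSV with sidecar metadata", {
  m <- build_cell(desk_geometry())
  cu <- run_indentation(m, desk_tip(), desk_sim(3), equil_steps = 200)
  p <- file.path(tempdir(), "curve.csv")
  write_curve(cu, p)
  cu2 <- read_curve(p)
  expect_equal(cu2$travel, cu$travel)
  expect_equal(cu2$force, cu$force)
  expect_equal(attr(cu2, "seed"), attr(cu, "seed"))
  expect_false(attr(cu2, "ruptured"))
})
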