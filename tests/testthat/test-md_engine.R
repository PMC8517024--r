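test_that("a force-free bead travels ballistically", {
  s <- free_bead(v = c(0.3, -0.2))
  sim <- sim_config(dt = 0.01, n_steps = 100, damping = 0, temperature = 0,
                    record_every = 100)
  tr <- run_md(s$config, s$table, sim)
  expect_equal(tr$final$positions[1, ], c(0.3, -0.2) * 1, tolerance = 1e-12)
  expect_equal(tr$final$velocities[1, ], c(0.3, -0.2), tolerance = 1e-14)
})

test_that("a relaxed cell at rest is a fixed point of NVE dynamics", {
  m <- build_cell(desk_geometry(), springs = spring_constants(theta0 = "constructed"))
  tab <- m$table
  tab$pair_rules <- NULL   # bonded terms only: exact mechanical equilibrium
  sim <- sim_config(dt = 0.002, n_steps = 200, damping = 0, temperature = 0,
                    record_every = 200)
  tr <- run_md(m$config, tab, sim)
  expect_lt(max(abs(tr$final$positions - m$config$positions)), 1e-12)
})

test_that("trajectories are bitwise identical under a fixed seed", {
  m <- build_cell(desk_geometry())
  sim <- sim_config(dt = 0.002, n_steps = 300, damping = 2, temperature = 0.05,
                    seed = 42, record_every = 50)
  t1 <- run_md(m$config, m$table, sim)
  t2 <- run_md(m$config, m$table, sim)
  expect_identical(t1$final$positions, t2$final$positions)
  expect_identical(t1$kinetic, t2$kinetic)
  sim$seed <- 43
  t3 <- run_md(m$config, m$table, sim)
  expect_false(identical(t1$final$positions, t3$final$positions))
})

test_that("NVE conserves energy and momentum on the perturbed cell", {
  m <- build_cell(desk_geometry(), springs = spring_constants(theta0 = "constructed"))
  cfg <- m$config
  cfg$positions <- cfg$positions * 1.01   # 1% radial strain
  sim <- sim_config(dt = 1e-3, n_steps = 2000, damping = 0, temperature = 0,
                    record_every = 50)
  tr <- run_md(cfg, m$table, sim)
  E <- tr$kinetic + tr$potential
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-3)
  # total momentum stays zero (no tip, no anchors, started at rest)
  expect_lt(max(abs(colSums(tr$final$velocities))), 1e-10)
})

test_that("a FENE bond oscillates at the harmonic-limit frequency sqrt(2 kF / m)", {
  kF <- 12
  cfg <- structure(list(positions = rbind(c(0, 0), c(1.02, 0)),  # a << drmax
                        velocities = matrix(0, 2, 2),
                        type = c(1L, 1L), cell_id = c(1L, 1L)),
                   class = "bead_config")
  tab <- structure(list(
    bonds = data.frame(i = 1, j = 2, class = "kF11", kF = kF, r0 = 1, drmax = 0.5),
    angles = NULL, pair_rules = NULL, eps00 = 0, eps03 = 0),
    class = "interaction_table")
  sim <- sim_config(dt = 5e-4, n_steps = 8000, damping = 0, temperature = 0,
                    record_every = 1, record_frames = TRUE)
  tr <- run_md(cfg, tab, sim)
  sep <- tr$frames[2, 1, ] - tr$frames[1, 1, ] - 1   # extension about r0
  # period from zero crossings of the extension
  sgn <- sign(sep)
  crossings <- which(diff(sgn) != 0 & sgn[-length(sgn)] != 0)
  n_half <- length(crossings) - 1
  period <- 2 * (tr$times[crossings[length(crossings)]] - tr$times[crossings[1]]) / n_half
  omega <- 2 * pi / period
  expect_equal(omega, sqrt(2 * kF), tolerance = 0.01)
})

test_that("thermostatted free beads reach 2D equipartition", {
  n <- 150
  cfg <- structure(list(positions = matrix(runif(2 * n, 0, 100), n, 2),
                        velocities = matrix(0, n, 2),
                        type = rep(5L, n),   # a type with no pair rules: ideal gas
                        cell_id = rep(1L, n)),
                   class = "bead_config")
  tab <- structure(list(bonds = NULL, angles = NULL, pair_rules = NULL,
                        eps00 = 0, eps03 = 0),
                   class = "interaction_table")
  Tset <- 0.5
  sim <- sim_config(dt = 0.01, n_steps = 6000, damping = 1, temperature = Tset,
                    seed = 3, record_every = 20)
  tr <- run_md(cfg, tab, sim)
  half <- tr$kinetic[-(1:(length(tr$kinetic) / 2))]
  # 2D: <KE> per bead = k_B T
  expect_equal(mean(half) / n, Tset, tolerance = 0.05)
})

test_that("overextension and instability raise informative errors", {
  cfg <- structure(list(positions = rbind(c(0, 0), c(1, 0)),
                        velocities = rbind(c(-5, 0), c(5, 0)),
                        type = c(1L, 1L), cell_id = c(1L, 1L)),
                   class = "bead_config")
  tab <- structure(list(
    bonds = data.frame(i = 1, j = 2, class = "kF11", kF = 5, r0 = 1, drmax = 0.3),
    angles = NULL, pair_rules = NULL, eps00 = 0, eps03 = 0),
    class = "interaction_table")
  sim <- sim_config(dt = 0.01, n_steps = 500, damping = 0, temperature = 0)
  expect_error(run_md(cfg, tab, sim), "overextended")
})

test_that("trajectory export writes parseable extended-XYZ and energy logs", {
  m <- build_cell(desk_geometry())
  sim <- sim_config(n_steps = 100, record_every = 50, record_frames = TRUE)
  tr <- run_md(m$config, m$table, sim)
  xyz <- file.path(tempdir(), "traj.xyz")
  elog <- file.path(tempdir(), "traj_energy.csv")
  write_trajectory_xyz(tr, xyz, m$config, elog)
  lines <- readLines(xyz)
  n <- nrow(m$config$positions)
  expect_equal(length(lines), length(tr$times) * (n + 2))
  expect_equal(as.integer(lines[1]), n)
  e <- read.csv(elog)
  expect_equal(nrow(e), length(tr$times))
  expect_true(all(is.finite(e$potential)))
})
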