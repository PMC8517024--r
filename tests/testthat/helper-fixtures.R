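# Shared fixtures: small random bead systems for force-gradient oracles,
# a reduced-resolution ("desk") cell geometry for dynamics tests, and a
# rigid-wall target for probe calibration checks.

# random small system with bonds, one angle, and mixed LJ/WCA pair rules;
# bead positions are spread out so no pair starts inside the steep core
random_small_system <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:12, 1)
  repeat {
    pos <- matrix(stats::runif(2 * n, 0, 3 * sqrt(n)), n, 2)
    if (min(stats::dist(pos)) > 0.85) break
  }
  type <- sample(c(0L, 1L, 3L), n, replace = TRUE)
  cfg <- structure(list(positions = pos, velocities = matrix(0, n, 2),
                        type = type, cell_id = rep(1L, n)),
                   class = "bead_config")
  # bond a random chain subset, with r0 near the current length
  nb <- sample(1:(n - 1), 1)
  ii <- seq_len(nb)
  d <- sqrt(rowSums((pos[ii, , drop = FALSE] - pos[ii + 1, , drop = FALSE])^2))
  bonds <- data.frame(i = ii, j = ii + 1, class = "kF00",
                      kF = stats::runif(nb, 5, 30),
                      r0 = d * stats::runif(nb, 0.9, 1.1),
                      drmax = d)
  angles <- if (n >= 3)
    data.frame(i = 1L, j = 2L, k = 3L, kB = stats::runif(1, 1, 10),
               theta0 = stats::runif(1, 1, pi))
  else data.frame(i = integer(), j = integer(), k = integer(),
                  kB = numeric(), theta0 = numeric())
  pr <- data.frame(
    type_i = c(0L, 0L, 0L, 1L, 1L, 3L),
    type_j = c(0L, 3L, 1L, 1L, 3L, 3L),
    potential = c("LJ", "LJ", "WCA", "WCA", "WCA", "WCA"),
    epsilon = stats::runif(6, 0.5, 2),
    sigma = stats::runif(6, 0.8, 1.2),
    cutoff = 0, stringsAsFactors = FALSE)
  pr$cutoff <- ifelse(pr$potential == "LJ", 2.5 * pr$sigma, pr$sigma)
  table <- structure(list(bonds = bonds, angles = angles, pair_rules = pr,
                          eps00 = 1, eps03 = 1),
                     class = "interaction_table")
  list(config = cfg, table = table)
}

fd_gradient <- function(config, table, h = 1e-6) {
  n <- nrow(config$positions)
  g <- matrix(0, n, 2)
  for (i in seq_len(n)) for (d in 1:2) {
    cp <- config; cm <- config
    cp$positions[i, d] <- cp$positions[i, d] + h
    cm$positions[i, d] <- cm$positions[i, d] - h
    g[i, d] <- -(total_energy(cp, table) - total_energy(cm, table)) / (2 * h)
  }
  g
}

# reduced-resolution cell: same architecture, minutes-scale dynamics
desk_geometry <- function() {
  geometry_config(n_membrane_beads = 41L, n_nuclear_beads = 11L,
                  typeI_beads = 4L, typeI_length_um = 1.0,
                  typeII_beads = 3L, typeII_length_um = 0.8,
                  n_typeI_filaments = 5L)
}

desk_pull_spec <- function(target = "edge", seeds = 1:3) {
  pull_spec(target = target, pull_spring = 20, ramp_rate = 0.15,
            seeds = seeds, sim = sim_config(damping = 0.5))
}

# single free bead and an empty interaction table
free_bead <- function(v = c(0.3, -0.2)) {
  cfg <- structure(list(positions = matrix(0, 1, 2),
                        velocities = matrix(v, 1, 2),
                        type = 0L, cell_id = 1L),
                   class = "bead_config")
  tab <- structure(list(bonds = NULL, angles = NULL,
                        pair_rules = NULL, eps00 = 0, eps03 = 0),
                   class = "interaction_table")
  list(config = cfg, table = tab)
}
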