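test_that("default single-cell build matches the reference architecture", {
  m <- build_cell()
  cfg <- m$config
  expect_equal(sum(cfg$type == 0L), 201)
  nuc <- which(cfg$type == 1L)[1:33]  # nuclear ring is built right after the membrane
  expect_equal(length(nuc), 33)
  # filament census: two type II per type I
  kinds <- vapply(m$filaments, function(f) f$kind, character(1))
  expect_equal(sum(kinds == "II"), 2 * sum(kinds == "I"))
  expect_equal(sum(cfg$type == 3L), length(m$filaments))
  # spring-constant relations
  expect_equal(m$springs$kF11, m$springs$kF00)
  expect_equal(m$springs$kF13, 5 * m$springs$kF11)
  # physical sizes recovered from coordinates via the length unit
  lu <- m$geometry$length_unit
  mem <- cfg$positions[cfg$type == 0L, ]
  expect_equal(2 * mean(sqrt(rowSums(mem^2))) * lu, 5.25, tolerance = 1e-9)
  f1 <- m$filaments[[which(kinds == "I")[1]]]$beads
  expect_equal(sum(sqrt(rowSums((cfg$positions[f1[-1], ] -
    cfg$positions[f1[-length(f1)], ])^2))) * lu, 1.5, tolerance = 1e-9)
  f2 <- m$filaments[[which(kinds == "II")[1]]]$beads
  expect_equal(sum(sqrt(rowSums((cfg$positions[f2[-1], ] -
    cfg$positions[f2[-length(f2)], ])^2))) * lu, 1.2, tolerance = 1e-9)
})

test_that("membrane rings are closed and counts are deterministic", {
  for (g in list(geometry_config(), desk_geometry())) {
    m <- build_cell(g)
    mem_bonds <- m$table$bonds[m$table$bonds$class == "kF00", ]
    expect_equal(nrow(mem_bonds), g$n_membrane_beads)  # closed ring
    # golden counts: bonds and angles are exact functions of the geometry
    nI <- g$n_typeI_filaments; nII <- 2 * nI
    expected_bonds <- g$n_membrane_beads + g$n_nuclear_beads +
      nI * (g$typeI_beads - 1) + nII * (g$typeII_beads - 1) +
      nI +   # nuclear anchors
      nI     # head-to-membrane bonds
    expect_equal(nrow(m$table$bonds), expected_bonds)
    expected_angles <- g$n_membrane_beads + g$n_nuclear_beads +
      nI * (g$typeI_beads - 2) + nII * (g$typeII_beads - 2)
    expect_equal(nrow(m$table$angles), expected_angles)
    # identical rebuild
    m2 <- build_cell(g)
    expect_identical(m$config$positions, m2$config$positions)
  }
})

test_that("labels partition and every head terminates exactly one filament", {
  m <- build_cell()
  expect_true(all(m$config$type %in% c(0L, 1L, 3L)))
  heads <- vapply(m$filaments, function(f) f$head, integer(1))
  expect_equal(sort(heads), which(m$config$type == 3L))
  expect_equal(anyDuplicated(heads), 0L)
  # kF13 bonds attach type-3 heads to type-0 membrane beads
  hb <- m$table$bonds[m$table$bonds$class == "kF13", ]
  expect_true(all(m$config$type[hb$i] == 3L))
  expect_true(all(m$config$type[hb$j] == 0L))
})

test_that("as-built state is a bonded-energy minimum with constructed angles", {
  m <- build_cell(springs = spring_constants(theta0 = "constructed"))
  bonded_only <- m$table
  bonded_only$pair_rules <- NULL
  expect_lt(total_energy(m$config, bonded_only), 1e-9)
})

test_that("infeasible geometry is rejected with a diagnostic", {
  expect_error(geometry_config(typeI_length_um = 3), "fit inside")
  expect_error(geometry_config(nucleus_diameter_um = 6), "smaller than")
})

test_that("hexagonal colonies classify edge and center cells", {
  g <- desk_geometry()
  col7 <- build_colony(7, g)
  expect_equal(sum(col7$cells$role == "center"), 1)
  expect_equal(sum(col7$cells$role == "edge"), 6)
  expect_equal(sum(col7$config$type == 0L), 7 * g$n_membrane_beads)
  col2 <- build_colony(2, g)
  expect_equal(col2$cells$role, c("edge", "edge"))
  # full default colony: 7 x 201 membrane beads
  col_full <- build_colony(7, geometry_config())
  expect_equal(sum(col_full$config$type == 0L), 7 * 201)
  expect_error(build_colony(7, g, gap = -1), "overlap")
  expect_error(build_colony(7, g, gap = 10), "cutoff")
})

test_that("model serialization round-trips losslessly", {
  m <- build_cell(desk_geometry(), eps00 = 1.5, eps03 = 3)
  base <- file.path(tempdir(), "model_rt")
  write_model(m, base)
  m2 <- read_model(base)
  expect_equal(m2$config$positions, m$config$positions, ignore_attr = TRUE)
  expect_equal(m2$config$type, m$config$type)
  expect_equal(m2$config$cell_id, m$config$cell_id)
  expect_equal(as.data.frame(m2$table$bonds), as.data.frame(m$table$bonds),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(m2$table$pair_rules),
               as.data.frame(m$table$pair_rules), ignore_attr = TRUE)
  expect_equal(m2$table$eps03, 3)
  # forces computed from the re-read model are identical
  f1 <- total_forces(m$config, m$table)
  f2 <- total_forces(m2$config, m2$table)
  expect_equal(f2$forces, f1$forces)
})
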