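# Construction of the coarse-grained cell: a closed plasma-membrane ring, a
# nuclear ring, and radial actin filaments of two kinds (type I anchored to
# the nuclear membrane, type II free), with FENE bond, bend-angle and
# type-pair interaction tables.
#
# Bead type labels: 0 = plasma membrane, 1 = filament body / nuclear
# membrane, 3 = filament head (outer end, next to the plasma membrane),
# 7 = AFM tip.

#' Geometry of the coarse-grained cell
#'
#' Defaults reproduce the reference cell: a plasma membrane of 201 beads
#' with diameter 5.25 um, a nuclear membrane of 33 beads with diameter
#' 1.5 um, and radial actin filaments -- type I (10 beads, 1.5 um, inner
#' end anchored to the nuclear membrane) interspersed with twice as many
#' type II (8 beads, 1.2 um, free at both ends) in a repeating I,II,II
#' pattern.
#'
#' All dynamics run in reduced (dimensionless) units.  The length scale is
#' fixed so that the as-built spacing of neighbouring membrane beads is one
#' reduced unit (`length_unit` micrometres per reduced unit, stored as
#' metadata); physical micrometre values are recovered by multiplying by
#' `length_unit`.
#'
#' @param n_membrane_beads number of plasma-membrane beads (default 201).
#' @param cell_diameter_um plasma-membrane diameter in micrometres (5.25).
#' @param n_nuclear_beads number of nuclear-membrane beads (default 33).
#' @param nucleus_diameter_um nuclear diameter in micrometres (1.5).
#' @param typeI_beads beads per type I filament (default 10).
#' @param typeI_length_um type I filament length in micrometres (1.5).
#' @param typeII_beads beads per type II filament (default 8).
#' @param typeII_length_um type II filament length in micrometres (1.2).
#' @param n_typeI_filaments number of type I filaments; with the default
#'   I,II,II interspersal the total filament count is three times this.
#'   Default 11, so the 33 filaments tile the 33 nuclear beads.
#' @param interspersal_pattern repeating filament-kind sequence; only the
#'   default `c("I","II","II")` ratio (two type II per type I) is built.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(n_membrane_beads = 201L,
                            cell_diameter_um = 5.25,
                            n_nuclear_beads = 33L,
                            nucleus_diameter_um = 1.5,
                            typeI_beads = 10L,
                            typeI_length_um = 1.5,
                            typeII_beads = 8L,
                            typeII_length_um = 1.2,
                            n_typeI_filaments = 11L,
                            interspersal_pattern = c("I", "II", "II")) {
  cfg <- list(n_membrane_beads = as.integer(n_membrane_beads),
              cell_diameter_um = cell_diameter_um,
              n_nuclear_beads = as.integer(n_nuclear_beads),
              nucleus_diameter_um = nucleus_diameter_um,
              typeI_beads = as.integer(typeI_beads),
              typeI_length_um = typeI_length_um,
              typeII_beads = as.integer(typeII_beads),
              typeII_length_um = typeII_length_um,
              n_typeI_filaments = as.integer(n_typeI_filaments),
              interspersal_pattern = interspersal_pattern)
  cfg$length_unit <- pi * cell_diameter_um / cfg$n_membrane_beads
  with(cfg, {
    stopifnot(n_membrane_beads >= 3, n_nuclear_beads >= 3,
              typeI_beads >= 3, typeII_beads >= 3,
              cell_diameter_um > 0, nucleus_diameter_um > 0,
              n_typeI_filaments >= 1)
    if (nucleus_diameter_um >= cell_diameter_um)
      stop("nucleus_diameter must be smaller than cell_diameter")
    if (typeI_length_um + nucleus_diameter_um / 2 >= cell_diameter_um / 2)
      stop("type I filament length + nucleus radius must fit inside the cell radius")
  })
  structure(cfg, class = "geometry_config")
}

#' Spring constants of the bond and bend terms
#'
#' Bond stiffness classes: `kF00` for membrane--membrane bonds, `kF11` for
#' filament-internal and nuclear-membrane bonds, and `kF13` for the bond
#' between a type I filament head and its nearest plasma-membrane bead.
#' Under default construction the reference relations `kF11 = kF00` and
#' `kF13 = 5 * kF11` hold.
#'
#' @param kF00 membrane bond FENE stiffness (reduced units; default 30).
#' @param kF11 filament / nuclear bond stiffness (default `kF00`).
#' @param kF13 filament-head-to-membrane bond stiffness (default `5 * kF11`).
#' @param kB bend stiffness (default 10).
#' @param theta0 equilibrium bend angle: `pi` (straight / locally flat,
#'   the default) or `"constructed"` to use the as-built angles (making the
#'   initial state an exact bonded-energy minimum).
#' @param drmax_frac maximal FENE extension/compression as a fraction of
#'   each bond's equilibrium length (default 0.5).
#' @return An object of class `spring_constants`.
#' @export
spring_constants <- function(kF00 = 30, kF11 = kF00, kF13 = 5 * kF11,
                             kB = 10, theta0 = pi, drmax_frac = 0.5) {
  stopifnot(kF00 >= 0, kF11 >= 0, kF13 >= 0, kB >= 0, drmax_frac > 0)
  structure(list(kF00 = kF00, kF11 = kF11, kF13 = kF13, kB = kB,
                 theta0 = theta0, drmax_frac = drmax_frac),
            class = "spring_constants")
}

ring_points <- function(n, radius, center, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

ring_theta0 <- function(n) pi - 2 * pi / n

new_bead_config <- function(positions, type, cell_id) {
  structure(list(positions = positions,
                 velocities = matrix(0, nrow(positions), 2),
                 type = as.integer(type),
                 cell_id = as.integer(cell_id)),
            class = "bead_config")
}

#' @export
print.bead_config <- function(x, ...) {
  cat("<bead_config> ", nrow(x$positions), " beads, ",
      length(unique(x$cell_id)), " cell(s); types: ",
      paste(sprintf("%d:%d", as.integer(names(table(x$type))),
                    as.integer(table(x$type))), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Build a single coarse-grained cell
#'
#' Places the plasma-membrane ring (type 0), nuclear ring (type 1) and
#' radial filaments per the interspersal pattern; assigns FENE bonds
#' (classes `kF00`/`kF11`/`kF13`), bend triples along each ring and
#' filament, and the non-bonded type-pair rules.  Each bond's equilibrium
#' length `r0` is its as-constructed length, so the built state is
#' mechanically relaxed; `drmax = drmax_frac * r0`.
#'
#' Pair rules: membrane--membrane (0,0) is an attractive Lennard-Jones well
#' of depth `eps00` (cell--cell adhesion); membrane--filament-head (0,3) is
#' a Lennard-Jones well of depth `eps03` (cortical contractility, the
#' actomyosin grip of filament heads on the membrane); all other type pairs
#' are purely repulsive WCA (excluded volume).  `sigma03` defaults to the
#' as-built standoff distance between filament heads and the membrane, so
#' at rest the free (type II) heads sit at the bottom of the well and the
#' well curvature -- proportional to `eps03` -- acts as a cortical coupling
#' stiffness.
#'
#' @param config a [geometry_config()].
#' @param springs a [spring_constants()].
#' @param center cell-centre coordinates (reduced units).
#' @param eps00 membrane--membrane attraction energy (default 1).
#' @param eps03 filament-head--membrane attraction energy (default 2).
#' @param head_standoff distance between free (type II) filament heads and
#'   the membrane at construction (default 1.2, i.e. contact scale: the
#'   cortical grip acts where cortex and membrane touch).
#' @param sigma03 equilibrium distance of the (0,3) rule; defaults to
#'   `head_standoff`, so free heads rest at the bottom of the well.
#' @param lj_cutoff_factor LJ cutoff as a multiple of sigma (default 2.5).
#' @return An object of class `cell_model`: a list with elements `config`
#'   (a `bead_config`), `table` (an `interaction_table` with `bonds`,
#'   `angles`, `pair_rules`, `eps00`, `eps03`), `geometry`, `springs`, and
#'   per-filament bookkeeping (`filaments`).
#' @export
build_cell <- function(config = geometry_config(),
                       springs = spring_constants(),
                       center = c(0, 0),
                       eps00 = 1, eps03 = 2, head_standoff = 1.2,
                       sigma03 = NULL, lj_cutoff_factor = 2.5) {
  stopifnot(inherits(config, "geometry_config"), eps00 >= 0, eps03 >= 0)
  lu <- config$length_unit
  R_cell <- config$cell_diameter_um / lu / 2
  R_nuc <- config$nucleus_diameter_um / lu / 2
  n_mem <- config$n_membrane_beads
  n_nuc <- config$n_nuclear_beads

  pos <- ring_points(n_mem, R_cell, center)
  type <- rep(0L, n_mem)
  pos <- rbind(pos, ring_points(n_nuc, R_nuc, center))
  type <- c(type, rep(1L, n_nuc))

  nI <- config$typeI_beads
  nII <- config$typeII_beads
  LI <- config$typeI_length_um / lu
  LII <- config$typeII_length_um / lu
  sI <- LI / (nI - 1)
  sII <- LII / (nII - 1)
  headI_radius <- R_nuc + sI + (nI - 1) * sI
  head_gap <- R_cell - headI_radius
  if (head_gap <= 0)
    stop("geometric infeasibility: type I filament would cross the membrane")

  pat <- config$interspersal_pattern
  n_fil <- length(pat) * config$n_typeI_filaments
  fil_kind <- rep(pat, config$n_typeI_filaments)
  fil_angle <- 2 * pi * (seq_len(n_fil) - 1) / n_fil

  bonds <- list(); angles <- list(); filaments <- list()
  add_ring <- function(start, n, kF, bclass, theta0_ring) {
    idx <- start + seq_len(n) - 1L
    nb <- cbind(idx, c(idx[-1], idx[1]))
    d <- sqrt(rowSums((pos[nb[, 1], , drop = FALSE] - pos[nb[, 2], , drop = FALSE])^2))
    bonds[[length(bonds) + 1]] <<- data.frame(
      i = nb[, 1], j = nb[, 2], class = bclass, kF = kF, r0 = d,
      drmax = springs$drmax_frac * d)
    prv <- c(idx[n], idx[-n]); nxt <- c(idx[-1], idx[1])
    angles[[length(angles) + 1]] <<- data.frame(
      i = prv, j = idx, k = nxt, kB = springs$kB, theta0 = theta0_ring)
  }
  th_ring <- function(n) {
    if (identical(springs$theta0, "constructed")) ring_theta0(n) else springs$theta0
  }
  add_ring(1L, n_mem, springs$kF00, "kF00", th_ring(n_mem))
  add_ring(n_mem + 1L, n_nuc, springs$kF11, "kF11", th_ring(n_nuc))
  th_fil <- if (identical(springs$theta0, "constructed")) pi else springs$theta0

  mem_idx <- seq_len(n_mem)
  nuc_idx <- n_mem + seq_len(n_nuc)
  nearest <- function(p, cand) cand[which.min(colSums((t(pos[cand, , drop = FALSE]) - p)^2))]

  for (f in seq_len(n_fil)) {
    ang <- fil_angle[f]
    u <- c(cos(ang), sin(ang))
    if (fil_kind[f] == "I") {
      radii <- R_nuc + sI * seq_len(nI)
      nb <- nI; sp <- sI
    } else {
      outer_r <- R_cell - head_standoff
      radii <- outer_r - sII * ((nII - 1):0)
      nb <- nII; sp <- sII
      if (min(radii) <= R_nuc)
        stop("geometric infeasibility: type II filament would cross the nucleus")
    }
    start <- nrow(pos) + 1L
    fp <- cbind(center[1] + radii * u[1], center[2] + radii * u[2])
    pos <- rbind(pos, fp)
    type <- c(type, c(rep(1L, nb - 1L), 3L))
    idx <- start + seq_len(nb) - 1L
    d <- rep(sp, nb - 1L)
    bonds[[length(bonds) + 1]] <- data.frame(
      i = idx[-nb], j = idx[-1], class = "kF11", kF = springs$kF11, r0 = d,
      drmax = springs$drmax_frac * d)
    if (nb >= 3)
      angles[[length(angles) + 1]] <- data.frame(
        i = idx[1:(nb - 2)], j = idx[2:(nb - 1)], k = idx[3:nb],
        kB = springs$kB, theta0 = th_fil)
    if (fil_kind[f] == "I") {
      anc <- nearest(fp[1, ], nuc_idx)
      d_anc <- sqrt(sum((pos[anc, ] - fp[1, ])^2))
      bonds[[length(bonds) + 1]] <- data.frame(
        i = idx[1], j = anc, class = "kF11", kF = springs$kF11, r0 = d_anc,
        drmax = springs$drmax_frac * d_anc)
      hm <- nearest(fp[nb, ], mem_idx)
      d_hm <- sqrt(sum((pos[hm, ] - fp[nb, ])^2))
      bonds[[length(bonds) + 1]] <- data.frame(
        i = idx[nb], j = hm, class = "kF13", kF = springs$kF13, r0 = d_hm,
        drmax = springs$drmax_frac * d_hm)
    }
    filaments[[f]] <- list(kind = fil_kind[f], beads = idx, head = idx[nb])
  }

  if (is.null(sigma03)) sigma03 <- head_standoff
  # eps03 is the cortical grip of a cell's own filament heads on its
  # membrane.  Across cells the cortex can only pull on a neighbour's
  # membrane through an adhesive junction, so the cross-cell head grip is
  # junction-mediated: well depth eps00 * eps03 (in units of the baseline
  # adhesion), vanishing without adhesion.  eps00 itself acts within and
  # between cells.
  eps03_cross <- eps00 * eps03
  pair_rules <- data.frame(
    type_i = c(0L, 0L, 0L, 0L, 1L, 1L, 3L),
    type_j = c(0L, 3L, 3L, 1L, 1L, 3L, 3L),
    potential = c("LJ", "LJ",
                  if (eps03_cross > 0) "LJ" else "WCA",
                  "WCA", "WCA", "WCA", "WCA"),
    epsilon = c(eps00, eps03, if (eps03_cross > 0) eps03_cross else 1,
                1, 1, 1, 1),
    sigma = c(1, sigma03, if (eps03_cross > 0) sigma03 else 1,
              1, 1, 1, 1),
    cutoff = c(lj_cutoff_factor * 1, lj_cutoff_factor * sigma03,
               if (eps03_cross > 0) lj_cutoff_factor * sigma03 else 1,
               1, 1, 1, 1),
    scope = c("any", "same_cell", "cross_cell", "any", "any", "any", "any"),
    stringsAsFactors = FALSE)

  table <- structure(list(
    bonds = do.call(rbind, bonds),
    angles = do.call(rbind, angles),
    pair_rules = pair_rules,
    eps00 = eps00, eps03 = eps03),
    class = "interaction_table")
  structure(list(config = new_bead_config(pos, type, rep(1L, nrow(pos))),
                 table = table,
                 geometry = config, springs = springs,
                 filaments = filaments,
                 center = center,
                 R_cell = R_cell, head_gap = head_gap),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model> ", nrow(x$config$positions), " beads (",
      sum(x$config$type == 0), " membrane, ", sum(x$config$type == 1),
      " filament/nuclear, ", sum(x$config$type == 3), " filament heads), ",
      nrow(x$table$bonds), " bonds, ", nrow(x$table$angles), " bend triples\n",
      sep = "")
  cat("  eps00 = ", x$table$eps00, ", eps03 = ", x$table$eps03,
      ", length unit = ", signif(x$geometry$length_unit, 4), " um\n", sep = "")
  invisible(x)
}

hex_centers <- function(n, d) {
  # hexagonal packing: center first, then rings of 6, 12, ...
  pts <- matrix(c(0, 0), 1, 2)
  ax <- cbind(cos(pi / 3 * (0:5)), sin(pi / 3 * (0:5)))
  ring <- 1
  while (nrow(pts) < n) {
    for (corner in 1:6) {
      a <- ring * ax[corner, ]
      b <- ring * ax[corner %% 6 + 1, ]
      for (k in 0:(ring - 1))
        pts <- rbind(pts, a + (b - a) * k / ring)
    }
    ring <- ring + 1
  }
  pts[seq_len(n), , drop = FALSE] * d
}

#' Build a hexagonally packed colony of cells
#'
#' Replicates the single-cell geometry on a hexagonal lattice.  Membrane
#' beads of different cells interact only through the (0,0) pair rule with
#' well depth `eps00`, the model's cell--cell adhesion.  Cells are
#' classified `"center"` (6 neighbours on the lattice) or `"edge"`.
#'
#' @param n_cells number of cells (`>= 2`).
#' @param config,springs,eps00,eps03 as in [build_cell()].
#' @param gap inter-cell membrane clearance (reduced units); must be
#'   positive (no overlapping membranes) and smaller than the (0,0) rule's
#'   cutoff so that adhesion engages.  Default 1.
#' @param ... further arguments passed to [build_cell()].
#' @return A `cell_model` with multi-cell `config` (per-bead `cell_id`)
#'   and a `cells` data frame (`cell_id`, `cx`, `cy`, `role`).
#' @export
build_colony <- function(n_cells, config = geometry_config(),
                         springs = spring_constants(),
                         eps00 = 1, eps03 = 2, gap = 1, ...) {
  stopifnot(n_cells >= 2)
  if (gap <= 0) stop("overlapping initial membranes: gap must be > 0")
  proto <- build_cell(config, springs, center = c(0, 0),
                      eps00 = eps00, eps03 = eps03, ...)
  cutoff00 <- proto$table$pair_rules$cutoff[
    proto$table$pair_rules$type_i == 0 & proto$table$pair_rules$type_j == 0]
  if (gap >= cutoff00)
    stop("gap must be smaller than the (0,0) pair-rule cutoff for adhesion to engage")
  d <- 2 * proto$R_cell + gap
  centers <- hex_centers(n_cells, d)
  nb_per_cell <- nrow(proto$config$positions)

  pos <- NULL; type <- integer(0); cell_id <- integer(0)
  bonds <- NULL; angles <- NULL
  for (c_i in seq_len(n_cells)) {
    off <- (c_i - 1L) * nb_per_cell
    pos <- rbind(pos, sweep(proto$config$positions, 2, -centers[c_i, ]))
    type <- c(type, proto$config$type)
    cell_id <- c(cell_id, rep(c_i, nb_per_cell))
    b <- proto$table$bonds; b$i <- b$i + off; b$j <- b$j + off
    a <- proto$table$angles
    a$i <- a$i + off; a$j <- a$j + off; a$k <- a$k + off
    bonds <- rbind(bonds, b); angles <- rbind(angles, a)
  }
  # lattice-neighbour count -> edge/center role
  dd <- as.matrix(stats::dist(centers))
  nnb <- rowSums(dd > 0 & dd < 1.01 * d)
  role <- ifelse(nnb >= 6, "center", "edge")

  table <- structure(list(bonds = bonds, angles = angles,
                          pair_rules = proto$table$pair_rules,
                          eps00 = eps00, eps03 = eps03),
                     class = "interaction_table")
  structure(list(config = new_bead_config(pos, type, cell_id),
                 table = table,
                 geometry = config, springs = springs,
                 cells = data.frame(cell_id = seq_len(n_cells),
                                    cx = centers[, 1], cy = centers[, 2],
                                    role = role, stringsAsFactors = FALSE),
                 R_cell = proto$R_cell, head_gap = proto$head_gap),
            class = "cell_model")
}

#' Serialize a cell model to a JSON config and CSV bead table
#'
#' Writes `<basename>.json` (geometry, springs, bonds, angles, pair rules)
#' and `<basename>.csv` (columns `id`, `cell_id`, `type`, `x`, `y`, `vx`,
#' `vy`).  The round trip through [read_model()] is lossless.
#'
#' @param model a `cell_model`.
#' @param basename path prefix for the two files.
#' @return The two file paths, invisibly.
#' @export
write_model <- function(model, basename) {
  cfg <- model$config
  beads <- data.frame(id = seq_len(nrow(cfg$positions)),
                      cell_id = cfg$cell_id, type = cfg$type,
                      x = cfg$positions[, 1], y = cfg$positions[, 2],
                      vx = cfg$velocities[, 1], vy = cfg$velocities[, 2])
  csv <- paste0(basename, ".csv")
  jsn <- paste0(basename, ".json")
  utils::write.csv(beads, csv, row.names = FALSE)
  meta <- list(geometry = unclass(model$geometry),
               springs = unclass(model$springs),
               bonds = model$table$bonds,
               angles = model$table$angles,
               pair_rules = model$table$pair_rules,
               eps00 = model$table$eps00, eps03 = model$table$eps03,
               cells = model$cells, R_cell = model$R_cell,
               head_gap = model$head_gap)
  jsonlite::write_json(meta, jsn, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(jsn, csv))
}

#' Read a cell model written by [write_model()]
#'
#' @param basename path prefix used in [write_model()].
#' @return A `cell_model`.
#' @export
read_model <- function(basename) {
  beads <- utils::read.csv(paste0(basename, ".csv"))
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  cfg <- new_bead_config(cbind(beads$x, beads$y), beads$type, beads$cell_id)
  cfg$velocities <- cbind(beads$vx, beads$vy)
  geometry <- structure(meta$geometry, class = "geometry_config")
  springs <- structure(meta$springs, class = "spring_constants")
  table <- structure(list(bonds = as.data.frame(meta$bonds),
                          angles = as.data.frame(meta$angles),
                          pair_rules = as.data.frame(meta$pair_rules),
                          eps00 = meta$eps00, eps03 = meta$eps03),
                     class = "interaction_table")
  out <- list(config = cfg, table = table, geometry = geometry,
              springs = springs, R_cell = meta$R_cell,
              head_gap = meta$head_gap)
  if (!is.null(meta$cells)) out$cells <- as.data.frame(meta$cells)
  structure(out, class = "cell_model")
}
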