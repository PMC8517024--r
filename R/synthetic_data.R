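# Seeded synthetic-data generators.  Every generator returns its output
# together with a `truth` record (the planted ground truth) and a `spec`
# record (kind, parameters, noise model, seed), so analysis stages can be
# round-trip tested without external data.

noise_model <- function(kind = c("none", "gaussian", "multiplicative"),
                        sd = 0.02) {
  kind <- match.arg(kind)
  list(kind = kind, sd = sd)
}

apply_noise <- function(x, noise, scale = stats::sd(x)) {
  switch(noise$kind,
         none = x,
         gaussian = x + stats::rnorm(length(x), 0, noise$sd * scale),
         multiplicative = x * (1 + stats::rnorm(length(x), 0, noise$sd)))
}

fixture_spec <- function(kind, parameters, noise, seed) {
  list(kind = kind, parameters = parameters, noise_model = noise, seed = seed)
}

#' Synthetic Sneddon (conical-indenter) force--indentation curve
#'
#' Forward model of the Hertz--Sneddon fit:
#' \eqn{F = C\,E/(1-\nu^2)\tan(\alpha)\,\delta^2} past the contact point,
#' zero before, with optional noise.
#'
#' @param E elastic modulus (`> 0`, or 0 for an identically zero curve).
#'   With travel in micrometres and E in kPa, forces are in nN.
#' @param half_angle probe half-opening angle in degrees (default 9).
#' @param poisson Poisson ratio (default 0.45).
#' @param contact_point curve offset (travel at first contact).
#' @param model_form `"cone"` (default) or `"pyramid"`.
#' @param travel_max,n sampling grid: `n` points on `[0, travel_max]`.
#' @param noise a noise model: `list(kind, sd)` with kind `"none"`,
#'   `"gaussian"` (additive, sd relative to the force scale) or
#'   `"multiplicative"`.
#' @param seed RNG seed (mandatory).
#' @return List with `curve` (data frame `travel`, `force`), `truth`
#'   (`E`, `contact_point`, ...), `spec`.
#' @export
make_sneddon_curve <- function(E, half_angle = 9, poisson = 0.45,
                               contact_point = 0.5,
                               model_form = "cone",
                               travel_max = 2.5, n = 300L,
                               noise = noise_model("none"), seed = 1L) {
  stopifnot(E >= 0)
  set.seed(seed)
  K <- hertz_prefactor(model_form) * tan(half_angle * pi / 180) /
    (1 - poisson^2)
  travel <- seq(0, travel_max, length.out = n)
  force <- K * E * pmax(travel - contact_point, 0)^2
  force <- apply_noise(force, noise, scale = max(force, .Machine$double.eps))
  list(curve = data.frame(travel = travel, force = force),
       truth = list(E = E, contact_point = contact_point,
                    half_angle = half_angle, poisson = poisson,
                    model_form = model_form),
       spec = fixture_spec("sneddon_curve",
                           list(E = E, half_angle = half_angle,
                                poisson = poisson,
                                contact_point = contact_point),
                           noise, seed))
}

ellipse_perimeter <- function(a, b) {
  e2 <- 1 - (min(a, b) / max(a, b))^2
  4 * max(a, b) * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2),
                                   0, pi / 2, rel.tol = 1e-12)$value
}

#' Rasterized shape mask with analytic shape-index truths
#'
#' Rasterizes a disc, ellipse, rectangle or polygon on a pixel grid
#' (pixel-centre inclusion test) and returns the closed-form area,
#' perimeter, circularity (4 pi area / perimeter^2) and solidity of the
#' continuous shape for oracle comparison.
#'
#' @param kind `"disc"`, `"ellipse"`, `"rectangle"` or `"polygon"`.
#' @param parameters kind-specific: disc `list(radius)`; ellipse
#'   `list(a, b, angle = 0)` (semi-axes, rotation in radians); rectangle
#'   `list(L, W)`; polygon `list(vertices)` (an `n x 2` matrix, pixel
#'   units, centred on the image centre).
#' @param resolution image side length in pixels (default fits the shape
#'   with a margin).
#' @param seed RNG seed (kept for interface symmetry; rasterization is
#'   deterministic).
#' @return List with `mask` (0/1 integer matrix), `truth` (`area`,
#'   `perimeter`, `circularity`, `solidity`), `spec`.
#' @export
make_shape_mask <- function(kind = c("disc", "ellipse", "rectangle", "polygon"),
                            parameters = list(radius = 100),
                            resolution = NULL, seed = 1L) {
  kind <- match.arg(kind)
  p <- parameters
  extent <- switch(kind,
                   disc = p$radius,
                   ellipse = max(p$a, p$b),
                   rectangle = max(p$L, p$W) / 2,
                   polygon = max(abs(p$vertices)))
  if (is.null(resolution)) resolution <- ceiling(2 * extent + 10)
  cx <- (resolution + 1) / 2
  gx <- matrix(seq_len(resolution) - cx, resolution, resolution)
  gy <- matrix(seq_len(resolution) - cx, resolution, resolution, byrow = TRUE)
  inside <- switch(kind,
    disc = gx^2 + gy^2 <= p$radius^2,
    ellipse = {
      ang <- if (is.null(p$angle)) 0 else p$angle
      u <- gx * cos(ang) + gy * sin(ang)
      v <- -gx * sin(ang) + gy * cos(ang)
      (u / p$a)^2 + (v / p$b)^2 <= 1
    },
    rectangle = abs(gx) <= p$L / 2 & abs(gy) <= p$W / 2,
    polygon = {
      # even-odd ray casting, vectorized over pixels
      vx <- p$vertices[, 1]; vy <- p$vertices[, 2]
      nv <- length(vx)
      acc <- matrix(FALSE, resolution, resolution)
      j <- nv
      for (i in seq_len(nv)) {
        cross <- ((vy[i] > gy) != (vy[j] > gy)) &
          (gx < (vx[j] - vx[i]) * (gy - vy[i]) / (vy[j] - vy[i]) + vx[i])
        acc <- xor(acc, cross)
        j <- i
      }
      acc
    })
  truth <- switch(kind,
    disc = {
      A <- pi * p$radius^2; P <- 2 * pi * p$radius
      list(area = A, perimeter = P, circularity = 1, solidity = 1)
    },
    ellipse = {
      A <- pi * p$a * p$b; P <- ellipse_perimeter(p$a, p$b)
      list(area = A, perimeter = P, circularity = 4 * pi * A / P^2,
           solidity = 1)
    },
    rectangle = {
      A <- p$L * p$W; P <- 2 * (p$L + p$W)
      list(area = A, perimeter = P, circularity = 4 * pi * A / P^2,
           solidity = 1)
    },
    polygon = {
      A <- polygon_area(p$vertices)
      P <- sum(sqrt(rowSums((p$vertices -
        p$vertices[c(2:nrow(p$vertices), 1), , drop = FALSE])^2)))
      h <- grDevices::chull(p$vertices)
      list(area = A, perimeter = P, circularity = 4 * pi * A / P^2,
           solidity = A / polygon_area(p$vertices[h, , drop = FALSE]))
    })
  list(mask = inside + 0L, truth = truth,
       spec = fixture_spec("shape_mask", c(list(kind = kind), p),
                           noise_model("none"), seed))
}

#' Synthetic TIRF focal-adhesion scene
#'
#' Plants bright paxillin ellipses inside an actin-positive cell footprint
#' over labelled nuclei, with known counts for round-trip testing of
#' [segment_focal_adhesions()].
#'
#' @param n_nuclei number of nuclei (default 3).
#' @param fas_per_cell planted FAs per nucleus (default 4).
#' @param dim image dimensions (pixels).
#' @param fa_axes semi-axes of each planted FA ellipse.
#' @param background background intensity of the paxillin channel.
#' @param noise a noise model applied to both intensity channels.
#' @param seed RNG seed.
#' @return List with `paxillin`, `actin` (intensity matrices), `nuclei`
#'   (label matrix), `truth` (`n_fas`, `fas_per_cell`, per-FA centres and
#'   areas), `spec`.
#' @export
make_fa_scene <- function(n_nuclei = 3L, fas_per_cell = 4L,
                          dim = c(160L, 160L), fa_axes = c(5, 2.5),
                          background = 0.05,
                          noise = noise_model("none"), seed = 1L) {
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  gx <- matrix(seq_len(nr), nr, nc)
  gy <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # cell footprint: horizontal band with rounded margins
  margin <- 12
  foot <- gx > margin & gx < nr - margin & gy > margin & gy < nc - margin
  actin <- ifelse(foot, 0.6, 0.02)
  nuclei <- matrix(0L, nr, nc)
  nuc_r <- 9
  nuc_cx <- seq(margin + 2 * nuc_r, nr - margin - 2 * nuc_r,
                length.out = n_nuclei)
  for (k in seq_len(n_nuclei))
    nuclei[(gx - nuc_cx[k])^2 + (gy - nc / 2)^2 <= nuc_r^2] <- k

  n_fas <- n_nuclei * fas_per_cell
  # FA centres on a jittered grid inside the footprint, away from edges
  grid_n <- ceiling(sqrt(n_fas))
  cxs <- seq(margin + 12, nr - margin - 12, length.out = grid_n)
  cys <- seq(margin + 12, nc - margin - 12, length.out = grid_n)
  centres <- expand.grid(x = cxs, y = cys)[seq_len(n_fas), ]
  centres$x <- centres$x + stats::runif(n_fas, -2, 2)
  centres$y <- centres$y + stats::runif(n_fas, -2, 2)
  pax <- matrix(background, nr, nc)
  areas <- numeric(n_fas)
  for (k in seq_len(n_fas)) {
    sel <- ((gx - centres$x[k]) / fa_axes[1])^2 +
           ((gy - centres$y[k]) / fa_axes[2])^2 <= 1
    pax[sel] <- 1
    areas[k] <- sum(sel)
  }
  pax <- matrix(apply_noise(pax, noise, scale = 1), nr, nc)
  actin <- matrix(apply_noise(actin, noise, scale = 1), nr, nc)
  list(paxillin = pax, actin = actin, nuclei = nuclei,
       truth = list(n_fas = n_fas, n_nuclei = n_nuclei,
                    fas_per_cell = n_fas / n_nuclei,
                    centres = centres, areas = areas),
       spec = fixture_spec("fa_scene",
                           list(n_nuclei = n_nuclei,
                                fas_per_cell = fas_per_cell, dim = dim),
                           noise, seed))
}

#' Synthetic 3-channel FRET stack with known index and bleed-through
#'
#' Builds donor, FRET and acceptor channels from a true index map:
#' `fret = true_index * donor + alpha * donor + beta * acceptor`.
#'
#' @param true_index_map matrix of ground-truth FRET indices.
#' @param alpha,beta bleed-through coefficients used in the forward model.
#' @param donor_map donor-channel intensities (same shape; default
#'   uniform 100).
#' @param acceptor_map acceptor-channel intensities (default
#'   `0.5 * donor_map`).
#' @param noise a noise model applied to all three channels.
#' @param seed RNG seed.
#' @return List with `donor`, `fret`, `acceptor`, `truth` (`index_map`,
#'   `alpha`, `beta`), `spec`.
#' @export
make_fret_stack <- function(true_index_map, alpha = 0.3, beta = 0.1,
                            donor_map = NULL, acceptor_map = NULL,
                            noise = noise_model("none"), seed = 1L) {
  set.seed(seed)
  if (is.null(donor_map))
    donor_map <- matrix(100, nrow(true_index_map), ncol(true_index_map))
  if (is.null(acceptor_map)) acceptor_map <- 0.5 * donor_map
  stopifnot(all(dim(true_index_map) == dim(donor_map)),
            all(dim(true_index_map) == dim(acceptor_map)))
  fret <- true_index_map * donor_map + alpha * donor_map + beta * acceptor_map
  dm <- dim(donor_map)
  out <- lapply(list(donor = donor_map, fret = fret, acceptor = acceptor_map),
                function(ch) matrix(apply_noise(ch, noise,
                                                scale = mean(abs(ch))), dm[1], dm[2]))
  c(out, list(truth = list(index_map = true_index_map, alpha = alpha,
                           beta = beta),
              spec = fixture_spec("fret_stack",
                                  list(alpha = alpha, beta = beta),
                                  noise, seed)))
}

#' Synthetic 2D point pattern with known spatial summaries
#'
#' @param kind `"lattice"` (unit-spacing square grid), `"poisson"`
#'   (homogeneous Poisson process) or `"clustered"` (parent-offspring
#'   Thomas-like process).
#' @param n for `"lattice"`, points per side; for `"clustered"`, number of
#'   parents.
#' @param intensity Poisson intensity (points per unit area).
#' @param window side length of the square observation window.
#' @param cluster_sd,offspring for `"clustered"`: offspring dispersion and
#'   mean offspring per parent.
#' @param seed RNG seed.
#' @return List with `points` (`n x 2` matrix), `truth` (kind-specific:
#'   lattice neighbour distances, Poisson expected nearest-neighbour
#'   distance `1 / (2 sqrt(intensity))`), `spec`.
#' @export
make_point_pattern <- function(kind = c("lattice", "poisson", "clustered"),
                               n = 10L, intensity = 1, window = 10,
                               cluster_sd = 0.3, offspring = 5, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  pts <- switch(kind,
    lattice = as.matrix(expand.grid(x = seq_len(n), y = seq_len(n))),
    poisson = {
      m <- stats::rpois(1, intensity * window^2)
      cbind(stats::runif(m, 0, window), stats::runif(m, 0, window))
    },
    clustered = {
      par <- cbind(stats::runif(n, 0, window), stats::runif(n, 0, window))
      do.call(rbind, lapply(seq_len(n), function(i) {
        m <- stats::rpois(1, offspring)
        if (m == 0) return(NULL)
        cbind(stats::rnorm(m, par[i, 1], cluster_sd),
              stats::rnorm(m, par[i, 2], cluster_sd))
      }))
    })
  if (anyDuplicated(pts)) stop("degenerate pattern: duplicate points")
  truth <- switch(kind,
    lattice = list(interior_nn_distances = c(1, 1, 1, 1, sqrt(2)),
                   spacing = 1),
    poisson = list(expected_nn_distance = 1 / (2 * sqrt(intensity)),
                   intensity = intensity),
    clustered = list(n_parents = n, cluster_sd = cluster_sd))
  list(points = pts, truth = truth,
       spec = fixture_spec("point_pattern",
                           list(kind = kind, n = n, intensity = intensity,
                                window = window),
                           noise_model("none"), seed))
}

#' Synthetic AFM height profile with planted peak prominences
#'
#' Triangular peaks of the requested prominences on a flat (or noisy)
#' baseline, regularly spaced.
#'
#' @param peak_prominences vector of planted prominences (height units,
#'   e.g. nm).
#' @param spacing samples between peak centres (default 40).
#' @param width half-width of each triangular peak in samples.
#' @param baseline baseline height.
#' @param noise a noise model (additive noise uses `sd` in height units
#'   directly).
#' @param threshold prominence threshold used for the stored truth count
#'   (default 15; strict `>`).
#' @param seed RNG seed.
#' @return List with `profile` (numeric vector), `truth`
#'   (`n_above_threshold`, `prominences`), `spec`.
#' @export
make_height_profile <- function(peak_prominences = c(20), spacing = 40L,
                                width = 8L, baseline = 0,
                                noise = noise_model("none"),
                                threshold = 15, seed = 1L) {
  set.seed(seed)
  npk <- length(peak_prominences)
  len <- spacing * (npk + 1L)
  x <- rep(baseline, len)
  for (k in seq_len(npk)) {
    c0 <- k * spacing
    for (d in -width:width) {
      i <- c0 + d
      if (i >= 1 && i <= len)
        x[i] <- x[i] + peak_prominences[k] * (1 - abs(d) / (width + 1))
    }
  }
  if (noise$kind == "gaussian") x <- x + stats::rnorm(len, 0, noise$sd)
  else x <- apply_noise(x, noise, scale = max(abs(x), 1))
  list(profile = x,
       truth = list(n_above_threshold = sum(peak_prominences > threshold),
                    prominences = peak_prominences),
       spec = fixture_spec("height_profile",
                           list(prominences = peak_prominences,
                                spacing = spacing, width = width),
                           noise, seed))
}

#' Write a synthetic fixture to disk with a JSON truth sidecar
#'
#' Curves, point sets and profiles are written as CSV; images and masks as
#' TIFF (intensities scaled to `[0, 1]`; the scale factor is recorded in
#' the sidecar).  The sidecar `<basename>.json` stores the fixture's
#' `spec` and `truth`.
#'
#' @param fixture a generator result (any `make_*` output).
#' @param basename path prefix.
#' @return Vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, basename) {
  paths <- character(0)
  add_csv <- function(df, suffix) {
    p <- paste0(basename, suffix, ".csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  scales <- list()
  add_tiff <- function(img, suffix) {
    p <- paste0(basename, suffix, ".tif")
    sc <- max(img, 1e-12)
    EBImage::writeImage(img / sc, p, type = "tiff")
    scales[[suffix]] <<- sc
    paths <<- c(paths, p)
  }
  kind <- fixture$spec$kind
  switch(kind,
    sneddon_curve = add_csv(fixture$curve, ""),
    point_pattern = add_csv(data.frame(x = fixture$points[, 1],
                                       y = fixture$points[, 2]), ""),
    height_profile = add_csv(data.frame(height = fixture$profile), ""),
    shape_mask = add_tiff(fixture$mask, ""),
    fa_scene = {
      add_tiff(fixture$paxillin, "_paxillin")
      add_tiff(fixture$actin, "_actin")
      add_tiff(fixture$nuclei, "_nuclei")
    },
    fret_stack = {
      add_tiff(fixture$donor, "_donor")
      add_tiff(fixture$fret, "_fret")
      add_tiff(fixture$acceptor, "_acceptor")
    },
    stop("unknown fixture kind: ", kind))
  side <- paste0(basename, ".json")
  jsonlite::write_json(list(spec = fixture$spec, truth = fixture$truth,
                            tiff_scales = scales),
                       side, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(c(paths, side))
}
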