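test_that("a finely digitized disc has circularity 1", {
  disc <- make_shape_mask("disc", list(radius = 120))
  expect_equal(circularity(disc$mask), 1, tolerance = 0.02)
  expect_equal(crofton_perimeter(disc$mask), 2 * pi * 120, tolerance = 0.01 * 2 * pi * 120)
})

test_that("elongated shapes approach circularity 0", {
  for (N in c(50, 200, 1000)) {
    line <- matrix(0L, 3, N + 2)
    line[2, 2:(N + 1)] <- 1L
    expect_lt(circularity(line), 15 / N)
  }
  expect_lt(circularity(matrix(1L, 1, 1000)), 0.02)
})

test_that("ellipse circularity matches the elliptic-integral closed form", {
  for (ab in list(c(200, 10), c(120, 60))) {
    el <- make_shape_mask("ellipse", list(a = ab[1], b = ab[2]))
    expect_equal(circularity(el$mask), el$truth$circularity,
                 tolerance = 0.03)
  }
})

test_that("circularity is invariant under right-angle rotation and translation", {
  el <- make_shape_mask("ellipse", list(a = 80, b = 30))$mask
  expect_identical(circularity(el), circularity(t(el)[ncol(el):1, ]))  # 90 deg
  shifted <- matrix(0L, nrow(el) + 14, ncol(el) + 6)
  shifted[8:(7 + nrow(el)), 4:(3 + ncol(el))] <- el
  expect_identical(circularity(el), circularity(shifted))
  # arbitrary rotation: within 3% at >= 100 px radius
  r30 <- make_shape_mask("ellipse", list(a = 150, b = 100, angle = pi / 7))
  r0 <- make_shape_mask("ellipse", list(a = 150, b = 100))
  expect_equal(circularity(r30$mask), circularity(r0$mask), tolerance = 0.03)
})

test_that("solidity is 1 for convex shapes and bounded by 1 always", {
  disc <- make_shape_mask("disc", list(radius = 80))$mask
  expect_equal(solidity(disc), 1, tolerance = 0.02)
  expect_lte(solidity(disc), 1)
  rect <- make_shape_mask("rectangle", list(L = 120, W = 40))$mask
  expect_equal(solidity(rect), 1, tolerance = 0.02)
  # plus sign: 5 unit squares of a 3x3 cross; hull is the octagon of area 7
  plus <- matrix(0L, 62, 62)
  plus[21:40, 1:60] <- 1L
  plus[1:60, 21:40] <- 1L
  expect_equal(solidity(plus), (5 * 400) / (7 * 400), tolerance = 0.02)
  expect_lte(solidity(plus), 1)
  expect_error(solidity(matrix(0L, 5, 5)), "empty")
  expect_error(circularity(matrix(0L, 5, 5)), "empty")
})

test_that("lattice nearest-neighbour distances enumerate exactly", {
  pat <- make_point_pattern("lattice", n = 8)
  nn <- nn_distance_density(pat$points, k = 5)
  # exhaustive enumeration on the 8x8 grid: interior points pool
  # {1,1,1,1,sqrt(2)}, edges {1,1,1,sqrt(2),sqrt(2)}, corners {1,1,sqrt(2),2,2}
  expect_equal(sum(abs(nn$distances - 1) < 1e-9), 4 * 2 + 24 * 3 + 36 * 4)
  expect_equal(sum(abs(nn$distances - sqrt(2)) < 1e-9), 4 * 1 + 24 * 2 + 36 * 1)
  expect_equal(sum(abs(nn$distances - 2) < 1e-9), 4 * 2)
  expect_equal(length(nn$distances), 5 * 64)
  # histogram integrates to one
  h <- nn$histogram
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
  expect_error(nn_distance_density(pat$points[1:5, ], k = 5), "k \\+ 1")
})

test_that("near-coincident points put all density mass near zero", {
  set.seed(4)
  pts <- matrix(rnorm(40, sd = 1e-4), 20, 2)
  nn <- nn_distance_density(pts, k = 5)
  expect_lt(max(nn$distances), 1e-3)
})

test_that("ruffle counting uses strict prominence thresholds", {
  flat <- make_height_profile(numeric(0), seed = 1)
  expect_equal(count_ruffles(flat$profile), 0)
  one <- make_height_profile(20, seed = 1)
  expect_equal(count_ruffles(one$profile), 1)
  multi <- make_height_profile(c(10, 14.9, 15.1, 40), seed = 1)
  expect_equal(count_ruffles(multi$profile), 2)
  expect_equal(count_ruffles(multi$profile), multi$truth$n_above_threshold)
  # mirrored profile counts the same
  expect_equal(count_ruffles(rev(multi$profile)), 2)
  # exactly 15 is not counted ("greater than")
  at15 <- make_height_profile(c(15, 15.0001), seed = 1)
  expect_equal(count_ruffles(at15$profile), 1)
  # per-cell sum over four profiles
  four <- lapply(1:4, function(i) make_height_profile(c(20, 30), seed = i)$profile)
  expect_equal(count_ruffles(four), 8)
})

test_that("focal-adhesion pipeline recovers planted scenes exactly", {
  sc <- make_fa_scene(n_nuclei = 3, fas_per_cell = 4, seed = 7)
  seg <- segment_focal_adhesions(sc$paxillin, sc$actin, sc$nuclei)
  expect_equal(seg$n_fas, 12)
  expect_equal(seg$n_nuclei, 3)
  expect_equal(seg$fas_per_cell, 4.0)
  expect_equal(nrow(seg$stats), 12)
  expect_true(all(seg$stats$circularity > 0.5))  # planted ellipses are compact
  # all-background paxillin segments nothing
  seg0 <- segment_focal_adhesions(matrix(0.05, 160, 160), sc$actin, sc$nuclei)
  expect_equal(seg0$n_fas, 0)
  # an FA planted outside the actin footprint is removed by the AND step
  pax2 <- sc$paxillin
  gx <- matrix(seq_len(160), 160, 160)
  gy <- matrix(seq_len(160), 160, 160, byrow = TRUE)
  pax2[(gx - 5)^2 + (gy - 5)^2 <= 9] <- 1   # bright blob in the corner
  seg2 <- segment_focal_adhesions(pax2, sc$actin, sc$nuclei)
  expect_equal(seg2$n_fas, 12)
  # adding one inside increments the count by exactly one
  pax3 <- sc$paxillin
  pax3[(gx - 80)^2 + (gy - 25)^2 <= 6] <- 1
  seg3 <- segment_focal_adhesions(pax3, sc$actin, sc$nuclei)
  expect_equal(seg3$n_fas, 13)
  expect_error(segment_focal_adhesions(sc$paxillin, sc$actin,
                                       matrix(0L, 160, 160)), "zero")
  expect_error(segment_focal_adhesions(sc$paxillin[1:50, ], sc$actin,
                                       sc$nuclei), "shape")
})

test_that("ratiometric FRET correction inverts the forward model", {
  mask <- matrix(1L, 20, 20)
  donor <- matrix(100, 20, 20)
  # alpha = beta = 0, FRET = 2 x donor
  r <- fret_index_ratiometric(donor, 2 * donor, 0.5 * donor,
                              fret_params(0, 0), mask)
  expect_equal(unname(r), 2)
  # planted index with bleed-through recovers exactly
  st <- make_fret_stack(matrix(0.8, 20, 20), alpha = 0.3, beta = 0.1)
  r2 <- fret_index_ratiometric(st$donor, st$fret, st$acceptor,
                               fret_params(0.3, 0.1), mask)
  expect_equal(unname(r2), 0.8, tolerance = 1e-12)
  # adding donor bleed-through only, with the right alpha, changes nothing
  st3 <- make_fret_stack(matrix(0.8, 20, 20), alpha = 0.9, beta = 0.1)
  r3 <- fret_index_ratiometric(st3$donor, st3$fret, st3$acceptor,
                               fret_params(0.9, 0.1), mask)
  expect_equal(unname(r3), 0.8, tolerance = 1e-12)
  # zero-index map corrects to zero
  st0 <- make_fret_stack(matrix(0, 20, 20), alpha = 0.3, beta = 0.1)
  expect_equal(unname(fret_index_ratiometric(st0$donor, st0$fret, st0$acceptor,
                                             fret_params(0.3, 0.1), mask)), 0)
  # scaling the donor map leaves the recovered index unchanged
  st4 <- make_fret_stack(matrix(0.8, 20, 20), alpha = 0.3, beta = 0.1,
                         donor_map = matrix(500, 20, 20))
  expect_equal(unname(fret_index_ratiometric(st4$donor, st4$fret, st4$acceptor,
                                             fret_params(0.3, 0.1), mask)), 0.8)
  # non-positive donor pixels are excluded with a warning
  donor2 <- donor; donor2[1, 1] <- 0
  expect_warning(fret_index_ratiometric(donor2, 2 * donor2, donor2,
                                        fret_params(0, 0), mask), "excluded")
})

test_that("single-chain FRET index is the per-FA FRET/CFP mean", {
  fa <- matrix(0L, 30, 30)
  fa[5:10, 5:10] <- 1L
  fa[20:25, 20:25] <- 2L
  cfp <- matrix(50, 30, 30)
  fret <- matrix(0, 30, 30)
  fret[fa == 1L] <- 0.4 * 50
  fret[fa == 2L] <- 0.9 * 50
  idx <- fret_index_singlechain(fret, cfp, fa)
  expect_equal(unname(idx), c(0.4, 0.9))
  expect_equal(unname(fret_index_singlechain(cfp, cfp, fa)), c(1, 1))
  expect_equal(unname(fret_index_singlechain(matrix(0, 30, 30), cfp, fa)), c(0, 0))
})

test_that("nuclear/cytoplasmic classification respects the equal band", {
  expect_equal(nuclear_cytoplasmic_class(10, 5), "N>C")
  expect_equal(nuclear_cytoplasmic_class(5, 5, 0), "N=C")
  expect_equal(nuclear_cytoplasmic_class(100, 95, 0.1), "N=C")
  expect_equal(nuclear_cytoplasmic_class(100, 80, 0.1), "N>C")
  expect_equal(nuclear_cytoplasmic_class(80, 100, 0.1), "N<C")
  expect_equal(nuclear_cytoplasmic_class(c(10, 5, 1), c(5, 5, 10)),
               c("N>C", "N=C", "N<C"))
})

test_that("boundary/cytoplasm ratio recovers planted contrasts", {
  img <- matrix(2, 40, 40)
  b <- matrix(FALSE, 40, 40); b[10, ] <- TRUE
  cmask <- matrix(FALSE, 40, 40); cmask[25:30, ] <- TRUE
  expect_equal(boundary_cytoplasm_ratio(img, b, cmask), 1)
  img[b] <- 6
  expect_equal(boundary_cytoplasm_ratio(img, b, cmask), 3)
  img2 <- matrix(1, 40, 40); img2[b] <- 2.5
  expect_equal(boundary_cytoplasm_ratio(img2, b, cmask), 2.5)
  expect_error(boundary_cytoplasm_ratio(img, b, b), "disjoint")
  expect_error(boundary_cytoplasm_ratio(img, b, matrix(FALSE, 40, 40)),
               "non-empty")
})
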