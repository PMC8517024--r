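# Focal-adhesion segmentation from TIRF images: rolling-ball background
# subtraction on the paxillin channel, moments auto-threshold, hole
# filling; mean auto-threshold on the actin channel with dilate / fill /
# open; logical AND of the two masks; connected components are the FAs.

#' Rolling-ball background estimate
#'
#' Grey-level erosion followed by dilation with a ball-shaped (non-flat)
#' structuring element of the given radius -- the surface traced by a ball
#' of that radius rolling under the intensity landscape.  Subtracting it
#' removes smooth background while preserving features smaller than the
#' ball.
#'
#' @param img numeric intensity matrix.
#' @param radius ball radius in pixels (default 30).
#' @return List with `background` and `subtracted` (clamped at 0).
#' @export
rolling_ball <- function(img, radius = 30L) {
  bg <- cpp_rolling_ball(img, as.integer(radius))
  list(background = bg, subtracted = pmax(img - bg, 0))
}

#' Moments-preserving (Tsai) auto-threshold
#'
#' Chooses the threshold for which a binary image preserves the first
#' three grey-level moments of the input, computed on a 256-bin histogram.
#'
#' @param img numeric intensity matrix.
#' @return Threshold value on the intensity scale of `img`.
#' @export
threshold_moments <- function(img) {
  v <- as.vector(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  bin <- pmin(nb - 1L, floor((v - lo) / (hi - lo) * nb))
  p <- tabulate(bin + 1L, nbins = nb) / length(v)
  z <- (seq_len(nb) - 1)
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1 * m1
  c0 <- (-m2 * m2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- sqrt(max(c1 * c1 - 4 * c0, 0))
  z0 <- 0.5 * (-c1 - disc)
  z1 <- 0.5 * (-c1 + disc)
  p0 <- (z1 - m1) / (z1 - z0)      # target fraction of pixels below threshold
  cum <- cumsum(p)
  t_bin <- which(cum >= p0)[1]
  lo + (t_bin - 0.5) / nb * (hi - lo)
}

#' Mean auto-threshold
#'
#' The mean grey level of the image; with a dark background, pixels above
#' it are foreground.
#'
#' @param img numeric intensity matrix.
#' @return The mean intensity.
#' @export
threshold_mean <- function(img) mean(img)

brush3 <- function() EBImage::makeBrush(3, shape = "box")

#' Segment focal adhesions from paxillin / actin / nuclei images
#'
#' Pipeline: rolling-ball background subtraction (radius `rolling_radius`)
#' on the paxillin channel, moments auto-threshold (dark background),
#' binarize, fill holes; actin channel: mean auto-threshold (dark
#' background), binarize, dilate, fill holes, open (3x3 box, one
#' iteration); final FA mask = logical AND of the two; connected
#' components of the final mask are the focal adhesions.  FAs per cell is
#' the number of segmented FAs divided by the number of segmented nuclei.
#'
#' @param paxillin,actin numeric intensity matrices of identical shape.
#' @param nuclei integer label matrix of segmented nuclei (0 background),
#'   same shape; produced by any external instance segmenter or by
#'   [make_fa_scene()].
#' @param rolling_radius rolling-ball radius in pixels (default 30).
#' @param min_area discard components smaller than this many pixels
#'   (default 1, i.e. keep all).
#' @return List with `labels` (FA label matrix), `n_fas`, `n_nuclei`,
#'   `fas_per_cell`, and `stats` (per-FA `area` in pixels and
#'   `circularity`).
#' @export
segment_focal_adhesions <- function(paxillin, actin, nuclei,
                                    rolling_radius = 30L, min_area = 1L) {
  if (!all(dim(paxillin) == dim(actin)) || !all(dim(paxillin) == dim(nuclei)))
    stop("paxillin, actin and nuclei images must have identical shape")
  n_nuclei <- length(setdiff(unique(as.vector(nuclei)), 0))
  if (n_nuclei == 0) stop("zero segmented nuclei: FAs per cell undefined")

  pax <- rolling_ball(paxillin, rolling_radius)$subtracted
  pax_mask <- pax > threshold_moments(pax)
  pax_mask <- EBImage::fillHull(pax_mask * 1)

  act_mask <- actin > threshold_mean(actin)
  act_mask <- EBImage::dilate(act_mask * 1, brush3())
  act_mask <- EBImage::fillHull(act_mask)
  act_mask <- EBImage::opening(act_mask, brush3())

  fa_mask <- (pax_mask > 0) & (act_mask > 0)
  labels <- EBImage::bwlabel(fa_mask * 1)
  labels <- matrix(as.integer(labels), nrow(fa_mask), ncol(fa_mask))
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  if (min_area > 1 && length(areas)) {
    drop <- which(areas < min_area)
    labels[labels %in% drop] <- 0L
    old <- sort(unique(labels[labels > 0]))
    labels <- matrix(match(labels, old, nomatch = 0L), nrow(labels), ncol(labels))
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
  }
  n_fas <- length(areas)
  stats <- if (n_fas) data.frame(
    fa = seq_len(n_fas), area = areas,
    circularity = vapply(seq_len(n_fas),
                         function(l) circularity(labels == l), numeric(1)))
  else data.frame(fa = integer(0), area = integer(0), circularity = numeric(0))
  list(labels = labels, n_fas = n_fas, n_nuclei = n_nuclei,
       fas_per_cell = n_fas / n_nuclei, stats = stats)
}
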