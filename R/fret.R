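# Ratiometric and single-chain FRET indices, and simple compartment
# intensity classifiers.

#' Bleed-through parameters for ratiometric FRET
#'
#' @param alpha donor (CyPet) bleed-through coefficient into the FRET
#'   channel (`>= 0`).
#' @param beta acceptor (YPet) bleed-through coefficient (`>= 0`).
#' @return An object of class `fret_params`.
#' @export
fret_params <- function(alpha = 0, beta = 0) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "fret_params")
}

#' Ratiometric FRET index with bleed-through correction
#'
#' Pixel-wise corrected index
#' \deqn{R = \frac{FRET - \alpha\,CyPet - \beta\,YPet}{CyPet},}
#' averaged per labelled region of `mask`.  Pixels with non-positive donor
#' intensity are excluded with a warning (an error if a region loses all
#' its pixels).
#'
#' @param donor CyPet (donor) intensity matrix.
#' @param fret FRET-channel intensity matrix.
#' @param acceptor YPet (acceptor) intensity matrix.
#' @param p a [fret_params()].
#' @param mask integer label matrix (0 = background) of the regions to
#'   average over.
#' @return Named numeric vector of per-region mean indices (names are the
#'   region labels).
#' @export
fret_index_ratiometric <- function(donor, fret, acceptor, p, mask) {
  stopifnot(all(dim(donor) == dim(fret)), all(dim(donor) == dim(acceptor)),
            all(dim(donor) == dim(mask)))
  labs <- setdiff(sort(unique(as.vector(mask))), 0)
  if (!length(labs)) stop("mask has no labelled regions")
  bad <- donor <= 0 & mask > 0
  if (any(bad))
    warning(sum(bad), " pixel(s) with non-positive donor intensity excluded")
  R <- (fret - p$alpha * donor - p$beta * acceptor) / donor
  out <- vapply(labs, function(l) {
    sel <- mask == l & donor > 0
    if (!any(sel)) stop("region ", l, ": all pixels excluded (donor <= 0)")
    mean(R[sel])
  }, numeric(1))
  names(out) <- labs
  out
}

#' Single-chain FRET index (FRET / CFP)
#'
#' For single-chain tension sensors the index is the FRET channel (donor
#' excitation, acceptor emission) divided by the CFP channel (donor
#' excitation, donor emission), averaged per focal adhesion.
#'
#' @param fret FRET-channel intensity matrix.
#' @param cfp CFP-channel intensity matrix (`> 0` on the mask).
#' @param fa_mask integer FA label matrix (0 = background).
#' @return Named numeric vector of per-FA mean ratios.
#' @export
fret_index_singlechain <- function(fret, cfp, fa_mask) {
  stopifnot(all(dim(fret) == dim(cfp)), all(dim(fret) == dim(fa_mask)))
  labs <- setdiff(sort(unique(as.vector(fa_mask))), 0)
  if (!length(labs)) stop("fa_mask has no labelled regions")
  bad <- cfp <= 0 & fa_mask > 0
  if (any(bad))
    warning(sum(bad), " pixel(s) with non-positive CFP intensity excluded")
  out <- vapply(labs, function(l) {
    sel <- fa_mask == l & cfp > 0
    if (!any(sel)) stop("FA ", l, ": all pixels excluded (CFP <= 0)")
    mean(fret[sel] / cfp[sel])
  }, numeric(1))
  names(out) <- labs
  out
}

#' Classify nuclear versus cytoplasmic signal
#'
#' Returns `"N=C"` when `|nuc - cyt| <= equal_tolerance * max(nuc, cyt)`,
#' otherwise `"N>C"` or `"N<C"` by the sign of the difference.
#'
#' @param nuc_intensity,cyt_intensity non-negative intensities
#'   (vectorized).
#' @param equal_tolerance relative tolerance defining "equal"
#'   (default 0.1).
#' @return Character vector in `{"N>C", "N=C", "N<C"}`.
#' @export
nuclear_cytoplasmic_class <- function(nuc_intensity, cyt_intensity,
                                      equal_tolerance = 0.1) {
  stopifnot(all(nuc_intensity >= 0), all(cyt_intensity >= 0),
            equal_tolerance >= 0)
  d <- nuc_intensity - cyt_intensity
  tol <- equal_tolerance * pmax(nuc_intensity, cyt_intensity)
  ifelse(abs(d) <= tol, "N=C", ifelse(d > 0, "N>C", "N<C"))
}

#' Boundary-to-cytoplasm intensity ratio
#'
#' Mean intensity over the boundary mask divided by the mean over the
#' cytoplasm mask (e.g. junctional versus cytoplasmic immunointensity).
#'
#' @param image intensity matrix.
#' @param boundary_mask,cytoplasm_mask disjoint non-empty logical masks.
#' @return The ratio.
#' @export
boundary_cytoplasm_ratio <- function(image, boundary_mask, cytoplasm_mask) {
  stopifnot(all(dim(image) == dim(boundary_mask)),
            all(dim(image) == dim(cytoplasm_mask)))
  if (!any(boundary_mask) || !any(cytoplasm_mask))
    stop("masks must be non-empty")
  if (any(boundary_mask & cytoplasm_mask))
    stop("boundary and cytoplasm masks must be disjoint")
  cyt <- mean(image[cytoplasm_mask > 0])
  if (cyt == 0) stop("zero cytoplasmic mean intensity")
  mean(image[boundary_mask > 0]) / cyt
}
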