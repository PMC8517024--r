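#' @useDynLib cellmech, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Pair potential parameters
#'
#' Parameters of a non-bonded pair interaction between two bead types:
#' either a Lennard-Jones well (attractive, used for membrane--membrane and
#' membrane--filament-head contacts) or its purely repulsive
#' Weeks--Chandler--Andersen (WCA) truncation (excluded volume).
#'
#' The Lennard-Jones form used throughout is
#' \deqn{U_{LJ}(r) = \epsilon[(\sigma/r)^{12} - 2(\sigma/r)^6],}
#' which has its minimum \eqn{-\epsilon} exactly at \eqn{r = \sigma}.
#'
#' @param epsilon well-depth energy (reduced units), `>= 0`.
#' @param sigma equilibrium distance (reduced units), `> 0`.
#' @param cutoff interaction range. For `kind = "LJ"` defaults to
#'   `2.5 * sigma` (with an energy shift so the potential is continuous,
#'   i.e. zero, at the cutoff); use `Inf` for the untruncated form.
#'   For `kind = "WCA"` the cutoff is always `sigma`.
#' @param kind `"LJ"` or `"WCA"`.
#' @return An object of class `pair_params`.
#' @export
pair_params <- function(epsilon, sigma = 1, cutoff = NULL, kind = c("LJ", "WCA")) {
  kind <- match.arg(kind)
  stopifnot(epsilon >= 0, sigma > 0)
  if (kind == "WCA") {
    cutoff <- sigma
  } else if (is.null(cutoff)) {
    cutoff <- Inf
  }
  if (kind == "LJ" && cutoff < sigma)
    stop("LJ cutoff must be >= sigma")
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff, kind = kind),
            class = "pair_params")
}

#' FENE bond parameters
#'
#' Finitely extensible nonlinear elastic bond
#' \deqn{U_{FENE}(r) = -\frac{\kappa_F \Delta r_{max}^2}{2}
#'   \log\left[1 - \left(\frac{r - r_0}{\Delta r_{max}}\right)^2\right],}
#' defined only for \eqn{|r - r_0| < \Delta r_{max}}; it diverges at the
#' maximal extension/compression, preventing unphysical bond stretching.
#'
#' @param kF spring constant \eqn{\kappa_F} (reduced units).
#' @param r0 equilibrium bond length.
#' @param drmax maximal extension/compression \eqn{\Delta r^{max}} (`> 0`).
#' @return An object of class `fene_params`.
#' @export
fene_params <- function(kF, r0, drmax) {
  stopifnot(kF >= 0, r0 > 0, drmax > 0)
  structure(list(kF = kF, r0 = r0, drmax = drmax), class = "fene_params")
}

#' Bend (three-bead angular) parameters
#'
#' @param kB bend spring constant \eqn{\kappa_B}, `>= 0`.
#' @param theta0 equilibrium angle in radians, in `(0, pi]`.
#' @return An object of class `bend_params`.
#' @export
bend_params <- function(kB, theta0 = pi) {
  stopifnot(kB >= 0, theta0 > 0, theta0 <= pi)
  structure(list(kB = kB, theta0 = theta0), class = "bend_params")
}

#' Lennard-Jones pair energy
#'
#' Evaluates \eqn{U_{LJ}(r) = \epsilon[(\sigma/r)^{12} - 2(\sigma/r)^6]}.
#' With a finite cutoff the energy is shifted so that it is continuous
#' (zero) at the cutoff and identically zero beyond it.
#'
#' @param r distance(s), `> 0`.
#' @param p a [pair_params()] object.
#' @return Energy, vectorized over `r`.
#' @export
lj_energy <- function(r, p) {
  if (any(r <= 0)) stop("lj_energy: r must be > 0")
  s6 <- (p$sigma / r)^6
  u <- p$epsilon * (s6^2 - 2 * s6)
  if (is.finite(p$cutoff)) {
    s6c <- (p$sigma / p$cutoff)^6
    u <- u - p$epsilon * (s6c^2 - 2 * s6c)
    u[r >= p$cutoff] <- 0
  }
  u
}

#' Weeks--Chandler--Andersen pair energy
#'
#' The purely repulsive part of the Lennard-Jones potential:
#' \eqn{U_{LJ}(r) + \epsilon} for \eqn{r < \sigma}, zero for
#' \eqn{r \ge \sigma}; continuous at \eqn{\sigma}.
#'
#' @inheritParams lj_energy
#' @return Energy, vectorized over `r`.
#' @export
wca_energy <- function(r, p) {
  if (any(r <= 0)) stop("wca_energy: r must be > 0")
  s6 <- (p$sigma / r)^6
  u <- p$epsilon * (s6^2 - 2 * s6) + p$epsilon
  u[r >= p$sigma] <- 0
  u
}

#' FENE bond energy
#'
#' @param r distance(s); must satisfy `abs(r - r0) < drmax`.
#' @param p a [fene_params()] object.
#' @return Energy, vectorized over `r`; non-negative, zero at `r0`,
#'   diverging as `|r - r0|` approaches `drmax`.
#' @export
fene_energy <- function(r, p) {
  u <- (r - p$r0) / p$drmax
  if (any(abs(u) >= 1))
    stop("fene_energy: bond overextended (|r - r0| >= drmax)")
  -p$kF * p$drmax^2 / 2 * log(1 - u^2)
}

#' Bend energy of a three-bead angle
#'
#' \eqn{U_{bend}(\theta) = \frac{\kappa_B}{2}(\cos\theta - \cos\theta_0)^2}.
#'
#' @param theta angle(s) in radians, in `[0, pi]`.
#' @param p a [bend_params()] object.
#' @return Energy, vectorized over `theta`.
#' @export
bend_energy <- function(theta, p) {
  ct <- pmin(1, pmax(-1, cos(theta)))
  p$kB / 2 * (ct - cos(p$theta0))^2
}

# ---- pair-rule table <-> dense matrices used by the C++ kernels -------------
# Each rule has a scope: "any" (default), "same_cell" (e.g. the cortical
# eps03 grip, which is intra-cell), or "cross_cell" (e.g. excluded volume
# between filament heads and foreign membranes).

rule_scope <- function(pr) {
  if (is.null(pr$scope)) rep("any", nrow(pr)) else pr$scope
}

rule_set <- function(pr, scopes) {
  eps <- matrix(0, 8, 8); sig <- matrix(1, 8, 8)
  cut <- matrix(0, 8, 8); kind <- matrix(0L, 8, 8)
  if (!is.null(pr) && nrow(pr)) {
    sc <- rule_scope(pr)
    for (q in which(sc %in% scopes)) {
      a <- pr$type_i[q] + 1L; b <- pr$type_j[q] + 1L
      k <- if (pr$potential[q] == "LJ") 1L else 2L
      co <- if (k == 2L) pr$sigma[q] else pr$cutoff[q]
      eps[a, b] <- eps[b, a] <- pr$epsilon[q]
      sig[a, b] <- sig[b, a] <- pr$sigma[q]
      cut[a, b] <- cut[b, a] <- co
      kind[a, b] <- kind[b, a] <- k
    }
  }
  list(eps = eps, sig = sig, cut = cut, kind = kind)
}

pair_rule_matrices <- function(table) {
  pr <- table$pair_rules
  list(same = rule_set(pr, c("any", "same_cell")),
       cross = rule_set(pr, c("any", "cross_cell")))
}

bonds_matrix <- function(table) {
  b <- table$bonds
  if (is.null(b) || !nrow(b)) return(matrix(0, 0, 5))
  as.matrix(b[, c("i", "j", "kF", "r0", "drmax")])
}

angles_matrix <- function(table) {
  a <- table$angles
  if (is.null(a) || !nrow(a)) return(matrix(0, 0, 5))
  as.matrix(a[, c("i", "j", "k", "kB", "theta0")])
}

empty_anchors <- function() matrix(0, 0, 7)

#' Total potential energy of a bead configuration
#'
#' Sums all bonded terms (FENE bonds, bend triples) and non-bonded pair
#' terms under the interaction table's type-pair rules.  Beads joined by a
#' bond are excluded from non-bonded interactions.  Implemented in R,
#' independently of the compiled force kernel, so the two can be checked
#' against each other by finite differences.
#'
#' @param config a [bead_config] (see [build_cell()]).
#' @param table an [interaction_table] (see [build_cell()]).
#' @return Total potential energy (reduced units).
#' @export
total_energy <- function(config, table) {
  pos <- config$positions
  e <- 0
  b <- table$bonds
  if (!is.null(b) && nrow(b)) {
    d <- sqrt(rowSums((pos[b$i, , drop = FALSE] - pos[b$j, , drop = FALSE])^2))
    u <- (d - b$r0) / b$drmax
    if (any(abs(u) >= 1)) stop("total_energy: FENE bond overextended")
    e <- e + sum(-b$kF * b$drmax^2 / 2 * log(1 - u^2))
  }
  a <- table$angles
  if (!is.null(a) && nrow(a)) {
    v1 <- pos[a$i, , drop = FALSE] - pos[a$j, , drop = FALSE]
    v2 <- pos[a$k, , drop = FALSE] - pos[a$j, , drop = FALSE]
    ct <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ct <- pmin(1, pmax(-1, ct))
    e <- e + sum(a$kB / 2 * (ct - cos(a$theta0))^2)
  }
  pr <- table$pair_rules
  if (!is.null(pr) && nrow(pr)) {
    excl <- character(0)
    if (!is.null(b) && nrow(b))
      excl <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    dmat <- as.matrix(stats::dist(pos))
    idx <- which(upper.tri(dmat), arr.ind = TRUE)
    key <- paste(idx[, 1], idx[, 2])
    idx <- idx[!(key %in% excl), , drop = FALSE]
    ti <- config$type[idx[, 1]]; tj <- config$type[idx[, 2]]
    same <- config$cell_id[idx[, 1]] == config$cell_id[idx[, 2]]
    r <- dmat[idx]
    sc <- rule_scope(pr)
    for (q in seq_len(nrow(pr))) {
      sel <- (ti == pr$type_i[q] & tj == pr$type_j[q]) |
             (ti == pr$type_j[q] & tj == pr$type_i[q])
      if (sc[q] == "same_cell") sel <- sel & same
      if (sc[q] == "cross_cell") sel <- sel & !same
      if (!any(sel)) next
      p <- pair_params(pr$epsilon[q], pr$sigma[q],
                       cutoff = pr$cutoff[q], kind = pr$potential[q])
      e <- e + if (pr$potential[q] == "LJ") sum(lj_energy(r[sel], p)) else
        sum(wca_energy(r[sel], p))
    }
  }
  e
}

#' Per-bead forces of a bead configuration
#'
#' Forces are the negative gradient of [total_energy()] (bonded FENE and
#' bend terms plus non-bonded type-pair terms); Newton's third law holds
#' pairwise and the internal forces sum to zero.
#'
#' @inheritParams total_energy
#' @return A list with `forces` (an `n x 2` matrix) and `potential`
#'   (the total potential energy).
#' @export
total_forces <- function(config, table) {
  m <- pair_rule_matrices(table)
  cpp_total_forces(config$positions, as.integer(config$type),
                   as.integer(config$cell_id),
                   bonds_matrix(table), angles_matrix(table),
                   m$same, m$cross, empty_anchors())
}
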