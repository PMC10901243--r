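# Lu-Chipman polar decomposition M = M_delta . M_R . M_D and the per-pixel
# anisotropy parameters derived from it (fast-axis orientation theta, linear
# retardance, depolarization power) together with the element-ratio angles
# alphaP (diattenuation azimuth, from m21/m31) and alphaQ (from m42/m43).
#
# All half-angle ratios use two-argument arctangent and are reduced to the
# axial domain [0, 180), avoiding the quadrant ambiguity of a plain arctan.

half_atan2_deg <- function(y, x) wrap_axial(0.5 * atan2(y, x) * 180 / pi)

# symmetric square root of a PSD 3x3 matrix via eigendecomposition
sqrtm_sym3 <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  lam <- sqrt(pmax(e$values, 0))
  e$vectors %*% (lam * t(e$vectors))
}

#' Lu-Chipman polar decomposition of a Mueller matrix
#'
#' Factors a (normalized) Mueller matrix as the ordered product
#' `M = M_delta %*% M_R %*% M_D` of a depolarizer (with polarizance), a pure
#' retarder and a diattenuator. The diattenuator is built from the first
#' row's diattenuation vector; the depolarizer submatrix is recovered as the
#' signed symmetric square-root factor of `m' m'^T` with the sign of
#' `det(m')`; the retarder is what remains, re-orthogonalized by
#' nearest-rotation projection when numerical inversion leaves a defect
#' above `1e-9`.
#'
#' @param M A 4x4 Mueller matrix with `m11 > 0` and diattenuation
#'   magnitude strictly below 1.
#' @return An object of class `mmpd_factors`: list with elements `M_delta`,
#'   `M_R`, `M_D` (each 4x4, m11 = 1), `D` (diattenuation magnitude), and
#'   `retarder_defined` (FALSE when `m'` is singular so no retarder can be
#'   attributed).
#' @export
#' @examples
#' f <- lu_chipman(linear_retarder(60, 20))
#' f$M_R   # equals the input: a pure retarder is its own retarder factor
lu_chipman <- function(M) {
  M <- normalize_mueller(M)
  dvec <- M[1, 2:4]
  D <- sqrt(sum(dvec^2))
  if (D >= 1 - 1e-9)
    stop("degenerate diattenuator: diattenuation magnitude ", signif(D, 6),
         " >= 1; M_D is singular")
  if (D > 0) {
    dhat <- dvec / D
    mD <- sqrt(1 - D^2) * diag(3) + (1 - sqrt(1 - D^2)) * tcrossprod(dhat)
  } else mD <- diag(3)
  MD <- rbind(c(1, dvec), cbind(dvec, mD))
  dimnames(MD) <- NULL
  Mp <- M %*% solve(MD)
  mp <- Mp[2:4, 2:4]
  Pdelta <- Mp[2:4, 1]
  detmp <- det(mp)
  mdelta <- sqrtm_sym3(mp %*% t(mp))
  if (detmp < 0) mdelta <- -mdelta
  Mdelta <- rbind(c(1, 0, 0, 0), cbind(Pdelta, mdelta))
  retarder_defined <- abs(det(mdelta)) > 1e-12
  if (retarder_defined) {
    mR <- solve(mdelta, mp)
    defect <- max(abs(mR %*% t(mR) - diag(3)))
    if (defect > 1e-9) {                      # nearest rotation projection
      sv <- svd(mR)
      mR <- sv$u %*% t(sv$v)
      if (det(mR) < 0) mR <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
    }
    MR <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), mR))
  } else {
    MR <- diag(4)                             # flagged, not meaningful
  }
  structure(list(M_delta = Mdelta, M_R = MR, M_D = MD, D = D,
                 retarder_defined = retarder_defined),
            class = "mmpd_factors")
}

#' Fast-axis orientation from a retarder factor
#'
#' The retardance vector has components `r_i` proportional to
#' `sum_jk epsilon_ijk mR[j, k]` (Levi-Civita contraction of the 3x3
#' retarder submatrix); the fast-axis orientation is
#' `theta = 1/2 * atan2(r2, r1)` reduced to `[0, 180)`. For a pure linear
#' retarder this equals the construction axis. Undefined (NA) when the total
#' retardance is 0 or 180 degrees (`sin delta` below `tol`).
#'
#' @param M_R A pure-retarder Mueller matrix (e.g. `lu_chipman(M)$M_R`).
#' @param tol Floor on `sin` of the total retardance below which the
#'   orientation is undefined.
#' @return Orientation angle in degrees on `[0, 180)`, or `NA_real_`.
#' @export
retardance_theta <- function(M_R, tol = 1e-9) {
  stopifnot(is.matrix(M_R), all(dim(M_R) == c(4L, 4L)))
  m <- M_R[2:4, 2:4]
  r1 <- m[2, 3] - m[3, 2]
  r2 <- m[3, 1] - m[1, 3]
  r3 <- m[1, 2] - m[2, 1]
  # |r| = 2 sin(total retardance); orientation meaningless when ~0
  if (sqrt(r1^2 + r2^2 + r3^2) / 2 < tol) return(NA_real_)
  if (sqrt(r1^2 + r2^2) < tol) return(NA_real_)  # purely circular retarder
  half_atan2_deg(r2, r1)
}

#' Linear retardance magnitude of a retarder factor
#'
#' Standard Lu-Chipman linear-retardance expression
#' `delta = acos(sqrt((m22 + m33)^2 + (m32 - m23)^2) - 1)` (4x4 element
#' indices), in degrees, clamped to `[0, 180]`.
#'
#' @param M_R A pure-retarder Mueller matrix.
#' @param tol Allowed overshoot of the acos argument beyond `[-1, 1]`
#'   before an error is raised (within it, the argument is clamped).
#' @return Linear retardance in degrees.
#' @export
linear_retardance <- function(M_R, tol = 1e-9) {
  stopifnot(is.matrix(M_R), all(dim(M_R) == c(4L, 4L)))
  a <- sqrt((M_R[2, 2] + M_R[3, 3])^2 + (M_R[3, 2] - M_R[2, 3])^2) - 1
  if (a > 1 + tol || a < -1 - tol)
    stop("linear retardance argument ", signif(a, 6), " outside [-1, 1]")
  acos(min(1, max(-1, a))) * 180 / pi
}

#' Depolarization power of a depolarizer factor
#'
#' `Delta = 1 - |tr(m_delta)| / 3` over the 3x3 submatrix (equivalently
#' `1 - |tr(M_delta) - 1| / 3` on the 4x4 since `M_delta[1, 1] = 1`);
#' 0 for a nondepolarizing element, 1 for an ideal depolarizer.
#'
#' @param M_delta A depolarizer Mueller matrix (e.g. `lu_chipman(M)$M_delta`).
#' @return Scalar in `[0, 1]`.
#' @export
depolarization_power <- function(M_delta) {
  stopifnot(is.matrix(M_delta), all(dim(M_delta) == c(4L, 4L)))
  min(1, max(0, 1 - abs(sum(diag(M_delta)[2:4])) / 3))
}

#' Diattenuation azimuth alphaP from Mueller elements
#'
#' `alphaP = 1/2 * atan2(m31, m21)` on `[0, 180)`: the azimuth of maximum
#' transmittance of the linear diattenuation (first-column convention).
#' Masked (`NA`) when `sqrt(m21^2 + m31^2)` falls below `floor` times m11,
#' where the orientation is undefined.
#'
#' @param M A 4x4 Mueller matrix.
#' @param floor Relative magnitude floor (default `1e-6`).
#' @return Angle in degrees on `[0, 180)`, or `NA_real_`.
#' @export
alpha_p <- function(M, floor = 1e-6) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  m21 <- M[2, 1] / M[1, 1]
  m31 <- M[3, 1] / M[1, 1]
  if (sqrt(m21^2 + m31^2) <= floor) return(NA_real_)
  half_atan2_deg(m31, m21)
}

#' Birefringence-related azimuth alphaQ from Mueller elements
#'
#' `alphaQ = 1/2 * atan2(m42, -m43)` on `[0, 180)`. For a pure linear
#' retarder (e.g. a quarter-wave plate, where `m42 = sin 2 theta` and
#' `m43 = -cos 2 theta`) this equals the fast-axis orientation; when
#' scattering or diattenuation couple into m42/m43 it becomes unstable,
#' which is exactly the degeneracy the decomposition-based theta avoids.
#'
#' @inheritParams alpha_p
#' @return Angle in degrees on `[0, 180)`, or `NA_real_`.
#' @export
alpha_q <- function(M, floor = 1e-6) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  m42 <- M[4, 2] / M[1, 1]
  m43 <- M[4, 3] / M[1, 1]
  if (sqrt(m42^2 + m43^2) <= floor) return(NA_real_)
  half_atan2_deg(m42, -m43)
}

# mask reason bits for decompose_image
MASK_THETA_UNDEFINED <- 1L
MASK_ALPHAP_FLOOR    <- 2L
MASK_ALPHAQ_FLOOR    <- 4L
MASK_DECOMP_FAILED   <- 8L

#' Per-pixel anisotropy parameter maps from a Mueller image
#'
#' Applies [lu_chipman()] pixelwise and collects the six scalar maps:
#' fast-axis orientation `theta`, linear retardance `delta_lr`,
#' depolarization power `Delta`, diattenuation azimuth `alphaP`,
#' element-ratio azimuth `alphaQ`, and diattenuation magnitude `D`. Pixels
#' failing a precondition are masked (`NA` in the affected map) with a
#' bitwise reason code, never NaN-propagated: 1 = theta undefined
#' (near-zero retardance), 2 = alphaP below floor, 4 = alphaQ below floor,
#' 8 = decomposition failed (degenerate diattenuator or singular
#' depolarizer).
#'
#' @param img A [mueller_image()].
#' @param angle_floor Relative floor for the alphaP/alphaQ element
#'   magnitudes (see [alpha_p()]).
#' @param theta_tol Floor on `sin`(total retardance) for theta.
#' @return An object of class `param_maps`: list of H x W matrices `theta`,
#'   `delta_lr`, `Delta`, `alphaP`, `alphaQ`, `D`, and integer `mask`.
#' @export
decompose_image <- function(img, angle_floor = 1e-6, theta_tol = 1e-9) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img)
  H <- d[1]; W <- d[2]
  z <- matrix(NA_real_, H, W)
  maps <- list(theta = z, delta_lr = z, Delta = z, alphaP = z, alphaQ = z,
               D = z, mask = matrix(0L, H, W))
  for (h in seq_len(H)) for (w in seq_len(W)) {
    M <- matrix(img[h, w, , ], 4L, 4L)
    maps$alphaP[h, w] <- ap <- alpha_p(M, angle_floor)
    maps$alphaQ[h, w] <- aq <- alpha_q(M, angle_floor)
    if (is.na(ap)) maps$mask[h, w] <- maps$mask[h, w] + MASK_ALPHAP_FLOOR
    if (is.na(aq)) maps$mask[h, w] <- maps$mask[h, w] + MASK_ALPHAQ_FLOOR
    f <- tryCatch(lu_chipman(M), error = function(e) NULL)
    if (is.null(f) || !f$retarder_defined) {
      maps$mask[h, w] <- maps$mask[h, w] + MASK_DECOMP_FAILED
      next
    }
    maps$D[h, w] <- f$D
    maps$Delta[h, w] <- depolarization_power(f$M_delta)
    maps$delta_lr[h, w] <- linear_retardance(f$M_R)
    th <- retardance_theta(f$M_R, theta_tol)
    maps$theta[h, w] <- th
    if (is.na(th)) maps$mask[h, w] <- maps$mask[h, w] + MASK_THETA_UNDEFINED
  }
  structure(maps, class = "param_maps", dim_hw = c(H, W))
}

#' @export
print.param_maps <- function(x, ...) {
  d <- attr(x, "dim_hw")
  cat(sprintf("<param_maps %d x %d pixels; %d masked>\n", d[1], d[2],
              sum(x$mask != 0L)))
  for (nm in c("theta", "delta_lr", "Delta", "alphaP", "alphaQ", "D")) {
    v <- x[[nm]]
    cat(sprintf("  %-8s mean %8.3f  sd %8.3f  (NA: %d)\n", nm,
                mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
                sum(is.na(v))))
  }
  invisible(x)
}
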