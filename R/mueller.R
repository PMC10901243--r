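# Degrees are the angle unit throughout the package. Axial (orientation)
# angles live on [0, 180): an axis at a and at a + 180 are the same axis.

deg2rad <- function(x) x * (pi / 180)

#' Reduce an angle to the axial domain [0, 180)
#'
#' Orientation angles (fast axis, diattenuation azimuth) are 180-degree
#' periodic: an axis at `a` degrees and at `a + 180` degrees are physically
#' identical. This maps any finite angle onto the canonical representative.
#'
#' @param angle Numeric vector of angles in degrees.
#' @return Angles reduced modulo 180 into `[0, 180)`.
#' @export
#' @examples
#' wrap_axial(c(-10, 190, 180))
wrap_axial <- function(angle) {
  stopifnot(is.numeric(angle), all(is.finite(angle)))
  angle %% 180
}

#' Mueller rotation matrix
#'
#' The change-of-basis matrix that rotates the linear-polarization frame by
#' `angle` degrees counterclockwise (positive angles counterclockwise from
#' the horizontal x-axis, looking into the beam). Only the Q/U block is
#' affected, with the characteristic double-angle arguments.
#'
#' @param angle Rotation angle in degrees.
#' @return A 4x4 numeric matrix `R(angle)`; satisfies
#'   `R(a) %*% R(b) == R(a + b)`.
#' @export
#' @examples
#' rotation_matrix(0)           # identity
#' rotation_matrix(45)[2:3, 2:3]
rotation_matrix <- function(angle) {
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  c2 <- cospi(angle / 90)   # cos(2 angle), exact at multiples of 45 deg
  s2 <- sinpi(angle / 90)
  matrix(c(1, 0, 0, 0,
           0, c2, -s2, 0,
           0, s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Linear retarder Mueller matrix
#'
#' Homogeneous linear retarder with retardance `delta` and fast axis at
#' `axis` degrees, i.e. `R(axis) %*% linear_retarder(delta, 0) %*% R(-axis)`.
#' With `delta = 90` this is the quarter-wave-plate matrix whose last row is
#' `(0, sin 2a, -cos 2a, 0)`.
#'
#' @param delta Retardance magnitude in degrees, in `[0, 180]`.
#' @param axis Fast-axis orientation in degrees.
#' @return A 4x4 Mueller matrix.
#' @export
#' @examples
#' linear_retarder(90, 30)    # quarter-wave plate at 30 degrees
linear_retarder <- function(delta, axis = 0) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  stopifnot(is.numeric(axis), length(axis) == 1L, is.finite(axis))
  if (delta < 0 || delta > 180)
    stop("retardance `delta` must be in [0, 180] degrees, got ", delta)
  cd <- cospi(delta / 180)
  sd <- sinpi(delta / 180)
  c2 <- cospi(axis / 90)
  s2 <- sinpi(axis / 90)
  # closed form of R(axis) . diag-block retarder . R(-axis)
  matrix(c(
    1, 0, 0, 0,
    0, c2^2 + s2^2 * cd, c2 * s2 * (1 - cd), -s2 * sd,
    0, c2 * s2 * (1 - cd), s2^2 + c2^2 * cd, c2 * sd,
    0, s2 * sd, -c2 * sd, cd), 4, 4, byrow = TRUE)
}

#' Linear diattenuator Mueller matrix
#'
#' m11-normalized linear diattenuator with diattenuation magnitude `D` and
#' maximum-transmittance axis at `axis` degrees. The diattenuation vector is
#' `D * (cos 2 axis, sin 2 axis, 0)`; `D = 1` is an ideal linear polarizer
#' (up to the m11 = 1/2 physical transmission scale, which normalization
#' drops).
#'
#' @param D Diattenuation magnitude, in `[0, 1]`.
#' @param axis Transmission-axis orientation in degrees.
#' @return A 4x4 Mueller matrix with `m11 = 1`.
#' @export
linear_diattenuator <- function(D, axis = 0) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D))
  stopifnot(is.numeric(axis), length(axis) == 1L, is.finite(axis))
  if (D < 0 || D > 1)
    stop("diattenuation `D` must be in [0, 1], got ", D)
  c2 <- cospi(axis / 90)
  s2 <- sinpi(axis / 90)
  dvec <- D * c(c2, s2, 0)
  s <- sqrt(pmax(0, 1 - D^2))
  dd <- tcrossprod(c(c2, s2, 0))
  m <- s * diag(3) + (1 - s) * dd
  out <- rbind(c(1, dvec), cbind(dvec, m))
  dimnames(out) <- NULL
  out
}

#' Diagonal depolarizer Mueller matrix
#'
#' `diag(1, d1, d2, d3)`: each Stokes polarization component is shrunk by
#' its coefficient. The depolarization power of this element is
#' `1 - (d1 + d2 + d3) / 3`.
#'
#' @param d1,d2,d3 Depolarization coefficients in `[0, 1]` (1 = no
#'   depolarization). `d1` may also be a length-3 vector.
#' @return A 4x4 diagonal Mueller matrix.
#' @export
depolarizer_diag <- function(d1, d2 = NULL, d3 = NULL) {
  d <- if (length(d1) == 3L && is.null(d2)) d1 else c(d1, d2, d3)
  stopifnot(is.numeric(d), length(d) == 3L, all(is.finite(d)))
  if (any(d < 0 | d > 1))
    stop("depolarization coefficients must be in [0, 1]")
  diag(c(1, d))
}

#' Compose layered Mueller matrices in propagation order
#'
#' Light traversing layers 1, 2, ..., n in sequence is described by the
#' product with the last-encountered layer leftmost:
#' `M = M_n %*% ... %*% M_1`.
#'
#' @param layers A nonempty list of 4x4 Mueller matrices, first-encountered
#'   layer first.
#' @return The composite 4x4 Mueller matrix.
#' @export
#' @examples
#' qwp <- linear_retarder(90, 0)
#' compose_layers(list(qwp, qwp))   # half-wave plate at 0 degrees
compose_layers <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a nonempty list of 4x4 matrices")
  M <- layers[[1L]]
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  if (length(layers) > 1L)
    for (k in 2:length(layers)) {
      Mk <- layers[[k]]
      stopifnot(is.matrix(Mk), all(dim(Mk) == c(4L, 4L)))
      M <- Mk %*% M
    }
  M
}

#' Stokes vector constructor
#'
#' @param I,Q,U,V Stokes components; `I >= 0` and the polarized part must
#'   not exceed the intensity (`Q^2 + U^2 + V^2 <= I^2` within tolerance).
#' @return A length-4 numeric vector `c(I, Q, U, V)`.
#' @export
stokes <- function(I, Q = 0, U = 0, V = 0) {
  s <- c(I, Q, U, V)
  stopifnot(is.numeric(s), length(s) == 4L, all(is.finite(s)))
  if (I < 0) stop("Stokes I must be nonnegative")
  if (Q^2 + U^2 + V^2 > I^2 + 1e-9)
    stop("unphysical Stokes vector: Q^2 + U^2 + V^2 > I^2")
  s
}

#' Degree of polarization of a Stokes vector
#' @param s Length-4 Stokes vector.
#' @return `sqrt(Q^2 + U^2 + V^2) / I`.
#' @export
degree_of_polarization <- function(s) {
  stopifnot(is.numeric(s), length(s) == 4L)
  if (s[1] <= 0) stop("zero-intensity Stokes vector")
  sqrt(sum(s[2:4]^2)) / s[1]
}

#' Normalize a Mueller matrix to m11 = 1
#' @param M A 4x4 Mueller matrix with `m11 > 0`.
#' @return `M / M[1, 1]`.
#' @export
normalize_mueller <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  if (!is.finite(M[1, 1]) || M[1, 1] <= 0)
    stop("m11 must be positive for a physically meaningful Mueller matrix")
  M / M[1, 1]
}

#' Element-bound physicality check
#'
#' Checks the basic bound `|mij| <= m11` for all elements (no Cloude
#' eigenvalue filtering; the pipeline consumes its own simulated matrices).
#'
#' @param M A 4x4 Mueller matrix.
#' @param tol Numerical slack on the bound.
#' @return `TRUE`/`FALSE`.
#' @export
is_physical_mueller <- function(M, tol = 1e-9) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  is.finite(M[1, 1]) && M[1, 1] > 0 && all(abs(M) <= M[1, 1] + tol)
}
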