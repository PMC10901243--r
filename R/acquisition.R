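# Dual-rotating quarter-wave-plate acquisition: both the polarization state
# generator (PSG) and analyzer (PSA) are a fixed polarizer followed by a
# stepped QWP. 30 frames with R1 stepping 6 deg/frame and R2 30 deg/frame
# give an (overdetermined) rank-16 linear system for the 16 Mueller
# elements, inverted per pixel by least squares.

#' Acquisition protocol for the dual-rotating-retarder polarimeter
#'
#' Describes the synchronized rotation scheme: at frame k (1-based) the PSG
#' retarder R1 sits at `(k - 1) * psg_step` degrees and the PSA retarder R2
#' at `(k - 1) * psa_step` degrees; both polarizers are fixed.
#'
#' @param n_frames Number of frames; at least 16 for invertibility.
#' @param psg_step,psa_step Retarder rotation steps in degrees per frame.
#' @param psg_retardance,psa_retardance Retardances of R1/R2 in degrees.
#' @param polarizer_axes Length-2 vector: transmission axes of P1 (PSG) and
#'   P2 (PSA) in degrees.
#' @return An object of class `acquisition_protocol`.
#' @export
#' @examples
#' acquisition_protocol()   # the default 30-frame, 6/30 degree protocol
acquisition_protocol <- function(n_frames = 30L, psg_step = 6, psa_step = 30,
                                 psg_retardance = 90, psa_retardance = 90,
                                 polarizer_axes = c(0, 0)) {
  n_frames <- as.integer(n_frames)
  stopifnot(length(n_frames) == 1L, is.finite(n_frames))
  if (n_frames < 16L) stop("`n_frames` must be >= 16 for invertibility")
  if (psg_step <= 0 || psa_step <= 0) stop("rotation steps must be positive")
  stopifnot(length(polarizer_axes) == 2L, all(is.finite(polarizer_axes)))
  structure(list(n_frames = n_frames, psg_step = psg_step,
                 psa_step = psa_step, psg_retardance = psg_retardance,
                 psa_retardance = psa_retardance,
                 polarizer_axes = polarizer_axes),
            class = "acquisition_protocol")
}

check_frame <- function(frame, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) ||
      frame < 1L || frame > protocol$n_frames)
    stop("`frame` must be an integer in 1..", protocol$n_frames)
  frame
}

polarizer_mueller <- function(axis) 0.5 * linear_diattenuator(1, axis)

#' Polarization state produced by the PSG at a given frame
#'
#' Unit unpolarized light through P1 then the stepped QWP R1. The result is
#' fully polarized (degree of polarization 1).
#'
#' @param frame 1-based frame index in `1..n_frames` (frame 1 has both
#'   retarders at 0 degrees).
#' @param protocol An [acquisition_protocol()].
#' @return A length-4 Stokes vector.
#' @export
psg_state <- function(frame, protocol = acquisition_protocol()) {
  frame <- check_frame(frame, protocol)
  qwp <- linear_retarder(protocol$psg_retardance,
                         (frame - 1) * protocol$psg_step)
  drop(qwp %*% polarizer_mueller(protocol$polarizer_axes[1]) %*% c(1, 0, 0, 0))
}

#' Analyzer row of the PSA at a given frame
#'
#' First row of `P2 %*% QWP(R2 angle)`: the detected intensity for a sample
#' with Mueller matrix `M` at frame `k` is
#' `psa_row(k) %*% M %*% psg_state(k)`.
#'
#' @inheritParams psg_state
#' @return A length-4 numeric analyzer vector.
#' @export
psa_row <- function(frame, protocol = acquisition_protocol()) {
  frame <- check_frame(frame, protocol)
  qwp <- linear_retarder(protocol$psa_retardance,
                         (frame - 1) * protocol$psa_step)
  drop((polarizer_mueller(protocol$polarizer_axes[2]) %*% qwp)[1, ])
}

#' Design matrix of the acquisition protocol
#'
#' Row k is the outer product `psa_row(k) x psg_state(k)` flattened in
#' row-major Mueller element order (m11, m12, ..., m44), so that
#' `I = A %*% vec(M)`.
#'
#' @param protocol An [acquisition_protocol()].
#' @return An `n_frames` x 16 numeric matrix.
#' @export
design_matrix <- function(protocol = acquisition_protocol()) {
  A <- matrix(0, protocol$n_frames, 16L)
  for (k in seq_len(protocol$n_frames)) {
    a <- psa_row(k, protocol)
    s <- psg_state(k, protocol)
    A[k, ] <- as.vector(t(outer(a, s)))  # row-major (i, j) -> a_i s_j
  }
  A
}

# vec a mueller_image into a 16 x Npix matrix, row-major element order
vec_mueller_image <- function(img) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img)
  npix <- d[1] * d[2]
  V <- matrix(0, 16L, npix)
  r <- 0L
  for (i in 1:4) for (j in 1:4) {
    r <- r + 1L
    V[r, ] <- as.vector(img[, , i, j])
  }
  V
}

unvec_mueller_image <- function(V, H, W) {
  arr <- array(0, c(H, W, 4L, 4L))
  r <- 0L
  for (i in 1:4) for (j in 1:4) {
    r <- r + 1L
    arr[, , i, j] <- matrix(V[r, ], H, W)
  }
  mueller_image(arr)
}

#' Per-pixel Mueller matrix image
#'
#' Container for an H x W grid of 4x4 Mueller matrices, stored as an
#' `H x W x 4 x 4` array. `img[h, w, i, j]` is element m_ij (1-based, as in
#' all user-facing element names) of pixel (h, w).
#'
#' @param data Either an `H x W x 4 x 4` array, or a single 4x4 matrix to be
#'   replicated over `shape`.
#' @param shape Length-2 integer `c(H, W)`, used when `data` is 4x4.
#' @return An object of classes `mueller_image` and `array`.
#' @export
#' @examples
#' mueller_image(linear_retarder(90, 30), shape = c(8, 8))
mueller_image <- function(data, shape = NULL) {
  if (is.matrix(data) && all(dim(data) == c(4L, 4L))) {
    stopifnot(!is.null(shape), length(shape) == 2L)
    H <- as.integer(shape[1]); W <- as.integer(shape[2])
    arr <- array(rep(as.vector(data), each = H * W), c(H, W, 4L, 4L))
  } else {
    arr <- data
    stopifnot(is.array(arr), length(dim(arr)) == 4L,
              all(dim(arr)[3:4] == c(4L, 4L)))
  }
  structure(arr, class = c("mueller_image", "array"))
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<mueller_image %d x %d pixels>\n", d[1], d[2]))
  cat("mean matrix (m11-normalized):\n")
  mu <- apply(x, c(3, 4), mean)
  print(round(mu / mu[1, 1], 4))
  invisible(x)
}

#' Extract one pixel's Mueller matrix
#' @param img A [mueller_image()].
#' @param h,w Pixel row/column (1-based).
#' @return A 4x4 matrix.
#' @export
pixel_matrix <- function(img, h, w) {
  stopifnot(inherits(img, "mueller_image"))
  matrix(img[h, w, , ], 4L, 4L)
}

#' Normalize every pixel of a Mueller image to m11 = 1
#' @param img A [mueller_image()].
#' @return A [mueller_image()] with `m11 = 1` everywhere.
#' @export
normalize_mueller_image <- function(img) {
  stopifnot(inherits(img, "mueller_image"))
  m11 <- img[, , 1L, 1L]
  if (any(!is.finite(m11)) || any(m11 <= 0))
    stop("every pixel must have m11 > 0")
  arr <- unclass(img)
  for (i in 1:4) for (j in 1:4) arr[, , i, j] <- arr[, , i, j] / m11
  mueller_image(arr)
}

#' Simulate the 30-frame intensity stack for a sample
#'
#' Per pixel and frame, the detected intensity is
#' `psa_row(k) %*% M %*% psg_state(k)`, optionally perturbed by zero-mean
#' Gaussian noise with standard deviation `noise_sd` relative to each
#' intensity (clipped at zero).
#'
#' @param sample A [mueller_image()].
#' @param protocol An [acquisition_protocol()].
#' @param noise_sd Relative intensity noise SD (e.g. `0.002` for 0.2%).
#' @param seed Optional integer seed for reproducible noise.
#' @return An `intensity_stack`: array `n_frames x H x W` with the protocol
#'   attached as attribute `protocol`.
#' @export
simulate_stack <- function(sample, protocol = acquisition_protocol(),
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(sample, "mueller_image"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a nonnegative scalar")
  d <- dim(sample)
  A <- design_matrix(protocol)
  I <- A %*% vec_mueller_image(sample)       # n_frames x Npix
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I * (1 + matrix(rnorm(length(I), sd = noise_sd), nrow(I), ncol(I)))
    I[I < 0] <- 0
  }
  structure(array(I, c(protocol$n_frames, d[1], d[2])),
            protocol = protocol,
            class = c("intensity_stack", "array"))
}

#' Reconstruct a Mueller image from an intensity stack
#'
#' Per-pixel least-squares inversion of the linear system
#' `I = A %*% vec(M)` with `A` the protocol's [design_matrix()]. On the
#' evenly stepped 30-frame protocol this is mathematically equivalent to the
#' classical Fourier-coefficient reconstruction; a noise-free round trip
#' recovers the sample matrix to better than 1e-9 per element.
#'
#' @param stack An `intensity_stack` from [simulate_stack()] (or read from
#'   disk), frames x H x W.
#' @param protocol The protocol used for acquisition; defaults to the one
#'   attached to `stack`.
#' @return A [mueller_image()] (unnormalized; overall gain in m11).
#' @export
reconstruct_mueller <- function(stack, protocol = attr(stack, "protocol")) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (is.null(protocol)) protocol <- acquisition_protocol()
  d <- dim(stack)
  if (d[1] != protocol$n_frames)
    stop("stack has ", d[1], " frames but protocol expects ",
         protocol$n_frames)
  A <- design_matrix(protocol)
  rk <- qr(A)$rank
  if (rk < 16L)
    stop("acquisition protocol is rank-deficient: design matrix rank ", rk,
         " < 16; Mueller matrix not identifiable")
  sv <- svd(A)
  Ainv <- sv$v %*% (t(sv$u) / sv$d)          # pseudoinverse, 16 x n_frames
  I <- matrix(stack, d[1], d[2] * d[3])
  unvec_mueller_image(Ainv %*% I, d[2], d[3])
}

#' Air-calibration error of a reconstructed empty-path image
#'
#' For an acquisition of air (no sample) the true Mueller matrix is the
#' identity; the calibration figure of merit is the maximum over pixels and
#' elements of `|mij - delta_ij|` after m11 normalization.
#'
#' @param M A [mueller_image()] (normalized internally).
#' @return A nonnegative scalar.
#' @export
air_calibration_error <- function(M) {
  M <- normalize_mueller_image(M)
  tgt <- diag(4)
  err <- 0
  for (i in 1:4) for (j in 1:4)
    err <- max(err, max(abs(M[, , i, j] - tgt[i, j])))
  err
}
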