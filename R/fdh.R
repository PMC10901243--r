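# Axial (180-degree periodic) frequency distribution histograms and the
# bimodal fast-axis statistics built on them: circular peak finding, the
# angular FWHM beta, classification of theta peaks into the
# intrinsic-birefringence peak (theta_b) and the form-birefringence peak
# (theta_c) using the diattenuation azimuth alphaP, and the share
# gamma = peak(theta_b) / (peak(theta_b) + peak(theta_c)).

#' Axial distance between two orientation angles
#'
#' Smallest rotation taking one axis onto the other on the 180-degree
#' periodic domain; always in `[0, 90]`.
#'
#' @param a,b Angles in degrees (vectorized).
#' @return Axial distances in degrees.
#' @export
#' @examples
#' axial_distance(170, 20)   # 30, not 150
axial_distance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), all(is.finite(a)), all(is.finite(b)))
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Frequency distribution histogram on the axial domain
#'
#' Bins orientation angles (reduced modulo 180) into equal-width bins
#' covering `[0, 180)` and normalizes to unit total mass. `NA` angles
#' (masked pixels) are dropped; the retained count is recorded so coverage
#' can be reported.
#'
#' @param angles Numeric vector of angles in degrees (NAs allowed).
#' @param bin_width Bin width in degrees; must divide 180.
#' @return An object of class `axial_fdh`: list with `bin_width`,
#'   `bin_centers`, `mass` (sums to 1), `n_samples`.
#' @export
#' @examples
#' fdh <- build_fdh(c(44.7, 45.2, 45.0, 134.9), bin_width = 1)
build_fdh <- function(angles, bin_width = 1) {
  stopifnot(is.numeric(angles))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0 ||
      abs(180 / bin_width - round(180 / bin_width)) > 1e-9)
    stop("`bin_width` must be a positive divisor of 180 degrees")
  a <- angles[!is.na(angles)]
  if (length(a) == 0L) stop("no unmasked angles to histogram")
  if (any(!is.finite(a))) stop("angles must be finite or NA")
  a <- a %% 180
  nb <- as.integer(round(180 / bin_width))
  idx <- pmin(floor(a / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_width = bin_width,
                 bin_centers = (seq_len(nb) - 0.5) * bin_width,
                 mass = counts / length(a),
                 n_samples = length(a)),
            class = "axial_fdh")
}

#' @export
print.axial_fdh <- function(x, ...) {
  cat(sprintf("<axial_fdh: %d bins of %g deg, n = %d>\n",
              length(x$mass), x$bin_width, x$n_samples))
  invisible(x)
}

#' Circular mean orientation of an FDH
#'
#' Mean of the doubled angles (the standard axial-data device), mapped back
#' to `[0, 180)`.
#'
#' @param fdh An [build_fdh()] histogram.
#' @return Angle in degrees.
#' @export
fdh_circular_mean <- function(fdh) {
  stopifnot(inherits(fdh, "axial_fdh"))
  th2 <- deg2rad(2 * fdh$bin_centers)
  wrap_axial(0.5 * atan2(sum(fdh$mass * sin(th2)),
                         sum(fdh$mass * cos(th2))) * 180 / pi)
}

# circular topographic prominence of bin i: height minus the higher of the
# two base valleys (minimum encountered walking each way until a strictly
# higher bin, or all the way around for a global maximum)
circular_prominence <- function(mass, i) {
  nb <- length(mass)
  base <- c(NA_real_, NA_real_)
  for (s in 1:2) {
    step <- if (s == 1) -1L else 1L
    lo <- mass[i]
    j <- i
    for (k in seq_len(nb - 1L)) {
      j <- ((j - 1L + step) %% nb) + 1L
      if (mass[j] > mass[i]) break
      lo <- min(lo, mass[j])
    }
    base[s] <- lo
  }
  mass[i] - max(base)
}

#' Find peaks of an axial histogram
#'
#' Wraparound-aware local maxima, greedily selected in order of decreasing
#' mass subject to a minimum pairwise axial separation and a minimum
#' circular prominence. Each accepted peak is annotated with its angular
#' FWHM via [beta_width()]. A flat histogram has no prominent maxima and
#' yields an empty peak set (modality 0).
#'
#' @param fdh An [build_fdh()] histogram.
#' @param max_peaks Maximum number of peaks returned.
#' @param min_separation Minimum axial distance between accepted peaks
#'   (degrees).
#' @param min_prominence Minimum circular prominence, as a fraction of the
#'   maximum bin mass.
#' @return An object of class `peak_set`: data.frame with columns `angle`
#'   (bin center, degrees), `density` (probability mass of the peak bin)
#'   and `beta` (FWHM in degrees, possibly NA), sorted by density
#'   descending.
#' @export
find_peaks <- function(fdh, max_peaks = 4L, min_separation = 20,
                       min_prominence = 0.1) {
  stopifnot(inherits(fdh, "axial_fdh"))
  mass <- fdh$mass
  nb <- length(mass)
  lft <- mass[c(nb, seq_len(nb - 1L))]
  rgt <- mass[c(seq_len(nb)[-1L], 1L)]
  cand <- which(mass >= lft & mass >= rgt & mass > 0)
  # drop plateau duplicates: keep the first bin of any run of equal maxima
  if (length(cand) > 1L) {
    keep <- rep(TRUE, length(cand))
    for (q in seq_along(cand)) {
      prev <- ((cand[q] - 2L) %% nb) + 1L
      if (prev %in% cand && mass[prev] == mass[cand[q]]) keep[q] <- FALSE
    }
    if (!all(keep) && any(keep)) cand <- cand[keep]
  }
  thr <- min_prominence * max(mass)
  cand <- cand[vapply(cand, function(i) circular_prominence(mass, i),
                      0) >= thr & thr > 0]
  cand <- cand[order(mass[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in cand) {
    if (length(sel) >= max_peaks) break
    if (all(axial_distance(fdh$bin_centers[i],
                           fdh$bin_centers[sel]) >= min_separation) ||
        length(sel) == 0L)
      sel <- c(sel, i)
  }
  res <- data.frame(angle = fdh$bin_centers[sel], density = mass[sel],
                    beta = vapply(fdh$bin_centers[sel],
                                  function(a) beta_width(fdh, a), 0))
  class(res) <- c("peak_set", "data.frame")
  res
}

#' Angular FWHM (beta) of an FDH peak
#'
#' Width of the peak at half its maximum: from the peak bin, walk
#' circularly left and right to the first crossings of half the peak mass,
#' interpolating linearly between bins, and return the angular span between
#' the two crossings. `NA` (with a warning) if a crossing is not found
#' within 90 degrees on a side.
#'
#' @param fdh An [build_fdh()] histogram.
#' @param peak_angle Angle (degrees) of the peak; snapped to the nearest
#'   bin center.
#' @return FWHM in degrees, or `NA_real_`.
#' @export
beta_width <- function(fdh, peak_angle) {
  stopifnot(inherits(fdh, "axial_fdh"), is.numeric(peak_angle),
            length(peak_angle) == 1L, is.finite(peak_angle))
  mass <- fdh$mass
  nb <- length(mass)
  bw <- fdh$bin_width
  i0 <- which.min(axial_distance(fdh$bin_centers, peak_angle))
  half <- mass[i0] / 2
  if (half <= 0) return(NA_real_)
  max_steps <- min(nb - 1L, as.integer(ceiling(90 / bw)))
  span <- c(NA_real_, NA_real_)
  for (s in 1:2) {
    step <- if (s == 1) -1L else 1L
    j_prev <- i0
    found <- FALSE
    for (k in seq_len(max_steps)) {
      j <- ((j_prev - 1L + step) %% nb) + 1L
      if (mass[j] < half) {
        frac <- (mass[j_prev] - half) / (mass[j_prev] - mass[j])
        span[s] <- (k - 1L + frac) * bw
        found <- TRUE
        break
      }
      j_prev <- j
    }
    if (!found) {
      warning("half-maximum crossing not found within 90 degrees of peak")
      return(NA_real_)
    }
  }
  sum(span)
}

#' Share of the intrinsic-birefringence peak
#'
#' `gamma = peak_b / (peak_b + peak_c)`: the statistical weight of the
#' intrinsic-birefringence peak within the bimodal pair.
#'
#' @param peak_b Probability mass at the intrinsic-birefringence peak.
#' @param peak_c Probability mass at the form-birefringence peak.
#' @return Scalar in `[0, 1]`.
#' @export
gamma_share <- function(peak_b, peak_c) {
  stopifnot(is.numeric(peak_b), is.numeric(peak_c),
            length(peak_b) == 1L, length(peak_c) == 1L)
  if (peak_b < 0 || peak_c < 0) stop("peak masses must be nonnegative")
  if (peak_b + peak_c == 0) stop("undefined share: both peak masses are zero")
  peak_b / (peak_b + peak_c)
}

#' Classify theta peaks into intrinsic and form birefringence
#'
#' The diattenuation azimuth alphaP is set by cylindrical scattering alone
#' and always peaks perpendicular to the fiber long axis, so the fiber axis
#' is the alphaP peak + 90 degrees. The fast-axis peak of form birefringence
#' (`theta_c`) is parallel to the fiber axis; the intrinsic-birefringence
#' peak (`theta_b`) is perpendicular to it. Classification is refused (with
#' a modality report) when alphaP is not unimodal or theta has more than
#' two peaks - the multi-layer stacking regimes where no single fiber axis
#' exists.
#'
#' @param theta_peaks A [find_peaks()] result for the theta FDH.
#' @param alphaP_fdh The alphaP [build_fdh()] histogram.
#' @param ... Peak-finding options passed to [find_peaks()] for alphaP.
#' @return An object of class `bimodal_summary`: list with `theta_b`,
#'   `theta_c`, `peak_b`, `peak_c`, `beta_b`, `beta_c`, `gamma`,
#'   `fiber_axis`, `modality` (number of theta peaks), `alphaP_modality`,
#'   `refused` (logical) and `reason`. With a single theta peak, `gamma`
#'   is 0 or 1 according to which class the lone peak falls into
#'   (axial distance threshold 45 degrees).
#' @export
classify_peaks <- function(theta_peaks, alphaP_fdh, ...) {
  stopifnot(inherits(theta_peaks, "peak_set"), inherits(alphaP_fdh, "axial_fdh"))
  ap_peaks <- find_peaks(alphaP_fdh, ...)
  out <- list(theta_b = NA_real_, theta_c = NA_real_,
              peak_b = NA_real_, peak_c = NA_real_,
              beta_b = NA_real_, beta_c = NA_real_,
              gamma = NA_real_, fiber_axis = NA_real_,
              modality = nrow(theta_peaks),
              alphaP_modality = nrow(ap_peaks),
              refused = FALSE, reason = "")
  refuse <- function(reason) {
    out$refused <- TRUE
    out$reason <- reason
    structure(out, class = "bimodal_summary")
  }
  if (nrow(ap_peaks) != 1L)
    return(refuse(sprintf(
      "alphaP FDH has %d peaks; need exactly one dominant diattenuation azimuth",
      nrow(ap_peaks))))
  out$fiber_axis <- wrap_axial(ap_peaks$angle[1] + 90)
  if (nrow(theta_peaks) == 0L)
    return(refuse("theta FDH has no prominent peak"))
  if (nrow(theta_peaks) > 2L)
    return(refuse(sprintf(
      "theta FDH has %d peaks; multi-orientation stacking, no bimodal classification",
      nrow(theta_peaks))))
  dist_fib <- axial_distance(theta_peaks$angle, out$fiber_axis)
  if (nrow(theta_peaks) == 2L) {
    if (abs(dist_fib[1] - dist_fib[2]) < 1e-9)
      return(refuse("both theta peaks equidistant from the fiber axis"))
    ic <- which.min(dist_fib)   # form peak: parallel to fiber axis
    ib <- 3L - ic
    out$theta_c <- theta_peaks$angle[ic]; out$peak_c <- theta_peaks$density[ic]
    out$beta_c <- theta_peaks$beta[ic]
    out$theta_b <- theta_peaks$angle[ib]; out$peak_b <- theta_peaks$density[ib]
    out$beta_b <- theta_peaks$beta[ib]
    out$gamma <- gamma_share(out$peak_b, out$peak_c)
  } else {
    if (dist_fib[1] < 45) {     # lone peak along fiber: pure form birefringence
      out$theta_c <- theta_peaks$angle[1]; out$peak_c <- theta_peaks$density[1]
      out$beta_c <- theta_peaks$beta[1]
      out$gamma <- 0
    } else {                    # lone peak across fiber: pure intrinsic
      out$theta_b <- theta_peaks$angle[1]; out$peak_b <- theta_peaks$density[1]
      out$beta_b <- theta_peaks$beta[1]
      out$gamma <- 1
    }
  }
  structure(out, class = "bimodal_summary")
}

#' @export
print.bimodal_summary <- function(x, ...) {
  if (x$refused) {
    cat("<bimodal_summary: classification refused>\n  ", x$reason, "\n")
    return(invisible(x))
  }
  cat("<bimodal_summary>\n")
  cat(sprintf("  fiber axis      %6.1f deg (from alphaP peak + 90)\n",
              x$fiber_axis))
  cat(sprintf("  theta_c (form)  %6.1f deg  peak %.4f  beta %5.2f\n",
              x$theta_c, x$peak_c, x$beta_c))
  cat(sprintf("  theta_b (intr.) %6.1f deg  peak %.4f  beta %5.2f\n",
              x$theta_b, x$peak_b, x$beta_b))
  cat(sprintf("  gamma           %6.3f\n", x$gamma))
  invisible(x)
}
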