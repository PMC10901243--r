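# Synthetic Mueller-image phantoms with ground truth. The physical coupling
# of cylindrical scattering and lattice birefringence inside one fiber is
# modeled phenomenologically as a per-pixel two-component fast-axis mixture:
# with probability mixture_w the pixel's retarder axis is perpendicular to
# the fiber (intrinsic birefringence), otherwise parallel (form
# birefringence from aligned-cylinder scattering). Diattenuation from
# cylinder scattering always has its transmission axis perpendicular to the
# fiber. This reproduces the histogram-level phenomenology (bimodal theta,
# unimodal alphaP perpendicular to the fiber) without radiative transfer.

LAYER_KINDS <- c("nonbirefringent_cylinder", "pure_birefringent",
                 "birefringent_cylinder")

#' Specification of a single phantom layer
#'
#' @param kind One of `"nonbirefringent_cylinder"` (e.g. glass fiber:
#'   scattering only, fast axis parallel to the fiber),
#'   `"pure_birefringent"` (e.g. air-dried tendon: intrinsic birefringence
#'   only, fast axis perpendicular to the fiber, no diattenuation or
#'   depolarization), or `"birefringent_cylinder"` (e.g. silk: both, giving
#'   the cross-perpendicular bimodal fast-axis distribution).
#' @param fiber_axis Fiber long-axis orientation in degrees.
#' @param delta_form Retardance (degrees) of the form-birefringence
#'   component (axis parallel to the fiber).
#' @param delta_intrinsic Retardance (degrees) of the intrinsic component
#'   (axis perpendicular to the fiber).
#' @param D Diattenuation magnitude of cylinder scattering (transmission
#'   axis perpendicular to the fiber).
#' @param depol Length-3 depolarization coefficients `(d1, d2, d3)`.
#' @param sigma_axis Angular noise SD (degrees) on the per-pixel axis draw.
#' @param mixture_w Probability a pixel draws the intrinsic component
#'   (birefringent_cylinder only); the generative twin of the observable
#'   share gamma.
#' @return An object of class `layer_spec`.
#' @export
#' @examples
#' silk_spec(fiber_axis = 0, mixture_w = 0.6)
layer_spec <- function(kind, fiber_axis = 0, delta_form = 30,
                       delta_intrinsic = 30, D = 0.1,
                       depol = c(0.9, 0.9, 0.8), sigma_axis = 8,
                       mixture_w = 0.5) {
  kind <- match.arg(kind, LAYER_KINDS)
  stopifnot(is.finite(fiber_axis), delta_form >= 0, delta_intrinsic >= 0,
            D >= 0, D <= 1, length(depol) == 3L, all(depol >= 0 & depol <= 1),
            sigma_axis >= 0, mixture_w >= 0, mixture_w <= 1)
  if (kind == "nonbirefringent_cylinder" && delta_intrinsic != 0)
    stop("a nonbirefringent cylinder layer must have delta_intrinsic = 0")
  if (kind == "pure_birefringent" && (D > 1e-6 || any(depol < 1 - 1e-6)))
    stop("a pure birefringent layer must have D ~ 0 and depol ~ (1,1,1)")
  structure(list(kind = kind, fiber_axis = wrap_axial(fiber_axis),
                 delta_form = delta_form, delta_intrinsic = delta_intrinsic,
                 D = D, depol = depol, sigma_axis = sigma_axis,
                 mixture_w = mixture_w),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
glass_fiber_spec <- function(fiber_axis = 0, delta_form = 30, D = 0.1,
                             depol = c(0.95, 0.95, 0.9), sigma_axis = 5) {
  layer_spec("nonbirefringent_cylinder", fiber_axis, delta_form,
             delta_intrinsic = 0, D = D, depol = depol,
             sigma_axis = sigma_axis, mixture_w = 0)
}

#' @rdname layer_spec
#' @export
dried_tendon_spec <- function(fiber_axis = 0, delta_intrinsic = 40,
                              sigma_axis = 5) {
  layer_spec("pure_birefringent", fiber_axis, delta_form = 0,
             delta_intrinsic = delta_intrinsic, D = 0, depol = c(1, 1, 1),
             sigma_axis = sigma_axis, mixture_w = 1)
}

#' @rdname layer_spec
#' @export
silk_spec <- function(fiber_axis = 0, delta_form = 30, delta_intrinsic = 30,
                      D = 0.1, depol = c(0.9, 0.9, 0.8), sigma_axis = 8,
                      mixture_w = 0.5) {
  layer_spec("birefringent_cylinder", fiber_axis, delta_form,
             delta_intrinsic, D, depol, sigma_axis, mixture_w)
}

#' Draw one pixel's Mueller matrix for a layer
#'
#' Per-pixel matrix `depolarizer %*% retarder %*% diattenuator` with the
#' diattenuation axis fixed perpendicular to the fiber and the retarder
#' axis drawn from the layer's kind-specific distribution (see
#' [layer_spec()]) using the current RNG state. Call `set.seed()` upstream
#' for reproducibility.
#'
#' @param spec A [layer_spec()].
#' @return A 4x4 Mueller matrix; attribute `axis` records the drawn
#'   retarder axis and `component` which mixture branch was taken
#'   (`"form"` or `"intrinsic"`).
#' @export
layer_matrix <- function(spec) {
  stopifnot(inherits(spec, "layer_spec"))
  noise <- if (spec$sigma_axis > 0) rnorm(1, 0, spec$sigma_axis) else 0
  if (spec$kind == "nonbirefringent_cylinder") {
    comp <- "form"
  } else if (spec$kind == "pure_birefringent") {
    comp <- "intrinsic"
  } else {
    comp <- if (runif(1) < spec$mixture_w) "intrinsic" else "form"
  }
  if (comp == "intrinsic") {
    axis <- wrap_axial(spec$fiber_axis + 90 + noise)
    delta <- spec$delta_intrinsic
  } else {
    axis <- wrap_axial(spec$fiber_axis + noise)
    delta <- spec$delta_form
  }
  M <- depolarizer_diag(spec$depol) %*%
    linear_retarder(delta, axis) %*%
    linear_diattenuator(spec$D, wrap_axial(spec$fiber_axis + 90))
  attr(M, "axis") <- axis
  attr(M, "component") <- comp
  M
}

#' Generate a phantom Mueller image with ground truth
#'
#' Each pixel belongs to one region; the layers active in its region are
#' drawn independently with [layer_matrix()] and composed in propagation
#' order with [compose_layers()].
#'
#' @param layers List of [layer_spec()] objects, first-encountered layer
#'   first.
#' @param shape Length-2 integer `c(H, W)`.
#' @param regions Optional integer H x W matrix of region ids (1-based);
#'   default: one region covering the image.
#' @param region_layers Optional list mapping region id to the integer
#'   indices of `layers` active there; default: all layers everywhere.
#'   Every region id appearing in `regions` must be covered.
#' @param seed Optional integer seed.
#' @return List with `image` (a [mueller_image()]) and `truth` (class
#'   `phantom_truth`: the layer specs, regions, region-layer map, per-region
#'   fiber axis and mixture weight, and the seed).
#' @export
#' @examples
#' ph <- generate_phantom(list(silk_spec(mixture_w = 0.6)),
#'                        shape = c(16, 16), seed = 1)
generate_phantom <- function(layers, shape = c(128L, 128L), regions = NULL,
                             region_layers = NULL, seed = NULL) {
  stopifnot(is.list(layers), length(layers) > 0L,
            all(vapply(layers, inherits, TRUE, "layer_spec")))
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (is.null(regions)) regions <- matrix(1L, H, W)
  stopifnot(is.matrix(regions), all(dim(regions) == c(H, W)))
  if (is.null(region_layers))
    region_layers <- stats::setNames(list(seq_along(layers)), "1")
  ids <- sort(unique(as.integer(regions)))
  if (any(is.na(ids)) || !all(as.character(ids) %in% names(region_layers)))
    stop("uncovered pixels: every region id must have an entry in `region_layers`")
  for (rl in region_layers)
    stopifnot(all(rl %in% seq_along(layers)), length(rl) > 0L)
  if (!is.null(seed)) set.seed(seed)
  arr <- array(0, c(H, W, 4L, 4L))
  for (h in seq_len(H)) for (w in seq_len(W)) {
    active <- region_layers[[as.character(regions[h, w])]]
    M <- layer_matrix(layers[[active[1L]]])
    if (length(active) > 1L)
      for (k in active[-1L]) M <- layer_matrix(layers[[k]]) %*% M
    arr[h, w, , ] <- M
  }
  truth <- structure(list(
    layers = layers, regions = regions, region_layers = region_layers,
    fiber_axis = vapply(layers, `[[`, 0, "fiber_axis"),
    mixture_w = vapply(layers, `[[`, 0, "mixture_w"),
    shape = c(H, W), seed = seed), class = "phantom_truth")
  list(image = mueller_image(arr), truth = truth)
}

#' Silk thickness series: stacking more birefringent-cylinder layers
#'
#' Emulates winding additional silk layers: the phantom with L layers uses
#' depolarization coefficients raised to the L-th power (depolarization
#' accumulates multiplicatively with thickness) and a geometrically
#' decaying intrinsic share `w_L = w_1 * rho^(L - 1)` (multiple scattering
#' progressively buries the intrinsic-birefringence signal of individual
#' fibers). The schedule is recorded in each truth object.
#'
#' @param n_layers Maximum number of layers; phantoms for L = 1..n_layers.
#' @param base_spec A `birefringent_cylinder` [layer_spec()]; its
#'   `mixture_w` is `w_1`.
#' @param rho Geometric decay of the intrinsic share per added layer
#'   (`0 < rho < 1`).
#' @param shape,seed As in [generate_phantom()]; seeds `seed + L - 1` are
#'   used per element.
#' @return List of length `n_layers` of [generate_phantom()] results; each
#'   truth gains fields `n_layers` and `scheduled_w`.
#' @export
silk_layer_series <- function(n_layers, base_spec = silk_spec(),
                              rho = 0.8, shape = c(64L, 64L), seed = 1L) {
  stopifnot(inherits(base_spec, "layer_spec"),
            base_spec$kind == "birefringent_cylinder",
            n_layers >= 1, rho > 0, rho < 1)
  out <- vector("list", n_layers)
  for (L in seq_len(n_layers)) {
    wL <- base_spec$mixture_w * rho^(L - 1)
    spec <- layer_spec("birefringent_cylinder", base_spec$fiber_axis,
                       base_spec$delta_form, base_spec$delta_intrinsic,
                       base_spec$D, base_spec$depol^L,
                       base_spec$sigma_axis, wL)
    ph <- generate_phantom(list(spec), shape = shape, seed = seed + L - 1L)
    ph$truth$n_layers <- L
    ph$truth$scheduled_w <- wL
    out[[L]] <- ph
  }
  out
}

STRETCH_STATES <- c("NS", "CS1", "CS2", "LS1", "LS2")

#' Muscle stretching series: transverse vs. longitudinal stretch
#'
#' Five-state sweep of the intrinsic share emulating skeletal-muscle
#' stretching: transverse stretching (CS1, CS2) packs more overlapping
#' filaments per unit length, strengthening form birefringence (lower w);
#' longitudinal stretching (LS1, LS2) tightens the molecular lattice,
#' strengthening intrinsic birefringence (higher w). NS is the unstretched
#' reference.
#'
#' @param base_spec A `birefringent_cylinder` [layer_spec()]; its
#'   `mixture_w` is used for NS.
#' @param w_schedule Named numeric of scheduled intrinsic shares for the
#'   five states; must be monotone decreasing NS -> CS2 and increasing
#'   NS -> LS2.
#' @param shape,seed As in [generate_phantom()].
#' @return Named list (NS, CS1, CS2, LS1, LS2) of [generate_phantom()]
#'   results; each truth gains `state` and `scheduled_w`.
#' @export
stretch_series <- function(base_spec = silk_spec(mixture_w = 0.5),
                           w_schedule = c(NS = base_spec$mixture_w,
                                          CS1 = base_spec$mixture_w - 0.12,
                                          CS2 = base_spec$mixture_w - 0.24,
                                          LS1 = base_spec$mixture_w + 0.12,
                                          LS2 = base_spec$mixture_w + 0.24),
                           shape = c(64L, 64L), seed = 1L) {
  stopifnot(inherits(base_spec, "layer_spec"),
            base_spec$kind == "birefringent_cylinder",
            setequal(names(w_schedule), STRETCH_STATES),
            all(w_schedule >= 0 & w_schedule <= 1))
  if (!(w_schedule["CS2"] < w_schedule["CS1"] &&
        w_schedule["CS1"] < w_schedule["NS"] &&
        w_schedule["NS"] < w_schedule["LS1"] &&
        w_schedule["LS1"] < w_schedule["LS2"]))
    stop("w_schedule must decrease NS -> CS2 and increase NS -> LS2")
  out <- vector("list", 5L)
  names(out) <- STRETCH_STATES
  for (k in seq_along(STRETCH_STATES)) {
    st <- STRETCH_STATES[k]
    spec <- layer_spec("birefringent_cylinder", base_spec$fiber_axis,
                       base_spec$delta_form, base_spec$delta_intrinsic,
                       base_spec$D, base_spec$depol, base_spec$sigma_axis,
                       unname(w_schedule[st]))
    ph <- generate_phantom(list(spec), shape = shape, seed = seed + k - 1L)
    ph$truth$state <- st
    ph$truth$scheduled_w <- unname(w_schedule[st])
    out[[st]] <- ph
  }
  out
}

#' Two-layer crossed-fiber phantom with an overlap region
#'
#' Geometry of the serial-combination (SCM) stacking experiment: two fiber
#' layers at different orientations laid out in vertical bands, with a
#' central band where light traverses both. The whole-image theta FDH then
#' shows three peaks (each single layer plus the bisector orientation of
#' the overlap).
#'
#' @param spec1,spec2 [layer_spec()]s of the two layers.
#' @param shape Length-2 `c(H, W)`.
#' @param seed Optional integer seed.
#' @return As [generate_phantom()]; region 1 = layer 1 only (left third),
#'   region 2 = overlap (middle third), region 3 = layer 2 only.
#' @export
crossed_layers_phantom <- function(spec1 = glass_fiber_spec(fiber_axis = 0),
                                   spec2 = glass_fiber_spec(fiber_axis = 60),
                                   shape = c(128L, 128L), seed = NULL) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  b1 <- floor(W / 3); b2 <- floor(2 * W / 3)
  regions <- matrix(3L, H, W)
  regions[, seq_len(b1)] <- 1L
  regions[, (b1 + 1):b2] <- 2L
  generate_phantom(list(spec1, spec2), shape = c(H, W), regions = regions,
                   region_layers = list(`1` = 1L, `2` = c(1L, 2L), `3` = 2L),
                   seed = seed)
}
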