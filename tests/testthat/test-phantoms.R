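test_that("layer specs enforce kind consistency", {
  expect_error(layer_spec("nonbirefringent_cylinder", delta_intrinsic = 10),
               "delta_intrinsic")
  expect_error(layer_spec("pure_birefringent", D = 0.2), "pure birefringent")
  expect_s3_class(silk_spec(mixture_w = 0.3), "layer_spec")
  expect_equal(glass_fiber_spec(fiber_axis = 200)$fiber_axis, 20)
})

test_that("single-pixel layer draws follow the orientation rules", {
  set.seed(81)
  # glass: fast axis parallel to the fiber, diattenuation axis across it
  g <- glass_fiber_spec(fiber_axis = 0, sigma_axis = 0)
  M <- layer_matrix(g)
  expect_equal(attr(M, "axis"), 0)
  expect_lt(axial_distance(retardance_theta(lu_chipman(M)$M_R), 0), 1e-6)
  expect_lt(axial_distance(alpha_p(M), 90), 1e-6)
  # air-dried tendon: fast axis perpendicular to the fiber
  t <- dried_tendon_spec(fiber_axis = 0, sigma_axis = 0)
  Mt <- layer_matrix(t)
  expect_equal(attr(Mt, "axis"), 90)
  expect_lt(axial_distance(retardance_theta(lu_chipman(Mt)$M_R), 90), 1e-6)
  # silk with w = 0.5 and no angular noise: axes exactly 0 or 90,
  # balanced between components
  s <- silk_spec(fiber_axis = 0, sigma_axis = 0, mixture_w = 0.5)
  axes <- replicate(10000, attr(layer_matrix(s), "axis"))
  expect_setequal(unique(axes), c(0, 90))
  expect_gt(chisq.test(table(axes))$p.value, 1e-3)
})

test_that("phantom generation is deterministic and validates coverage", {
  ph1 <- generate_phantom(list(silk_spec()), shape = c(8, 8), seed = 5)
  ph2 <- generate_phantom(list(silk_spec()), shape = c(8, 8), seed = 5)
  expect_identical(unclass(ph1$image), unclass(ph2$image))
  ph3 <- generate_phantom(list(silk_spec()), shape = c(8, 8), seed = 6)
  expect_false(identical(unclass(ph1$image), unclass(ph3$image)))
  regions <- matrix(1L, 4, 4); regions[1, 1] <- 2L
  expect_error(generate_phantom(list(silk_spec()), shape = c(4, 4),
                                regions = regions,
                                region_layers = list(`1` = 1L)),
               "uncovered")
})

test_that("single glass layer gives a unimodal theta FDH at the fiber axis", {
  ph <- generate_phantom(list(glass_fiber_spec(fiber_axis = 40)),
                         shape = c(48, 48), seed = 9)
  maps <- decompose_image(ph$image)
  pk <- find_peaks(build_fdh(as.vector(maps$theta), 1))
  expect_equal(nrow(pk), 1L)
  expect_lt(axial_distance(pk$angle, 40), 2)
  ap <- find_peaks(build_fdh(as.vector(maps$alphaP), 1))
  expect_equal(nrow(ap), 1L)
  expect_lt(axial_distance(ap$angle, 130), 2)
})

test_that("degenerate limits behave as constructed", {
  # zero angular noise: exactly two occupied theta bins
  ph <- generate_phantom(list(silk_spec(sigma_axis = 0, mixture_w = 0.5)),
                         shape = c(24, 24), seed = 10)
  maps <- decompose_image(ph$image)
  fdh <- build_fdh(as.vector(maps$theta), 1)
  expect_equal(sum(fdh$mass > 0), 2L)
  # no diattenuation: alphaP masked everywhere
  ph0 <- generate_phantom(list(silk_spec(D = 0)), shape = c(8, 8), seed = 11)
  maps0 <- decompose_image(ph0$image)
  expect_true(all(is.na(maps0$alphaP)))
})

test_that("full pipeline recovers phantom ground truth", {
  for (cfg in list(list(w = 0.35, axis = 0), list(w = 0.65, axis = 120))) {
    ph <- generate_phantom(list(silk_spec(fiber_axis = cfg$axis,
                                          mixture_w = cfg$w)),
                           shape = c(96, 96), seed = 12)
    maps <- decompose_image(ph$image)
    s <- classify_peaks(find_peaks(build_fdh(as.vector(maps$theta), 1)),
                        build_fdh(as.vector(maps$alphaP), 1))
    expect_false(s$refused)
    expect_lt(axial_distance(s$fiber_axis, cfg$axis), 2)
    expect_lt(abs(axial_distance(s$theta_b, s$theta_c) - 90), 3)
    expect_lt(abs(s$gamma - cfg$w), 0.05)
  }
})

test_that("silk layer series deepens depolarization and drains gamma", {
  series <- silk_layer_series(4, silk_spec(mixture_w = 0.65),
                              shape = c(48, 48), seed = 13)
  Delta <- gam <- numeric(4)
  for (L in 1:4) {
    maps <- decompose_image(series[[L]]$image)
    Delta[L] <- mean(maps$Delta, na.rm = TRUE)
    s <- classify_peaks(find_peaks(build_fdh(as.vector(maps$theta), 1)),
                        build_fdh(as.vector(maps$alphaP), 1))
    gam[L] <- s$gamma
    # alphaP peak fixed perpendicular to the fiber at every thickness
    ap <- find_peaks(build_fdh(as.vector(maps$alphaP), 1))
    expect_lt(axial_distance(ap$angle[1], 90), 2)
    expect_equal(series[[L]]$truth$scheduled_w, 0.65 * 0.8^(L - 1))
  }
  expect_true(all(diff(Delta) > 0))
  expect_true(all(diff(gam) < 0))
})

test_that("stretch series orders gamma as CS2 < NS < LS2", {
  sw <- stretch_series(silk_spec(mixture_w = 0.5), shape = c(48, 48),
                       seed = 14)
  gam <- sapply(sw, function(ph) {
    maps <- decompose_image(ph$image)
    classify_peaks(find_peaks(build_fdh(as.vector(maps$theta), 1)),
                   build_fdh(as.vector(maps$alphaP), 1))$gamma
  })
  expect_lt(gam["CS2"], gam["NS"])
  expect_lt(gam["NS"], gam["LS2"])
  for (st in names(sw))
    expect_lt(abs(gam[[st]] - sw[[st]]$truth$scheduled_w), 0.08)
  expect_error(stretch_series(silk_spec(mixture_w = 0.5),
                              w_schedule = c(NS = 0.5, CS1 = 0.6, CS2 = 0.3,
                                             LS1 = 0.7, LS2 = 0.8)),
               "monotone|decrease")
})

test_that("crossed glass layers produce the serial-combination geometry", {
  ph <- crossed_layers_phantom(shape = c(36, 36), seed = 15)
  maps <- decompose_image(ph$image)
  # overlap band: equivalent fast axis near the 30-degree bisector
  region_mean <- function(r)
    fdh_circular_mean(build_fdh(maps$theta[ph$truth$regions == r], 1))
  expect_lt(axial_distance(region_mean(2L), 30), 3)
  # single-layer bands keep their own axes
  expect_lt(axial_distance(region_mean(1L), 0), 2)
  expect_lt(axial_distance(region_mean(3L), 60), 2)
})

test_that("stacked silk at 45 degrees defeats bimodal classification", {
  ph <- generate_phantom(list(silk_spec(fiber_axis = 0),
                              silk_spec(fiber_axis = 45)),
                         shape = c(40, 40), seed = 16)
  maps <- decompose_image(ph$image)
  s <- classify_peaks(find_peaks(build_fdh(as.vector(maps$theta), 1)),
                      build_fdh(as.vector(maps$alphaP), 1))
  expect_true(s$refused)
})
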