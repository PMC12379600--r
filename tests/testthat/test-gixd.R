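# Diffraction analysis: unit-cell geometry, indexing round trips, image
# reduction and mixing areas.

test_that("a single untilted peak gives hexagonal packing geometry", {
  cell <- solve_unit_cell(data.frame(q_xy = 1.5, q_z = 0))
  expect_equal(cell$cell_class, "hexagonal")
  d <- 2 * pi / 1.5
  expect_equal(cell$A_chain, 2 * d^2 / sqrt(3), tolerance = 1e-12)
  expect_equal(cell$A_chain, 20.26, tolerance = 1e-3)
  expect_equal(cell$A_pair, 2 * cell$A_chain)
  expect_equal(cell$tilt_deg, 0)
})

test_that("three equal in-plane peaks at the horizon degenerate to hexagonal", {
  pk <- data.frame(q_xy = rep(1.5, 3), q_z = rep(0, 3))
  cell <- solve_unit_cell(pk)
  expect_equal(cell$tilt_deg, 0)
  expect_equal(cell$A_chain, 2 * (2 * pi / 1.5)^2 / sqrt(3), tolerance = 1e-9)
})

test_that("indexing round-trips 50 random cells across all three classes", {
  set.seed(77)
  for (i in 1:50) {
    kind <- sample(c("hex", "nn", "ob"), 1)
    if (kind == "hex") {
      a <- runif(1, 4.6, 5.1)
      truth <- list(a = a, b = a, gamma_deg = 120, tilt_deg = 0,
                    azimuth_deg = 0)
    } else if (kind == "nn") {
      truth <- nn_tilt_cell(runif(1, 4.7, 5.1), runif(1, 112, 119),
                            runif(1, 5, 25))
    } else {
      truth <- list(a = runif(1, 4.7, 5.0), b = runif(1, 4.9, 5.3),
                    gamma_deg = runif(1, 110, 118),
                    tilt_deg = runif(1, 5, 25), azimuth_deg = runif(1, 5, 80))
    }
    pk <- peaks_from_cell(truth$a, truth$b, truth$gamma_deg, truth$tilt_deg,
                          truth$azimuth_deg)
    cell <- solve_unit_cell(pk)
    A_true <- truth$a * truth$b * sin(truth$gamma_deg * pi / 180)
    expect_equal(cell$A_chain, A_true, tolerance = 1e-6)
    expect_equal(cell$tilt_deg, truth$tilt_deg, tolerance = 1e-4)
    # the solved d-spacings reproduce the observed positions
    expect_equal(sort(unname(cell$d_spacings)),
                 sort(rep(2 * pi / pk$q_xy, pk$multiplicity)),
                 tolerance = 1e-9)
  }
})

test_that("tilt geometry: A_xs = A_chain cos t and tilting dilates the cell", {
  expect_equal(23.4 * cos(30 * pi / 180), 20.26, tolerance = 1e-3)
  t1 <- nn_tilt_cell(4.9, 116, 10); t2 <- nn_tilt_cell(4.9, 116, 20)
  c1 <- solve_unit_cell(peaks_from_cell(t1$a, t1$b, t1$gamma_deg, t1$tilt_deg,
                                        t1$azimuth_deg))
  c2 <- solve_unit_cell(peaks_from_cell(t2$a, t2$b, t2$gamma_deg, t2$tilt_deg,
                                        t2$azimuth_deg))
  # same in-plane cell, larger tilt -> smaller cross-section
  expect_equal(c1$A_chain, c2$A_chain, tolerance = 1e-9)
  expect_gt(c1$A_xs, c2$A_xs)
  at <- chain_areas_and_tilt(c2)
  expect_equal(at$A_xs, c2$A_chain * cos(c2$tilt_deg * pi / 180))
  expect_equal(at$A_pair, 2 * c2$A_chain)
})

test_that("inconsistent rod positions raise an indexing error", {
  pk <- peaks_from_cell(4.9, 5.05, 116, 16, 25)
  pk$q_z[2] <- pk$q_z[2] + 0.2
  expect_error(solve_unit_cell(pk), class = "monofilm_indexing_error")
})

test_that("the image pipeline recovers synthetic peaks and cells", {
  # single peak at (1.500, 0) with high SNR
  hex <- list(a = 2 * (2 * pi / 1.5) / sqrt(3), b = 2 * (2 * pi / 1.5) / sqrt(3),
              gamma_deg = 120, tilt_deg = 0, azimuth_deg = 0)
  g <- gen_gixd(hex, seed = 2)
  pk <- reduce_to_bragg_peaks(g$image)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$q_xy, 1.5, tolerance = 2e-3)
  expect_lt(pk$q_z, 0.05)
  cell <- solve_unit_cell(pk)
  expect_equal(cell$A_chain, g$truth$A_chain, tolerance = 1e-2)

  # NN-tilt and oblique maps
  nn <- nn_tilt_cell(4.95, 117, 12)
  gn <- gen_gixd(nn, seed = 3)
  cn <- solve_unit_cell(reduce_to_bragg_peaks(gn$image))
  expect_equal(cn$A_chain, gn$truth$A_chain, tolerance = 0.05)
  expect_equal(cn$tilt_deg, 12, tolerance = 0.3)

  ob <- list(a = 4.9, b = 5.05, gamma_deg = 116, tilt_deg = 16,
             azimuth_deg = 25)
  go <- gen_gixd(ob, seed = 4)
  pko <- reduce_to_bragg_peaks(go$image)
  expect_equal(nrow(pko), 3)
  co <- solve_unit_cell(pko)
  expect_equal(co$A_chain, go$truth$A_chain, tolerance = 0.05)
  expect_equal(co$tilt_deg, 16, tolerance = 0.3)
})

test_that("a flat background raises the no-peak condition, not a fit failure", {
  img <- gen_gixd(list(a = 4.837, b = 4.837, gamma_deg = 120, tilt_deg = 0),
                  intensity = 0, seed = 5)$image
  expect_error(reduce_to_bragg_peaks(img), class = "monofilm_no_peaks")
})

test_that("two overlapping peaks are both resolved", {
  qx <- seq(1.30, 1.60, by = 0.0015)
  qz <- seq(0, 0.3, by = 0.01)
  lam <- outer(rep(50, length(qx)), rep(1, length(qz))) +
    1000 * outer(monofilm:::pseudo_voigt(qx, 1.42, 0.03, 0),
                 exp(-qz^2 / 0.02)) +
    1000 * outer(monofilm:::pseudo_voigt(qx, 1.47, 0.03, 0),
                 exp(-qz^2 / 0.02))
  set.seed(1)
  img <- gixd_image(qx, qz, matrix(rpois(length(lam), lam), nrow = length(qx)))
  pk <- reduce_to_bragg_peaks(img, n_peaks = 2)
  expect_equal(sort(pk$q_xy), c(1.42, 1.47), tolerance = 4e-3)
})

test_that("peak centers are unbiased over seeded noisy images", {
  hex <- list(a = 4.837, b = 4.837, gamma_deg = 120, tilt_deg = 0,
              azimuth_deg = 0)
  errs <- vapply(1:20, function(s) {
    g <- gen_gixd(hex, seed = s)
    reduce_to_bragg_peaks(g$image)$q_xy[1] - g$truth$peaks$q_xy[1]
  }, numeric(1))
  fwhm <- 0.015
  expect_lt(abs(mean(errs)), 0.1 * fwhm)
})

test_that("excess areas and chain-fraction conversion follow the mixing rule", {
  expect_equal(excess_area(41.0, c(41.0, 40.0), c(1, 0)), 0)
  expect_equal(excess_area(40.5, c(41.0, 40.0), c(0.5, 0.5)), 0)
  # CL molecule fraction 0.25 in PG -> CL chain fraction 0.4
  ex <- excess_area(40, c(41, 40), fractions = c(0.75, 0.25),
                    basis = "chains", n_chains = c(2, 4))
  expect_equal(ex, 40 - (0.6 * 41 + 0.4 * 40))
  expect_equal(ideal_mixing_area(c(41, 40), c(0.75, 0.25), basis = "chains",
                                 n_chains = c(2, 4)), 0.6 * 41 + 0.4 * 40)
  expect_error(excess_area(40, c(41, 40), c(0.5, 0.4)), "sum to 1")
})
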