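# The specular reflectivity engine: Parratt recursion with Nevot-Croce
# roughness, resolution smearing, and the real-space SLD profile.

test_that("homogeneous media reflect nothing and a D2O interface totally below q_c", {
  q <- c(0.005, 0.02, 0.1, 0.4)
  st <- slab_stack(list(slab(20, 3e-6, 0)), medium_above = 3e-6,
                   medium_below = 3e-6)
  expect_equal(parratt_reflectivity(st, q)$R, rep(0, 4))

  d2o <- slab_stack(list(), medium_below = 6.38e-6)
  qc <- sqrt(16 * pi * 6.38e-6)
  expect_equal(qc, 0.0179, tolerance = 5e-3)
  below <- parratt_reflectivity(d2o, c(0.005, 0.010, 0.9999 * qc))$R
  expect_equal(below, rep(1, 3), tolerance = 1e-12)
  expect_lt(parratt_reflectivity(d2o, 0.05)$R[1], 0.01)
})

test_that("single-interface reflectivity matches the closed-form Fresnel formula", {
  q <- seq(0.005, 0.5, length.out = 200)
  for (rho in c(2e-6, 6.38e-6, 9.4e-6)) {
    st <- slab_stack(list(), medium_below = rho)
    expect_equal(parratt_reflectivity(st, q)$R, fresnel_single(q, rho),
                 tolerance = 1e-12)
  }
})

test_that("a 20 A slab gives Kiessig minima spaced 2*pi/20", {
  st <- slab_stack(list(slab(20, 3e-6, 0)), medium_below = 6.38e-6)
  q <- seq(0.05, 1.2, by = 5e-4)
  R <- parratt_reflectivity(st, q)$R
  mins <- q[which(diff(sign(diff(R))) == 2) + 1]
  expect_true(all(abs(diff(mins) - 2 * pi / 20) < 0.01))
})

test_that("Parratt agrees with the transfer-matrix oracle on random stacks", {
  set.seed(101)
  q <- seq(0.01, 0.5, length.out = 60)
  worst <- 0
  for (i in 1:100) {
    st <- random_stack()
    R1 <- parratt_reflectivity(st, q)$R
    R2 <- abeles_reflectivity(st, q)
    worst <- max(worst, max(abs(R1 - R2) / pmax(R2, 1e-300)))
  }
  expect_lt(worst, 1e-8)
})

test_that("reflectivity envelope decays monotonically for a single sharp interface", {
  st <- slab_stack(list(), medium_below = 4e-6)
  q <- seq(0.03, 0.6, length.out = 300)
  R <- parratt_reflectivity(st, q)$R
  expect_true(all(diff(R) <= 0))
})

test_that("invalid inputs are rejected", {
  st <- slab_stack(list(), medium_below = 4e-6)
  expect_error(parratt_reflectivity(st, c(0.1, -0.2)), "q must be")
  expect_error(slab(-1, 1e-6), "thickness")
  expect_error(slab(10, NaN), "finite")
  expect_error(slab(10, 1e-6, -0.5), "roughness")
})

test_that("micro-sliced roughness agrees with Nevot-Croce for moderate sigma", {
  st <- slab_stack(list(slab(20, 4e-6, 3)), medium_below = 6.38e-6,
                   roughness_below = 3)
  q <- seq(0.03, 0.3, length.out = 40)
  Rnc <- parratt_reflectivity(st, q)$R
  Rms <- parratt_reflectivity(st, q, microslice = TRUE, slice_dz = 0.25)$R
  expect_equal(Rms, Rnc, tolerance = 0.02)
})

test_that("zero smearing is the identity and smearing straddles a sharp edge", {
  st <- slab_stack(list(), medium_below = 6.38e-6)
  q <- seq(0.01, 0.05, by = 5e-5)
  curve <- parratt_reflectivity(st, q)
  expect_identical(apply_resolution(curve, 0)$R, curve$R)
  qc <- sqrt(16 * pi * 6.38e-6)
  sm <- model_reflectivity(st, c(qc * 0.999, qc, qc * 1.001), dq_over_q = 0.07)$R
  expect_lt(sm[2], 1)                       # below the total-reflection value
  expect_gt(sm[2], parratt_reflectivity(st, qc * 1.02)$R)
})

test_that("quadrature smearing matches brute-force convolution on smooth fringes", {
  st <- slab_stack(list(slab(20, 3e-6, 2)), medium_below = 6.38e-6,
                   roughness_below = 2)
  a <- stack_arrays_fixture(st)
  q0s <- c(0.15, 0.25, 0.4)
  sm <- model_reflectivity(st, q0s, dq_over_q = 0.07)$R
  bf <- vapply(q0s, function(q0) {
    s <- 0.07 * q0 / (2 * sqrt(2 * log(2)))
    stats::integrate(function(u)
      stats::dnorm(u, 0, s) * abeles_reflectivity(st, q0 + u),
      -7 * s, 7 * s, rel.tol = 1e-9)$value
  }, numeric(1))
  expect_equal(sm, bf, tolerance = 1e-4)
})

test_that("curve-based smearing agrees with model-based smearing", {
  st <- slab_stack(list(slab(22, 3e-6, 3)), medium_below = 6.38e-6,
                   roughness_below = 3)
  qfine <- seq(0.02, 0.45, by = 2e-4)
  qout <- seq(0.05, 0.4, by = 0.01)
  sm_curve <- apply_resolution(parratt_reflectivity(st, qfine), 0.07)
  sm_model <- model_reflectivity(st, qout, dq_over_q = 0.07)$R
  interp <- stats::approx(sm_curve$q, sm_curve$R, xout = qout)$y
  expect_equal(interp, sm_model, tolerance = 1e-3)
})

test_that("sld_profile is a step function at zero roughness and erf-mixed otherwise", {
  st0 <- slab_stack(list(slab(20, 3e-6, 0)), medium_below = 6e-6)
  z <- c(-5, 5, 15, 25)
  expect_equal(sld_profile(st0, z), c(0, 3e-6, 3e-6, 6e-6))
  st <- slab_stack(list(slab(20, 3e-6, 2)), medium_below = 6e-6,
                   roughness_below = 3)
  # at each interface the profile is the mean of adjacent SLDs
  expect_equal(sld_profile(st, 0), 1.5e-6)
  expect_equal(sld_profile(st, 20), 4.5e-6)
  expect_equal(sld_profile(st, c(-50, 200)), c(0, 6e-6))
})

test_that("profile-integrated excess SLD equals the slab sum", {
  st <- slab_stack(list(slab(20, 3e-6, 3), slab(10, 1e-6, 2)),
                   medium_below = 6.38e-6, roughness_below = 3)
  z <- seq(-80, 120, by = 0.005)
  p <- sld_profile(st, z)
  # subtract a reference profile with the same media but no slabs
  ref <- sld_profile(slab_stack(list(slab(20, 0, 3), slab(10, 0, 2)),
                                medium_above = 0,
                                medium_below = 6.38e-6, roughness_below = 3), z)
  got <- pracma::trapz(z, p - ref)
  want <- 20 * 3e-6 + 10 * 1e-6         # sum d_i * sld_i
  expect_equal(got, want, tolerance = 1e-3 * abs(want))
})
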