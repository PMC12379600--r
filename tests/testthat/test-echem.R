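# Chronocoulometry: transient integration, absolute referencing, film
# pressure by double integration, and lock-in capacitance.

test_that("transient integration matches the closed-form exponential charge", {
  tau <- 0.01; I0 <- -50; Tend <- 0.15
  t <- seq(0, Tend, length.out = 400)
  tr1 <- chrono_transient(-0.2, t, I0 * exp(-t / tau))
  tr2 <- chrono_transient(-1.0, t, rep(0, length(t)))
  cc <- charge_density_from_transients(list(tr1, tr2), pzc_bare = NULL,
                                       label = "bare")
  q_expected <- -I0 * tau * (1 - exp(-Tend / tau))
  got <- cc$sigma_M[cc$E == -0.2]
  expect_equal(got, q_expected, tolerance = 1e-3 * abs(q_expected))
  expect_equal(cc$sigma_M[cc$E == -1.0], 0)
  expect_false(attr(cc, "absolute"))
})

test_that("the bare curve crosses zero exactly at its pzc after referencing", {
  g <- gen_chrono(noise = 0, seed = 1)
  bare <- charge_density_from_transients(g$bare, pzc_bare = g$truth$pzc_bare,
                                         label = "bare")
  expect_true(attr(bare, "absolute"))
  expect_equal(stats::approx(bare$E, bare$sigma_M,
                             xout = g$truth$pzc_bare)$y, 0,
               tolerance = 1e-9)
  expect_equal(find_pzc(bare), g$truth$pzc_bare, tolerance = 1e-3)
})

test_that("pzc interpolation and the multi-crossing rule behave", {
  lin <- charge_curve(seq(-1, 1, 0.1), 3 * (seq(-1, 1, 0.1) - 0.2))
  expect_equal(find_pzc(lin), 0.2, tolerance = 1e-12)
  two <- charge_curve(c(-0.10, -0.05), c(-1, 1))
  expect_equal(find_pzc(two), -0.075)
  wig <- charge_curve(c(-1, -0.5, 0, 0.5), c(-1, 1, -1, 1))
  expect_warning(p <- find_pzc(wig), "multiple")
  expect_equal(p, 0.25)
  expect_error(find_pzc(charge_curve(1:3, c(1, 2, 3))), "cross zero")
})

test_that("film pressure: identical curves give zero, constant offset gives the rectangle", {
  E <- seq(-1.05, 0.45, by = 0.05)
  bare <- charge_curve(E, 20 * (E - 0.2), "bare", E_des = -1.05)
  expect_equal(max(abs(film_pressure(bare, bare, E_des = -1.05)$Pi)), 0)
  # constant 10 uC/cm2 offset over 0.5 V -> 50 mN/m
  E2 <- seq(0, 0.5, by = 0.01)
  film2 <- charge_curve(E2, rep(10, length(E2)), "film", E_des = 0)
  bare2 <- charge_curve(E2, rep(0, length(E2)), "bare", E_des = 0)
  fp <- film_pressure(film2, bare2, E_des = 0)
  expect_equal(fp$Pi[fp$E == 0.5], 50, tolerance = 1e-9)
  expect_equal(fp$Pi[fp$E == 0], 0)
})

test_that("capacitor-model round trip matches the closed-form parabola difference", {
  g <- gen_chrono(noise = 0, seed = 3)
  bare <- charge_density_from_transients(g$bare, pzc_bare = g$truth$pzc_bare,
                                         label = "bare")
  film <- charge_density_from_transients(g$film, bare = bare, label = "film")
  expect_equal(film$sigma_M, g$truth$sigma_film,
               tolerance = 5e-3 * max(abs(g$truth$sigma_film)))
  expect_equal(find_pzc(film), g$truth$pzc_film, tolerance = 5e-3)
  fp <- film_pressure(film, bare, E_des = g$truth$E_des)
  expect_equal(fp$Pi, g$truth$Pi_closed_form(fp$E),
               tolerance = 0.01 * max(abs(fp$Pi)))
  expect_equal(fp$Pi[fp$E == g$truth$E_des], 0)
})

test_that("the pressure derivative returns the charge difference", {
  g <- gen_chrono(noise = 0, seed = 4)
  bare <- charge_density_from_transients(g$bare, pzc_bare = g$truth$pzc_bare,
                                         label = "bare")
  film <- charge_density_from_transients(g$film, bare = bare, label = "film")
  fp <- film_pressure(film, bare, E_des = g$truth$E_des)
  mid <- 2:(nrow(fp) - 1)
  dPi <- (fp$Pi[mid + 1] - fp$Pi[mid - 1]) / (fp$E[mid + 1] - fp$E[mid - 1])
  diff_sigma <- (g$truth$sigma_film - g$truth$sigma_bare)[mid]
  expect_equal(dPi / 10, diff_sigma, tolerance = 0.02 * max(abs(diff_sigma)))
})

test_that("series-RC lock-in inversion recovers the capacitance", {
  Rs <- 10          # ohm cm2
  C <- 20           # uF/cm2
  om <- 2 * pi * 20
  dE <- 0.005
  X <- 1 / (om * C * 1e-6)
  Z2 <- Rs^2 + X^2
  i_ip <- dE * Rs / Z2 * 1e6
  i_q <- dE * X / Z2 * 1e6
  expect_equal(capacitance_from_lockin(i_ip, i_q, om, dE), C,
               tolerance = 1e-3 * C)
  # purely capacitive limit and amplitude invariance
  expect_equal(capacitance_from_lockin(0, om * dE * C, om, dE), C)
  expect_equal(capacitance_from_lockin(2 * i_ip, 2 * i_q, om, 2 * dE),
               capacitance_from_lockin(i_ip, i_q, om, dE), tolerance = 1e-9)
  expect_error(capacitance_from_lockin(1, -1, om, dE), "quadrature")
})

test_that("generated transients integrate then differentiate back (charge conservation)", {
  g <- gen_chrono(noise = 0, seed = 6)
  bare <- charge_density_from_transients(g$bare, pzc_bare = g$truth$pzc_bare,
                                         label = "bare")
  expect_equal(bare$sigma_M, g$truth$sigma_bare,
               tolerance = 5e-3 * max(abs(g$truth$sigma_bare)))
})
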