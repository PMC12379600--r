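# Independent oracles and fixture builders used across the test files.

# Transfer-matrix (Abeles characteristic-matrix) reflectivity, coded
# independently of the package's Parratt recursion: per-interface Fresnel
# coefficients with Nevot-Croce factors assembled as a 2x2 matrix product.
abeles_reflectivity <- function(stack, q) {
  a <- stack_arrays_fixture(stack)
  sld <- a$sld; d <- a$d; sig <- a$sigma
  nm <- length(sld)
  vapply(q, function(qq) {
    k <- vapply(seq_len(nm), function(j) {
      kk <- sqrt(as.complex((qq / 2)^2 - 4 * pi * (sld[j] - sld[1])))
      if (Im(kk) < 0) -kk else kk
    }, complex(1))
    M <- diag(2) + 0i
    for (j in seq_len(nm - 1)) {
      r <- (k[j] - k[j + 1]) / (k[j] + k[j + 1]) *
        exp(-2 * k[j] * k[j + 1] * sig[j]^2)
      beta <- if (j == 1) 0 + 0i else k[j] * d[j - 1]
      M <- M %*% matrix(c(exp(-1i * beta), r * exp(1i * beta),
                          r * exp(-1i * beta), exp(1i * beta)), 2, 2)
    }
    Mod(M[2, 1] / M[1, 1])^2
  }, numeric(1))
}

# Flatten a slab_stack without using package internals.
stack_arrays_fixture <- function(stack) {
  list(sld = c(stack$medium_above,
               vapply(stack$slabs, function(s) s$sld, complex(1)),
               stack$medium_below),
       d = vapply(stack$slabs, function(s) s$thickness, numeric(1)),
       sigma = c(vapply(stack$slabs, function(s) s$roughness_top, numeric(1)),
                 stack$roughness_below))
}

random_stack <- function() {
  ns <- sample(0:6, 1)
  slabs <- lapply(seq_len(ns), function(k)
    slab(runif(1, 5, 60), runif(1, -2e-6, 7e-6), runif(1, 0, 4)))
  slab_stack(slabs, medium_below = runif(1, 2e-6, 7e-6),
             roughness_below = runif(1, 0, 4))
}

# Closed-form Fresnel reflectivity of a single sharp interface.
fresnel_single <- function(q, sld_below, sld_above = 0) {
  k0 <- q / 2
  k1 <- sqrt(as.complex(k0^2 - 4 * pi * (sld_below - sld_above)))
  Mod((k0 - k1) / (k0 + k1))^2
}

# NN-tilt cell parameters: a = b lattice with tilt along the bisector of the
# reciprocal basis vectors (the nearest-neighbour direction).
nn_tilt_cell <- function(a, gamma_deg, tilt_deg) {
  g <- gamma_deg * pi / 180
  det <- a * a * sin(g)
  G10 <- 2 * pi * c(a * sin(g), -a * cos(g)) / det
  G01 <- 2 * pi * c(0, a) / det
  bis <- G10 + G01
  list(a = a, b = a, gamma_deg = gamma_deg, tilt_deg = tilt_deg,
       azimuth_deg = atan2(bis[2], bis[1]) * 180 / pi)
}

# Hand summation of coherent scattering lengths (fm -> Angstrom),
# independent of the package's formula machinery.
formula_b_fixture <- function(formula) {
  b <- c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803, P = 5.13,
         Na = 3.63)
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  el <- sub("[0-9]+$", "", toks)
  n <- as.numeric(sub("^[A-Za-z]+", "", toks)); n[is.na(n)] <- 1
  sum(n * b[el]) * 1e-5
}

# Study-condition lipid mixtures used in several tests.
pg_mix <- function() lipid_mixture(c(DMPG = 1))
ternary_mix <- function() lipid_mixture(c(DMPE = 0.8, DMPG = 0.15, TMCL = 0.05))
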