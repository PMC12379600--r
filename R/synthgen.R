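# Seeded generators that emulate the statistical structure of each
# measurement stage, so the full analysis chain is testable without beamline
# or electrode data.  Every generator returns the data together with a
# machine-readable truth record, and restores the caller's RNG state.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic multi-contrast reflectivity datasets
#'
#' Forward two-slab model, Gaussian dq/q resolution smearing, multiplicative
#' Gaussian noise (counting statistics at high rates) with a consistent `dR`
#' column.
#'
#' @param params True [monolayer_params()].
#' @param contrasts List of [contrast_spec()].
#' @param q List of q grids (recycled), inverse Angstrom. Default
#'   0.018-0.6 for X-rays and 0.012-0.3 for neutrons.
#' @param noise_rel Relative noise level (0 gives the exact smeared model).
#' @param dq_over_q Fractional resolution per contrast (recycled);
#'   default 0.07 for neutron time-of-flight and 0.01 for X-ray contrasts.
#' @param seed Integer seed.
#' @param V_water Water molecular volume, cubic Angstrom.
#' @return List with `datasets` (list of [reflectivity_curve()]) and
#'   `truth` (true parameters, derived structure, per-contrast headgroup
#'   slab SLD, seed and noise settings).
#' @export
gen_reflectivity <- function(params, contrasts, q = NULL, noise_rel = 0.02,
                             dq_over_q = NULL, seed = 1,
                             V_water = V_WATER_DEFAULT) {
  stopifnot(inherits(params, "monolayer_params"))
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  nc <- length(contrasts)
  if (is.null(dq_over_q))
    dq_over_q <- vapply(contrasts, function(ct)
      if (ct$radiation == "neutron") 0.07 else 0.01, numeric(1))
  dq_over_q <- rep_len(dq_over_q, nc)
  if (is.null(q))
    q <- lapply(contrasts, function(ct)
      if (ct$radiation == "neutron") seq(0.012, 0.30, by = 0.003)
      else seq(0.018, 0.60, by = 0.004))
  if (is.numeric(q)) q <- list(q)
  q <- rep_len(q, nc)
  with_seed(seed, {
    datasets <- vector("list", nc)
    head_slds <- numeric(nc)
    for (i in seq_len(nc)) {
      st <- build_stack(params, contrasts[[i]], V_water = V_water)
      head_slds[i] <- Re(st$slabs[[2]]$sld)
      Rm <- model_reflectivity(st, q[[i]], dq_over_q = dq_over_q[i])$R
      dR <- pmax(noise_rel * Rm, 1e-12)
      Rn <- if (noise_rel > 0)
        pmax(Rm + dR * stats::rnorm(length(Rm)), 1e-15) else Rm
      datasets[[i]] <- reflectivity_curve(
        q[[i]], Rn, dR = dR,
        contrast_label = paste0(contrasts[[i]]$radiation, "_",
                                contrasts[[i]]$subphase))
    }
    A_M <- params$V_tail / params$d_tail
    phi <- params$solvent_fraction
    V_solv <- A_M * params$d_hg
    truth <- list(params = params,
                  A_M = A_M,
                  n_w = phi * V_solv / V_water,
                  V_head = (1 - phi) * V_solv,
                  head_slab_sld = head_slds,
                  noise_rel = noise_rel, dq_over_q = dq_over_q, seed = seed)
    list(datasets = datasets, truth = truth)
  })
}

#' Synthetic GIXD intensity map
#'
#' Places 2D peaks - pseudo-Voigt in `q_xy` times Gaussian rod in `q_z` - at
#' the Bragg positions of a known cell on a smooth (linear in `q_xy`)
#' background, with Poisson counting noise.
#'
#' @param cell List with `a`, `b`, `gamma_deg`, `tilt_deg`, `azimuth_deg`
#'   describing the true chain lattice.
#' @param intensity Peak amplitude (counts) for a multiplicity-1 reflection;
#'   degenerate rods add.
#' @param fwhm_xy In-plane peak FWHM, inverse Angstrom.
#' @param rod_sigma Rod Gaussian width in `q_z`, inverse Angstrom.
#' @param background Length-2 numeric `(b0, b1)`: counts offset and slope
#'   versus `q_xy`.
#' @param q_xy,q_z Axis vectors of the map.
#' @param poisson Apply Poisson noise (`FALSE` gives the noise-free map).
#' @param seed Integer seed.
#' @return List with `image` (a [gixd_image()]) and `truth` (cell, solved
#'   areas/tilt, peak table).
#' @export
gen_gixd <- function(cell, intensity = 500, fwhm_xy = 0.015, rod_sigma = 0.10,
                     background = c(40, 10),
                     q_xy = seq(1.20, 1.80, by = 0.0015),
                     q_z = seq(0, 0.72, by = 0.008),
                     poisson = TRUE, seed = 1) {
  pk <- peaks_from_cell(cell$a, cell$b, cell$gamma_deg,
                        tilt_deg = cell$tilt_deg %||% 0,
                        azimuth_deg = cell$azimuth_deg %||% 0)
  lam <- outer(background[1] + background[2] * q_xy, rep(1, length(q_z)))
  for (k in seq_len(nrow(pk))) {
    px <- pseudo_voigt(q_xy, pk$q_xy[k], fwhm_xy, 0.3)
    pz <- exp(-(q_z - pk$q_z[k])^2 / (2 * rod_sigma^2))
    lam <- lam + intensity * pk$multiplicity[k] * outer(px, pz)
  }
  img <- with_seed(seed, {
    counts <- if (poisson)
      matrix(stats::rpois(length(lam), lam), nrow = nrow(lam)) else lam
    gixd_image(q_xy, q_z, counts)
  })
  g <- cell$gamma_deg * pi / 180
  A_chain <- cell$a * cell$b * sin(g)
  truth <- list(cell = cell, peaks = pk, A_chain = A_chain,
                A_pair = 2 * A_chain,
                A_xs = A_chain * cos((cell$tilt_deg %||% 0) * pi / 180),
                tilt_deg = cell$tilt_deg %||% 0, seed = seed)
  list(image = img, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic surface pressure-area isotherm
#'
#' Piecewise-linear branches (liquid-expanded, coexistence plateau,
#' liquid-condensed, solid) with Gaussian-rounded corners and additive
#' Gaussian pressure noise. Corner rounding by a symmetric kernel leaves the
#' branch tangents unchanged, so the constructed transition pressures are
#' exactly the tangent-intersection values.
#'
#' @param plateau_Pi Le-Lc plateau (onset) pressure, mN/m; `NA` omits the
#'   plateau.
#' @param kink_Pi Lc-S kink pressure, mN/m; `NA` omits the solid branch.
#' @param slope_le,slope_plateau,slope_lc,slope_s Branch slopes
#'   `-dPi/dA` (mN/m per square Angstrom), all > 0.
#' @param A_lift Lift-off area (pressure zero), square Angstrom.
#' @param plateau_len Plateau length in area, square Angstrom.
#' @param Pi_max Final pressure of the compression, mN/m.
#' @param n Number of points.
#' @param noise_sd Gaussian pressure noise, mN/m.
#' @param round_w Corner-rounding kernel width, square Angstrom.
#' @param seed Integer seed.
#' @return List with `iso` (an [isotherm()]) and `truth`.
#' @export
gen_isotherm <- function(plateau_Pi = 12, kink_Pi = 27,
                         slope_le = 0.30, slope_plateau = 0.04,
                         slope_lc = 1.4, slope_s = 6.0,
                         A_lift = 95, plateau_len = 12, Pi_max = 52,
                         n = 400, noise_sd = 0.1, round_w = 0.6, seed = 1) {
  has_plateau <- is.finite(plateau_Pi) && plateau_len > 0
  has_kink <- is.finite(kink_Pi)
  if (has_plateau && has_kink && plateau_Pi >= kink_Pi)
    stop("plateau pressure must be below kink pressure")
  # corner areas (A decreasing) and pressures, accumulated branch by branch
  Acorn <- A_lift; Pcorn <- 0; slopes <- c()
  add_branch <- function(slope, dPi = NULL, dA = NULL) {
    if (is.null(dA)) dA <- dPi / slope
    Acorn <<- c(Acorn, Acorn[length(Acorn)] - dA)
    Pcorn <<- c(Pcorn, Pcorn[length(Pcorn)] + slope * dA)
    slopes <<- c(slopes, slope)
  }
  if (has_plateau) {
    add_branch(slope_le, dPi = plateau_Pi)
    add_branch(slope_plateau, dA = plateau_len)
    if (has_kink) {
      add_branch(slope_lc, dPi = kink_Pi - Pcorn[length(Pcorn)])
      add_branch(slope_s, dPi = Pi_max - kink_Pi)
    } else {
      add_branch(slope_lc, dPi = Pi_max - Pcorn[length(Pcorn)])
    }
  } else if (has_kink) {
    # condensed-only compression: Lc branch straight into the solid kink
    add_branch(slope_lc, dPi = kink_Pi)
    add_branch(slope_s, dPi = Pi_max - kink_Pi)
  } else {
    # single-branch isotherm: no transition features at all
    add_branch(slope_le, dPi = Pi_max)
  }
  A <- seq(A_lift, Acorn[length(Acorn)], length.out = n)
  Pi_sharp <- function(Av) {
    sapply(Av, function(a) {
      j <- findInterval(-a, -Acorn, all.inside = TRUE)
      Pcorn[j] + slopes[j] * (Acorn[j] - a)
    })
  }
  Pi0 <- if (round_w > 0) {
    # Gaussian rounding of corners by quadrature over the sharp curve
    gh <- gauss_hermite_17()
    vapply(A, function(a)
      sum(gh$w * Pi_sharp(a + sqrt(2) * round_w * gh$x)) / sqrt(pi),
      numeric(1))
  } else Pi_sharp(A)
  iso <- with_seed(seed, {
    Pn <- Pi0 + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    isotherm(A, Pn)
  })
  truth <- list(plateau_Pi = if (has_plateau) plateau_Pi else NA_real_,
                kink_Pi = if (has_kink) kink_Pi else NA_real_,
                corners_A = Acorn, corners_Pi = Pcorn, slopes = slopes,
                noise_sd = noise_sd, seed = seed)
  list(iso = iso, truth = truth)
}

#' Synthetic chronocoulometric transients
#'
#' Capacitor-model electrode: in each adsorption state the charge density is
#' `sigma(E) = C (E - pzc)`; stepping from the hold potential to the
#' desorption potential produces an exponential transient
#' `I(t) = (dQ/tau) exp(-t/tau)` with `tau = R_cell C`. The film desorbs at
#' the step, so every film transient relaxes to the bare desorbed state.
#'
#' @param C_film,C_bare Differential capacitances, uF/cm2.
#' @param pzc_film,pzc_bare Potentials of zero charge, V.
#' @param R_cell Series cell resistance, ohm cm2.
#' @param E Hold-potential grid, V.
#' @param E_des Desorption potential, V.
#' @param t_max Transient length, s.
#' @param n_t Samples per transient (log-spaced after t = 0).
#' @param noise Gaussian current noise, uA/cm2.
#' @param seed Integer seed.
#' @return List with `film`, `bare` (lists of [chrono_transient()]) and
#'   `truth` (closed-form sigma curves and pressure parabola parameters).
#' @export
gen_chrono <- function(C_film = 2, C_bare = 25,
                       pzc_film = 0.10, pzc_bare = 0.30,
                       R_cell = 300, E = seq(-1.05, 0.40, by = 0.05),
                       E_des = -1.05, t_max = 0.15, n_t = 1200,
                       noise = 0, seed = 1) {
  stopifnot(C_film > 0, C_bare > 0, R_cell > 0)
  tgrid <- c(0, pracma::logspace(-6, log10(t_max), n_t - 1))
  sigma_des <- C_bare * (E_des - pzc_bare)   # uC/cm2, shared desorbed state
  make <- function(Ck, pzck, film) {
    lapply(E, function(e) {
      s_hold <- Ck * (e - pzck)
      s_end <- if (film) sigma_des else C_bare * (E_des - pzc_bare)
      dQ <- s_end - s_hold                      # uC/cm2 passed in the step
      tau <- R_cell * Ck * 1e-6                 # s
      i <- dQ / tau * exp(-tgrid / tau)         # uA/cm2
      chrono_transient(e, tgrid, i, E_des = E_des)
    })
  }
  out <- with_seed(seed, {
    film <- make(C_film, pzc_film, film = TRUE)
    bare <- make(C_bare, pzc_bare, film = FALSE)
    if (noise > 0) {
      film <- lapply(film, function(tr) {
        tr$i <- tr$i + stats::rnorm(length(tr$i), 0, noise); tr })
      bare <- lapply(bare, function(tr) {
        tr$i <- tr$i + stats::rnorm(length(tr$i), 0, noise); tr })
    }
    list(film = film, bare = bare)
  })
  truth <- list(C_film = C_film, C_bare = C_bare, pzc_film = pzc_film,
                pzc_bare = pzc_bare, R_cell = R_cell, E = E, E_des = E_des,
                sigma_film = C_film * (E - pzc_film),
                sigma_bare = C_bare * (E - pzc_bare),
                Pi_closed_form = function(Ev) {
                  UC_V_TO_MN_PER_M *
                    (C_film / 2 * ((Ev - pzc_film)^2 - (E_des - pzc_film)^2) -
                     C_bare / 2 * ((Ev - pzc_bare)^2 - (E_des - pzc_bare)^2))
                },
                seed = seed)
  list(film = out$film, bare = out$bare, truth = truth)
}
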