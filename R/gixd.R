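# Grazing-incidence diffraction: reduce 2D intensity maps to Bragg peaks and
# solve the 2D unit cell of the chain lattice, its area per chain, tilt
# angle and azimuth, and chain cross-sectional area.

#' Gridded GIXD intensity map
#'
#' @param q_xy,q_z Monotone axis vectors (inverse Angstrom).
#' @param intensity Matrix of counts, `length(q_xy)` rows by `length(q_z)`
#'   columns, all >= 0.
#' @return Object of class `gixd_image`.
#' @export
gixd_image <- function(q_xy, q_z, intensity) {
  stopifnot(is.matrix(intensity),
            nrow(intensity) == length(q_xy), ncol(intensity) == length(q_z))
  if (is.unsorted(q_xy, strictly = TRUE) || is.unsorted(q_z, strictly = TRUE))
    stop("axis vectors must be strictly increasing")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  storage.mode(intensity) <- "double"
  structure(list(q_xy = as.numeric(q_xy), q_z = as.numeric(q_z),
                 intensity = intensity),
            class = "gixd_image")
}

# Pseudo-Voigt of unit height: Gaussian/Lorentzian mix with common FWHM.
pseudo_voigt <- function(x, x0, fwhm, eta = 0.5) {
  u <- (x - x0) / fwhm
  (1 - eta) * exp(-4 * log(2) * u^2) + eta / (1 + 4 * u^2)
}

no_peaks_error <- function(msg) {
  stop(errorCondition(msg, class = c("monofilm_no_peaks", "error", "condition")))
}
indexing_error <- function(msg, residuals = NULL) {
  stop(errorCondition(msg, residuals = residuals,
                      class = c("monofilm_indexing_error", "error", "condition")))
}

#' Reduce a GIXD image to Bragg peaks
#'
#' Integrates intensity over `q_z` to an in-plane profile, fits a sum of
#' pseudo-Voigt peaks on a linear background to locate `q_xy` positions and
#' widths, then fits a Gaussian (plus constant) to the rod slice around each
#' peak to obtain its `q_z` position.
#'
#' @param image A [gixd_image()].
#' @param n_peaks Number of peaks to fit; `NULL` detects automatically
#'   (at most 3).
#' @param qz_range Length-2 integration range in `q_z`; default full range.
#' @param snr Detection threshold in noise units.
#' @return Object of class `bragg_peak_set`: data.frame with columns
#'   `q_xy`, `q_z`, `fwhm_xy`, `intensity`, `label`, sorted by `q_xy`.
#' @export
reduce_to_bragg_peaks <- function(image, n_peaks = NULL, qz_range = NULL,
                                  snr = 5) {
  stopifnot(inherits(image, "gixd_image"))
  qz_keep <- if (is.null(qz_range)) rep(TRUE, length(image$q_z)) else
    image$q_z >= qz_range[1] & image$q_z <= qz_range[2]
  qx <- image$q_xy
  prof <- apply(image$intensity[, qz_keep, drop = FALSE], 1,
                function(row) pracma::trapz(image$q_z[qz_keep], row))
  # robust linear background from the lower part of the profile
  lowset <- prof <= stats::quantile(prof, 0.4)
  bgfit <- stats::lm(prof[lowset] ~ qx[lowset])
  bg <- bgfit$coefficients[1] + bgfit$coefficients[2] * qx
  resid <- prof - bg
  noise <- stats::mad(diff(prof)) / sqrt(2)
  if (noise == 0) noise <- max(1e-12, 1e-6 * max(abs(prof)))
  # candidate maxima on a lightly smoothed residual
  k <- stats::filter(resid, rep(1 / 5, 5), sides = 2)
  k[is.na(k)] <- 0
  is_max <- c(FALSE, diff(sign(diff(k))) == -2, FALSE)
  cand <- which(is_max & resid > snr * noise)
  if (!length(cand)) no_peaks_error("no diffraction peak above threshold")
  cand <- cand[order(resid[cand], decreasing = TRUE)]
  # merge maxima closer than roughly a peak width
  sep <- 12
  keep <- integer(0)
  for (i in cand) if (!length(keep) || all(abs(i - keep) > sep)) keep <- c(keep, i)
  auto_n <- is.null(n_peaks)
  if (auto_n) n_peaks <- min(length(keep), 3L)
  if (length(keep) < n_peaks) {
    # split the strongest candidate to seed unresolved overlapping peaks
    while (length(keep) < n_peaks) keep <- c(keep, keep[1] + sep)
  }
  keep <- sort(keep[seq_len(n_peaks)])
  dqx <- mean(diff(qx))
  init <- c(as.numeric(bgfit$coefficients), 0.3)   # b0, b1, eta
  lower <- c(-Inf, -Inf, 0); upper <- c(Inf, Inf, 1)
  for (i in keep) {
    init <- c(init, qx[i], 0.02, max(resid[i], noise))
    lower <- c(lower, min(qx), 3 * dqx, 0)
    upper <- c(upper, max(qx), (max(qx) - min(qx)) / 2, Inf)
  }
  model <- function(p) {
    y <- p[1] + p[2] * qx
    for (j in seq_len(n_peaks)) {
      o <- 3 + 3 * (j - 1)
      y <- y + p[o + 3] * pseudo_voigt(qx, p[o + 1], p[o + 2], p[3])
    }
    y
  }
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = function(p) model(p) - prof,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  if (!(fit$info %in% 1:4))
    stop("peak fit did not converge (residual norm ",
         signif(sqrt(sum(fit$fvec^2)), 4), ")")
  p <- fit$par
  pk <- data.frame(q_xy = numeric(n_peaks), q_z = NA_real_,
                   fwhm_xy = numeric(n_peaks), intensity = numeric(n_peaks),
                   label = "unassigned")
  for (j in seq_len(n_peaks)) {
    o <- 3 + 3 * (j - 1)
    pk$q_xy[j] <- p[o + 1]; pk$fwhm_xy[j] <- p[o + 2]; pk$intensity[j] <- p[o + 3]
  }
  if (auto_n) {  # prune spurious shoulder components picked up from noise
    good <- pk$intensity > pmax(5 * noise, 0.03 * max(pk$intensity))
    if (!any(good)) no_peaks_error("no diffraction peak above threshold")
    pk <- pk[good, , drop = FALSE]
  }
  for (j in seq_len(nrow(pk)))
    pk$q_z[j] <- fit_rod_qz(image, pk$q_xy[j], pk$fwhm_xy[j],
                            others = pk$q_xy[-j])
  pk <- pk[order(pk$q_xy), ]
  rownames(pk) <- NULL
  structure(pk, class = c("bragg_peak_set", "data.frame"))
}

# Gaussian + constant fit to the q_z rod profile in a window around q_xy0;
# the window is clipped at half the distance to neighbouring peaks.
fit_rod_qz <- function(image, qxy0, fwhm, others = numeric(0)) {
  hw <- 1.5 * fwhm
  if (length(others)) hw <- min(hw, 0.45 * min(abs(others - qxy0)))
  hw <- max(hw, 2.5 * mean(diff(image$q_xy)))
  win <- abs(image$q_xy - qxy0) <= hw
  if (sum(win) < 2) win <- abs(image$q_xy - qxy0) <= 5 * mean(diff(image$q_xy))
  rod <- apply(image$intensity[win, , drop = FALSE], 2, sum)
  qz <- image$q_z
  base <- stats::quantile(rod, 0.2)
  amp0 <- max(rod) - base
  qz0 <- qz[which.max(rod)]
  fit <- minpack.lm::nls.lm(
    par = c(qz0 = qz0, s = 0.1, amp = amp0, b = base),
    lower = c(min(qz) - 0.3, 0.01, 0, -Inf),
    upper = c(max(qz), diff(range(qz)), Inf, Inf),
    fn = function(p) p[3] * exp(-(qz - p[1])^2 / (2 * p[2]^2)) + p[4] - rod,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  max(unname(fit$par[1]), 0)
}

#' Solve the 2D unit cell from 1-3 Bragg peaks
#'
#' One peak at `q_z = 0` is hexagonal close packing with untilted chains;
#' two peaks (degenerate \{10,01\} rod above the horizon plus \{-11\} at
#' `q_z = 0`) are a nearest-neighbour-tilt distorted hexagonal cell; three
#' peaks are an oblique cell with the tilt between symmetry directions. Tilt
#' magnitude and azimuth are solved jointly from the rod positions via
#' `q_z(G) = tan(t) (G . u)`.
#'
#' @param peaks A `bragg_peak_set` or data.frame with `q_xy` and `q_z`.
#' @param qz_zero_tol Rod positions below this (inverse Angstrom) count as
#'   being on the horizon.
#' @param tol Relative consistency tolerance for the rod/tilt closure.
#' @return Object of class `unit_cell_2d` with fields `cell_class`,
#'   `d_spacings`, `A_chain`, `A_pair`, `A_xs`, `tilt_deg`,
#'   `tilt_azimuth_deg`, `qz_residual`.
#' @export
solve_unit_cell <- function(peaks, qz_zero_tol = 0.05, tol = 0.005) {
  qxy <- peaks$q_xy; qz <- peaks$q_z
  stopifnot(all(qxy > 0), all(qz >= 0), length(qxy) >= 1, length(qxy) <= 3)
  n <- length(qxy)
  if (n == 1) {
    d <- 2 * pi / qxy
    A <- 2 * d^2 / sqrt(3)
    return(new_cell("hexagonal", c(d10 = d, d01 = d, d11 = d),
                    A, 0, 0, qz_resid = abs(qz)))
  }
  if (n == 2) {
    i_nd <- which.min(abs(qz))            # smallest |q_z| is the {-11} peak
    i_d <- setdiff(1:2, i_nd)
    qn <- qxy[i_nd]; qd <- qxy[i_d]; qzd <- qz[i_d]
    cth <- 1 - qn^2 / (2 * qd^2)
    if (abs(cth) >= 1)
      indexing_error("two-peak set inconsistent with a centred cell",
                     residuals = c(cos_theta = cth))
    th <- acos(cth)
    A <- (2 * pi)^2 / (qd^2 * sin(th))
    t <- atan2(qzd, qd * cos(th / 2))
    dsp <- sort(2 * pi / c(qd, qd, qn), decreasing = TRUE)
    cls <- if (abs(qn - qd) < tol * qd && qzd < qz_zero_tol)
      "hexagonal" else "NN-tilt"
    if (cls == "hexagonal") t <- 0
    return(new_cell(cls, stats::setNames(dsp, c("d10", "d01", "d11")),
                    A, t * 180 / pi, 0, qz_resid = abs(qz[i_nd])))
  }
  solve_oblique(qxy, qz, qz_zero_tol, tol)
}

new_cell <- function(cls, dsp, A_chain, tilt_deg, azimuth_deg, qz_resid = 0) {
  structure(list(cell_class = cls, d_spacings = dsp, A_chain = A_chain,
                 A_pair = 2 * A_chain,
                 A_xs = A_chain * cos(tilt_deg * pi / 180),
                 tilt_deg = tilt_deg, tilt_azimuth_deg = azimuth_deg,
                 qz_residual = max(qz_resid)),
            class = "unit_cell_2d")
}

#' @export
print.unit_cell_2d <- function(x, ...) {
  cat(sprintf("unit_cell_2d [%s]: A_chain=%.2f A^2 (pair %.2f)  t=%.1f deg  A_xs=%.2f A^2\n",
              x$cell_class, x$A_chain, x$A_pair, x$tilt_deg, x$A_xs))
  cat("  d-spacings:", paste(sprintf("%.4f", x$d_spacings), collapse = " "), "A\n")
  invisible(x)
}

# Three-peak oblique indexing: choose which observed peak is the difference
# vector {-11}, build G10 along x, solve the tilt vector v = tan(t) u from
# the rod positions (sign enumeration + least-squares refinement).
solve_oblique <- function(qxy, qz, qz_zero_tol, tol) {
  best <- NULL
  qbar <- mean(qxy)
  for (ic in 1:3) {
    iab <- setdiff(1:3, ic)
    for (swap in c(FALSE, TRUE)) {
      ia <- iab[1 + swap]; ib <- iab[2 - swap]
      qa <- qxy[ia]; qb <- qxy[ib]; qc <- qxy[ic]
      cth <- (qa^2 + qb^2 - qc^2) / (2 * qa * qb)
      if (abs(cth) >= 1) next
      th <- acos(cth)
      G10 <- c(qa, 0)
      G01 <- qb * c(cos(th), sin(th))
      G11 <- G01 - G10
      for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
        vx <- s1 * qz[ia] / qa
        vy <- (s2 * qz[ib] - G01[1] * vx) / G01[2]
        v0 <- c(vx, vy)
        obj <- function(v) {
          sum((c(abs(sum(G10 * v)), abs(sum(G01 * v)), abs(sum(G11 * v))) -
                 qz[c(ia, ib, ic)])^2)
        }
        opt <- stats::optim(v0, obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-14, maxit = 2000))
        res <- sqrt(opt$value / 3)
        if (is.null(best) || res < best$res)
          best <- list(res = res, v = opt$par, th = th, qa = qa, qb = qb,
                       qc = qc, ia = ia, ib = ib, ic = ic)
      }
    }
  }
  if (is.null(best))
    indexing_error("no 2D cell reproduces the three peak positions",
                   residuals = qxy)
  if (best$res > tol * qbar)
    indexing_error(sprintf("rod positions inconsistent with any cell (rms %.4g)",
                           best$res),
                   residuals = best$res)
  A <- (2 * pi)^2 / (best$qa * best$qb * sin(best$th))
  v <- best$v
  t <- atan(sqrt(sum(v^2)))
  az <- atan2(v[2], v[1]) * 180 / pi
  az <- az %% 180
  dsp <- 2 * pi / c(best$qa, best$qb, best$qc)
  cls <- if (t * 180 / pi < 1e-6 && diff(range(qxy)) < tol * qbar)
    "hexagonal" else "oblique"
  if (cls == "hexagonal") t <- 0
  new_cell(cls, stats::setNames(dsp, c("d10", "d01", "d11")),
           A, t * 180 / pi, az, qz_resid = best$res)
}

#' Areas and tilt from a solved cell
#'
#' @param cell A `unit_cell_2d`.
#' @return List with `A_chain`, `A_pair = 2 A_chain`, cross-sectional area
#'   `A_xs = A_chain cos(t)` and tilt `t` in degrees.
#' @export
chain_areas_and_tilt <- function(cell) {
  stopifnot(inherits(cell, "unit_cell_2d"))
  list(A_chain = cell$A_chain, A_pair = cell$A_pair,
       A_xs = cell$A_chain * cos(cell$tilt_deg * pi / 180),
       tilt_deg = cell$tilt_deg)
}

#' Excess mixing area
#'
#' Deviation of a mixture's area from the ideal-mixing (linear) reference,
#' `excess = A_mix - sum(w_i A_i)`. With `basis = "chains"` the mole
#' fractions are first converted to chain fractions using the chain counts
#' (cardiolipin counts 4), which is the natural basis when areas are quoted
#' per chain or per pair of chains.
#'
#' @param area_mix Measured mixture area.
#' @param component_areas Pure-component areas on the same basis.
#' @param fractions Mole fractions (per molecule), summing to 1.
#' @param basis `"molecules"` or `"chains"`.
#' @param n_chains Chains per molecule for each component (required for
#'   `basis = "chains"`).
#' @return The excess area (same units as the inputs).
#' @export
excess_area <- function(area_mix, component_areas, fractions,
                        basis = c("molecules", "chains"), n_chains = NULL) {
  basis <- match.arg(basis)
  stopifnot(length(component_areas) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  w <- if (basis == "chains") {
    if (is.null(n_chains)) stop("basis = 'chains' needs n_chains")
    cf <- fractions * n_chains
    cf / sum(cf)
  } else fractions
  area_mix - sum(w * component_areas)
}

#' Forward Bragg-peak positions from a 2D cell
#'
#' Generates the observable (q_xy, q_z) positions of the \{10\}, \{01\} and
#' \{-11\} reflections of a 2D lattice with tilted chains; degenerate
#' reflections are merged. Used by the synthetic-image generator and for
#' round-trip validation of [solve_unit_cell()].
#'
#' @param a,b Lattice constants, Angstrom.
#' @param gamma_deg Cell angle, degrees.
#' @param tilt_deg Chain tilt from the surface normal, degrees.
#' @param azimuth_deg Tilt azimuth, degrees from the `G10` reciprocal
#'   direction.
#' @return data.frame with `q_xy`, `q_z`, `multiplicity`.
#' @export
peaks_from_cell <- function(a, b, gamma_deg, tilt_deg = 0, azimuth_deg = 0) {
  g <- gamma_deg * pi / 180
  det <- a * b * sin(g)
  A_ <- c(a, 0); B_ <- b * c(cos(g), sin(g))
  G10 <- 2 * pi * c(B_[2], -B_[1]) / det
  G01 <- 2 * pi * c(-A_[2], A_[1]) / det
  Gs <- list(G10, G01, G01 - G10)
  v <- tan(tilt_deg * pi / 180) *
    c(cos(azimuth_deg * pi / 180), sin(azimuth_deg * pi / 180))
  pk <- data.frame(
    q_xy = vapply(Gs, function(G) sqrt(sum(G^2)), numeric(1)),
    q_z = vapply(Gs, function(G) abs(sum(G * v)), numeric(1)))
  # merge degenerate reflections
  key <- paste(round(pk$q_xy, 9), round(pk$q_z, 9))
  agg <- stats::aggregate(list(multiplicity = rep(1L, nrow(pk))),
                          by = list(key = key), FUN = sum)
  first <- !duplicated(key)
  out <- pk[first, ]
  out$multiplicity <- agg$multiplicity[match(key[first], agg$key)]
  out <- out[order(out$q_xy), ]
  rownames(out) <- NULL
  out
}
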