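# PM-IRRAS band analysis: multi-band pseudo-Voigt deconvolution of the C-H
# and C=O stretching regions, the hydrogen-bonded (solvated) carbonyl
# fraction, and acyl-chain tilt from integrated absorbances against a
# randomly-oriented reference.

#' Infrared spectrum container
#'
#' @param wavenumber Wavenumber axis, 1/cm, monotone.
#' @param signal Absorbance-like signal.
#' @param region Free-text region label (e.g. `"CH"`, `"CO"`).
#' @return Object of class `ir_spectrum` (a data.frame).
#' @export
ir_spectrum <- function(wavenumber, signal, region = "") {
  stopifnot(length(wavenumber) == length(signal))
  if (is.unsorted(wavenumber) && is.unsorted(rev(wavenumber)))
    stop("wavenumber must be monotone")
  ord <- order(wavenumber)
  structure(data.frame(wavenumber = wavenumber[ord], signal = signal[ord]),
            class = c("ir_spectrum", "data.frame"), region = region)
}

#' Band template table
#'
#' @param center Initial band centers, 1/cm.
#' @param fwhm Initial widths, 1/cm.
#' @param role Band roles: `"sym"`, `"asym"` (methylene stretches entering
#'   the tilt algebra), `"fermi"` (Fermi-resonance companions, excluded from
#'   tilt), `"free-CO"`, `"hbond-CO"`.
#' @return data.frame usable as `templates` in [fit_bands()].
#' @export
band_templates <- function(center, fwhm, role) {
  stopifnot(length(center) == length(fwhm), length(center) == length(role))
  data.frame(center = center, fwhm = fwhm, role = role)
}

#' Multi-band deconvolution of an IR region
#'
#' Least-squares fit of a sum of pseudo-Voigt bands plus a linear baseline.
#' For a carbonyl region (templates containing `free-CO`/`hbond-CO` roles)
#' the solvated fraction `area(hbond) / total CO area` is also returned.
#'
#' @param spec An [ir_spectrum()].
#' @param templates A [band_templates()] data.frame with starting centers
#'   and widths.
#' @param eta Initial Gaussian/Lorentzian mixing (0 = Gaussian), fitted and
#'   shared across bands.
#' @return Object of class `band_fit`: list with `bands` (data.frame of
#'   center, fwhm, height, area, role), `baseline` coefficients,
#'   `solvated_fraction` (or `NA`), `rss`.
#' @export
fit_bands <- function(spec, templates, eta = 0.3) {
  stopifnot(inherits(spec, "ir_spectrum"), nrow(templates) >= 1)
  x <- spec$wavenumber; y <- spec$signal
  nb <- nrow(templates)
  span <- diff(range(x))
  p0 <- c(min(y), 0, eta)
  lower <- c(-Inf, -Inf, 0); upper <- c(Inf, Inf, 1)
  for (j in seq_len(nb)) {
    h0 <- max(stats::approx(x, y, xout = templates$center[j], rule = 2)$y -
                min(y), 1e-6)
    p0 <- c(p0, templates$center[j], templates$fwhm[j], h0)
    lower <- c(lower, templates$center[j] - 0.25 * span, 0.5, 0)
    upper <- c(upper, templates$center[j] + 0.25 * span, span, Inf)
  }
  model <- function(p) {
    yy <- p[1] + p[2] * (x - mean(x))
    for (j in seq_len(nb)) {
      o <- 3 + 3 * (j - 1)
      yy <- yy + p[o + 3] * pseudo_voigt(x, p[o + 1], p[o + 2], p[3])
    }
    yy
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = function(p) model(p) - y,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  if (!(fit$info %in% 1:4))
    stop("band fit did not converge; residual norm ",
         signif(sqrt(sum(fit$fvec^2)), 4))
  p <- fit$par
  # area of a unit-height pseudo-Voigt with shared eta
  area_factor <- (1 - p[3]) * sqrt(pi / (4 * log(2))) + p[3] * pi / 2
  bands <- data.frame(center = p[3 + 3 * (seq_len(nb) - 1) + 1],
                      fwhm = p[3 + 3 * (seq_len(nb) - 1) + 2],
                      height = p[3 + 3 * (seq_len(nb) - 1) + 3],
                      role = templates$role)
  bands$area <- bands$height * bands$fwhm * area_factor
  co <- templates$role %in% c("free-CO", "hbond-CO")
  solv <- if (any(co)) {
    tot <- sum(bands$area[co])
    if (tot > 0) sum(bands$area[bands$role == "hbond-CO"]) / tot else NA_real_
  } else NA_real_
  structure(list(bands = bands,
                 baseline = c(intercept = unname(p[1]), slope = unname(p[2])),
                 eta = unname(p[3]), solvated_fraction = solv,
                 rss = sum(fit$fvec^2)),
            class = "band_fit")
}

#' @export
print.band_fit <- function(x, ...) {
  cat("band_fit:\n")
  print(within(x$bands, { area <- signif(area, 4) }))
  if (is.finite(x$solvated_fraction))
    cat(sprintf("solvated carbonyl fraction: %.1f%%\n",
                100 * x$solvated_fraction))
  invisible(x)
}

#' Chain tilt from integrated absorbances
#'
#' On a metal surface only the component of a transition dipole moment (TDM)
#' along the surface normal absorbs; comparing the measured integrated
#' absorbance of a mode with the value computed for a randomly oriented
#' film gives the TDM angle from the normal via
#' `cos^2(theta) = A_measured / (3 A_random)`. The methylene symmetric and
#' asymmetric stretch TDMs are perpendicular to each other and to the chain
#' axis, so the chain tilt follows from
#' `cos^2(t) = 1 - cos^2(theta_sym) - cos^2(theta_asym)`.
#'
#' @param A_measured Named or ordered numeric of integrated absorbances for
#'   the two modes (`sym`, `asym`).
#' @param A_random Corresponding randomly-oriented reference absorbances
#'   (> 0), from optical modelling.
#' @return List with `theta_deg` (per-mode TDM angles) and `tilt_deg`
#'   (chain tilt from the surface normal), degrees.
#' @export
tilt_from_absorbance <- function(A_measured, A_random) {
  stopifnot(length(A_measured) == 2, length(A_random) == 2)
  if (any(A_random <= 0)) stop("A_random must be > 0")
  c2 <- A_measured / (3 * A_random)
  if (any(c2 < 0 | c2 > 1))
    stop("cos^2(theta) outside [0, 1]: inconsistent absorbances")
  c2t <- 1 - sum(c2)
  if (c2t < 0 || c2t > 1)
    stop("cos^2(tilt) outside [0, 1]: inconsistent absorbances")
  list(theta_deg = unname(acos(sqrt(c2)) * 180 / pi),
       tilt_deg = unname(acos(sqrt(c2t)) * 180 / pi))
}
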