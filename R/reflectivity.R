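#' Interfacial slab
#'
#' A homogeneous layer in a stratified-interface model. The roughness is the
#' Gaussian width (in Angstrom) of the interface *above* the slab, i.e.
#' between this slab and the previous medium.
#'
#' @param thickness Layer thickness in Angstrom (>= 0).
#' @param sld Scattering length density in inverse square Angstrom. May be
#'   complex; the imaginary part models absorption and defaults to 0.
#' @param roughness_top Gaussian interfacial width in Angstrom (>= 0).
#' @return An object of class `slab`.
#' @export
slab <- function(thickness, sld, roughness_top = 0) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L,
            length(sld) == 1L, is.numeric(roughness_top),
            length(roughness_top) == 1L)
  if (!is.finite(thickness) || thickness < 0)
    stop("slab thickness must be finite and >= 0")
  if (!is.finite(Re(sld)) || !is.finite(Im(as.complex(sld))))
    stop("slab SLD must be finite")
  if (!is.finite(roughness_top) || roughness_top < 0)
    stop("slab roughness must be finite and >= 0")
  structure(list(thickness = thickness, sld = as.complex(sld),
                 roughness_top = roughness_top),
            class = "slab")
}

#' Stack of interfacial slabs
#'
#' Ordered slabs between two semi-infinite media, fronting (typically air,
#' SLD 0) first. `roughness_below` is the width of the final interface to the
#' backing medium.
#'
#' @param slabs List of [slab()] objects, fronting to backing; may be empty.
#' @param medium_above Fronting SLD (default 0, air).
#' @param medium_below Backing (subphase) SLD.
#' @param roughness_below Gaussian width of the bottom interface in Angstrom.
#' @return An object of class `slab_stack`.
#' @export
slab_stack <- function(slabs = list(), medium_above = 0, medium_below,
                       roughness_below = 0) {
  if (inherits(slabs, "slab")) slabs <- list(slabs)
  stopifnot(is.list(slabs))
  for (s in slabs) if (!inherits(s, "slab")) stop("slabs must be slab objects")
  if (!is.finite(roughness_below) || roughness_below < 0)
    stop("roughness_below must be finite and >= 0")
  structure(list(medium_above = as.complex(medium_above),
                 slabs = slabs,
                 medium_below = as.complex(medium_below),
                 roughness_below = roughness_below),
            class = "slab_stack")
}

#' @export
print.slab_stack <- function(x, ...) {
  cat("slab_stack:", length(x$slabs), "slab(s)\n")
  cat(sprintf("  fronting SLD %.3g\n", Re(x$medium_above)))
  for (s in x$slabs)
    cat(sprintf("  slab d=%.2f A  SLD=%.4g  sigma_top=%.2f A\n",
                s$thickness, Re(s$sld), s$roughness_top))
  cat(sprintf("  backing SLD %.4g  sigma=%.2f A\n",
              Re(x$medium_below), x$roughness_below))
  invisible(x)
}

# Flatten a stack into parallel vectors: sld[i], thickness (slabs only),
# sigma[j] for interface j (length n_slab + 1).
stack_arrays <- function(stack) {
  ns <- length(stack$slabs)
  sld <- c(stack$medium_above,
           vapply(stack$slabs, function(s) s$sld, complex(1)),
           stack$medium_below)
  d <- vapply(stack$slabs, function(s) s$thickness, numeric(1))
  sigma <- c(vapply(stack$slabs, function(s) s$roughness_top, numeric(1)),
             stack$roughness_below)
  list(sld = sld, d = d, sigma = sigma, n = ns)
}

#' Reflectivity curve container
#'
#' @param q Momentum transfer q_z in inverse Angstrom, strictly increasing, > 0.
#' @param R Reflectivity (dimensionless).
#' @param dR One-sigma uncertainty on R (optional).
#' @param dq Resolution width (FWHM, inverse Angstrom; optional, per point).
#' @param contrast_label Free-text label (e.g. `"xrr"`, `"nr_d2o"`).
#' @return An object of class `reflectivity_curve` (also a data.frame).
#' @export
reflectivity_curve <- function(q, R, dR = NULL, dq = NULL,
                               contrast_label = "") {
  q <- as.numeric(q); R <- as.numeric(R)
  stopifnot(length(q) == length(R))
  if (any(!is.finite(q)) || any(!is.finite(R))) stop("q and R must be finite")
  if (any(q <= 0)) stop("q must be > 0")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (any(R < 0)) stop("R must be >= 0")
  df <- data.frame(q = q, R = R)
  if (!is.null(dR)) {
    stopifnot(length(dR) == length(q))
    if (any(dR < 0)) stop("dR must be >= 0")
    df$dR <- as.numeric(dR)
  }
  if (!is.null(dq)) {
    stopifnot(length(dq) == length(q))
    df$dq <- as.numeric(dq)
  }
  structure(df, class = c("reflectivity_curve", "data.frame"),
            contrast_label = contrast_label)
}

#' Specular reflectivity of a slab stack (Parratt recursion)
#'
#' Exact reflectivity |r(q)|^2 of a stratified interface, computed by the
#' recursive interface summation with Nevot-Croce Gaussian-roughness factors.
#' For strongly diffuse interfaces (sigma > d/2) the stack can be micro-sliced
#' into thin steps of the error-function profile before the recursion.
#'
#' @param stack A [slab_stack()].
#' @param q Momentum transfer values in inverse Angstrom (> 0).
#' @param microslice If `TRUE`, approximate roughness by slicing the
#'   error-function SLD profile into thin sharp slabs instead of Nevot-Croce
#'   factors. Default `FALSE`.
#' @param slice_dz Slice thickness in Angstrom when `microslice = TRUE`.
#' @return A [reflectivity_curve()] with the model reflectivity.
#' @examples
#' s <- slab_stack(slab(20, 3e-6, 3), medium_below = 6.38e-6,
#'                 roughness_below = 3)
#' rc <- parratt_reflectivity(s, seq(0.02, 0.4, by = 0.002))
#' @export
parratt_reflectivity <- function(stack, q, microslice = FALSE, slice_dz = 0.5) {
  stopifnot(inherits(stack, "slab_stack"))
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  if (microslice) stack <- microslice_stack(stack, slice_dz)
  a <- stack_arrays(stack)
  R <- parratt_kernel(q, a$sld, a$d, a$sigma)
  reflectivity_curve(q, R, contrast_label = "model")
}

# Core recursion; sld length n+2, d length n, sigma length n+1.
parratt_kernel <- function(q, sld, d, sigma) {
  nq <- length(q)
  nmed <- length(sld)
  k0 <- q / 2                         # normal wavevector in fronting medium
  # kz in each medium: sqrt(k0^2 - 4 pi (rho_j - rho_0))
  kz <- matrix(0i, nrow = nq, ncol = nmed)
  for (j in seq_len(nmed)) {
    kj <- sqrt(as.complex(k0^2 - 4 * pi * (sld[j] - sld[1])))
    kz[, j] <- ifelse(Im(kj) < 0, -kj, kj)  # evanescent/absorbed waves decay
  }
  # recursion from the bottom interface upward
  r <- 0i
  for (j in (nmed - 1):1) {
    k1 <- kz[, j]; k2 <- kz[, j + 1]
    rj <- (k1 - k2) / (k1 + k2) * exp(-2 * k1 * k2 * sigma[j]^2)
    if (j == nmed - 1) {
      r <- rj
    } else {
      beta <- exp(2i * k2 * d[j])     # phase across slab j (medium j+1)
      r <- (rj + r * beta) / (1 + rj * r * beta)
    }
  }
  Mod(r)^2
}

# Replace rough interfaces by a ladder of thin sharp slabs following the
# error-function profile.  Used as a cross-check when sigma is not small
# compared with slab thicknesses.
microslice_stack <- function(stack, dz = 0.5) {
  a <- stack_arrays(stack)
  zb <- cumsum(c(0, a$d))            # interface depths
  total <- sum(a$d)
  pad <- 6 * max(a$sigma, 1)
  zgrid <- seq(-pad, total + pad, by = dz)
  prof <- sld_profile_kernel(zgrid + dz / 2, a)
  n <- length(zgrid)
  slabs <- lapply(seq_len(n), function(i) slab(dz, prof[i], 0))
  slab_stack(slabs, medium_above = stack$medium_above,
             medium_below = stack$medium_below, roughness_below = 0)
}

#' Real-space SLD profile of a stack
#'
#' Error-function-broadened scattering-length-density profile. Depth z is
#' measured from the top interface (fronting side negative).
#'
#' @param stack A [slab_stack()].
#' @param z Depth values in Angstrom.
#' @return Numeric (or complex) vector of SLD at each z.
#' @export
sld_profile <- function(stack, z) {
  stopifnot(inherits(stack, "slab_stack"))
  a <- stack_arrays(stack)
  p <- sld_profile_kernel(z, a)
  if (all(Im(p) == 0)) Re(p) else p
}

sld_profile_kernel <- function(z, a) {
  zb <- cumsum(c(0, a$d))            # positions of the n+1 interfaces
  prof <- rep(a$sld[1], length(z))
  for (j in seq_along(zb)) {
    s <- a$sigma[j]
    step <- if (s > 0) {
      0.5 * (1 + pracma::erf((z - zb[j]) / (s * sqrt(2))))
    } else {
      as.numeric(z >= zb[j])
    }
    prof <- prof + (a$sld[j + 1] - a$sld[j]) * step
  }
  prof
}

# 17-point Gauss-Hermite rule, cached at load time.
.gh_cache <- new.env(parent = emptyenv())
gauss_hermite_17 <- function() {
  if (is.null(.gh_cache$gh)) .gh_cache$gh <- pracma::gaussHermite(17)
  .gh_cache$gh
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Resolution-smeared model reflectivity
#'
#' Evaluates the Parratt model convolved with a Gaussian q-resolution of
#' constant relative FWHM `dq_over_q` (or a per-point FWHM vector `dq`),
#' using 17-point Gauss-Hermite quadrature at every output point. This is the
#' forward model used for fitting and data generation; it evaluates the exact
#' model at each quadrature node rather than interpolating a sampled curve.
#'
#' @inheritParams parratt_reflectivity
#' @param dq_over_q Fractional resolution FWHM/q (e.g. 0.07 for the usual 7
#'   percent time-of-flight binning). Ignored when `dq` is given.
#' @param dq Optional per-point FWHM in inverse Angstrom.
#' @return A [reflectivity_curve()].
#' @export
model_reflectivity <- function(stack, q, dq_over_q = 0, dq = NULL) {
  q <- as.numeric(q)
  if (is.null(dq) && dq_over_q == 0) return(parratt_reflectivity(stack, q))
  fw <- if (!is.null(dq)) as.numeric(dq) else dq_over_q * q
  sig <- fw * FWHM_TO_SIGMA
  gh <- gauss_hermite_17()
  a <- stack_arrays(stack)
  Rsm <- numeric(length(q))
  for (i in seq_along(q)) {
    qq <- q[i] + sqrt(2) * sig[i] * gh$x
    qq <- pmax(qq, 1e-6)             # clamp below-zero nodes
    Rsm[i] <- sum(gh$w * parratt_kernel(qq, a$sld, a$d, a$sigma)) / sqrt(pi)
  }
  reflectivity_curve(q, Rsm, dq = fw, contrast_label = "model")
}

#' Gaussian resolution smearing of a sampled curve
#'
#' Smears an already-sampled reflectivity curve with a Gaussian of FWHM
#' `dq_over_q * q`, by Gauss-Hermite quadrature over a linear interpolant of
#' the input samples (edge-clamped beyond the sampled range). Use
#' [model_reflectivity()] when the underlying slab model is available; this
#' variant serves measured or pre-tabulated curves.
#'
#' @param curve A [reflectivity_curve()], ideally finely sampled.
#' @param dq_over_q Fractional resolution FWHM/q (>= 0).
#' @return A [reflectivity_curve()] on the same q grid with a `dq` column.
#' @export
apply_resolution <- function(curve, dq_over_q) {
  stopifnot(inherits(curve, "reflectivity_curve"), dq_over_q >= 0)
  if (dq_over_q == 0) return(curve)
  gh <- gauss_hermite_17()
  f <- stats::approxfun(curve$q, curve$R, rule = 2)
  sig <- dq_over_q * curve$q * FWHM_TO_SIGMA
  Rsm <- vapply(seq_len(nrow(curve)), function(i) {
    sum(gh$w * f(curve$q[i] + sqrt(2) * sig[i] * gh$x)) / sqrt(pi)
  }, numeric(1))
  reflectivity_curve(curve$q, Rsm, dq = dq_over_q * curve$q,
                     contrast_label = attr(curve, "contrast_label"))
}
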