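# Chronocoulometry and differential capacitance on film-covered electrodes:
# potential-step transients -> relative charge density -> absolute
# referencing via the potential of zero charge -> film pressure by double
# integration (Lippmann relation), plus series-RC lock-in capacitance.

# 1 uC cm^-2 x 1 V = 10 mN/m (= 10 mJ m^-2).
UC_V_TO_MN_PER_M <- 10

#' Potential-step current transient
#'
#' @param E Step potential of interest, V.
#' @param t Time from the step, s, increasing from 0.
#' @param i Current density, uA/cm2 (cathodic negative).
#' @param E_des Desorption potential the film is stepped to, V.
#' @return Object of class `chrono_transient`.
#' @export
chrono_transient <- function(E, t, i, E_des = -1.05) {
  stopifnot(length(t) == length(i), length(E) == 1L)
  if (t[1] < 0 || is.unsorted(t, strictly = TRUE))
    stop("time must increase from 0")
  structure(list(E = E, t = as.numeric(t), i = as.numeric(i), E_des = E_des),
            class = "chrono_transient")
}

#' Charge density curve from potential-step transients
#'
#' Integrates each transient (trapezoidal rule) to the relative charge
#' density between its hold potential and the desorption potential, then
#' converts to absolute charge density: the bare-electrode curve is offset
#' to cross zero at its potential of zero charge, and a film curve is
#' anchored through the shared desorbed state, where film and bare surfaces
#' are equivalent.
#'
#' @param transients List of [chrono_transient()] objects covering a
#'   potential sequence.
#' @param pzc_bare Potential of zero charge of the bare electrode, V. If
#'   `NULL`, only relative charges are returned (flagged in the result).
#' @param bare A `charge_curve` for the bare electrode (already absolute);
#'   required to anchor a film curve absolutely.
#' @param label `"bare"` or `"film"`.
#' @return Object of class `charge_curve`: data.frame with `E` (V) and
#'   `sigma_M` (uC/cm2), attribute `absolute` TRUE/FALSE.
#' @export
charge_density_from_transients <- function(transients, pzc_bare = NULL,
                                           bare = NULL,
                                           label = c("bare", "film")) {
  label <- match.arg(label)
  stopifnot(length(transients) >= 2)
  E <- vapply(transients, function(tr) tr$E, numeric(1))
  # sigma(E) - sigma(desorbed state): stepping E -> E_des passes charge
  # sigma(des) - sigma(E), so the relative charge at E is minus the integral
  q_rel <- vapply(transients, function(tr) {
    -pracma::trapz(tr$t, tr$i)
  }, numeric(1))
  ord <- order(E)
  E <- E[ord]; q_rel <- q_rel[ord]
  E_des <- transients[[1]]$E_des
  absolute <- FALSE
  sigma <- q_rel
  if (label == "bare") {
    if (!is.null(pzc_bare)) {
      off <- stats::approx(E, q_rel, xout = pzc_bare, rule = 2)$y
      sigma <- q_rel - off
      absolute <- TRUE
    }
  } else {
    if (!is.null(bare)) {
      if (!isTRUE(attr(bare, "absolute")))
        stop("bare curve must be absolute to anchor a film curve")
      anchor <- stats::approx(bare$E, bare$sigma_M, xout = E_des, rule = 2)$y
      sigma <- q_rel + anchor
      absolute <- TRUE
    }
  }
  structure(data.frame(E = E, sigma_M = sigma),
            class = c("charge_curve", "data.frame"),
            label = label, absolute = absolute, E_des = E_des)
}

#' Charge curve constructor (for already-reduced data)
#'
#' @param E Potential, V.
#' @param sigma_M Charge density, uC/cm2.
#' @param label `"bare"` or `"film"`.
#' @param absolute Whether the charges are absolutely referenced.
#' @param E_des Desorption potential, V.
#' @return A `charge_curve`.
#' @export
charge_curve <- function(E, sigma_M, label = "bare", absolute = TRUE,
                         E_des = min(E)) {
  stopifnot(length(E) == length(sigma_M))
  ord <- order(E)
  structure(data.frame(E = E[ord], sigma_M = sigma_M[ord]),
            class = c("charge_curve", "data.frame"),
            label = label, absolute = absolute, E_des = E_des)
}

#' Potential of zero charge of a charge curve
#'
#' Linear interpolation between the samples bracketing the zero crossing;
#' with several crossings the one nearest the positive potential limit is
#' returned with a warning.
#'
#' @param curve A `charge_curve`.
#' @return The pzc in V.
#' @export
find_pzc <- function(curve) {
  E <- curve$E; s <- curve$sigma_M
  hit <- which(s == 0)
  cross <- which(s[-length(s)] * s[-1] < 0)
  pzcs <- c(E[hit],
            vapply(cross, function(i) {
              E[i] - s[i] * (E[i + 1] - E[i]) / (s[i + 1] - s[i])
            }, numeric(1)))
  if (!length(pzcs)) stop("charge curve does not cross zero")
  pzcs <- sort(unique(pzcs))
  if (length(pzcs) > 1)
    warning("multiple zero crossings; returning the most positive")
  max(pzcs)
}

#' Film pressure from charge-density curves
#'
#' Double integration of the Lippmann relation: the film pressure (surface
#' tension lowering) at potential E is the area between the film and bare
#' charge curves, `Pi(E) = integral from E_des to E of
#' (sigma_film - sigma_bare) dE'`, converted from uC V / cm2 to mN/m
#' (factor 10). The film curve is linearly interpolated onto the bare grid.
#'
#' @param film,bare `charge_curve` objects on overlapping potential grids.
#' @param E_des Desorption potential (integration origin), V.
#' @return Object of class `film_pressure_curve`: data.frame with `E` (V)
#'   and `Pi` (mN/m).
#' @export
film_pressure <- function(film, bare, E_des = attr(film, "E_des")) {
  lo <- max(min(film$E), min(bare$E))
  hi <- min(max(film$E), max(bare$E))
  if (lo >= hi) stop("film and bare potential grids do not overlap")
  E <- sort(unique(c(bare$E[bare$E >= lo & bare$E <= hi], E_des)))
  if (E_des < lo - 1e-9 || E_des > hi + 1e-9)
    stop("E_des must lie inside the common potential range")
  sf <- stats::approx(film$E, film$sigma_M, xout = E, rule = 2)$y
  sb <- stats::approx(bare$E, bare$sigma_M, xout = E, rule = 2)$y
  d <- sf - sb
  Pi <- pracma::cumtrapz(E, d)[, 1]
  Pi <- Pi - stats::approx(E, Pi, xout = E_des)$y   # zero at desorption
  structure(data.frame(E = E, Pi = UC_V_TO_MN_PER_M * Pi),
            class = c("film_pressure_curve", "data.frame"), E_des = E_des)
}

#' Differential capacitance from lock-in components
#'
#' Series-RC inversion of the in-phase and quadrature current responses to a
#' small AC perturbation: `C = (i_ip^2 + i_q^2) / (omega dE i_q)`. In the
#' purely capacitive limit (`i_ip = 0`) this reduces to `i_q / (omega dE)`.
#'
#' @param i_ip,i_q In-phase and quadrature current amplitudes, uA/cm2.
#' @param omega Angular frequency, rad/s (e.g. `2*pi*20` for 20 Hz).
#' @param dE_amplitude AC amplitude, V (e.g. 0.005).
#' @return Capacitance in uF/cm2 (vectorised).
#' @export
capacitance_from_lockin <- function(i_ip, i_q, omega, dE_amplitude) {
  stopifnot(dE_amplitude > 0, omega > 0)
  if (any(i_q <= 0)) stop("quadrature component must be > 0 (capacitive response)")
  (i_ip^2 + i_q^2) / (omega * dE_amplitude * i_q)
}
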