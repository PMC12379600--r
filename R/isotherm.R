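# Surface pressure-area isotherm analysis: compressibility modulus
# C_s^-1 = -A dPi/dA and extraction of the Le-Lc plateau onset and the
# Lc-S kink pressure.

#' Surface pressure-area isotherm
#'
#' @param A Molecular area, square Angstrom per molecule; strictly
#'   decreasing along compression (barrier-reversal points are dropped with
#'   a warning).
#' @param Pi Surface pressure, mN/m.
#' @param T_C Subphase temperature, Celsius (metadata).
#' @param label Composition label.
#' @return Object of class `isotherm` (a data.frame ordered by decreasing A).
#' @export
isotherm <- function(A, Pi, T_C = 19.5, label = "") {
  stopifnot(length(A) == length(Pi))
  if (any(!is.finite(A)) || any(!is.finite(Pi))) stop("A and Pi must be finite")
  ord <- order(A, decreasing = TRUE)
  A <- A[ord]; Pi <- Pi[ord]
  keep <- !duplicated(A)
  if (any(!keep)) {
    warning("dropped ", sum(!keep), " barrier-reversal/duplicate point(s)")
    A <- A[keep]; Pi <- Pi[keep]
  }
  structure(data.frame(A = A, Pi = Pi),
            class = c("isotherm", "data.frame"), T_C = T_C, label = label)
}

sg_smooth <- function(y, window, order = 3) {
  n <- length(y)
  if (is.null(window) || window <= 1 || n < window) return(y)
  if (window %% 2 == 0) window <- window + 1
  signal::sgolayfilt(y, p = min(order, window - 1), n = window)
}

# Centred finite-difference derivative on a possibly non-uniform grid.
fd_gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Compressibility modulus along an isotherm
#'
#' `C_s^-1 = -A dPi/dA` at fixed molecule number and temperature, from
#' centred finite differences on an optionally Savitzky-Golay-smoothed
#' pressure trace. A stiffer film has a larger modulus; it vanishes on a
#' coexistence plateau.
#'
#' @param iso An [isotherm()] (>= 5 points).
#' @param window Savitzky-Golay window length in points (odd; `NULL` for raw
#'   differentiation). Default 9, polynomial order 3.
#' @param order Savitzky-Golay polynomial order.
#' @return data.frame with columns `A`, `Pi`, `Cs_inv` (mN/m), aligned to
#'   the isotherm.
#' @export
compressibility_modulus <- function(iso, window = 9, order = 3) {
  stopifnot(inherits(iso, "isotherm"))
  if (nrow(iso) < 5) stop("need at least 5 isotherm points")
  if (is.unsorted(rev(iso$A), strictly = TRUE))
    stop("A must be strictly decreasing after cleaning")
  Pis <- sg_smooth(iso$Pi, window, order)
  dPi <- fd_gradient(Pis, iso$A)
  data.frame(A = iso$A, Pi = iso$Pi, Cs_inv = -iso$A * dPi)
}

#' Detect phase-transition pressures
#'
#' Finds the liquid-expanded to liquid-condensed (Le-Lc) plateau onset and
#' the liquid-condensed to solid (Lc-S) kink. The plateau is located as the
#' run of near-zero slope flanked by steeper branches; the onset pressure is
#' the intersection of the tangent to the Le branch with the plateau line.
#' The kink is located at the maximum of the second derivative of Pi(A) in
#' the condensed region and its pressure refined as the intersection of the
#' two condensed branch tangents. Absent features are reported as absent
#' (`NA`), never fabricated.
#'
#' @param iso An [isotherm()].
#' @param window Smoothing window (points) used before differentiation.
#' @return Object of class `transition_set`: list with `Pi_LeLc_onset`,
#'   `A_LeLc`, `Pi_LcS`, `A_LcS` (each `NA` when the feature is absent).
#' @export
detect_transitions <- function(iso, window = 9) {
  stopifnot(inherits(iso, "isotherm"))
  n <- nrow(iso)
  if (n < 15) stop("isotherm too short for transition detection")
  A <- iso$A
  Pis <- sg_smooth(iso$Pi, window)
  # a wider window for region finding and guards: finite-difference slopes
  # amplify pressure noise on densely sampled isotherms
  w2 <- max(window, (n %/% 16) %/% 2 * 2 + 1)
  slope_s <- sg_smooth(-fd_gradient(sg_smooth(iso$Pi, w2), A), w2)
  edge <- max(3L, w2 %/% 2 + 2L)
  core <- (edge + 1):(n - edge)
  # reference Le-branch slope: first decile of the compression
  i_le <- core[core <= stats::quantile(core, 0.12)]
  m_le <- stats::median(slope_s[i_le])
  m_min <- min(slope_s[core])
  i_min <- core[which.min(slope_s[core])]
  out <- list(Pi_LeLc_onset = NA_real_, A_LeLc = NA_real_,
              Pi_LcS = NA_real_, A_LcS = NA_real_)
  plateau_idx <- integer(0)
  if (is.finite(m_le) && m_le > 0 && m_min < 0.4 * m_le && i_min > min(i_le)) {
    thr <- 0.4 * m_le   # plateau shoulder level, robust to noisy slope dips
    # contiguous sub-threshold run around the slope minimum
    mask <- slope_s <= thr
    lo <- hi <- i_min
    while (lo - 1 >= min(core) && mask[lo - 1]) lo <- lo - 1
    while (hi + 1 <= max(core) && mask[hi + 1]) hi <- hi + 1
    plateau_idx <- lo:hi
    # require steeper slopes on both sides (otherwise it is an endpoint sag)
    left_ok <- any(slope_s[core[core < lo]] > 2 * thr)
    right_ok <- any(slope_s[core[core > hi]] > 2 * thr)
    if (left_ok && right_ok && length(plateau_idx) >= 8) {
      trim <- min(5L, (length(plateau_idx) - 3L) %/% 2)
      pl_fit <- plateau_idx[(trim + 1):(length(plateau_idx) - trim)]
      le_idx <- core[core < lo - 5 & slope_s[core] > 0.7 * m_le]
      if (length(le_idx) >= 3 && length(pl_fit) >= 3) {
        f_le <- stats::lm(Pis[le_idx] ~ A[le_idx])
        f_pl <- stats::lm(Pis[pl_fit] ~ A[pl_fit])
        cA <- -(f_le$coefficients[1] - f_pl$coefficients[1]) /
          (f_le$coefficients[2] - f_pl$coefficients[2])
        out$A_LeLc <- unname(cA)
        out$Pi_LeLc_onset <- unname(f_pl$coefficients[1] +
                                      f_pl$coefficients[2] * cA)
      }
    } else plateau_idx <- integer(0)
  }
  # kink search in the condensed region (below the plateau, or everywhere)
  cond <- if (length(plateau_idx)) core[core > max(plateau_idx) + 5] else core
  # kink = change point of the slope between the two condensed branches,
  # located by a sliding two-window median contrast (robust to noise without
  # wide smoothing, which would wash out a short solid branch)
  h <- max(5L, n %/% 40)
  excl <- max(3L, window %/% 2 + 2L)
  slope_f <- sg_smooth(-fd_gradient(Pis, A), window)
  cand <- cond[cond > min(cond) + h + excl - 1 & cond < max(cond) - h - excl + 1]
  if (length(cand) > 5) {
    D <- vapply(cand, function(i)
      stats::median(slope_f[(i + excl):(i + excl + h - 1)]) -
        stats::median(slope_f[(i - excl - h + 1):(i - excl)]), numeric(1))
    i_k <- cand[which.max(D)]
    left <- max(min(cond), i_k - excl - 2L * h + 1L):(i_k - excl)
    right <- (i_k + excl):min(max(cond), i_k + excl + 2L * h - 1L)
    m1 <- stats::median(slope_f[left]); m2 <- stats::median(slope_f[right])
    if (m1 > 0 && m2 > 1.5 * m1 && max(D) > 0.5 * max(m1, 0.5 * m_le)) {
      f1 <- stats::lm(Pis[left] ~ A[left])
      f2 <- stats::lm(Pis[right] ~ A[right])
      cA <- -(f1$coefficients[1] - f2$coefficients[1]) /
        (f1$coefficients[2] - f2$coefficients[2])
      out$A_LcS <- unname(cA)
      out$Pi_LcS <- unname(f1$coefficients[1] + f1$coefficients[2] * cA)
    }
  }
  if (is.finite(out$Pi_LeLc_onset) && is.finite(out$Pi_LcS) &&
      out$Pi_LeLc_onset >= out$Pi_LcS)
    warning("detected onset pressure not below kink pressure; check isotherm")
  structure(out, class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  fmt <- function(v) if (is.finite(v)) sprintf("%.2f", v) else "absent"
  cat("transition_set: Le-Lc onset", fmt(x$Pi_LeLc_onset),
      "mN/m; Lc-S kink", fmt(x$Pi_LcS), "mN/m\n")
  invisible(x)
}

#' Ideal-mixing reference area
#'
#' Linear (ideal-mixing) reference for a mixture's molecular area, on a
#' molecule or chain basis; the corresponding excess is given by
#' [excess_area()].
#'
#' @inheritParams excess_area
#' @return The ideal-mixing area.
#' @export
ideal_mixing_area <- function(component_areas, fractions,
                              basis = c("molecules", "chains"),
                              n_chains = NULL) {
  basis <- match.arg(basis)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  w <- if (basis == "chains") {
    if (is.null(n_chains)) stop("basis = 'chains' needs n_chains")
    cf <- fractions * n_chains
    cf / sum(cf)
  } else fractions
  sum(w * component_areas)
}
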