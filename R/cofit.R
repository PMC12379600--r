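# Multi-contrast grid co-refinement of the two-slab monolayer model.
#
# Roughness sigma and tail volume V_tail are stepped on a fixed grid; at each
# grid point d_tail, d_hg, the headgroup solvent fraction and one intensity
# scale per dataset are refined by bounded Levenberg-Marquardt, jointly
# across all contrasts with shared structural parameters.

DEFAULT_BOUNDS <- list(d_tail = c(8, 30), d_hg = c(3, 16),
                       solvent_fraction = c(0, 1), scale = c(0.5, 2))

# Residual vector over all datasets for a free-parameter vector theta.
cofit_residuals <- function(theta, ctx) {
  nd <- length(ctx$datasets)
  p <- monolayer_params(ctx$composition, V_tail = ctx$V_tail,
                        d_tail = theta[["d_tail"]], d_hg = theta[["d_hg"]],
                        sigma = ctx$sigma,
                        solvent_fraction = min(max(theta[["solvent_fraction"]], 0), 1))
  unlist(lapply(seq_len(nd), function(i) {
    ds <- ctx$datasets[[i]]
    st <- build_stack(p, ctx$contrasts[[i]], V_water = ctx$V_water)
    Rm <- model_reflectivity(st, ds$q, dq_over_q = ctx$dq_over_q[i],
                             dq = ds$dq)$R
    sc <- theta[[paste0("scale", i)]]
    (sc * Rm - ds$R) / ds$dR
  }))
}

fit_one_grid_point <- function(ctx, init, n_starts, rng) {
  nd <- length(ctx$datasets)
  nm <- c("d_tail", "d_hg", "solvent_fraction", paste0("scale", seq_len(nd)))
  lower <- c(DEFAULT_BOUNDS$d_tail[1], DEFAULT_BOUNDS$d_hg[1],
             DEFAULT_BOUNDS$solvent_fraction[1],
             rep(DEFAULT_BOUNDS$scale[1], nd))
  upper <- c(DEFAULT_BOUNDS$d_tail[2], DEFAULT_BOUNDS$d_hg[2],
             DEFAULT_BOUNDS$solvent_fraction[2],
             rep(DEFAULT_BOUNDS$scale[2], nd))
  names(lower) <- names(upper) <- nm
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- init
    if (s > 1) {   # jittered restarts guard against local minima
      jit <- rng(length(nm))
      th0 <- pmin(pmax(init * (1 + 0.15 * jit), lower * 1.0001), upper * 0.9999)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = cofit_residuals, ctx = ctx,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    if (is.null(best) || chi2 < best$chi2)
      best <- list(fit = fit, chi2 = chi2, converged = fit$info %in% 1:4)
  }
  best
}

#' Grid-scan multi-contrast co-refinement
#'
#' For every (sigma, V_tail) grid point, refines `d_tail`, `d_hg`, the
#' headgroup solvent fraction and one intensity scale per dataset by bounded
#' weighted least squares jointly across the supplied contrasts (shared slab
#' thicknesses, roughness and tail SLD). Results are returned for all grid
#' points, sorted by chi-squared.
#'
#' @param datasets List of [reflectivity_curve()] objects (must carry `dR`).
#' @param contrasts List of [contrast_spec()], parallel to `datasets`.
#' @param composition A [lipid_mixture()] shared by all datasets.
#' @param sigma_grid,vtail_grid Numeric grids of fixed roughness (Angstrom)
#'   and tail volume per pair (cubic Angstrom). Defaults bracket the values
#'   typical of condensed myristoyl monolayers.
#' @param init Named starting values for `d_tail`, `d_hg`,
#'   `solvent_fraction` (scales start at 1).
#' @param dq_over_q Fractional resolution per dataset (recycled). Ignored
#'   for datasets carrying their own `dq` column.
#' @param q_min Optional per-dataset lower q cut (recycled); data below it
#'   are dropped before fitting (e.g. the total-reflection region of a D2O
#'   contrast).
#' @param n_starts Number of jittered optimiser starts per grid point.
#' @param seed Seed for the start jitter.
#' @param V_water Water molecular volume, cubic Angstrom.
#' @return Object of class `cofit_results`: list of `cofit_fit` objects
#'   sorted by chi-squared.
#' @export
cofit_grid <- function(datasets, contrasts, composition,
                       sigma_grid = seq(3.0, 4.5, by = 0.1),
                       vtail_grid = seq(650, 685, by = 2.5),
                       init = c(d_tail = 16, d_hg = 8, solvent_fraction = 0.1),
                       dq_over_q = 0, q_min = NULL, n_starts = 5, seed = 1,
                       V_water = V_WATER_DEFAULT) {
  if (inherits(datasets, "reflectivity_curve")) datasets <- list(datasets)
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  stopifnot(length(datasets) >= 1, length(datasets) == length(contrasts),
            length(sigma_grid) >= 1, length(vtail_grid) >= 1)
  dq_over_q <- rep_len(dq_over_q, length(datasets))
  if (!is.null(q_min)) {
    q_min <- rep_len(q_min, length(datasets))
    datasets <- lapply(seq_along(datasets), function(i) {
      ds <- datasets[[i]]
      ds[ds$q >= q_min[i], , drop = FALSE]
    })
  }
  datasets <- lapply(datasets, function(ds) {
    if (is.null(ds$dR)) ds$dR <- pmax(0.01 * ds$R, 1e-12)
    ds$dR <- pmax(ds$dR, 1e-15)
    ds
  })
  rng_state <- local({
    set.seed(seed)
    function(n) stats::runif(n, -1, 1)
  })
  nd <- length(datasets)
  init_full <- c(init, stats::setNames(rep(1, nd), paste0("scale", seq_len(nd))))
  results <- list()
  for (sg in sigma_grid) for (vt in vtail_grid) {
    ctx <- list(datasets = datasets, contrasts = contrasts,
                composition = composition, sigma = sg, V_tail = vt,
                dq_over_q = dq_over_q, V_water = V_water)
    b <- fit_one_grid_point(ctx, init_full, n_starts, rng_state)
    if (is.null(b)) {
      results[[length(results) + 1L]] <-
        structure(list(grid_point = c(sigma = sg, V_tail = vt),
                       chi2 = Inf, converged = FALSE),
                  class = "cofit_fit")
      next
    }
    th <- b$fit$par
    n_obs <- sum(vapply(datasets, nrow, integer(1)))
    n_par <- length(th)
    p <- monolayer_params(composition, V_tail = vt, d_tail = th[["d_tail"]],
                          d_hg = th[["d_hg"]], sigma = sg,
                          solvent_fraction = th[["solvent_fraction"]])
    phi <- th[["solvent_fraction"]]
    A_M <- vt / th[["d_tail"]]
    V_solv <- A_M * th[["d_hg"]]
    derived <- structure(list(A_M = A_M,
                              V_head = (1 - phi) * V_solv,
                              n_w = phi * V_solv / V_water,
                              V_total = vt + (1 - phi) * V_solv,
                              V_solvated = V_solv),
                         class = "derived_structure")
    results[[length(results) + 1L]] <- structure(
      list(best_params = p, theta = th,
           scales = th[grep("^scale", names(th))],
           chi2 = b$chi2, chi2_reduced = b$chi2 / max(n_obs - n_par, 1),
           n_obs = n_obs, n_par = n_par,
           derived = derived,
           grid_point = c(sigma = sg, V_tail = vt),
           converged = b$converged, ctx = ctx),
      class = "cofit_fit")
  }
  ord <- order(vapply(results, function(r) r$chi2, numeric(1)))
  structure(results[ord], class = "cofit_results")
}

#' @export
print.cofit_fit <- function(x, ...) {
  cat(sprintf("cofit_fit: sigma=%.2f V_tail=%.1f  chi2=%.4g (red. %.3g)%s\n",
              x$grid_point["sigma"], x$grid_point["V_tail"], x$chi2,
              x$chi2_reduced, if (isTRUE(x$converged)) "" else "  [not converged]"))
  if (!is.null(x$theta))
    cat(sprintf("  d_tail=%.2f  d_hg=%.2f  phi=%.3f  A_M=%.2f  n_w=%.2f  V_head=%.0f\n",
                x$theta[["d_tail"]], x$theta[["d_hg"]],
                x$theta[["solvent_fraction"]], x$derived$A_M, x$derived$n_w,
                x$derived$V_head))
  invisible(x)
}

#' @export
print.cofit_results <- function(x, ...) {
  cat("cofit_results:", length(x), "grid point(s), best first\n")
  for (r in utils::head(x, 5)) print(r)
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}

# Profile chi2 for one parameter fixed at `value`, re-optimising the others.
profile_chi2 <- function(fit, par_name, value) {
  ctx <- fit$ctx
  th <- fit$theta
  free <- setdiff(names(th), par_name)
  lower <- c(DEFAULT_BOUNDS$d_tail[1], DEFAULT_BOUNDS$d_hg[1],
             DEFAULT_BOUNDS$solvent_fraction[1],
             rep(DEFAULT_BOUNDS$scale[1], length(ctx$datasets)))
  upper <- c(DEFAULT_BOUNDS$d_tail[2], DEFAULT_BOUNDS$d_hg[2],
             DEFAULT_BOUNDS$solvent_fraction[2],
             rep(DEFAULT_BOUNDS$scale[2], length(ctx$datasets)))
  names(lower) <- names(upper) <- names(th)
  fn <- function(sub) {
    full <- th; full[free] <- sub; full[par_name] <- value
    cofit_residuals(full, ctx)
  }
  f <- minpack.lm::nls.lm(par = th[free], lower = lower[free],
                          upper = upper[free], fn = fn,
                          control = minpack.lm::nls.lm.control(maxiter = 100))
  sum(f$fvec^2)
}

param_bound <- function(par_name) {
  if (grepl("^scale", par_name)) DEFAULT_BOUNDS$scale
  else DEFAULT_BOUNDS[[par_name]]
}

#' Profile-likelihood confidence ranges
#'
#' One-parameter chi-squared profiling: each free parameter is stepped away
#' from its best value, the remaining parameters re-optimised, and the range
#' where `chi2 <= chi2_min + qchisq(level, 1)` (3.84 for 95 percent) is
#' bracketed and refined by root finding. Ranges that run into a parameter
#' bound are flagged one-sided/open.
#'
#' @param fit A converged `cofit_fit` (from [cofit_grid()]).
#' @param level Confidence level, default 0.95.
#' @param parameters Which free parameters to profile (default all three
#'   structural ones).
#' @return data.frame with columns `parameter`, `best`, `low`, `high`,
#'   `open_low`, `open_high`.
#' @export
confidence_ranges <- function(fit, level = 0.95,
                              parameters = c("d_tail", "d_hg",
                                             "solvent_fraction")) {
  stopifnot(inherits(fit, "cofit_fit"))
  if (!isTRUE(fit$converged)) stop("confidence ranges need a converged fit")
  dchi <- stats::qchisq(level, df = 1)
  target <- fit$chi2 + dchi
  out <- lapply(parameters, function(pn) {
    best <- fit$theta[[pn]]
    bnd <- param_bound(pn)
    side <- function(dir) {
      lim <- if (dir > 0) bnd[2] else bnd[1]
      step <- max(abs(best) * 0.02, 0.002)
      x_in <- best; x_out <- NA; open <- FALSE
      repeat {
        x <- x_in + dir * step
        if ((dir > 0 && x >= lim) || (dir < 0 && x <= lim)) {
          x <- lim
          if (profile_chi2(fit, pn, x) < target) {
            open <- TRUE; x_out <- lim; break
          }
        }
        if (profile_chi2(fit, pn, x) >= target) { x_out <- x; break }
        x_in <- x
        step <- step * 1.6
      }
      if (open) return(list(x = x_out, open = TRUE))
      r <- stats::uniroot(function(z) profile_chi2(fit, pn, z) - target,
                          lower = min(x_in, x_out), upper = max(x_in, x_out),
                          tol = max(abs(best), 1) * 1e-4)
      list(x = r$root, open = FALSE)
    }
    lo <- side(-1); hi <- side(+1)
    data.frame(parameter = pn, best = best, low = lo$x, high = hi$x,
               open_low = lo$open, open_high = hi$open)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select the best model given a reference molecular area
#'
#' Among grid-point fits whose chi-squared is within `(1 + rel_tol)` of the
#' minimum, returns the one whose molecular area `A_M` is closest to the
#' reference area (from diffraction or the isotherm). This makes the
#' two-criterion choice - goodness of fit and agreement with the
#' independently measured area - deterministic.
#'
#' @param results A `cofit_results` list (or list of `cofit_fit`).
#' @param reference_area Reference molecular area per pair of chains (square
#'   Angstrom).
#' @param rel_tol Relative chi-squared acceptance band (default 0.02).
#' @return The selected `cofit_fit`, with attributes `chi2_min` and
#'   `area_distance`.
#' @export
select_best_model <- function(results, reference_area, rel_tol = 0.02) {
  if (inherits(results, "cofit_fit")) results <- list(results)
  results <- Filter(function(r) is.finite(r$chi2), results)
  if (!length(results)) stop("no usable fits to select from")
  chi2s <- vapply(results, function(r) r$chi2, numeric(1))
  chi2_min <- min(chi2s)
  band <- results[chi2s <= (1 + rel_tol) * chi2_min]
  areas <- vapply(band, function(r) r$derived$A_M, numeric(1))
  pick <- band[[which.min(abs(areas - reference_area))]]
  attr(pick, "chi2_min") <- chi2_min
  attr(pick, "area_distance") <- abs(pick$derived$A_M - reference_area)
  pick
}
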