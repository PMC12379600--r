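#' Two-slab monolayer parameterization
#'
#' The monolayer is described by a tail slab (hydrocarbon chains only,
#' C13H27 per myristoyl chain) over a headgroup slab (glycerol backbone,
#' carbonyls, phosphate, polar group) on the subphase, with one common
#' Gaussian roughness at all three interfaces. All volumes and areas are per
#' pair of chains, so a four-chain cardiolipin contributes two pairs.
#'
#' @param composition A [lipid_mixture()].
#' @param V_tail Tail volume per pair of chains, cubic Angstrom (held fixed
#'   during a fit).
#' @param d_tail Tail slab thickness, Angstrom.
#' @param d_hg Headgroup slab thickness, Angstrom.
#' @param sigma Common interfacial roughness, Angstrom.
#' @param solvent_fraction Volume fraction of subphase water in the headgroup
#'   slab, in `[0, 1]`.
#' @param V_head Unsolvated headgroup volume per pair of chains (cubic
#'   Angstrom). If `NULL` (the default) the headgroup material is assumed to
#'   fill the non-solvent part of the slab, `V_head = (1 - phi) * A_M * d_hg`.
#' @return Object of class `monolayer_params`.
#' @export
monolayer_params <- function(composition, V_tail, d_tail, d_hg, sigma,
                             solvent_fraction, V_head = NULL) {
  stopifnot(inherits(composition, "lipid_mixture"))
  if (any(c(V_tail, d_tail, d_hg) <= 0)) stop("volumes and lengths must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (solvent_fraction < 0 || solvent_fraction > 1)
    stop("solvent_fraction must be in [0, 1]")
  structure(list(composition = composition, V_tail = V_tail, d_tail = d_tail,
                 d_hg = d_hg, sigma = sigma,
                 solvent_fraction = solvent_fraction, V_head = V_head),
            class = "monolayer_params")
}

#' @export
print.monolayer_params <- function(x, ...) {
  cat("monolayer_params:",
      paste0(x$composition$name, ":", signif(x$composition$mole_fraction, 3),
             collapse = " "), "\n")
  cat(sprintf("  V_tail=%.1f A^3  d_tail=%.2f A  d_hg=%.2f A  sigma=%.2f A  phi=%.3f\n",
              x$V_tail, x$d_tail, x$d_hg, x$sigma, x$solvent_fraction))
  cat(sprintf("  A_M = V_tail/d_tail = %.2f A^2 per pair of chains\n",
              x$V_tail / x$d_tail))
  invisible(x)
}

#' Build the two-slab stack for a contrast
#'
#' air | tail slab | headgroup slab | subphase, with the same roughness at
#' all three interfaces. The headgroup slab SLD is the volume-weighted mix of
#' headgroup material and subphase water.
#'
#' @param params A [monolayer_params()].
#' @param contrast A [contrast_spec()].
#' @param V_water Water molecular volume, cubic Angstrom.
#' @return A [slab_stack()].
#' @export
build_stack <- function(params, contrast, V_water = V_WATER_DEFAULT) {
  stopifnot(inherits(params, "monolayer_params"))
  A_M <- params$V_tail / params$d_tail
  phi <- params$solvent_fraction
  V_solv <- A_M * params$d_hg
  V_head <- if (is.null(params$V_head)) (1 - phi) * V_solv else params$V_head
  sl <- contrast_slds(params$composition, contrast,
                      V_tail = params$V_tail, V_water = V_water)
  head_mat_sld <- if (V_head > 0) sl$head_b / V_head else 0
  head_slab_sld <- (1 - phi) * head_mat_sld + phi * sl$subphase_sld
  slab_stack(
    list(slab(params$d_tail, sl$tail_sld, params$sigma),
         slab(params$d_hg, head_slab_sld, params$sigma)),
    medium_above = 0,
    medium_below = sl$subphase_sld,
    roughness_below = params$sigma)
}

#' Derived structural quantities from a fitted headgroup slab
#'
#' Inverts the slab-SLD mixing relation: given the fitted headgroup slab SLD,
#' the solvated headgroup volume `A_M * d_hg` and the known headgroup
#' scattering length, solve for the number of waters per lipid (per pair of
#' chains) and the unsolvated headgroup volume,
#' `n_w = (rho_slab * A_M * d_hg - b_head) / b_water` and
#' `V_head = A_M * d_hg - n_w * V_water`.
#'
#' @param params A [monolayer_params()] (supplies composition, V_tail,
#'   d_tail, d_hg).
#' @param head_slab_sld Fitted headgroup slab SLD (inverse square Angstrom).
#' @param contrast A [contrast_spec()].
#' @param V_water Water molecular volume, cubic Angstrom.
#' @param tol Tolerance (waters) before a negative solvation is flagged.
#' @return Object of class `derived_structure` with fields `A_M`, `V_head`,
#'   `n_w`, `V_total`, `V_solvated` (all per pair of chains).
#' @export
derive_structure <- function(params, head_slab_sld, contrast,
                             V_water = V_WATER_DEFAULT, tol = 0.05) {
  stopifnot(inherits(params, "monolayer_params"))
  A_M <- params$V_tail / params$d_tail
  if (A_M <= 0) stop("A_M must be > 0")
  V_solv <- A_M * params$d_hg
  sl <- contrast_slds(params$composition, contrast, V_water = V_water)
  n_w <- (head_slab_sld * V_solv - sl$head_b) / sl$water_b
  if (n_w < -tol)
    warning(sprintf("negative solvation: n_w = %.3f waters per lipid", n_w))
  V_head <- V_solv - n_w * V_water
  structure(list(A_M = A_M, V_head = V_head, n_w = n_w,
                 V_total = params$V_tail + V_head, V_solvated = V_solv),
            class = "derived_structure")
}

#' @export
print.derived_structure <- function(x, ...) {
  cat(sprintf("A_M = %.2f A^2  V_head = %.0f A^3  n_w = %.2f  V_total = %.0f A^3\n",
              x$A_M, x$V_head, x$n_w, x$V_total))
  invisible(x)
}

# Headgroup slab SLD implied by (V_head, n_w) under a contrast; used by the
# generators and the round-trip tests.
head_slab_sld_from <- function(params, n_w, contrast,
                               V_water = V_WATER_DEFAULT) {
  A_M <- params$V_tail / params$d_tail
  V_solv <- A_M * params$d_hg
  sl <- contrast_slds(params$composition, contrast, V_water = V_water)
  (sl$head_b + n_w * sl$water_b) / V_solv
}
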