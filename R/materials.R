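# Coherent neutron scattering lengths (fm) and electron counts for the
# elements occurring in phospholipids and their subphases.
NEUTRON_B_FM <- c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36,
                  O = 5.803, P = 5.13, Na = 3.63)
ELECTRONS <- c(H = 1, D = 1, C = 6, N = 7, O = 8, P = 15, Na = 11)
R_E_ANGSTROM <- 2.8179403e-5   # classical electron radius in Angstrom
FM_TO_ANGSTROM <- 1e-5
#' Default water molecular volume (cubic Angstrom, 19.5 C)
#' @export
V_WATER_DEFAULT <- 30.0

#' Parse a chemical formula into element counts
#'
#' @param formula Character like `"C26H54"` or `"C9H8O17P2Na2"`.
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]+$", "", toks)
  n <- as.numeric(sub("^[A-Za-z]+", "", paste0(toks, "")))
  n[is.na(n)] <- 1
  counts <- tapply(n, el, sum)
  out <- as.numeric(counts); names(out) <- names(counts)
  out
}

# Total coherent scattering length of a formula, in Angstrom.
# radiation "neutron" or "xray"; deuterate swaps all H for D.
formula_b <- function(counts, radiation, deuterate = FALSE) {
  if (deuterate && "H" %in% names(counts)) {
    counts["D"] <- sum(counts[c("D", "H")], na.rm = TRUE)
    counts <- counts[names(counts) != "H"]
    counts <- counts[!is.na(counts)]
  }
  unknown <- setdiff(names(counts), names(NEUTRON_B_FM))
  if (length(unknown))
    stop("unknown element(s) in formula: ", paste(unknown, collapse = ", "))
  if (radiation == "neutron") {
    sum(counts * NEUTRON_B_FM[names(counts)]) * FM_TO_ANGSTROM
  } else {
    sum(counts * ELECTRONS[names(counts)]) * R_E_ANGSTROM
  }
}

#' Lipid definition table
#'
#' Reads the shipped lipid registry (name, chain count, per-pair tail
#' formula, headgroup formula, exchangeable-H count). A user file with the
#' same columns can be supplied to add or override lipids.
#'
#' @param path Optional path to a CSV with the same columns as the shipped
#'   `lipids.csv`.
#' @return A data.frame, one row per lipid.
#' @export
lipid_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lipids.csv", package = "monofilm",
                        mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "n_chains", "tail_formula_per_pair", "head_formula",
            "n_exchangeable_H")
  if (!all(need %in% names(reg)))
    stop("lipid registry must have columns: ", paste(need, collapse = ", "))
  reg
}

LIPID_ALIASES <- c(PE = "DMPE", PG = "DMPG", CL = "TMCL")

#' Lipid mixture (monolayer composition)
#'
#' @param fractions Named numeric vector of mole fractions (per molecule),
#'   summing to 1. Names are registry names or the short aliases PE, PG, CL.
#' @param tails_deuterated Logical, recycled; `TRUE` marks a tail-deuterated
#'   analogue (d54 chains).
#' @param registry A [lipid_registry()] data.frame.
#' @return An object of class `lipid_mixture`: a data.frame with one row per
#'   component and per-pair-of-chains weights in column `pair_fraction`.
#' @export
lipid_mixture <- function(fractions, tails_deuterated = FALSE,
                          registry = lipid_registry()) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("mole fractions must sum to 1")
  nm <- names(fractions)
  nm <- ifelse(nm %in% names(LIPID_ALIASES), LIPID_ALIASES[nm], nm)
  idx <- match(nm, registry$name)
  if (anyNA(idx)) stop("unknown lipid(s): ", paste(nm[is.na(idx)], collapse = ", "))
  comp <- registry[idx, , drop = FALSE]
  comp$mole_fraction <- as.numeric(fractions)
  comp$tails_deuterated <- rep_len(as.logical(tails_deuterated), nrow(comp))
  pw <- comp$mole_fraction * comp$n_chains / 2
  comp$pair_fraction <- pw / sum(pw)
  rownames(comp) <- NULL
  structure(comp, class = c("lipid_mixture", "data.frame"))
}

#' Measurement contrast
#'
#' @param radiation `"xray"` or `"neutron"`.
#' @param subphase `"water"`, `"D2O"` or `"ACMW"` (air-contrast-matched
#'   water, 8 percent v/v D2O). Heavy-water subphases require neutrons.
#' @param energy_keV X-ray photon energy (metadata only; SLDs here use the
#'   non-resonant electron-density limit).
#' @param exchange Named integer vector: for each lipid in the composition,
#'   how many of its exchangeable headgroup hydrogens exchange with the
#'   subphase. Required for neutron contrasts (there is no safe default:
#'   plausible scenarios differ, e.g. 0 or 1 of the PE ammonium hydrogens).
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(radiation = c("xray", "neutron"),
                          subphase = c("water", "D2O", "ACMW"),
                          energy_keV = 12.5, exchange = NULL) {
  radiation <- match.arg(radiation)
  subphase <- match.arg(subphase)
  if (radiation == "xray" && subphase != "water")
    stop("D2O/ACMW subphases are neutron contrasts")
  if (radiation == "neutron" && is.null(exchange))
    stop("neutron contrasts require an explicit H/D exchange scenario")
  structure(list(radiation = radiation, subphase = subphase,
                 energy_keV = energy_keV, exchange = exchange),
            class = "contrast_spec")
}

# Deuterium fraction presented to exchangeable hydrogens.
subphase_d_fraction <- function(subphase) {
  switch(subphase, water = 0, D2O = 1, ACMW = 0.08)
}

# Scattering length of one subphase water molecule (Angstrom).
water_b <- function(contrast) {
  if (contrast$radiation == "xray") return(10 * R_E_ANGSTROM)
  fD <- subphase_d_fraction(contrast$subphase)
  (2 * ((1 - fD) * NEUTRON_B_FM["H"] + fD * NEUTRON_B_FM["D"]) +
     NEUTRON_B_FM["O"]) * FM_TO_ANGSTROM
}

#' Scattering length densities of a composition under a contrast
#'
#' Mole-fraction-weighted (per pair of chains) scattering lengths and SLDs of
#' the tail and headgroup regions plus the subphase. A cardiolipin molecule
#' counts as two pairs of chains, so all quantities are comparable across
#' two- and four-chain lipids.
#'
#' @param composition A [lipid_mixture()].
#' @param contrast A [contrast_spec()].
#' @param V_tail Tail volume per pair of chains (cubic Angstrom); needed for
#'   `tail_sld`.
#' @param V_head Unsolvated headgroup volume per pair (cubic Angstrom);
#'   needed for `head_sld`.
#' @param V_water Water molecular volume (cubic Angstrom).
#' @return List with `tail_b`, `head_b` (scattering lengths per pair of
#'   chains, Angstrom), `tail_sld`, `head_sld` (if volumes given),
#'   `subphase_sld`, `water_b`.
#' @export
contrast_slds <- function(composition, contrast, V_tail = NULL, V_head = NULL,
                          V_water = V_WATER_DEFAULT) {
  stopifnot(inherits(composition, "lipid_mixture"),
            inherits(contrast, "contrast_spec"))
  rad <- contrast$radiation
  fD <- if (rad == "neutron") subphase_d_fraction(contrast$subphase) else 0
  dB_ex <- (NEUTRON_B_FM["D"] - NEUTRON_B_FM["H"]) * FM_TO_ANGSTROM
  tail_b <- 0; head_b <- 0
  for (i in seq_len(nrow(composition))) {
    row <- composition[i, ]
    p <- row$pair_fraction
    tail_b <- tail_b + p * formula_b(parse_formula(row$tail_formula_per_pair),
                                     rad, deuterate = row$tails_deuterated)
    hb <- formula_b(parse_formula(row$head_formula), rad)
    if (rad == "neutron") {
      n_ex <- exchange_count(contrast$exchange, row$name, row$n_exchangeable_H)
      hb <- hb + n_ex * fD * dB_ex
    }
    head_b <- head_b + p * hb / (row$n_chains / 2)
  }
  wb <- water_b(contrast)
  out <- list(tail_b = unname(tail_b), head_b = unname(head_b),
              subphase_sld = unname(wb / V_water), water_b = unname(wb))
  if (!is.null(V_tail)) out$tail_sld <- out$tail_b / V_tail
  if (!is.null(V_head)) out$head_sld <- out$head_b / V_head
  out
}

exchange_count <- function(exchange, name, n_max) {
  if (is.null(exchange)) stop("exchange scenario required for neutron SLDs")
  alias <- names(LIPID_ALIASES)[match(name, LIPID_ALIASES)]
  key <- intersect(c(name, alias), names(exchange))
  if (!length(key))
    stop("exchange scenario missing for lipid ", name)
  n <- exchange[[key[1]]]
  if (n < 0 || n > n_max)
    stop("exchange count for ", name, " must be in 0..", n_max)
  n
}
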