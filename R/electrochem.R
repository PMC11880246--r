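# Equilibrium (Nernst) and reversal (GHK) potential solvers, and
# permeability-ratio inversion. Units: mV, mM, K throughout.

# CODATA physical constants
.GAS_CONSTANT <- 8.31446261815324   # J / (mol K)
.FARADAY      <- 96485.33212        # C / mol

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_K absolute temperature in kelvin.
#' @return RT/F in mV (about 25.69 mV at 298.15 K).
#' @export
rt_over_f_mV <- function(temperature_K) {
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    abort_bl("temperature_K must be > 0", "bl_domain_error")
  1000 * .GAS_CONSTANT * temperature_K / .FARADAY
}

#' Define an ion species of a bath pair
#'
#' Concentrations are given for the two sides of the bilayer. The "out"
#' side is the cis chamber (the protein-addition side) and "in" is trans;
#' this orientation makes a cation-selective channel in a 500:50 mM
#' cis:trans KCl gradient reverse at a positive potential.
#'
#' @param name short label, e.g. "K", "Ca", "Cl".
#' @param valence signed charge: -1, +1 or +2 for the supported equations.
#' @param conc_out_mM,conc_in_mM concentrations on the out (cis) and
#'   in (trans) sides, mM.
#' @param permeability non-negative relative permeability; one species is
#'   conventionally the reference with permeability 1.
#' @return an object of class `ion_species`.
#' @export
ion_species <- function(name, valence, conc_out_mM, conc_in_mM,
                        permeability = 1) {
  if (!valence %in% c(-1L, 1L, 2L))
    abort_bl("valence must be -1, +1 or +2", "bl_domain_error")
  if (conc_out_mM < 0 || conc_in_mM < 0)
    abort_bl("concentrations must be >= 0", "bl_domain_error")
  if (permeability < 0)
    abort_bl("permeability must be >= 0", "bl_domain_error")
  structure(list(name = name, valence = as.integer(valence),
                 conc_out_mM = conc_out_mM, conc_in_mM = conc_in_mM,
                 permeability = permeability),
            class = "ion_species")
}

#' Pair of bath solutions defining an electrochemical problem
#'
#' @param species list of [ion_species()] objects.
#' @param temperature_K absolute temperature; default 298.15 K.
#' @param rt_over_f_mV optional thermal voltage override in mV; when given
#'   it takes precedence over `temperature_K` (useful when only RT/F is
#'   known, e.g. back-computed from published reversal-potential /
#'   permeability-ratio pairs).
#' @return an object of class `bath_pair`.
#' @export
bath_pair <- function(species, temperature_K = 298.15, rt_over_f_mV = NULL) {
  if (inherits(species, "ion_species")) species <- list(species)
  if (!length(species) || !all(vapply(species, inherits, TRUE, "ion_species")))
    abort_bl("species must be a list of ion_species", "bl_input_error")
  rtf <- rt_over_f_mV %||% bilayerlab::rt_over_f_mV(temperature_K)
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm))
    abort_bl("duplicate species names in bath", "bl_input_error")
  structure(list(species = setNames(species, nm),
                 temperature_K = temperature_K,
                 rt_over_f_mV = rtf),
            class = "bath_pair")
}

#' Build a bath pair from salt recipes
#'
#' Each salt dissociates fully: `KCl: 500` contributes K+ 500 mM and
#' Cl- 500 mM; `CaCl2: 150` contributes Ca2+ 150 mM and Cl- 300 mM. The
#' resulting sides are electroneutral by construction. Permeabilities
#' default to 0 and are set afterwards with [set_permeability()] or the
#' `permeabilities` argument.
#'
#' @param cis,trans named numeric vectors of salt concentrations in mM,
#'   names among "KCl", "CaCl2", "NaCl".
#' @param permeabilities optional named numeric vector of relative
#'   permeabilities by ion name (e.g. `c(K = 1, Cl = 0.0315)`).
#' @inheritParams bath_pair
#' @return a `bath_pair`.
#' @export
bath_from_salts <- function(cis, trans, permeabilities = NULL,
                            temperature_K = 298.15, rt_over_f_mV = NULL) {
  salts <- list(
    KCl   = list(c(ion = "K",  z = 1, n = 1), c(ion = "Cl", z = -1, n = 1)),
    NaCl  = list(c(ion = "Na", z = 1, n = 1), c(ion = "Cl", z = -1, n = 1)),
    CaCl2 = list(c(ion = "Ca", z = 2, n = 1), c(ion = "Cl", z = -1, n = 2)))
  tally <- function(side) {
    out <- list()
    for (salt in names(side)) {
      if (!salt %in% names(salts))
        abort_bl(sprintf("unknown salt '%s'", salt), "bl_input_error")
      for (comp in salts[[salt]]) {
        ion <- comp[["ion"]]
        add <- side[[salt]] * as.numeric(comp[["n"]])
        out[[ion]] <- list(z = as.integer(comp[["z"]]),
                           c = (out[[ion]]$c %||% 0) + add)
      }
    }
    out
  }
  co <- tally(cis); ct <- tally(trans)
  ions <- union(names(co), names(ct))
  species <- lapply(ions, function(ion) {
    z <- (co[[ion]]$z %||% ct[[ion]]$z)
    p <- unname(permeabilities[ion])
    if (is.null(p) || length(p) == 0 || is.na(p)) p <- 0
    ion_species(ion, z,
                conc_out_mM = co[[ion]]$c %||% 0,
                conc_in_mM  = ct[[ion]]$c %||% 0,
                permeability = p)
  })
  # salts dissociate to neutral sides; guard against tally bugs
  for (side in c("conc_out_mM", "conc_in_mM")) {
    zc <- sum(vapply(species, function(s) s$valence * s[[side]], 0))
    tot <- sum(vapply(species, function(s) abs(s$valence) * s[[side]], 0))
    stopifnot(abs(zc) <= 1e-6 * max(tot, 1))
  }
  bath_pair(species, temperature_K, rt_over_f_mV)
}

#' Set the relative permeability of a species in a bath
#'
#' @param bath a `bath_pair`.
#' @param name species name.
#' @param permeability new non-negative relative permeability.
#' @return the modified `bath_pair`.
#' @export
set_permeability <- function(bath, name, permeability) {
  stopifnot(inherits(bath, "bath_pair"))
  if (!name %in% names(bath$species))
    abort_bl(sprintf("no species '%s' in bath", name), "bl_input_error")
  if (permeability < 0)
    abort_bl("permeability must be >= 0", "bl_domain_error")
  bath$species[[name]]$permeability <- permeability
  bath
}

#' @export
print.bath_pair <- function(x, ...) {
  cat(sprintf("Bath pair (RT/F = %.3f mV, T = %.2f K)\n",
              x$rt_over_f_mV, x$temperature_K))
  for (s in x$species)
    cat(sprintf("  %-3s z=%+d  out %g mM : in %g mM  P=%g\n",
                s$name, s$valence, s$conc_out_mM, s$conc_in_mM,
                s$permeability))
  invisible(x)
}

#' Nernst equilibrium potential
#'
#' E = (RT/zF) ln(c_out / c_in), the potential at which a single ion
#' species is at electrochemical equilibrium across the membrane.
#'
#' @param valence signed ionic charge (non-zero).
#' @param conc_out_mM,conc_in_mM concentrations on the out (cis) and in
#'   (trans) sides, both strictly positive, mM.
#' @param rt_over_f_mV thermal voltage RT/F in mV.
#' @return equilibrium potential in mV.
#' @examples
#' nernst_potential(+1, 500, 50, 25.97)  # ~59.8 mV
#' nernst_potential(+2, 150, 15, 25.97)  # ~29.9 mV
#' @export
nernst_potential <- function(valence, conc_out_mM, conc_in_mM, rt_over_f_mV) {
  if (valence == 0) abort_bl("valence must be non-zero", "bl_domain_error")
  if (conc_out_mM <= 0 || conc_in_mM <= 0)
    abort_bl("concentrations must be > 0", "bl_domain_error")
  (rt_over_f_mV / valence) * log(conc_out_mM / conc_in_mM)
}

.split_species <- function(bath) {
  z <- vapply(bath$species, `[[`, 0L, "valence")
  list(mono_cat = bath$species[z == 1L],
       div_cat  = bath$species[z == 2L],
       anion    = bath$species[z == -1L])
}

#' GHK reversal potential for monovalent ions
#'
#' Solves the monovalent Goldman-Hodgkin-Katz voltage equation
#' E_rev = (RT/F) ln\[(sum_cat P c_out + sum_an P c_in) /
#' (sum_cat P c_in + sum_an P c_out)\]. With a single permeant species it
#' reduces exactly to that species' Nernst potential.
#'
#' @param bath a `bath_pair` whose species are all monovalent.
#' @return reversal potential in mV.
#' @export
ghk_reversal_monovalent <- function(bath) {
  stopifnot(inherits(bath, "bath_pair"))
  sp <- .split_species(bath)
  if (length(sp$div_cat))
    abort_bl(paste("bath contains a divalent species; use",
                   "ghk_reversal_extended()"), "bl_unsupported_equation")
  P <- vapply(bath$species, `[[`, 0, "permeability")
  if (all(P == 0))
    abort_bl("all permeabilities are zero", "bl_domain_error")
  num <- sum(vapply(sp$mono_cat, function(s) s$permeability * s$conc_out_mM, 0)) +
         sum(vapply(sp$anion,    function(s) s$permeability * s$conc_in_mM, 0))
  den <- sum(vapply(sp$mono_cat, function(s) s$permeability * s$conc_in_mM, 0)) +
         sum(vapply(sp$anion,    function(s) s$permeability * s$conc_out_mM, 0))
  if (num <= 0 || den <= 0)
    abort_bl("GHK numerator/denominator must be positive", "bl_domain_error")
  bath$rt_over_f_mV * log(num / den)
}

# N(u)/D(u) of the implicit divalent GHK equation; u = exp(E F / RT).
# Anion terms (opt-in) carry the same (1+u) factor as monovalent cations
# so the equation reduces exactly to the monovalent GHK when all divalent
# concentrations are zero.
.ghk_ext_ratio <- function(bath, u, include_anions) {
  sp <- .split_species(bath)
  num <- sum(vapply(sp$mono_cat,
                    function(s) s$permeability * s$conc_out_mM * (1 + u), 0)) +
         sum(vapply(sp$div_cat,
                    function(s) 4 * s$permeability * s$conc_out_mM, 0))
  den <- sum(vapply(sp$mono_cat,
                    function(s) s$permeability * s$conc_in_mM * (1 + u), 0)) +
         sum(vapply(sp$div_cat,
                    function(s) 4 * s$permeability * s$conc_in_mM * u, 0))
  if (include_anions) {
    num <- num + sum(vapply(sp$anion,
                            function(s) s$permeability * s$conc_in_mM * (1 + u), 0))
    den <- den + sum(vapply(sp$anion,
                            function(s) s$permeability * s$conc_out_mM * (1 + u), 0))
  }
  c(num = num, den = den)
}

#' GHK reversal potential with divalent cations
#'
#' Solves the implicit divalent-extended GHK voltage equation
#' E = (RT/F) ln\[N(u)/D(u)\], u = exp(EF/RT), where divalent cations enter
#' with the factor 4 and the exponential weighting of the constant-field
#' derivation. By default anion terms are excluded, mirroring the common
#' bi-ionic form; `include_anions = TRUE` adds them in their standard GHK
#' positions. The root is found by bracket-scanned bisection on
#' \[-500, 500\] mV.
#'
#' @param bath a `bath_pair` containing at least one divalent cation with
#'   nonzero permeability (or zero divalent concentration, in which case
#'   the result equals [ghk_reversal_monovalent()]).
#' @param include_anions include monovalent anion terms; default FALSE.
#' @return reversal potential in mV.
#' @export
ghk_reversal_extended <- function(bath, include_anions = FALSE) {
  stopifnot(inherits(bath, "bath_pair"))
  rtf <- bath$rt_over_f_mV
  resid <- function(E) {
    nd <- .ghk_ext_ratio(bath, exp(E / rtf), include_anions)
    E - rtf * log(nd[["num"]] / nd[["den"]])
  }
  grid <- seq(-500, 500, by = 1)
  fv <- vapply(grid, resid, 0)
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(fv == 0)
  if (length(exact)) return(grid[exact[1]])
  if (length(flips) == 0)
    abort_bl("no sign change of the GHK residual in [-500, 500] mV",
             "bl_no_solution")
  if (length(flips) > 1)
    abort_bl(sprintf("multiple root brackets: %s",
                     paste(sprintf("[%g, %g]", grid[flips], grid[flips + 1]),
                           collapse = ", ")),
             "bl_ambiguous_root")
  lo <- grid[flips]; hi <- grid[flips + 1]
  flo <- resid(lo)
  # plain bisection: robust, tolerance well below reporting precision
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (abs(fm) < 1e-10 || (hi - lo) / 2 < 1e-12) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

.permeability_result <- function(num_sp, den_sp, ratio, e_rev_mV, method,
                                 rtf, forward_e) {
  if (is.finite(ratio) && abs(forward_e - e_rev_mV) > 1e-6)
    abort_bl(sprintf(
      "forward GHK at the solved ratio gives %.9f mV, not %.9f mV",
      forward_e, e_rev_mV), "bl_consistency_error")
  structure(list(numerator_species = num_sp, denominator_species = den_sp,
                 ratio = ratio, e_rev_mV = e_rev_mV, method = method,
                 rt_over_f_mV = rtf),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("P_%s / P_%s = %.4f  (E_rev = %.2f mV, RT/F = %.3f mV, %s)\n",
              x$numerator_species, x$denominator_species, x$ratio,
              x$e_rev_mV, x$rt_over_f_mV, x$method))
  invisible(x)
}

#' Invert the monovalent GHK equation for a cation/anion permeability ratio
#'
#' For a bath with one monovalent cation (the reference, permeability 1)
#' and one monovalent anion of unknown permeability, the GHK equation is
#' solved in closed form: with u = exp(E F/RT),
#' P_an/P_cat = (c_cat_out - u c_cat_in) / (u c_an_out - c_an_in).
#' The returned ratio is the cation-over-anion ratio (its reciprocal), the
#' form in which selectivity of cation channels is usually quoted.
#'
#' @param e_rev_mV measured reversal potential, mV.
#' @param bath a `bath_pair` containing the two species.
#' @param reference_cation,target_anion species names; defaults pick the
#'   unique cation and anion in the bath.
#' @return a `permeability_result` with `ratio` = P_cation / P_anion.
#' @examples
#' b <- bath_from_salts(c(KCl = 500), c(KCl = 50), rt_over_f_mV = 25.97)
#' invert_monovalent_ratio(52.77, b)$ratio  # ~31.77
#' @export
invert_monovalent_ratio <- function(e_rev_mV, bath,
                                    reference_cation = NULL,
                                    target_anion = NULL) {
  stopifnot(inherits(bath, "bath_pair"))
  sp <- .split_species(bath)
  if (length(sp$div_cat))
    abort_bl("divalent species present; use invert_divalent_ratio()",
             "bl_unsupported_equation")
  reference_cation <- reference_cation %||% {
    if (length(sp$mono_cat) != 1)
      abort_bl("specify reference_cation (bath has several cations)",
               "bl_input_error")
    sp$mono_cat[[1]]$name
  }
  target_anion <- target_anion %||% {
    if (length(sp$anion) != 1)
      abort_bl("specify target_anion (bath has several anions)",
               "bl_input_error")
    sp$anion[[1]]$name
  }
  cat_ <- bath$species[[reference_cation]]
  an_ <- bath$species[[target_anion]]
  if (is.null(cat_) || is.null(an_) || cat_$valence != 1L || an_$valence != -1L)
    abort_bl("reference cation / target anion not found or wrong valence",
             "bl_input_error")
  rtf <- bath$rt_over_f_mV
  u <- exp(e_rev_mV / rtf)
  num <- cat_$conc_out_mM - u * cat_$conc_in_mM
  den <- u * an_$conc_out_mM - an_$conc_in_mM
  # attainable window: cation Nernst (P_an = 0) down to the anion limit
  e_cat <- nernst_potential(1, cat_$conc_out_mM, cat_$conc_in_mM, rtf)
  p_an <- num / den
  if (abs(e_rev_mV - e_cat) < 1e-12 || p_an == 0) {
    p_an <- 0
  } else if (p_an < 0) {
    abort_bl(sprintf(
      "E_rev = %g mV lies outside the interval attainable between the ionic Nernst potentials",
      e_rev_mV), "bl_no_solution")
  }
  b2 <- bath
  b2$species[[reference_cation]]$permeability <- 1
  b2$species[[target_anion]]$permeability <- p_an
  fwd <- ghk_reversal_monovalent(b2)
  ratio <- if (p_an == 0) Inf else 1 / p_an
  .permeability_result(reference_cation, target_anion, ratio, e_rev_mV,
                       "closed_form_inverse", rtf,
                       if (p_an == 0) e_rev_mV else fwd)
}

#' Invert the divalent GHK equation for a divalent permeability
#'
#' With the reversal potential fixed, the divalent-extended GHK equation is
#' linear in the single unknown divalent permeability P_div:
#' P_div = (1+u)(M_out - u M_in + A) / (4 (c_div_in u^2 - c_div_out)),
#' u = exp(E F/RT), where M are the permeability-weighted monovalent cation
#' sums and A the optional anion terms. All monovalent permeabilities are
#' taken from the bath as fixed.
#'
#' @param e_rev_mV measured reversal potential, mV.
#' @param bath a `bath_pair` with exactly one divalent cation (the unknown)
#'   and fixed monovalent permeabilities.
#' @param include_anions include anion terms as in [ghk_reversal_extended()].
#' @param reference species name whose permeability scales the reported
#'   ratio denominator; defaults to the unique monovalent cation.
#' @return a `permeability_result` with `ratio` = P_divalent / P_reference.
#' @export
invert_divalent_ratio <- function(e_rev_mV, bath, include_anions = FALSE,
                                  reference = NULL) {
  stopifnot(inherits(bath, "bath_pair"))
  sp <- .split_species(bath)
  if (length(sp$div_cat) != 1)
    abort_bl("bath must contain exactly one divalent cation",
             "bl_input_error")
  div <- sp$div_cat[[1]]
  reference <- reference %||% {
    if (length(sp$mono_cat) != 1)
      abort_bl("specify reference (bath has several monovalent cations)",
               "bl_input_error")
    sp$mono_cat[[1]]$name
  }
  p_ref <- bath$species[[reference]]$permeability
  if (is.null(p_ref) || p_ref <= 0)
    abort_bl("reference species must have positive fixed permeability",
             "bl_input_error")
  rtf <- bath$rt_over_f_mV
  u <- exp(e_rev_mV / rtf)
  m_out <- sum(vapply(sp$mono_cat, function(s) s$permeability * s$conc_out_mM, 0))
  m_in  <- sum(vapply(sp$mono_cat, function(s) s$permeability * s$conc_in_mM, 0))
  a_num <- a_den <- 0
  if (include_anions) {
    a_num <- sum(vapply(sp$anion, function(s) s$permeability * s$conc_in_mM, 0))
    a_den <- sum(vapply(sp$anion, function(s) s$permeability * s$conc_out_mM, 0))
  }
  den <- 4 * (div$conc_in_mM * u^2 - div$conc_out_mM)
  num <- (1 + u) * (m_out + a_num - u * (m_in + a_den))
  if (abs(den) < 1e-12 * max(1, abs(num)))
    abort_bl("divalent permeability unidentifiable at this E_rev (degenerate denominator)",
             "bl_no_solution")
  p_div <- num / den
  # floating-point dust when E_rev sits exactly at the monovalent limit
  if (p_div < 0 && p_div > -1e-9) p_div <- 0
  if (p_div < 0)
    abort_bl("no non-negative divalent permeability reproduces this E_rev",
             "bl_no_solution")
  b2 <- bath
  b2$species[[div$name]]$permeability <- p_div
  fwd <- if (p_div == 0 && div$conc_out_mM == 0 && div$conc_in_mM == 0)
    e_rev_mV else ghk_reversal_extended(b2, include_anions)
  .permeability_result(div$name, reference, p_div / p_ref, e_rev_mV,
                       "closed_form_inverse", rtf, fwd)
}
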