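## Elemental bookkeeping of the growth medium and cell biomass.
## Standard atomic weights; compounds limited to the species the process
## balance needs.

.ATOMIC <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, Na = 22.990)

.COMPOUNDS <- list(
  nano3      = c(Na = 1, N = 1, O = 3),
  glucose    = c(C = 6, H = 12, O = 6),
  triolein   = c(C = 57, H = 104, O = 6),
  oleic_acid = c(C = 18, H = 34, O = 2),
  glycerol   = c(C = 3, H = 8, O = 3),
  water      = c(H = 2, O = 1)
)

molar_mass <- function(compound) {
  comp <- .COMPOUNDS[[compound]]
  if (is.null(comp)) {
    abort(paste0("unsupported compound: ", compound, " (supported: ",
                 paste(names(.COMPOUNDS), collapse = ", "), ")"))
  }
  sum(comp * .ATOMIC[names(comp)])
}

#' Mass fraction of an element in a medium compound
#'
#' Atomic-mass-based elemental fractions for the compounds entering the
#' process balances (NaNO3, glucose, triolein, oleic acid, glycerol, water).
#'
#' @param compound one of `"nano3"`, `"glucose"`, `"triolein"`,
#'   `"oleic_acid"`, `"glycerol"`, `"water"`.
#' @param element one of `"C"`, `"H"`, `"N"`, `"O"`, `"Na"`.
#' @return Mass fraction (g/g).
#' @examples
#' element_mass_fraction("nano3", "N")    # 0.1648
#' element_mass_fraction("glucose", "C")  # 0.4000
#' @export
element_mass_fraction <- function(compound, element) {
  comp <- .COMPOUNDS[[compound]]
  if (is.null(comp)) {
    abort(paste0("unsupported compound: ", compound))
  }
  if (!element %in% names(.ATOMIC)) {
    abort(paste0("unsupported element: ", element))
  }
  n <- comp[element]
  if (is.na(n)) return(0)
  unname(n * .ATOMIC[element] / molar_mass(compound))
}

#' Nitrogen ceiling of the growth medium
#'
#' Sodium nitrate is the sole nitrogen source; the elemental nitrogen it
#' carries caps the lipid-free biomass the growth phase can form. With
#' 3 g/L NaNO3 and the measured 6.2% w/w cellular nitrogen this gives
#' 0.49 g N/L, a ceiling of about 7.9 g/L biomass, and a maximum biomass
#' yield from nitrate of about 2.6 g/g.
#'
#' @param c_nano3 NaNO3 concentration (g/L).
#' @param biomass_n_fraction cellular nitrogen mass fraction (g/g), e.g.
#'   0.062 during growth.
#' @return A tibble with `available_n` (g N/L), `max_biomass` (g/L) and
#'   `max_yield` (g biomass / g NaNO3).
#' @examples
#' nitrogen_balance(3, 0.062)
#' @export
nitrogen_balance <- function(c_nano3, biomass_n_fraction) {
  if (c_nano3 <= 0) abort("c_nano3 must be positive")
  if (biomass_n_fraction <= 0) abort("biomass nitrogen fraction must be positive")
  available_n <- c_nano3 * element_mass_fraction("nano3", "N")
  max_biomass <- available_n / biomass_n_fraction
  tibble(available_n = available_n, max_biomass = max_biomass,
         max_yield = max_biomass / c_nano3)
}

#' Carbon recovery of the growth phase
#'
#' How much of the elemental carbon supplied as glucose ends up in the
#' biomass formed: 30 g/L glucose carries 12 g C/L; a batch forming
#' 5.46 g/L biomass at 48.5% C fixes 2.65 g C/L, i.e. about 22%.
#'
#' @param c_gluc glucose supplied (g/L).
#' @param c_x biomass formed (g/L).
#' @param w_c cellular carbon content (g/100 g biomass); default the growth
#'   phase value.
#' @return A tibble with `available_c` (g C/L), `biomass_c` (g C/L) and
#'   `fraction_in_biomass`.
#' @examples
#' carbon_balance(30, 5.46)
#' @export
carbon_balance <- function(c_gluc, c_x, w_c = 48.5) {
  if (c_gluc < 0 || c_x < 0) abort("inputs must be non-negative")
  available_c <- c_gluc * element_mass_fraction("glucose", "C")
  biomass_c <- c_x * w_c / 100
  tibble(
    available_c = available_c, biomass_c = biomass_c,
    fraction_in_biomass = if (available_c > 0) biomass_c / available_c else NA_real_
  )
}

#' Average cellular biomass composition by process phase
#'
#' CHN mass fractions of dried cells, averaged over many samples; the
#' remainder ("others") pools O, S and minerals. The production-phase cells
#' are carbon- and hydrogen-enriched and nitrogen-depleted because of
#' intracellular storage-lipid accumulation under nitrogen limitation.
#'
#' @return A tibble with `phase`, `w_c`, `w_h`, `w_n`, `w_other` (g/100 g).
#' @export
biomass_composition <- function() {
  tibble(
    phase = c("growth", "production"),
    w_c = c(48.5, 62.2), w_h = c(7.1, 9.2),
    w_n = c(6.2, 1.3), w_other = c(38.1, 27.3)
  )
}

#' Molar biomass formula from CHN mass fractions
#'
#' Normalises the elemental mass fractions to one carbon, treating the
#' "others" remainder as oxygen, giving a formula CH_a N_b O_c.
#'
#' @param w_c,w_h,w_n,w_other mass fractions (g/100 g biomass); `w_c` must
#'   be positive. The common scale cancels, so any rescaling of all four
#'   leaves the formula unchanged.
#' @return A tibble with subscripts `h`, `n`, `o` and a `formula` string.
#' @examples
#' molar_formula(48.5, 7.1, 6.2, 38.1)  # growth-phase cells
#' @export
molar_formula <- function(w_c, w_h, w_n, w_other) {
  if (w_c <= 0) abort("carbon fraction must be positive")
  if (min(w_h, w_n, w_other) < 0) abort("mass fractions must be non-negative")
  nc <- w_c / .ATOMIC["C"]
  h <- (w_h / .ATOMIC["H"]) / nc
  n <- (w_n / .ATOMIC["N"]) / nc
  o <- (w_other / .ATOMIC["O"]) / nc
  tibble(
    h = unname(h), n = unname(n), o = unname(o),
    formula = sprintf("CH%.3fN%.3fO%.3f", h, n, o)
  )
}

#' Fatty-acid yield of triolein hydrolysis
#'
#' The model treats plant oil as triolein; full hydrolysis of one mole
#' yields three moles of oleic acid and one of glycerol (consuming three
#' waters), so the fatty-acid mass yield is
#' `3 M(oleic acid) / M(triolein) = 0.957` g/g. The glycerol complement
#' plus the water taken up close the mass balance:
#' `3 M(oleate) + M(glycerol) = M(triolein) + 3 M(H2O)`.
#'
#' @return Yield (g fatty acid / g oil).
#' @examples
#' triolein_hydrolysis_yield()  # 0.957
#' @export
triolein_hydrolysis_yield <- function() {
  3 * molar_mass("oleic_acid") / molar_mass("triolein")
}
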