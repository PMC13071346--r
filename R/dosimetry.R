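#' Conversion constants for ethanol dosimetry
#'
#' Defaults follow the human MRS-derived distribution values commonly used to
#' anchor in vitro ethanol exposures: a serum-to-brain concentration ratio of
#' ~1.67, a serum-to-blood conversion factor of 1.24, and the molar mass of
#' ethanol (46.07 g/mol).
#'
#' @param serum_to_brain_ratio Serum concentration divided by brain
#'   concentration (dimensionless, default 1.67).
#' @param serum_to_blood_factor Serum concentration divided by whole-blood
#'   concentration (dimensionless, default 1.24).
#' @param ethanol_molar_mass Molar mass of ethanol in g/mol (default 46.07).
#' @param brain_water_factor Multiplicative factor applied when normalizing
#'   tissue g/L to molar units for brain water content; default 1 (no
#'   adjustment).
#' @return A list of class `etoh_constants`.
#' @export
#' @examples
#' dose_constants()
dose_constants <- function(serum_to_brain_ratio = 1.67,
                           serum_to_blood_factor = 1.24,
                           ethanol_molar_mass = 46.07,
                           brain_water_factor = 1) {
  stopifnot(
    serum_to_brain_ratio > 0, serum_to_blood_factor > 0,
    ethanol_molar_mass > 0, brain_water_factor > 0
  )
  structure(
    list(
      serum_to_brain_ratio = serum_to_brain_ratio,
      serum_to_blood_factor = serum_to_blood_factor,
      ethanol_molar_mass = ethanol_molar_mass,
      brain_water_factor = brain_water_factor
    ),
    class = "etoh_constants"
  )
}

new_dose_spec <- function(brain_mM, serum_mM, serum_mg_per_dL,
                          blood_mg_per_dL, bac_percent, provenance) {
  structure(
    list(
      brain_mM = brain_mM,
      serum_mM = serum_mM,
      serum_mg_per_dL = serum_mg_per_dL,
      blood_mg_per_dL = blood_mg_per_dL,
      bac_percent = bac_percent,
      provenance = provenance
    ),
    class = "dose_spec"
  )
}

#' @export
print.dose_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Ethanol dose (input: %s)\n",
      "  brain:  %.2f mM\n",
      "  serum:  %.2f mM  (%.1f mg/dL)\n",
      "  blood:  %.1f mg/dL\n",
      "  BAC:    %.2f %% (w/v)\n"
    ),
    x$provenance, x$brain_mM, x$serum_mM, x$serum_mg_per_dL,
    x$blood_mg_per_dL, x$bac_percent
  ))
  invisible(x)
}

#' Convert a brain ethanol concentration to the full dosimetry chain
#'
#' Populates a `dose_spec` from a brain concentration in mM by applying, in
#' order: brain mM -> serum mM (times the serum-to-brain ratio), serum mM ->
#' serum mg/dL (times molar mass / 10), serum -> blood (divided by the
#' serum-to-blood factor), and blood mg/dL -> %BAC (divided by 1000; %BAC is
#' grams ethanol per 100 mL blood, w/v). No rounding is applied; round only
#' at presentation.
#'
#' @param brain_mM Brain ethanol concentration in mM (nonnegative scalar).
#' @param constants A [dose_constants()] list.
#' @return A `dose_spec` with all compartments populated.
#' @export
#' @examples
#' from_brain_mM(35) # ~58.5 mM serum, ~269 mg/dL, ~0.22% BAC
from_brain_mM <- function(brain_mM, constants = dose_constants()) {
  stopifnot(is.numeric(brain_mM), length(brain_mM) == 1L, is.finite(brain_mM))
  if (brain_mM < 0) stop("brain_mM must be nonnegative")
  serum_mM <- brain_mM * constants$serum_to_brain_ratio
  serum_mg_per_dL <- serum_mM * constants$ethanol_molar_mass / 10
  blood_mg_per_dL <- serum_mg_per_dL / constants$serum_to_blood_factor
  bac_percent <- blood_mg_per_dL / 1000
  new_dose_spec(brain_mM, serum_mM, serum_mg_per_dL, blood_mg_per_dL,
                bac_percent, provenance = "brain_mM")
}

#' Convert a serum ethanol concentration (mM) to the full chain
#'
#' @inheritParams from_brain_mM
#' @param serum_mM Serum ethanol concentration in mM.
#' @return A `dose_spec`.
#' @export
from_serum_mM <- function(serum_mM, constants = dose_constants()) {
  stopifnot(is.numeric(serum_mM), length(serum_mM) == 1L, is.finite(serum_mM))
  if (serum_mM < 0) stop("serum_mM must be nonnegative")
  out <- from_brain_mM(serum_mM / constants$serum_to_brain_ratio, constants)
  out$provenance <- "serum_mM"
  out
}

#' Convert a blood alcohol concentration (%BAC, w/v) to the full chain
#'
#' @inheritParams from_brain_mM
#' @param bac_percent Blood alcohol concentration as g ethanol per 100 mL
#'   blood, expressed in percent.
#' @return A `dose_spec`.
#' @export
from_bac_percent <- function(bac_percent, constants = dose_constants()) {
  stopifnot(is.numeric(bac_percent), length(bac_percent) == 1L,
            is.finite(bac_percent))
  if (bac_percent < 0) stop("bac_percent must be nonnegative")
  blood_mg_per_dL <- bac_percent * 1000
  serum_mg_per_dL <- blood_mg_per_dL * constants$serum_to_blood_factor
  serum_mM <- serum_mg_per_dL * 10 / constants$ethanol_molar_mass
  out <- from_brain_mM(serum_mM / constants$serum_to_brain_ratio, constants)
  out$provenance <- "bac_percent"
  out
}

#' Convert a tissue ethanol concentration in g/L to mM
#'
#' `mM = 1000 * g_per_L / molar_mass * brain_water_factor`. With default
#' constants, 0.68 g/L in cortex maps to ~14.8 mM, matching the published
#' water-content-normalized value without further adjustment.
#'
#' @param g_per_L Tissue ethanol concentration in grams per litre.
#' @inheritParams from_brain_mM
#' @return Concentration in mM.
#' @export
#' @examples
#' tissue_g_per_L_to_mM(0.68) # ~14.8
tissue_g_per_L_to_mM <- function(g_per_L, constants = dose_constants()) {
  stopifnot(is.numeric(g_per_L), all(g_per_L >= 0))
  1000 * g_per_L / constants$ethanol_molar_mass * constants$brain_water_factor
}

#' Recompute a dose specification from one of its own fields
#'
#' Rebuilds the full compartment chain starting from the named field of an
#' existing `dose_spec`; with consistent constants the result reproduces all
#' other fields to floating-point accuracy.
#'
#' @param spec A `dose_spec`.
#' @param from One of `"brain_mM"`, `"serum_mM"`, `"bac_percent"`.
#' @inheritParams from_brain_mM
#' @return A `dose_spec`.
#' @export
round_trip <- function(spec, from = spec$provenance,
                       constants = dose_constants()) {
  stopifnot(inherits(spec, "dose_spec"))
  from <- match.arg(from, c("brain_mM", "serum_mM", "bac_percent"))
  switch(from,
    brain_mM = from_brain_mM(spec$brain_mM, constants),
    serum_mM = from_serum_mM(spec$serum_mM, constants),
    bac_percent = from_bac_percent(spec$bac_percent, constants)
  )
}
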