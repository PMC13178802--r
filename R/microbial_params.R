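#' Microbial biomass, respiration and derived quotients
#'
#' Microbial biomass carbon (MBC) and nitrogen (MBN) from chloroform
#' fumigation-extraction, basal microbial respiration (MR) from alkali-trap
#' titration, the metabolic quotient qCO2 (respiration per unit biomass
#' carbon, an indicator of maintenance-dominated, stressed communities) and
#' the microbial quotient Cmic/Corg (share of total organic carbon held in
#' microbial biomass).
#'
#' @name microbial_params
NULL

#' Microbial biomass carbon from fumigation-extraction
#'
#' `MBC = (C_fumigated - C_unfumigated) / kEC`, converted from mass to
#' molar units. A fumigated reading below the unfumigated one is retained
#' but flagged as a negative flux, never clamped.
#'
#' @param C_fumigated,C_unfumigated extractable carbon, micrograms C per g
#'   soil.
#' @param kEC extraction efficiency for carbon, in (0, 1] (default 0.45).
#' @return data frame with `MBC` (micromol C per g soil) and logical
#'   `negative_flux`.
#' @examples
#' microbial_biomass_c(450, 225) # 41.63 umol/g
#' @export
microbial_biomass_c <- function(C_fumigated, C_unfumigated, kEC = 0.45) {
  if (any(kEC <= 0) || any(kEC > 1)) .stopf("kEC must be in (0, 1]")
  flux <- (C_fumigated - C_unfumigated) / kEC
  data.frame(MBC = flux / .ATOMIC_MASS[["C"]],
             negative_flux = flux < 0)
}

#' Microbial biomass nitrogen from fumigation-extraction
#'
#' `MBN = (N_fumigated - N_unfumigated) / kEN` in micromol N per g soil.
#'
#' @param N_fumigated,N_unfumigated extractable nitrogen, micrograms N per g
#'   soil.
#' @param kEN extraction efficiency for nitrogen, in (0, 1] (default 0.54).
#' @return data frame with `MBN` (micromol N per g soil) and logical
#'   `negative_flux`.
#' @export
microbial_biomass_n <- function(N_fumigated, N_unfumigated, kEN = 0.54) {
  if (any(kEN <= 0) || any(kEN > 1)) .stopf("kEN must be in (0, 1]")
  flux <- (N_fumigated - N_unfumigated) / kEN
  data.frame(MBN = flux / .ATOMIC_MASS[["N"]],
             negative_flux = flux < 0)
}

#' Basal microbial respiration from alkali-trap titration
#'
#' CO2 evolved by unamended soil is trapped in NaOH and back-titrated; two
#' moles of NaOH are consumed per mole of CO2, so trapped CO2 (micromol) is
#' `(blank_titre - sample_titre) * acid_molarity * 1000 / 2`, divided by the
#' soil mass and normalized to a per-day rate.
#'
#' @param blank_titre,sample_titre acid volumes at the endpoint, mL
#'   (`blank_titre >= sample_titre` for a valid assay).
#' @param acid_molarity titrant concentration, mol per L.
#' @param soil_mass incubated soil, g.
#' @param incubation_h incubation time, hours (> 0).
#' @return data frame with `MR` (micromol CO2 per g soil per day) and
#'   logical `invalid` flag where the sample titre exceeds the blank.
#' @examples
#' basal_respiration(10, 8, 0.1, 10, 24) # 10 umol/g/day
#' @export
basal_respiration <- function(blank_titre, sample_titre, acid_molarity,
                              soil_mass, incubation_h) {
  if (any(incubation_h <= 0)) .stopf("incubation_h must be positive")
  if (any(soil_mass <= 0)) .stopf("soil_mass must be positive")
  trapped_umol <- (blank_titre - sample_titre) * acid_molarity * 1000 / 2
  data.frame(MR = trapped_umol / soil_mass * (24 / incubation_h),
             invalid = sample_titre > blank_titre)
}

#' Metabolic quotient qCO2
#'
#' Ratio of basal respiration (converted to mg CO2 per g soil per h) to
#' microbial biomass carbon (converted to g C per g soil). Higher values
#' indicate energy spent on maintenance rather than growth.
#'
#' @param MR basal respiration, micromol CO2 per g soil per day.
#' @param MBC microbial biomass carbon, micromol C per g soil (> 0).
#' @return qCO2 in mg CO2 per g MBC per h (`NA` where `MBC <= 0`).
#' @examples
#' metabolic_quotient(1.61, 24.59) # ~10
#' @export
metabolic_quotient <- function(MR, MBC) {
  mr_mg_h <- MR * .CO2_MASS / 1000 / 24
  mbc_g <- MBC * .ATOMIC_MASS[["C"]] * 1e-6
  ifelse(MBC <= 0, NA_real_, mr_mg_h / mbc_g)
}

#' Microbial quotient Cmic/Corg
#'
#' Percentage of the soil's total organic carbon held in microbial biomass,
#' with both terms on the micromol C per g soil scale.
#'
#' @param MBC microbial biomass carbon, micromol C per g soil.
#' @param TOC total organic carbon, g per kg soil (> 0).
#' @return Cmic/Corg in percent (`NA` where `TOC <= 0`).
#' @examples
#' microbial_quotient(37.31, 21.75) # ~2.06
#' @export
microbial_quotient <- function(MBC, TOC) {
  ifelse(TOC <= 0, NA_real_, 100 * MBC / mass_to_molar(TOC, "C"))
}

#' Per-sample microbiological parameter table
#'
#' Runs the fumigation-extraction, respiration and quotient calculations on
#' raw assay tables and joins them by sample.
#'
#' @param biomass data frame with `sample_id`, `group`, `C_fumigated`,
#'   `C_unfumigated`, `N_fumigated`, `N_unfumigated` and optionally `kEC`,
#'   `kEN` columns.
#' @param respiration data frame with `sample_id`, `blank_titre`,
#'   `sample_titre`, `acid_molarity`, `soil_mass`, `incubation_h`.
#' @param chemistry optional derived chemistry table with `group` and `TOC`
#'   (g/kg), used for the microbial quotient; when absent, `Cmic_Corg` is
#'   `NA`.
#' @return data frame with one row per sample: `MBC`, `MBN`, `MR`, `qCO2`,
#'   `Cmic_Corg` and quality flags.
#' @export
microbial_summary <- function(biomass, respiration, chemistry = NULL) {
  .check_cols(biomass, c("sample_id", "group", "C_fumigated",
                         "C_unfumigated", "N_fumigated", "N_unfumigated"),
              "biomass table")
  .check_cols(respiration, c("sample_id", "blank_titre", "sample_titre",
                             "acid_molarity", "soil_mass", "incubation_h"),
              "respiration table")
  kEC <- biomass$kEC %||% 0.45
  kEN <- biomass$kEN %||% 0.54
  bc <- microbial_biomass_c(biomass$C_fumigated, biomass$C_unfumigated, kEC)
  bn <- microbial_biomass_n(biomass$N_fumigated, biomass$N_unfumigated, kEN)
  out <- data.frame(sample_id = biomass$sample_id, group = biomass$group,
                    MBC = bc$MBC, MBN = bn$MBN,
                    negative_flux = bc$negative_flux | bn$negative_flux)
  resp <- respiration[match(out$sample_id, respiration$sample_id), ,
                      drop = FALSE]
  mr <- basal_respiration(resp$blank_titre, resp$sample_titre,
                          resp$acid_molarity, resp$soil_mass,
                          resp$incubation_h)
  out$MR <- mr$MR
  out$MR_invalid <- mr$invalid
  out$qCO2 <- metabolic_quotient(out$MR, out$MBC)
  if (!is.null(chemistry)) {
    .check_cols(chemistry, c("group", "TOC"), "chemistry table")
    toc <- chemistry$TOC[match(out$group, chemistry$group)]
    out$Cmic_Corg <- microbial_quotient(out$MBC, toc)
  } else {
    out$Cmic_Corg <- NA_real_
  }
  out
}
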