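#' Soil chemistry derivations and fertility indices
#'
#' Derives total organic carbon from organic matter, molar elemental ratios,
#' and the classical fertility indices (sum of bases, cation exchange
#' capacity, base saturation, aluminium saturation) from measured soil
#' chemistry, plus the qualitative suitability flags used to judge a soil
#' for crop production.
#'
#' @name soil_chemistry
NULL

#' Organic matter to total organic carbon
#'
#' `TOC = OM / 1.724` (Van Bemmelen factor).
#'
#' @param OM organic matter in g per kg soil (non-negative).
#' @return total organic carbon in g per kg soil.
#' @examples
#' om_to_toc(37.5) # 21.75
#' @export
om_to_toc <- function(OM) {
  if (any(OM < 0, na.rm = TRUE)) .stopf("OM must be non-negative")
  OM / .VAN_BEMMELEN
}

#' Mass concentration to molar concentration per gram of soil
#'
#' Converts a soil concentration to micromol of element per gram of soil
#' using atomic masses C 12.011, N 14.007, P 30.974. Carbon is expected in
#' g per kg (the TOC scale); nitrogen and phosphorus in mg per kg.
#'
#' @param x concentration (g/kg for `"C"`, mg/kg for `"N"` and `"P"`).
#' @param element one of `"C"`, `"N"`, `"P"`.
#' @return micromol of element per g soil.
#' @examples
#' mass_to_molar(21.75, "C") # ~1810.8
#' @export
mass_to_molar <- function(x, element = c("C", "N", "P")) {
  element <- match.arg(element)
  ug_per_g <- if (element == "C") x * 1000 else x
  ug_per_g / .ATOMIC_MASS[[element]]
}

#' Molar elemental ratios of soil C, N and P
#'
#' Quotients of the molar concentrations (micromol per g) of total organic
#' carbon, total nitrogen and phosphorus. Zero denominators yield `NA`.
#'
#' @param TOC total organic carbon, g per kg.
#' @param TN total nitrogen, mg per kg.
#' @param P phosphorus, mg per kg.
#' @return data frame with `CS_NS`, `CS_PS`, `NS_PS`.
#' @export
elemental_ratios <- function(TOC, TN, P) {
  cs <- mass_to_molar(TOC, "C")
  ns <- mass_to_molar(TN, "N")
  ps <- mass_to_molar(P, "P")
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  data.frame(CS_NS = safe_div(cs, ns),
             CS_PS = safe_div(cs, ps),
             NS_PS = safe_div(ns, ps))
}

#' Soil fertility indices
#'
#' Sum of bases `SB = Ca + Mg + K + Na`, cation exchange capacity
#' `CEC = SB + PA` (PA = potential acidity), base saturation
#' `V% = 100 * SB / CEC`, and aluminium saturation
#' `m% = 100 * Al / (SB + Al)`. All cations in mmolc per kg.
#'
#' @param Ca,Mg,K,Na,Al,PA exchangeable cation and potential acidity
#'   concentrations, mmolc per kg, all non-negative.
#' @return data frame with `SB`, `CEC`, `V_percent`, `m_percent`
#'   (`V_percent` is `NA` when `CEC = 0`; `m_percent` is 0 when `Al = 0`).
#' @export
fertility_indices <- function(Ca, Mg, K, Na, Al = 0, PA = 0) {
  args <- list(Ca = Ca, Mg = Mg, K = K, Na = Na, Al = Al, PA = PA)
  for (nm in names(args)) {
    if (any(args[[nm]] < 0, na.rm = TRUE)) {
      .stopf("'%s' must be non-negative", nm)
    }
  }
  SB <- Ca + Mg + K + Na
  CEC <- SB + PA
  V <- ifelse(CEC == 0, NA_real_, 100 * SB / CEC)
  m <- ifelse(SB + Al == 0, 0, 100 * Al / (SB + Al))
  data.frame(SB = SB, CEC = CEC, V_percent = V, m_percent = m)
}

#' Qualitative soil classification flags
#'
#' Applies the interpretive thresholds used for agronomic suitability:
#' slightly acidic pH (6.5 < pH <= 7), organic-matter rich (OM > 30 g/kg),
#' high TOC (> 20 g/kg), adequate phosphorus (> 10 mg/kg), high base
#' saturation (V% > 90), and overall crop suitability (adequate P together
#' with high V%). All inequalities are strict.
#'
#' @param record data frame (or one-row list) with `pH_water`, `OM`, `TOC`,
#'   `P` and `V_percent`.
#' @return data frame of logical flags `slightly_acidic`, `OM_rich`,
#'   `TOC_high`, `P_adequate`, `V_high`, `crop_suitable`.
#' @export
classify_soil <- function(record) {
  .check_cols(record, c("pH_water", "OM", "TOC", "P", "V_percent"),
              "chemistry record")
  data.frame(
    slightly_acidic = record$pH_water > 6.5 & record$pH_water <= 7,
    OM_rich = record$OM > 30,
    TOC_high = record$TOC > 20,
    P_adequate = record$P > 10,
    V_high = record$V_percent > 90,
    crop_suitable = record$P > 10 & record$V_percent > 90
  )
}

#' Derive the full augmented chemistry table
#'
#' Recomputes every derived quantity (TOC, molar ratios, fertility indices,
#' classification flags) from the measured columns; derived columns present
#' in the input are ignored and replaced.
#'
#' @param chemistry data frame with measured columns `pH_water`, `pH_KCl`,
#'   `OM` (g/kg), `TN` (mg/kg), `P` (mg/kg) and `Ca`, `Mg`, `K`, `Na`, `Al`,
#'   `PA` (mmolc/kg); identifier columns are carried through.
#' @return input augmented with `TOC`, `CS_NS`, `CS_PS`, `NS_PS`, `SB`,
#'   `CEC`, `V_percent`, `m_percent` and the [classify_soil()] flags.
#' @export
derive_chemistry <- function(chemistry) {
  measured <- c("pH_water", "pH_KCl", "OM", "TN", "P",
                "Ca", "Mg", "K", "Na", "Al", "PA")
  .check_cols(chemistry, measured, "chemistry table")
  out <- chemistry[, setdiff(names(chemistry),
                             c("TOC", "CS_NS", "CS_PS", "NS_PS", "SB", "CEC",
                               "V_percent", "m_percent")), drop = FALSE]
  out$TOC <- om_to_toc(out$OM)
  out <- cbind(out, elemental_ratios(out$TOC, out$TN, out$P))
  out <- cbind(out, fertility_indices(out$Ca, out$Mg, out$K, out$Na,
                                      out$Al, out$PA))
  cbind(out, classify_soil(out))
}
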