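#' Ecoenzymatic stoichiometry and enzyme vector analysis
#'
#' Soil microbial communities exude extracellular enzymes ("ecoenzymes") to
#' acquire carbon, nitrogen and phosphorus. The relative investment into the
#' three acquisition classes summarizes the nutrient limitation experienced by
#' the community. This file builds the C/N/P enzyme pools from the nine
#' assayed activities, their stoichiometric ratios, and the planar enzyme
#' vector whose length measures the strength of limitation and whose angle
#' discriminates phosphorus (> 45 degrees) from nitrogen (< 45 degrees)
#' limitation.
#'
#' @name stoichiometry
NULL

# The nine assayed activities, all in micromol product per g soil per h.
.ENZYMES <- c("beta_glucosidase", "cellulase", "xylanase", "dehydrogenase",
              "protease", "urease", "acid_phosphatase",
              "alkaline_phosphatase", "arylsulphatase")

#' Carbon, nitrogen and phosphorus ecoenzyme pools
#'
#' Builds the pooled acquisition activities from individual enzyme activities:
#' carbon enzymes `CE = beta_glucosidase + cellulase + xylanase -
#' dehydrogenase` (supply minus consumption, so `CE` may be negative and is
#' then flagged), nitrogen enzymes `NE = urease + protease`, and phosphorus
#' enzymes `PE = acid_phosphatase`.
#'
#' @param activities data frame with one row per sample and the nine enzyme
#'   activity columns (`beta_glucosidase`, `cellulase`, `xylanase`,
#'   `dehydrogenase`, `protease`, `urease`, `acid_phosphatase`,
#'   `alkaline_phosphatase`, `arylsulphatase`), all in
#'   micromol product per g soil per h. Identifier columns (`sample_id`,
#'   `group`) are carried through when present.
#' @return the input data frame augmented with numeric columns `CE`, `NE`,
#'   `PE` and a logical `CE_negative` flag.
#' @examples
#' eea_pools(data.frame(beta_glucosidase = 0.358, cellulase = 0.146,
#'   xylanase = 0.391, dehydrogenase = 2.35e-3, protease = 0.217,
#'   urease = 10.775, acid_phosphatase = 27.415,
#'   alkaline_phosphatase = 40.645, arylsulphatase = 1.764))
#' @export
eea_pools <- function(activities) {
  .check_cols(activities, .ENZYMES, "enzyme activity table")
  for (e in .ENZYMES) {
    v <- activities[[e]]
    if (!is.numeric(v) || anyNA(v)) {
      .stopf("activity '%s' must be numeric and complete", e)
    }
    if (any(v < 0)) .stopf("activity '%s' contains negative values", e)
  }
  out <- activities
  out$CE <- activities$beta_glucosidase + activities$cellulase +
    activities$xylanase - activities$dehydrogenase
  out$NE <- activities$urease + activities$protease
  out$PE <- activities$acid_phosphatase
  out$CE_negative <- out$CE < 0
  out
}

#' Stoichiometric ratios of the enzyme pools
#'
#' Plain quotients `CE/PE`, `CE/NE` and `NE/PE`. A zero denominator yields
#' `NA` (an undefined ratio), never an error.
#'
#' @param CE,NE,PE numeric vectors of pooled activities.
#' @return data frame with columns `CE_PE`, `CE_NE`, `NE_PE`.
#' @export
stoich_ratios <- function(CE, NE, PE) {
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  data.frame(CE_PE = safe_div(CE, PE),
             CE_NE = safe_div(CE, NE),
             NE_PE = safe_div(NE, PE))
}

#' Enzyme vector components
#'
#' The enzymatic vector lives in the unit square: the x-axis is the share of
#' carbon enzymes relative to carbon plus phosphorus enzymes,
#' `x = CE/(CE + PE)`, and the y-axis the share relative to carbon plus
#' nitrogen enzymes, `y = CE/(CE + NE)`. The vector is undefined (`NA`) when
#' `CE <= 0`.
#'
#' @param CE,NE,PE numeric vectors of pooled activities (`NE`, `PE` >= 0).
#' @return data frame with columns `x` and `y`, each in (0, 1) when all
#'   pools are positive.
#' @export
vector_components <- function(CE, NE, PE) {
  if (any(NE < 0, na.rm = TRUE) || any(PE < 0, na.rm = TRUE)) {
    .stopf("NE and PE must be non-negative")
  }
  ok <- !is.na(CE) & CE > 0
  x <- ifelse(ok, CE / (CE + PE), NA_real_)
  y <- ifelse(ok, CE / (CE + NE), NA_real_)
  data.frame(x = x, y = y)
}

#' Enzyme vector length and angle
#'
#' Polar summary of the point `(x, y)`: length `VL = sqrt(x^2 + y^2)`
#' (dimensionless; larger values mean stronger relative carbon investment,
#' i.e. carbon limitation) and angle `VA = atan2(y, x)` in degrees, mapped to
#' (0, 90) for the positive quadrant. The angle is undefined at the origin.
#'
#' @param x,y numeric vectors of vector components (non-negative).
#' @return data frame with columns `VL` and `VA` (degrees).
#' @export
vector_length_angle <- function(x, y) {
  VL <- sqrt(x^2 + y^2)
  VA <- ifelse(!is.na(x) & !is.na(y) & (x > 0 | y > 0),
               atan2(y, x) * 180 / pi, NA_real_)
  data.frame(VL = VL, VA = VA)
}

#' Classify nutrient limitation from the enzyme vector
#'
#' Vector angles above `angle_threshold` indicate phosphorus limitation,
#' below it nitrogen limitation, and exactly at it a balanced 1:1:1
#' C:N:P enzyme stoichiometry. The vector length qualifies the strength of
#' the limitation: below `length_low_cutoff` the limitation is called weak.
#'
#' @param VL,VA numeric vectors from [vector_length_angle()].
#' @param angle_threshold boundary angle in degrees (default 45).
#' @param length_low_cutoff vector length below which a limitation is
#'   qualified as weak (default 0.5; field surveys in arid agricultural
#'   systems report lengths above 0.5 for pronounced limitation).
#' @return data frame with columns `limitation` (one of `"P_limited"`,
#'   `"N_limited"`, `"balanced"`, `"undefined"`) and `strength` (`"weak"`,
#'   `"strong"`, or `NA` when balanced/undefined).
#' @export
classify_limitation <- function(VL, VA, angle_threshold = 45,
                                length_low_cutoff = 0.5) {
  limitation <- ifelse(is.na(VA), "undefined",
                ifelse(VA > angle_threshold, "P_limited",
                ifelse(VA < angle_threshold, "N_limited", "balanced")))
  strength <- ifelse(limitation %in% c("P_limited", "N_limited"),
                     ifelse(VL < length_low_cutoff, "weak", "strong"),
                     NA_character_)
  data.frame(limitation = limitation, strength = strength)
}

#' Alkaline/acid phosphatase fertility index
#'
#' The ratio of alkaline to acid phosphatase activity indicates whether a
#' soil needs liming for agronomic use: values above 0.5 indicate no
#' correction is needed.
#'
#' @param alkaline,acid numeric activities
#'   (micromol P-nitrophenol per g soil per h); `acid` must be positive.
#' @return data frame with `alk_acid_ratio` and character `liming_flag`.
#' @export
alk_acid_index <- function(alkaline, acid) {
  ratio <- ifelse(acid > 0, alkaline / acid, NA_real_)
  data.frame(alk_acid_ratio = ratio,
             liming_flag = ifelse(is.na(ratio), "undefined",
                           ifelse(ratio > 0.5, "no correction needed",
                                  "liming indicated")))
}

#' Per-sample ecoenzyme summary
#'
#' Runs the full stoichiometry stage on a per-sample activity table: pools,
#' ratios, vector components, length, angle, limitation call and the
#' alkaline/acid phosphatase index.
#'
#' @inheritParams eea_pools
#' @inheritParams classify_limitation
#' @return data frame with one row per input row and columns `CE`, `NE`,
#'   `PE`, `CE_PE`, `CE_NE`, `NE_PE`, `x`, `y`, `VL`, `VA`, `limitation`,
#'   `strength`, `alk_acid_ratio`, `liming_flag` (plus identifier columns).
#' @export
eea_summary <- function(activities, angle_threshold = 45,
                        length_low_cutoff = 0.5) {
  pooled <- eea_pools(activities)
  ids <- intersect(c("sample_id", "group", "compartment"), names(activities))
  out <- cbind(pooled[, c(ids, "CE", "NE", "PE", "CE_negative"),
                      drop = FALSE],
               stoich_ratios(pooled$CE, pooled$NE, pooled$PE),
               vector_components(pooled$CE, pooled$NE, pooled$PE))
  out <- cbind(out, vector_length_angle(out$x, out$y))
  out <- cbind(out, classify_limitation(out$VL, out$VA, angle_threshold,
                                        length_low_cutoff))
  cbind(out, alk_acid_index(activities$alkaline_phosphatase,
                            activities$acid_phosphatase))
}

#' Group-level ecoenzyme summary
#'
#' Aggregates replicate-level activities to one summary per group under two
#' conventions: `"of_means"` first averages the activities within each group
#' and then computes pools, ratios and vectors from the group-mean
#' activities; `"per_replicate"` computes the full summary per sample and
#' then averages the derived quantities. The two generally differ for
#' non-linear derived quantities (ratios, vector length/angle) — a Jensen
#' gap — and agree exactly when replicates are identical. Standard
#' deviations of the per-replicate quantities are reported in either mode.
#'
#' @inheritParams eea_pools
#' @param mode `"per_replicate"` (default) or `"of_means"`.
#' @inheritParams classify_limitation
#' @return data frame with one row per group, the derived quantities, their
#'   per-replicate standard deviations (suffix `_sd`), the number of
#'   replicates `n`, and the aggregation `mode` used.
#' @export
summarize_group <- function(activities,
                            mode = c("per_replicate", "of_means"),
                            angle_threshold = 45, length_low_cutoff = 0.5) {
  mode <- match.arg(mode)
  .check_cols(activities, c("group", .ENZYMES), "enzyme activity table")
  if (nrow(activities) == 0L) .stopf("no records to summarize")

  per_sample <- eea_summary(activities, angle_threshold, length_low_cutoff)
  num_cols <- c("CE", "NE", "PE", "CE_PE", "CE_NE", "NE_PE", "x", "y",
                "VL", "VA", "alk_acid_ratio")
  groups <- unique(activities$group)

  rows <- lapply(groups, function(g) {
    sel <- activities$group == g
    reps <- per_sample[sel, , drop = FALSE]
    sds <- vapply(num_cols, function(v) sd(reps[[v]]), numeric(1))
    if (mode == "of_means") {
      means <- as.data.frame(lapply(activities[sel, .ENZYMES, drop = FALSE],
                                    mean))
      means$group <- g
      derived <- eea_summary(means, angle_threshold, length_low_cutoff)
    } else {
      derived <- reps[1L, , drop = FALSE]
      derived[num_cols] <- lapply(reps[num_cols], mean)
      derived$group <- g
      cls <- classify_limitation(derived$VL, derived$VA, angle_threshold,
                                 length_low_cutoff)
      derived$limitation <- cls$limitation
      derived$strength <- cls$strength
    }
    derived <- derived[, c("group", num_cols, "limitation", "strength"),
                       drop = FALSE]
    for (v in num_cols) derived[[paste0(v, "_sd")]] <- sds[[v]]
    derived$n <- sum(sel)
    derived
  })
  out <- do.call(rbind, rows)
  out$mode <- mode
  rownames(out) <- NULL
  out
}
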