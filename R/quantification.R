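#' Microbial quantification estimators
#'
#' Converts raw enumeration observations from four complementary methods
#' into abundances per gram of sample: colony counting (CFU), the
#' most probable number (MPN) by maximum likelihood, total DNA extraction
#' (TDE) at an assumed DNA mass per cell, and epifluorescence microscopy
#' (EPI) with live/dead staining over a mosaic of microscope fields.
#'
#' @name quantification
NULL

#' Colony-forming units per gram
#'
#' `count * dilution_factor / plated_volume * suspension_volume /
#' sample_mass`. Plates with more colonies than `max_countable` are flagged
#' as uncountable; zero counts are flagged as below detection.
#'
#' @param colony_count non-negative integer colony count.
#' @param dilution_factor dilution of the plated suspension (>= 1).
#' @param plated_volume volume plated, mL.
#' @param suspension_volume volume of the initial suspension, mL.
#' @param sample_mass soil or rhizosphere mass suspended, g (> 0).
#' @param max_countable countability limit per plate (default 300).
#' @return data frame with `cfu_per_g`, logical `below_detection` and
#'   `uncountable`.
#' @examples
#' cfu_per_gram(30, 1e5, 0.1, 10, 1) # 3e8
#' @export
cfu_per_gram <- function(colony_count, dilution_factor, plated_volume,
                         suspension_volume, sample_mass,
                         max_countable = 300) {
  if (any(sample_mass <= 0)) .stopf("sample_mass must be positive")
  if (any(plated_volume <= 0) || any(suspension_volume <= 0)) {
    .stopf("volumes must be positive")
  }
  if (any(colony_count < 0)) .stopf("colony_count must be non-negative")
  if (any(dilution_factor < 1)) .stopf("dilution_factor must be >= 1")
  value <- colony_count * dilution_factor / plated_volume *
    suspension_volume / sample_mass
  data.frame(cfu_per_g = value,
             below_detection = colony_count == 0,
             uncountable = colony_count > max_countable)
}

# Log-likelihood of density lambda for an MPN dilution series under
# independent Poisson inoculation: each tube at inoculum v is positive with
# probability 1 - exp(-lambda * v).
.mpn_loglik <- function(lambda, inoculum, tubes, positives) {
  p <- -expm1(-lambda * inoculum) # 1 - exp(-x), accurate near 0
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  sum(positives * log(p)) - lambda * sum((tubes - positives) * inoculum)
}

# Score (d loglik / d lambda); decreasing in lambda.
.mpn_score <- function(lambda, inoculum, tubes, positives) {
  e <- exp(-lambda * inoculum)
  sum(positives * inoculum * e / -expm1(-lambda * inoculum)) -
    sum((tubes - positives) * inoculum)
}

#' Most probable number by maximum likelihood
#'
#' Estimates the density of culturable organisms from the pattern of
#' positive tubes across a serial-dilution design. Under independent Poisson
#' inoculation a tube receiving `v` grams of original sample is positive
#' with probability `1 - exp(-lambda * v)`; the estimate maximizes the
#' product of binomial likelihoods over dilution levels, solved by bracketed
#' root-finding on the score equation. The confidence interval uses a
#' log-normal approximation: the standard error of `log10(MPN)` from the
#' observed Fisher information.
#'
#' @param inoculum amount of original sample per tube at each level (g or
#'   mL), strictly decreasing.
#' @param tubes number of tubes per level.
#' @param positives number of positive tubes per level.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `mpn` (organisms per g), `se_log10`, `ci` (length-2
#'   vector), `status` (`"ok"`, `"below_detection"` for all-negative
#'   patterns) and `method` metadata. All tubes positive is an error (only a
#'   lower bound on the density exists).
#' @examples
#' mpn_estimate(c(0.1, 0.01, 0.001), c(3, 3, 3), c(3, 1, 0))
#' @export
mpn_estimate <- function(inoculum, tubes, positives, conf_level = 0.95) {
  if (length(inoculum) == 0L) .stopf("at least one dilution level required")
  if (length(tubes) != length(inoculum) ||
      length(positives) != length(inoculum)) {
    .stopf("inoculum, tubes and positives must have equal length")
  }
  if (any(positives < 0) || any(positives > tubes)) {
    .stopf("positives must be between 0 and tubes at every level")
  }
  if (any(inoculum <= 0)) .stopf("inoculum amounts must be positive")
  if (length(inoculum) > 1L && any(diff(inoculum) >= 0)) {
    .stopf("inoculum amounts must be strictly decreasing")
  }

  meta <- list(estimator = "maximum likelihood (Poisson inoculation)",
               ci = "log-normal approximation on log10(MPN)")
  if (all(positives == 0)) {
    # No growth anywhere: the MLE is 0; a one-sided upper bound comes from
    # the largest density compatible with all-negative tubes.
    upper <- -log(1 - conf_level) / sum(tubes * inoculum)
    return(list(mpn = 0, se_log10 = NA_real_, ci = c(0, upper),
                status = "below_detection", method = meta))
  }
  if (all(positives == tubes)) {
    .stopf("all tubes positive at every level: upper bound only")
  }

  upper <- 1 / min(inoculum)
  while (.mpn_score(upper, inoculum, tubes, positives) > 0) {
    upper <- upper * 10
  }
  root <- uniroot(.mpn_score, c(.Machine$double.eps, upper),
                  inoculum = inoculum, tubes = tubes, positives = positives,
                  tol = .Machine$double.eps^0.5)
  lambda <- root$root

  # Observed Fisher information for lambda.
  e <- exp(-lambda * inoculum)
  info <- sum(tubes * inoculum^2 * e / (1 - e))
  se_lambda <- 1 / sqrt(info)
  se_log10 <- se_lambda / (lambda * log(10))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- 10^(log10(lambda) + c(-1, 1) * z * se_log10)
  list(mpn = lambda, se_log10 = se_log10, ci = ci, status = "ok",
       method = meta)
}

#' Cells per gram from total DNA yield
#'
#' Converts an extracted DNA mass into a cell count at an assumed DNA
#' content of 8.14 fg per bacterial cell.
#'
#' @param dna_ng DNA yield, ng (non-negative).
#' @param sample_mass extracted sample mass, g (> 0).
#' @param fg_per_cell assumed DNA mass per cell, fg (default 8.14).
#' @return cells per gram.
#' @examples
#' tde_cells_per_gram(1, 1) # ~1.2285e5
#' @export
tde_cells_per_gram <- function(dna_ng, sample_mass,
                               fg_per_cell = .FG_DNA_PER_CELL) {
  if (any(dna_ng < 0)) .stopf("dna_ng must be non-negative")
  if (any(sample_mass <= 0)) .stopf("sample_mass must be positive")
  dna_ng * 1e6 / fg_per_cell / sample_mass
}

#' Cells per gram from epifluorescence microscopy mosaics
#'
#' Scales the mean count per microscope field up to the whole filter, the
#' whole suspension, and per gram of sample, separately for viable
#' (SYTO-9-only) and total (viable + propidium-iodide-stained) cells:
#' `mean count * (filter_area / field_area) * (suspension_volume /
#' aliquot_volume) / sample_mass`.
#'
#' @param live_counts,dead_counts integer counts per field (typically a
#'   mosaic of 25 fields).
#' @param field_area,filter_area areas in the same unit (e.g. square
#'   micrometres).
#' @param suspension_volume,aliquot_volume volumes, mL.
#' @param sample_mass g (> 0).
#' @return list with `viable_per_g`, `total_per_g`, `viability_fraction`
#'   (`NA` when no cells were seen), `n_fields` and `field_cv` (coefficient
#'   of variation of total per-field counts; `NA` for a single field).
#' @export
epi_cells_per_gram <- function(live_counts, dead_counts, field_area,
                               filter_area, suspension_volume,
                               aliquot_volume, sample_mass) {
  if (length(live_counts) < 1L) .stopf("at least one field required")
  if (length(dead_counts) != length(live_counts)) {
    .stopf("live and dead field counts must have equal length")
  }
  if (any(c(live_counts, dead_counts) < 0)) {
    .stopf("field counts must be non-negative")
  }
  if (any(sample_mass <= 0)) .stopf("sample_mass must be positive")
  scale <- (filter_area / field_area) *
    (suspension_volume / aliquot_volume) / sample_mass
  viable <- mean(live_counts) * scale
  total <- mean(live_counts + dead_counts) * scale
  totals <- live_counts + dead_counts
  list(viable_per_g = viable,
       total_per_g = total,
       viability_fraction = if (total == 0) NA_real_ else viable / total,
       n_fields = length(live_counts),
       field_cv = if (length(totals) > 1L && mean(totals) > 0) {
         sd(totals) / mean(totals)
       } else NA_real_)
}

#' Long-format method comparison table
#'
#' Assembles per-sample abundances from the four methods into a tidy long
#' table on the log10 scale, carrying below-detection entries as censored
#' flags (excluded from downstream correlations by default).
#'
#' @param abundances data frame with columns `sample_id`, `compartment`,
#'   `method` and `value` (organisms per g); optional logical `censored`.
#' @return same table augmented with `log10_value` (`NA` for censored or
#'   zero entries) and a logical `censored` column.
#' @export
method_comparison <- function(abundances) {
  .check_cols(abundances, c("sample_id", "compartment", "method", "value"),
              "abundance table")
  out <- abundances
  if (is.null(out$censored)) out$censored <- FALSE
  out$censored <- out$censored | out$value <= 0
  out$log10_value <- ifelse(out$censored, NA_real_, log10(out$value))
  out
}
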