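#' End-to-end analysis pipeline
#'
#' Orchestrates the stages — ingest or simulate, derive (stoichiometry,
#' chemistry, quantification, microbiological parameters), integrate
#' (ordination, tests, clustering, constrained ordination, PERMANOVA,
#' correlations) — into a single machine-readable report. Stages whose
#' inputs are missing are skipped and recorded, never fatal.
#'
#' @name pipeline
NULL

# Derive per-sample abundances from the raw quantification tables of a
# bundle, one row per sample x compartment x method, on the log10 scale.
.quantification_stage <- function(bundle) {
  out <- list()
  if (!is.null(bundle$cfu)) {
    cf <- bundle$cfu
    res <- cfu_per_gram(cf$colony_count, cf$dilution_factor,
                        cf$plated_volume, cf$suspension_volume,
                        cf$sample_mass)
    out$cfu <- data.frame(sample_id = cf$sample_id,
                          compartment = cf$compartment,
                          method = paste0("CFU_", cf$organism),
                          value = res$cfu_per_g,
                          censored = res$below_detection)
  }
  if (!is.null(bundle$mpn)) {
    keys <- unique(bundle$mpn[c("sample_id", "compartment")])
    vals <- vapply(seq_len(nrow(keys)), function(i) {
      sel <- bundle$mpn$sample_id == keys$sample_id[i] &
        bundle$mpn$compartment == keys$compartment[i]
      d <- bundle$mpn[sel, ][order(-bundle$mpn$inoculum[sel]), ]
      est <- tryCatch(mpn_estimate(d$inoculum, d$tubes, d$positives),
                      error = function(e) list(mpn = NA_real_))
      est$mpn
    }, numeric(1))
    out$mpn <- data.frame(keys, method = "MPN", value = vals,
                          censored = is.na(vals) | vals == 0)
  }
  if (!is.null(bundle$tde)) {
    td <- bundle$tde
    out$tde <- data.frame(sample_id = td$sample_id,
                          compartment = td$compartment, method = "TDE",
                          value = tde_cells_per_gram(td$dna_ng,
                                                     td$sample_mass),
                          censored = td$dna_ng == 0)
  }
  if (!is.null(bundle$epi)) {
    keys <- unique(bundle$epi[c("sample_id", "compartment")])
    vals <- vapply(seq_len(nrow(keys)), function(i) {
      d <- bundle$epi[bundle$epi$sample_id == keys$sample_id[i] &
                        bundle$epi$compartment == keys$compartment[i], ]
      epi_cells_per_gram(d$live_count, d$dead_count, d$field_area[1],
                         d$filter_area[1], d$suspension_volume[1],
                         d$aliquot_volume[1], d$sample_mass[1])$viable_per_g
    }, numeric(1))
    out$epi <- data.frame(keys, method = "EPI", value = vals,
                          censored = vals == 0)
  }
  if (length(out) == 0L) return(NULL)
  method_comparison(do.call(rbind, c(out, make.row.names = FALSE)))
}

#' Run the integrated analysis pipeline
#'
#' @param bundle an `"ecoenz_bundle"` (from [simulate_study()] or
#'   [read_bundle()]); tables set to `NULL` cause the dependent stages to be
#'   skipped and listed in the report.
#' @param mode group aggregation mode for the stoichiometry stage
#'   (see [summarize_group()]).
#' @param n_perm permutations for PERMANOVA and the redundancy analysis
#'   (>= 99; default 999).
#' @param seed integer seed governing every stochastic stage; stage seeds
#'   are derived as `seed`, `seed + 1` (PERMANOVA), `seed + 2` (RDA) and
#'   `seed + 3` (clustering).
#' @param k number of clusters for the k-means stage (default 3).
#' @param vif_threshold variance-inflation threshold for the environmental
#'   screen (default 2).
#' @param env_candidates chemistry variables offered to the screen for the
#'   redundancy analysis (default `c("TOC", "TN")`).
#' @param alpha significance level annotated on correlation tables
#'   (default 0.05).
#' @param outdir optional directory; when given, derived CSV tables and a
#'   JSON report are written there.
#' @return list of class `"ecoenz_report"` with elements `stoichiometry`
#'   (per-sample and per-group), `chemistry`, `quantification`,
#'   `microbial`, `multivariate` (PCA, component tests, clustering,
#'   PERMANOVA, RDA, correlations), `skipped`, and `config`.
#' @export
run_pipeline <- function(bundle, mode = c("per_replicate", "of_means"),
                         n_perm = 999, seed = 1, k = 3, vif_threshold = 2,
                         env_candidates = c("TOC", "TN"), alpha = 0.05,
                         outdir = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 99) .stopf("n_perm must be >= 99")
  report <- list(config = list(mode = mode, n_perm = n_perm, seed = seed,
                               k = k, vif_threshold = vif_threshold,
                               alpha = alpha))
  skipped <- character(0)

  stoich <- NULL
  if (!is.null(bundle$enzymes)) {
    per_sample <- cbind(eea_summary(bundle$enzymes),
                        bundle$enzymes[c("alkaline_phosphatase",
                                         "arylsulphatase")])
    report$stoichiometry <- list(
      per_sample = per_sample,
      per_group = summarize_group(bundle$enzymes, mode = mode))
    stoich <- per_sample
  } else skipped <- c(skipped, "stoichiometry")

  chem <- NULL
  if (!is.null(bundle$chemistry)) {
    chem <- derive_chemistry(bundle$chemistry)
    report$chemistry <- chem
  } else skipped <- c(skipped, "chemistry")

  quant <- .quantification_stage(bundle)
  if (!is.null(quant)) report$quantification <- quant
  else skipped <- c(skipped, "quantification")

  micro <- NULL
  if (!is.null(bundle$biomass) && !is.null(bundle$respiration)) {
    micro <- microbial_summary(bundle$biomass, bundle$respiration, chem)
    report$microbial <- micro
  } else skipped <- c(skipped, "microbial_params")

  if (!is.null(stoich) && !is.null(chem) && !is.null(micro)) {
    features <- assemble_features(stoich, chem, micro)
    groups <- attr(features, "groups")
    pca <- pca_ordination(features)
    perm <- permanova(features, groups, n_perm = n_perm, seed = seed + 1)
    clust <- kmeans_clusters(pca$scores, groups, k = k, seed = seed + 3)
    screen <- vif_screen(chem[match(stoich$group, chem$group),
                              env_candidates, drop = FALSE],
                         threshold = vif_threshold)
    env <- chem[match(stoich$group, chem$group), screen$selected,
                drop = FALSE]
    response <- features[, attr(features, "roles") == "biological",
                         drop = FALSE]
    rda <- rda_analysis(response, env, n_perm = n_perm, seed = seed + 2)
    rda$model <- NULL
    report$multivariate <- list(
      features = features,
      pca = pca,
      component_tests = component_tests(pca$scores, groups),
      clustering = clust,
      permanova = perm,
      vif_screen = screen,
      rda = rda)
    if (!is.null(quant)) {
      ok <- !quant$censored
      wide <- tapply(quant$log10_value[ok],
                     list(quant$sample_id[ok],
                          paste(quant$method[ok], quant$compartment[ok],
                                sep = ".")),
                     mean)
      wide <- wide[match(stoich$sample_id, rownames(wide)), , drop = FALSE]
      report$multivariate$quant_correlations <-
        spearman_matrix(wide, features, alpha = alpha)
    }
  } else skipped <- c(skipped, "multivariate")

  report$skipped <- skipped
  report <- structure(report, class = "ecoenz_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes the derived tables as CSV and the scalar results (test
#' statistics, p-values, explained-variance fractions, configuration) as a
#' JSON report.
#'
#' @param report an `"ecoenz_report"`.
#' @param outdir output directory (created if absent).
#' @return invisibly, the path of the JSON report.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!is.null(report$stoichiometry)) {
    write.csv(report$stoichiometry$per_sample,
              file.path(outdir, "stoichiometry_samples.csv"),
              row.names = FALSE)
    write.csv(report$stoichiometry$per_group,
              file.path(outdir, "stoichiometry_groups.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$chemistry)) {
    write.csv(report$chemistry, file.path(outdir, "chemistry_derived.csv"),
              row.names = FALSE)
  }
  if (!is.null(report$quantification)) {
    write.csv(report$quantification,
              file.path(outdir, "quantification.csv"), row.names = FALSE)
  }
  if (!is.null(report$microbial)) {
    write.csv(report$microbial,
              file.path(outdir, "microbial_params.csv"), row.names = FALSE)
  }
  json <- list(config = report$config, skipped = report$skipped)
  mv <- report$multivariate
  if (!is.null(mv)) {
    write.csv(data.frame(sample_id = rownames(mv$pca$scores),
                         group = attr(mv$features, "groups"),
                         mv$pca$scores[, 1:min(5, ncol(mv$pca$scores))]),
              file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    write.csv(data.frame(variable = rownames(mv$pca$loadings),
                         mv$pca$loadings[, 1:min(5, ncol(mv$pca$loadings))]),
              file.path(outdir, "pca_loadings.csv"), row.names = FALSE)
    json$pca <- list(prop_var = mv$pca$prop_var)
    json$component_tests <- lapply(mv$component_tests, function(ct) {
      if (is.character(ct)) return(ct)
      list(shapiro_p = ct$shapiro_p, levene_p = ct$levene_p,
           anova_p = ct$anova_p, kruskal_p = ct$kruskal_p,
           tukey = ct$tukey, dunn = ct$dunn)
    })
    json$clustering <- mv$clustering
    json$permanova <- unclass(mv$permanova)
    json$vif_screen <- mv$vif_screen
    json$rda <- mv$rda
  }
  path <- file.path(outdir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Validate a study bundle
#'
#' Report-only schema and invariant checks on the input tables: required
#' columns, negative activities, duplicated sample ids, tube-count
#' consistency, non-positive masses and volumes. Returns findings, never
#' raises.
#'
#' @param bundle an `"ecoenz_bundle"`.
#' @return data frame with columns `table`, `row`, `message`; zero rows for
#'   a clean bundle.
#' @export
validate_bundle <- function(bundle) {
  findings <- list()
  note <- function(tb, row, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(table = tb, row = row,
                                                     message = msg)
  }
  if (!is.null(bundle$enzymes)) {
    en <- bundle$enzymes
    miss <- setdiff(.ENZYMES, names(en))
    if (length(miss)) note("enzymes", NA, paste("missing columns:",
                                                paste(miss, collapse = ", ")))
    for (e in intersect(.ENZYMES, names(en))) {
      for (i in which(en[[e]] < 0)) {
        note("enzymes", i, sprintf("negative activity in '%s'", e))
      }
    }
    for (i in which(duplicated(en$sample_id))) {
      note("enzymes", i, sprintf("duplicated sample_id '%s'",
                                 en$sample_id[i]))
    }
  }
  if (!is.null(bundle$mpn)) {
    bad <- which(bundle$mpn$positives > bundle$mpn$tubes |
                   bundle$mpn$positives < 0)
    for (i in bad) note("mpn", i, "positives outside [0, tubes]")
  }
  if (!is.null(bundle$cfu)) {
    for (i in which(bundle$cfu$sample_mass <= 0)) {
      note("cfu", i, "non-positive sample_mass")
    }
    for (i in which(bundle$cfu$colony_count < 0)) {
      note("cfu", i, "negative colony_count")
    }
  }
  if (!is.null(bundle$chemistry)) {
    ch <- bundle$chemistry
    for (v in intersect(c("OM", "TN", "P", "Ca", "Mg", "K", "Na", "Al",
                          "PA"), names(ch))) {
      for (i in which(ch[[v]] < 0)) {
        note("chemistry", i, sprintf("negative '%s'", v))
      }
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(table = character(), row = integer(),
                      message = character()))
  }
  do.call(rbind, findings)
}
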