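#' Multivariate integration of chemical and biological soil variables
#'
#' Assembles the standardized feature matrix (25 variables by default),
#' ordains it by PCA with per-component hypothesis testing, clusters the
#' scores, correlates feature blocks by Spearman rank correlation, screens
#' environmental predictors by variance inflation, fits a redundancy
#' analysis with permutation inference, and tests group separation by
#' Euclidean PERMANOVA with a companion dispersion check.
#'
#' @name multivariate
NULL

# The 25 integrated variables: ecoenzyme pools and ratios, vector summary,
# two single-enzyme activities (AF alkaline phosphatase, SE arylsulphatase),
# soil chemistry, soil elemental ratios, and microbiological parameters.
.FEATURE_VARS <- c("CE", "NE", "PE", "CE_NE", "CE_PE", "NE_PE", "VL", "VA",
                   "AF", "SE", "TOC", "TN", "PS", "CaS", "KS", "MgS", "NaS",
                   "CEC", "pH", "TOC_TN", "TOC_PS", "TN_PS",
                   "MR", "MBC", "MBN")

#' Assemble the standardized feature matrix
#'
#' Joins the per-sample stoichiometry summary, the (group-constant, pooled)
#' derived chemistry broadcast to replicates, and the per-sample
#' microbiological parameters into the 25-variable matrix, then z-scores
#' every column. Quantification variables are excluded by design (they enter
#' the analysis through Spearman correlations instead).
#'
#' @param stoich per-sample output of [eea_summary()] plus the raw
#'   `alkaline_phosphatase` and `arylsulphatase` activities (as produced on
#'   the enzyme table of a study bundle).
#' @param chemistry derived chemistry from [derive_chemistry()] (one row per
#'   group).
#' @param microbial per-sample output of [microbial_summary()].
#' @param scale z-score the columns (default `TRUE`).
#' @return numeric matrix (samples x variables) with `rownames` the sample
#'   ids and attributes `groups` (character vector) and `roles` (variable
#'   role, `"biological"` or `"chemical"`).
#' @export
assemble_features <- function(stoich, chemistry, microbial, scale = TRUE) {
  .check_cols(stoich, c("sample_id", "group", "CE", "NE", "PE", "CE_NE",
                        "CE_PE", "NE_PE", "VL", "VA",
                        "alkaline_phosphatase", "arylsulphatase"),
              "stoichiometry table")
  .check_cols(chemistry, c("group", "TOC", "TN", "P", "Ca", "K", "Mg", "Na",
                           "CEC", "pH_water", "CS_NS", "CS_PS", "NS_PS"),
              "chemistry table")
  .check_cols(microbial, c("sample_id", "MR", "MBC", "MBN"),
              "microbial table")

  chem <- chemistry[match(stoich$group, chemistry$group), , drop = FALSE]
  micro <- microbial[match(stoich$sample_id, microbial$sample_id), ,
                     drop = FALSE]
  if (anyNA(micro$MBC)) .stopf("sample_ids do not align across tables")

  x <- data.frame(
    CE = stoich$CE, NE = stoich$NE, PE = stoich$PE,
    CE_NE = stoich$CE_NE, CE_PE = stoich$CE_PE, NE_PE = stoich$NE_PE,
    VL = stoich$VL, VA = stoich$VA,
    AF = stoich$alkaline_phosphatase, SE = stoich$arylsulphatase,
    TOC = chem$TOC, TN = chem$TN, PS = chem$P, CaS = chem$Ca, KS = chem$K,
    MgS = chem$Mg, NaS = chem$Na, CEC = chem$CEC, pH = chem$pH_water,
    TOC_TN = chem$CS_NS, TOC_PS = chem$CS_PS, TN_PS = chem$NS_PS,
    MR = micro$MR, MBC = micro$MBC, MBN = micro$MBN)
  if (anyNA(x)) .stopf("feature matrix contains missing values")
  m <- as.matrix(x)
  rownames(m) <- stoich$sample_id
  if (scale) {
    # z-score; a zero-variance column carries no information and is centred
    # to exact zeros rather than propagating NaN
    mu <- colMeans(m)
    sdev <- apply(m, 2, sd)
    m <- sweep(m, 2, mu)
    pos <- sdev > 0
    m[, pos] <- sweep(m[, pos, drop = FALSE], 2, sdev[pos], "/")
  }
  attr(m, "groups") <- as.character(stoich$group)
  attr(m, "roles") <- ifelse(.FEATURE_VARS %in%
                               c("TOC", "TN", "PS", "CaS", "KS", "MgS",
                                 "NaS", "CEC", "pH", "TOC_TN", "TOC_PS",
                                 "TN_PS"),
                             "chemical", "biological")[
                               match(colnames(m), .FEATURE_VARS)]
  m
}

#' Principal component analysis of the feature matrix
#'
#' Eigendecomposition of the covariance of the (already z-scored) matrix,
#' with a deterministic sign convention: on each axis the largest-magnitude
#' loading is made positive. Rank-deficient inputs are truncated to the
#' positive-eigenvalue axes.
#'
#' @param x numeric matrix, samples x variables (z-scored columns).
#' @return list of class `"ecoenz_pca"` with `scores`, `loadings`,
#'   `eigenvalues` and `prop_var` (explained-variance fractions summing
#'   to 1 over the retained axes).
#' @export
pca_ordination <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L) .stopf("need >= 2 samples and variables")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- p$sdev^2 > max(p$sdev^2) * 1e-12
  scores <- p$x[, keep, drop = FALSE]
  loadings <- p$rotation[, keep, drop = FALSE]
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- p$sdev[keep]^2
  structure(list(scores = scores, loadings = loadings, eigenvalues = eig,
                 prop_var = eig / sum(eig)),
            class = "ecoenz_pca")
}

#' Dunn's post-hoc test of pairwise group differences on ranks
#'
#' Rank-sum z statistics with tie correction after a Kruskal-Wallis test;
#' p-values are two-sided and Bonferroni-adjusted by default.
#'
#' @param x numeric response.
#' @param g group factor.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return data frame with `comparison`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(x, g, p_adjust = "bonferroni") {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
    z[k] <- (mean_ranks[a] - mean_ranks[b]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
             z = z, p_value = p,
             p_adjusted = p.adjust(p, method = p_adjust))
}

#' Hypothesis-test battery per ordination component
#'
#' For each retained component, tests normality (Shapiro-Wilk), variance
#' homogeneity (Levene, median-centred), group differences (one-way ANOVA
#' with Tukey pairwise comparisons) and the non-parametric counterparts
#' (Kruskal-Wallis with Dunn pairwise comparisons). The parametric and
#' non-parametric batteries are always reported side by side; the Tukey
#' results remain interpretable under non-normality when Levene confirms
#' homogeneous variances.
#'
#' @param scores matrix of component scores (samples x components).
#' @param groups group labels, one per sample (>= 2 groups with >= 2
#'   replicates each).
#' @param n_components number of leading components to test (default 2).
#' @return named list, one element per component, each containing
#'   `shapiro_p`, `levene_p`, `anova_p`, `tukey` (data frame), `kruskal_p`
#'   and `dunn` (data frame); or a character skip reason when fewer than 3
#'   observations are available.
#' @export
component_tests <- function(scores, groups,
                            n_components = min(2L, ncol(scores))) {
  g <- factor(groups)
  if (nlevels(g) < 2L) .stopf("need >= 2 groups")
  out <- list()
  for (j in seq_len(n_components)) {
    v <- scores[, j]
    nm <- colnames(scores)[j] %||% paste0("PC", j)
    if (length(v) < 3L) {
      out[[nm]] <- "skipped: fewer than 3 observations"
      next
    }
    fit <- aov(v ~ g)
    tk <- TukeyHSD(fit)$g
    out[[nm]] <- list(
      shapiro_p = shapiro.test(v)$p.value,
      levene_p = car::leveneTest(v ~ g)[1, "Pr(>F)"],
      anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
      tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_adjusted = tk[, "p adj"], row.names = NULL),
      kruskal_p = kruskal.test(v, g)$p.value,
      dunn = dunn_test(v, g))
  }
  out
}

#' k-means clustering of ordination scores with purity
#'
#' Seeded k-means (multiple restarts) on the score matrix; purity is the
#' fraction of samples whose cluster's majority group label matches their
#' own, and is invariant to permutations of cluster labels.
#'
#' @param scores numeric matrix of scores (or any sample-wise features).
#' @param groups reference group labels.
#' @param k number of clusters (default 3; must not exceed the sample
#'   count).
#' @param seed RNG seed for the restarts.
#' @param nstart number of random restarts (default 25).
#' @return list with `cluster` (integer assignments), `purity` and `sizes`.
#' @export
kmeans_clusters <- function(scores, groups, k = 3, seed = 1, nstart = 25) {
  if (k > nrow(scores)) .stopf("k must not exceed the number of samples")
  set.seed(seed)
  km <- kmeans(scores, centers = k, nstart = nstart)
  list(cluster = km$cluster,
       purity = cluster_purity(km$cluster, groups),
       sizes = km$size)
}

#' Cluster purity against reference labels
#'
#' @param cluster integer/character cluster assignments.
#' @param groups reference labels of the same length.
#' @return fraction in `[1/k, 1]` of samples whose cluster majority label
#'   matches their own label.
#' @export
cluster_purity <- function(cluster, groups) {
  tab <- table(cluster, groups)
  sum(apply(tab, 1, max)) / length(cluster)
}

#' Spearman rank correlation matrix with p-values
#'
#' Pairwise Spearman correlations (tie-corrected, two-sided p from the
#' t approximation) between the columns of `a` and `b`. Constant columns
#' yield `NA` correlations.
#'
#' @param a,b numeric matrices or data frames with paired rows; `b` defaults
#'   to `a`.
#' @param alpha significance threshold for the `significant` flag
#'   (default 0.05).
#' @return list with matrices `rho`, `p_value` and logical `significant`.
#' @export
spearman_matrix <- function(a, b = a, alpha = 0.05) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) .stopf("a and b must have paired rows")
  rho <- matrix(NA_real_, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
  p <- rho
  for (i in seq_len(ncol(a))) {
    for (j in seq_len(ncol(b))) {
      xi <- a[, i]; yj <- b[, j]
      ok <- complete.cases(xi, yj)
      if (sum(ok) < 3L || sd(xi[ok]) == 0 || sd(yj[ok]) == 0) next
      ct <- suppressWarnings(cor.test(xi[ok], yj[ok], method = "spearman",
                                      exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p_value = p, significant = !is.na(p) & p < alpha)
}

#' Iterative variance-inflation-factor screening
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` from regressing each candidate on the
#' others and repeatedly drops the highest-VIF variable until all remaining
#' VIFs are below the threshold. Ties are broken by dropping the
#' lexicographically first variable among the tied ones. A single variable
#' has VIF 1 by definition.
#'
#' @param env data frame or matrix of candidate environmental variables.
#' @param threshold VIF threshold (default 2, a stringent screen keeping
#'   only near-orthogonal predictors).
#' @return list with `selected` (column names kept), `vifs` (named vector
#'   for the kept set) and `dropped` (in drop order).
#' @export
vif_screen <- function(env, threshold = 2) {
  env <- as.data.frame(env)
  if (ncol(env) < 1L) .stopf("need at least one candidate variable")
  vif_of <- function(d) {
    if (ncol(d) == 1L) return(setNames(1, names(d)))
    vapply(names(d), function(v) {
      fit <- lm(d[[v]] ~ ., data = d[setdiff(names(d), v)])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character(0)
  repeat {
    vifs <- vif_of(env)
    if (all(vifs < threshold)) break
    worst <- sort(names(vifs)[vifs == max(vifs)])[1]
    dropped <- c(dropped, worst)
    env <- env[setdiff(names(env), worst)]
  }
  list(selected = names(env), vifs = vifs, dropped = dropped)
}

#' Redundancy analysis with permutation inference
#'
#' Constrained ordination of the (z-scored) response matrix on the
#' environmental predictors: the constrained axes are the eigen-structure of
#' the fitted values of the multivariate regression, the unconstrained axes
#' that of the residuals. The fit delegates to [vegan::rda()];
#' permutation p-values (global model, sequential per-axis, sequential
#' per-term) use seeded permutations, and the adjusted R-squared uses the
#' Ezekiel correction.
#'
#' @param response numeric matrix of response variables (samples x
#'   variables), typically the biological block of the feature matrix.
#' @param env data frame of environmental predictors (should have passed
#'   [vif_screen()]).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation tests.
#' @return list with `eigenvalues`, `constrained_prop` (fraction of total
#'   variance explained by the constraints), `axis_prop` (constrained-axis
#'   fractions), `adj_r2`, `p_global`, `p_axis`, `p_terms` and `vifs`.
#' @export
rda_analysis <- function(response, env, n_perm = 999, seed = 1) {
  env <- as.data.frame(env)
  response <- as.matrix(response)
  m <- vegan::rda(response ~ ., data = env)
  vifs <- vegan::vif.cca(m)
  if (any(!is.finite(vifs))) {
    .stopf("environmental variables are collinear to machine precision; re-screen with vif_screen()")
  }
  set.seed(seed)
  global <- vegan::anova.cca(m, permutations = n_perm)
  set.seed(seed)
  by_axis <- vegan::anova.cca(m, by = "axis", permutations = n_perm)
  set.seed(seed)
  by_term <- vegan::anova.cca(m, by = "terms", permutations = n_perm)
  eig <- m$CCA$eig
  list(eigenvalues = eig,
       constrained_prop = m$CCA$tot.chi / m$tot.chi,
       axis_prop = eig / sum(eig),
       adj_r2 = vegan::RsquareAdj(m)$adj.r.squared,
       p_global = global[["Pr(>F)"]][1],
       p_axis = setNames(by_axis[["Pr(>F)"]][seq_along(eig)], names(eig)),
       p_terms = setNames(
         by_term[["Pr(>F)"]][seq_len(ncol(env))], names(env)),
       vifs = vifs,
       model = m)
}

# Within-group sum of squared distances for a batch of label matrices.
# d2 is the n x n squared-distance matrix; labels an n x B matrix of group
# assignments. Returns a length-B vector of within-group SS.
.within_ss <- function(d2, labels, group_levels) {
  B <- ncol(labels)
  ss <- numeric(B)
  for (g in group_levels) {
    ind <- labels == g
    n_g <- colSums(ind)
    ss <- ss + colSums((d2 %*% ind) * ind) / (2 * n_g)
  }
  ss
}

# All permutations of 1..n as a matrix (n x n!); tiny n only.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(ncol(sub))) {
      out[, col] <- c(k, rest[sub[, j]])
      col <- col + 1L
    }
  }
  out
}

#' Euclidean PERMANOVA with dispersion check
#'
#' Permutational multivariate analysis of variance on the Euclidean
#' distance matrix of the feature matrix: pseudo-F from among- and
#' within-group sums of squared distances, `R^2 = SS_among / SS_total`, and
#' a permutation p-value under the `(1 + b) / (1 + B)` convention. With
#' `exhaustive = TRUE` all label permutations are enumerated (small samples
#' only) and the p-value is the exact proportion of arrangements with
#' `F >= F_obs`. A companion dispersion test (ANOVA on the distances to
#' group centroids, via [vegan::betadisper()]) checks the homogeneity
#' assumption.
#'
#' @param x numeric matrix (samples x variables).
#' @param groups group labels (>= 2 groups with >= 2 samples each).
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all label permutations instead (requires
#'   <= 9 samples).
#' @return list of class `"ecoenz_permanova"` with `F`, `R2`, `p_value`,
#'   `n_perm`, `df`, `ss` (among/within/total) and `dispersion_p`.
#' @export
permanova <- function(x, groups, n_perm = 999, seed = 1,
                      exhaustive = FALSE) {
  x <- as.matrix(x)
  g <- factor(groups)
  n <- nrow(x)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    .stopf("need >= 2 groups with >= 2 samples each")
  }
  d2 <- as.matrix(dist(x))^2
  if (all(d2 == 0)) .stopf("all pairwise distances are zero; F undefined")
  ss_total <- sum(d2) / (2 * n)
  levels_g <- levels(g)
  k <- nlevels(g)

  f_stat <- function(ss_within) {
    ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  }
  obs_within <- .within_ss(d2, matrix(g, n, 1), levels_g)
  f_obs <- f_stat(obs_within)

  if (exhaustive) {
    if (n > 9L) .stopf("exhaustive enumeration supported for <= 9 samples")
    perms <- .all_perms(n)
    labels <- matrix(as.character(g)[perms], n, ncol(perms))
    f_all <- f_stat(.within_ss(d2, labels, levels_g))
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- ncol(perms)
  } else {
    set.seed(seed)
    labels <- vapply(seq_len(n_perm),
                     function(i) as.character(g)[sample.int(n)],
                     character(n))
    f_perm <- f_stat(.within_ss(d2, labels, levels_g))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }

  bd <- vegan::betadisper(dist(x), g)
  disp_p <- anova(bd)[1, "Pr(>F)"]

  structure(list(F = f_obs, R2 = (ss_total - obs_within) / ss_total,
                 p_value = p, n_perm = n_used,
                 df = c(among = k - 1, within = n - k),
                 ss = c(among = ss_total - obs_within, within = obs_within,
                        total = ss_total),
                 dispersion_p = disp_p),
            class = "ecoenz_permanova")
}
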