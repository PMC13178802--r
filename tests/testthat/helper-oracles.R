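# Independent brute-force oracles used to pin down expected values.

# MPN likelihood-grid oracle: maximizes the product of binomial likelihoods
# over a dense log-spaced density grid, independently of the package's
# root-finding estimator.
mpn_grid_oracle <- function(inoculum, tubes, positives,
                            grid = 10^seq(-2, 5, length.out = 20000)) {
  loglik <- vapply(grid, function(lambda) {
    p <- 1 - exp(-lambda * inoculum)
    p <- pmin(pmax(p, 1e-300), 1)
    sum(positives * log(p) + (tubes - positives) * (-lambda * inoculum))
  }, numeric(1))
  grid[which.max(loglik)]
}

# Exhaustive PERMANOVA oracle for two groups of equal size: enumerates the
# distinct label splits with combn and computes pseudo-F directly from
# group sums of squared Euclidean distances.
permanova_enum_oracle <- function(x, groups) {
  x <- as.matrix(x)
  n <- nrow(x)
  g <- factor(groups)
  k <- nlevels(g)
  d2 <- as.matrix(dist(x))^2
  ss_total <- sum(d2) / (2 * n)
  f_of <- function(lab) {
    ss_w <- 0
    for (lev in unique(lab)) {
      idx <- which(lab == lev)
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((ss_total - ss_w) / (k - 1)) / (ss_w / (n - k))
  }
  f_obs <- f_of(as.character(g))
  sizes <- table(g)
  splits <- combn(n, sizes[[1]])
  f_all <- apply(splits, 2, function(idx) {
    lab <- rep(levels(g)[2], n)
    lab[idx] <- levels(g)[1]
    f_of(lab)
  })
  list(f = f_obs, p = mean(f_all >= f_obs - 1e-12))
}

# Spearman rho by explicit rank computation (Pearson correlation of ranks).
spearman_rank_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small per-sample activity record builder with defaults of zero.
activity_record <- function(..., sample_id = "s1", group = "g1") {
  base <- data.frame(sample_id = sample_id, group = group,
                     beta_glucosidase = 0, cellulase = 0, xylanase = 0,
                     dehydrogenase = 0, protease = 0, urease = 0,
                     acid_phosphatase = 0, alkaline_phosphatase = 0,
                     arylsulphatase = 0)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
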