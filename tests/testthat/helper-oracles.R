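# Independent oracles used across the suite. These deliberately use direct,
# brute-force formulations rather than the package's own code paths.

# Hand-rolled balanced two-way ANOVA sums of squares from cell means.
brute_force_ss <- function(y, g, e) {
  g <- as.character(g); e <- as.character(e)
  N <- length(y)
  grand <- mean(y)
  r <- N / (length(unique(g)) * length(unique(e)))
  gm <- tapply(y, g, mean)
  em <- tapply(y, e, mean)
  cm <- tapply(y, list(g, e), mean)
  ss_g <- r * length(unique(e)) * sum((gm - grand)^2)
  ss_e <- r * length(unique(g)) * sum((em - grand)^2)
  ss_cells <- r * sum((cm - grand)^2)
  ss_ge <- ss_cells - ss_g - ss_e
  ss_tot <- sum((y - grand)^2)
  list(G = ss_g, Env = ss_e, GxEnv = ss_ge, Residual = ss_tot - ss_cells,
       total = ss_tot)
}

# Direct generalized-least-squares fit of y ~ X at a fixed variance ratio,
# via an explicit inverse of V = K + delta * I (no spectral shortcut).
direct_gls <- function(y, X, K, delta) {
  V <- K + delta * diag(length(y))
  W <- solve(V)
  XtW <- crossprod(X, W)
  b <- solve(XtW %*% X, XtW %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- drop(crossprod(res, W %*% res)) / df
  covb <- s2 * solve(XtW %*% X)
  tstat <- drop(b) / sqrt(diag(covb))
  list(beta = drop(b), t = tstat, p = 2 * pt(-abs(tstat), df))
}

# Tiny deterministic trial table: two genotypes, one environment, two
# treatments, one replicate, hand-written counts.
tiny_trials <- function() {
  df <- data.frame(
    genotype_id = rep(c("g1", "g2"), each = 2),
    environment = "E1",
    treatment = rep(c("control", "drought"), 2),
    replicate = 1L,
    total_seeds = 50L,
    day1 = c(25L, 10L, 30L, 5L),
    day2 = c(10L, 5L, 10L, 5L),
    day3 = c(5L, 3L, 5L, 2L),
    day4 = c(0L, 0L, 0L, 0L),
    day5 = c(0L, 0L, 0L, 2L),
    day6 = c(0L, 0L, 0L, 0L),
    day7 = c(0L, 2L, 0L, 0L)
  )
  class(df) <- c("germination_trials", "data.frame")
  df
}

# Gaussian balanced genotype x environment x replicate layout with known
# variance components, for recovery checks.
simulate_balanced_layout <- function(n_geno, n_env, n_rep, s2g, s2ge, s2e) {
  g_eff <- rnorm(n_geno, 0, sqrt(s2g))
  ge_eff <- matrix(rnorm(n_geno * n_env, 0, sqrt(s2ge)), n_geno, n_env)
  d <- expand.grid(replicate = seq_len(n_rep), genotype_id = seq_len(n_geno),
                   environment = seq_len(n_env))
  d$y <- g_eff[d$genotype_id] + ge_eff[cbind(d$genotype_id, d$environment)] +
    rnorm(nrow(d), 0, sqrt(s2e))
  d$genotype_id <- paste0("g", d$genotype_id)
  d$environment <- paste0("E", d$environment)
  d
}

# Dosage matrix with independent SNPs at uniform MAF, no structure.
random_dosages <- function(n, m, maf_lo = 0.05, maf_hi = 0.5) {
  p <- runif(m, maf_lo, maf_hi)
  M <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  dimnames(M) <- list(sprintf("G%04d", seq_len(n)), sprintf("S%05d", seq_len(m)))
  M
}
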