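#' VanRaden kinship matrix from SNP dosages
#'
#' Centred cross-product genomic relationship matrix:
#' \eqn{K = Z Z' / (2 \sum_k p_k (1 - p_k))} where `Z` is the dosage matrix
#' with each SNP centred at twice its alternate-allele frequency.
#' Monomorphic SNPs are dropped first; the construction is deterministic.
#'
#' @param G A `genotype_matrix` (from [simulate_genotypes()] or
#'   [read_dosage()]) or a plain genotypes x SNPs dosage matrix in
#'   \{0, 1, 2\}.
#' @param maf Minimum minor-allele frequency; SNPs below it are excluded
#'   before centring (default 0, i.e. only monomorphic SNPs drop).
#' @return Symmetric genotypes x genotypes matrix with attribute
#'   `method = "vanraden"`.
#' @examples
#' g <- simulate_genotypes(sim_config(n_genotypes = 10, n_snps = 50, rng_seed = 1))
#' K <- kinship(g)
#' @export
kinship <- function(G, maf = 0) {
  M <- dosage_matrix(G)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1 & pmin(p, 1 - p) >= maf
  if (!any(keep)) stop("no polymorphic SNPs left after filtering")
  M <- M[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(M, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  attr(K, "method") <- "vanraden"
  K
}

dosage_matrix <- function(G) {
  M <- if (inherits(G, "genotype_matrix")) G$dosage else G
  if (!is.matrix(M)) stop("need a dosage matrix or genotype_matrix")
  storage.mode(M) <- "double"
  M
}

# EMMA-style restricted likelihood of the variance ratio delta = s2e/s2u on
# the null model, using the spectrum of the part of K orthogonal to X.
reml_delta <- function(y, X, K) {
  n <- length(y)
  q <- qr(X)$rank
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  lambda <- es$values[seq_len(n - q)]
  lambda[lambda < 1e-10] <- 1e-10
  eta <- drop(crossprod(es$vectors[, seq_len(n - q), drop = FALSE], y))
  ll <- function(logd) {
    d <- exp(logd)
    -0.5 * ((n - q) * log(sum(eta^2 / (lambda + d))) + sum(log(lambda + d)))
  }
  grid <- seq(-10, 10, length.out = 41)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE)
  delta <- exp(opt$maximum)
  s2u <- sum(eta^2 / (lambda + delta)) / (n - q)
  list(delta = delta, sigma2_u = s2u, sigma2_e = delta * s2u,
       logrl = opt$objective)
}

#' Mixed-linear-model association scan
#'
#' Single-marker scan under the mixed model
#' \eqn{y = \mu + s\beta + u + e}, \eqn{u \sim N(0, \sigma^2_u K)},
#' \eqn{e \sim N(0, \sigma^2_e I)}. The variance ratio is estimated once by
#' restricted maximum likelihood on the null (no-SNP) model via the spectral
#' decomposition of the kinship matrix, then held fixed while every SNP is
#' tested by generalized least squares on the whitened data (the
#' population-parameters-previously-determined / EMMAX approximation). Each
#' SNP enters as its alternate-allele dosage, i.e. an additive effect.
#'
#' Per SNP the scan reports the effect estimate, its standard error, the
#' Wald t statistic, a two-sided p-value, \eqn{-\log_{10}(p)}, and the
#' percent of phenotypic variation explained (PVE): the likelihood-ratio
#' \eqn{R^2} of the SNP term on the whitened scale, which for this Gaussian
#' model equals the partial \eqn{R^2} of the SNP, in percent.
#'
#' @param y Named numeric trait vector (names = genotype ids) or unnamed
#'   vector aligned with the rows of `G`.
#' @param G `genotype_matrix` or dosage matrix.
#' @param K Kinship matrix from [kinship()]; computed from `G` when `NULL`.
#'   `K = diag(n)` reduces the scan to ordinary least squares.
#' @param covariates Optional numeric matrix of fixed covariates (no
#'   intercept column; one is added).
#' @param maf Minor-allele-frequency filter applied before testing
#'   (default 0.05).
#' @param refit If `TRUE`, re-estimate the variance ratio per SNP (exact
#'   mixed-model refit) instead of the one-time null estimate. Slow;
#'   intended for small data or verification.
#' @return A data frame of class `"association_scan"` with columns `snp_id`,
#'   `chrom`, `pos`, `maf`, `beta`, `se`, `stat`, `p`, `neglog10p`, `pve`;
#'   attributes `varcomp` (null-model variance components) and `n`.
#' @examples
#' study <- simulate_study(sim_config(n_genotypes = 40, n_snps = 60,
#'                                    n_causal = 1, rng_seed = 11))
#' rel <- relative_indices(germination_traits(study$trials))
#' y <- with(rel[rel$environment == "E1", ], setNames(RGR, genotype_id))
#' scan <- mlm_scan(y, study$genotypes)
#' @export
mlm_scan <- function(y, G, K = NULL, covariates = NULL, maf = 0.05,
                     refit = FALSE) {
  M <- dosage_matrix(G)
  map <- if (inherits(G, "genotype_matrix")) G$map else
    data.frame(snp_id = colnames(M) %||% paste0("snp", seq_len(ncol(M))),
               chrom = NA_integer_, pos = NA_integer_)
  if (!is.null(names(y))) {
    if (!all(names(y) %in% rownames(M)))
      stop("trait genotype ids missing from the genotype matrix: ",
           paste(utils::head(setdiff(names(y), rownames(M))), collapse = ", "))
    M <- M[names(y), , drop = FALSE]
    if (!is.null(K) && !is.null(dimnames(K)))
      K <- K[names(y), names(y)]
  } else if (length(y) != nrow(M)) {
    stop("length(y) does not match the number of genotypes")
  }
  ok <- !is.na(y)
  y <- y[ok]; M <- M[ok, , drop = FALSE]
  n <- length(y)
  if (is.null(K)) K <- kinship(M, maf = maf) else K <- K[ok, ok, drop = FALSE]

  p_alt <- colMeans(M) / 2
  keep <- pmin(p_alt, 1 - p_alt) >= maf & p_alt > 0 & p_alt < 1
  if (!any(keep)) stop("no SNPs pass the MAF filter")
  M <- M[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  snp_maf <- pmin(p_alt, 1 - p_alt)[keep]

  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X0)$rank < ncol(X0)) stop("singular covariate design")
  null_fit <- reml_delta(y, X0, K)
  delta <- null_fit$delta

  ek <- eigen(K, symmetric = TRUE)
  d <- pmax(ek$values, 0)
  w <- 1 / sqrt(d + delta)
  Ut <- t(ek$vectors)
  yt <- w * drop(Ut %*% y)
  X0t <- w * (Ut %*% X0)
  St <- w * (Ut %*% M)

  # residualize against the whitened covariates, then marginal regressions
  B0 <- solve(crossprod(X0t), t(X0t))
  ey <- yt - X0t %*% (B0 %*% yt)
  Es <- St - X0t %*% (B0 %*% St)
  ss <- colSums(Es^2)
  degenerate <- ss < 1e-12
  ss[degenerate] <- NA_real_
  beta <- colSums(Es * drop(ey)) / ss
  rss0 <- sum(ey^2)
  rss1 <- pmax(rss0 - beta^2 * ss, 0)
  df <- n - ncol(X0) - 1
  se <- sqrt(rss1 / df / ss)
  stat <- beta / se
  pval <- 2 * stats::pt(-abs(stat), df)
  pve <- (rss0 - rss1) / rss0 * 100

  if (refit) {
    for (j in which(!degenerate)) {
      Xj <- cbind(X0, M[, j])
      fitj <- reml_delta(y, Xj, K)
      dj <- fitj$delta
      wj <- 1 / sqrt(d + dj)
      ytj <- wj * drop(Ut %*% y)
      Xtj <- wj * (Ut %*% Xj)
      cf <- stats::lm.fit(Xtj, ytj)
      sm <- sum(cf$residuals^2) / cf$df.residual
      Vb <- sm * chol2inv(qr.R(cf$qr))
      beta[j] <- cf$coefficients[ncol(Xj)]
      se[j] <- sqrt(Vb[ncol(Xj), ncol(Xj)])
      stat[j] <- beta[j] / se[j]
      pval[j] <- 2 * stats::pt(-abs(stat[j]), cf$df.residual)
    }
  }

  out <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                    maf = snp_maf, beta = beta, se = se, stat = stat,
                    p = pval, neglog10p = -log10(pval), pve = pve,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "varcomp") <- null_fit
  attr(out, "n") <- n
  class(out) <- c("association_scan", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Significant SNPs at a fixed -log10(p) threshold
#'
#' Subsets a scan to SNPs whose \eqn{-\log_{10}(p)} reaches the threshold
#' (inclusive: a SNP exactly at the threshold is kept), sorted by chromosome
#' and position.
#'
#' @param scan An [mlm_scan()] result.
#' @param threshold Significance threshold on the \eqn{-\log_{10}(p)} scale
#'   (default 5).
#' @return The qualifying rows of the scan, with attribute `threshold`.
#' @export
significant_snps <- function(scan, threshold = 5) {
  hit <- !is.na(scan$neglog10p) & scan$neglog10p >= threshold
  out <- scan[hit, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' Compare trait means between the allele groups of one SNP
#'
#' Splits genotypes into homozygous allele classes at a SNP (heterozygotes
#' excluded, matching the convention of contrasting the two homozygote
#' haplotype groups) and compares their trait means by one-way ANOVA.
#' Significance is annotated `**` for p < 0.01 and `***` for p < 0.001.
#'
#' @param snp_id SNP identifier present in `G`.
#' @param y Named trait vector (names = genotype ids).
#' @param G `genotype_matrix` (allele symbols taken from its map) or dosage
#'   matrix (groups labelled `ref`/`alt`).
#' @param include_het If `TRUE`, heterozygotes form a third group.
#' @return A list of class `"haplotype_effect"`: `snp_id`, `groups` (data
#'   frame: allele, n, mean, sd), `F`, `p`, `stars`.
#' @export
haplotype_compare <- function(snp_id, y, G, include_het = FALSE) {
  M <- dosage_matrix(G)
  if (!snp_id %in% colnames(M)) stop("SNP not found: ", snp_id)
  dos <- M[, snp_id]
  if (!is.null(names(y))) dos <- dos[names(y)]
  if (inherits(G, "genotype_matrix")) {
    row <- G$map[G$map$snp_id == snp_id, ]
    al <- c(row$ref, paste0(row$ref, "/", row$alt), row$alt)
  } else al <- c("ref", "het", "alt")
  grp <- factor(al[dos + 1], levels = al)
  if (!include_het) {
    keep <- dos != 1 & !is.na(y)
  } else keep <- !is.na(y)
  grp <- droplevels(grp[keep]); yy <- y[keep]
  sizes <- table(grp)
  if (nlevels(grp) < 2 || any(sizes < 2))
    stop("need at least 2 allele groups with >= 2 members each")
  fit <- stats::aov(yy ~ grp)
  tab <- summary(fit)[[1]]
  Fval <- tab[1, "F value"]; pval <- tab[1, "Pr(>F)"]
  stars <- if (pval < 0.001) "***" else if (pval < 0.01) "**" else ""
  groups <- data.frame(allele = levels(grp),
                       n = as.integer(sizes),
                       mean = tapply(yy, grp, mean),
                       sd = tapply(yy, grp, stats::sd),
                       row.names = NULL)
  structure(list(snp_id = snp_id, groups = groups, F = Fval, p = pval,
                 stars = stars), class = "haplotype_effect")
}

#' @export
print.haplotype_effect <- function(x, ...) {
  cat(sprintf("Allele-group comparison at %s: F = %0.3f, p = %0.3g %s\n",
              x$snp_id, x$F, x$p, x$stars))
  print(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Manhattan plot of an association scan
#'
#' Base-graphics Manhattan plot with the fixed significance threshold drawn
#' as a horizontal line. Cosmetic output; writes a PNG when `file` is given.
#'
#' @param scan An [mlm_scan()] result with `chrom`/`pos` filled in.
#' @param threshold Threshold line on the \eqn{-\log_{10}(p)} scale.
#' @param file Optional PNG path.
#' @param main Plot title.
#' @return Invisibly, the plotted data frame with cumulative coordinates.
#' @export
manhattan_plot <- function(scan, threshold = 5, file = NULL,
                           main = "Association scan") {
  d <- scan[order(scan$chrom, scan$pos), ]
  offs <- c(0, cumsum(tapply(d$pos, d$chrom, max)))
  d$x <- d$pos + offs[match(d$chrom, sort(unique(d$chrom)))]
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
  }
  cols <- c("grey30", "steelblue")[(as.integer(factor(d$chrom)) %% 2) + 1]
  graphics::plot(d$x, d$neglog10p, pch = 20, col = cols, xaxt = "n",
                 xlab = "Chromosome", ylab = expression(-log[10](italic(p))),
                 main = main,
                 ylim = c(0, max(d$neglog10p, threshold + 1, na.rm = TRUE)))
  graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(d)
}
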