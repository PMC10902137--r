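test_that("kinship is symmetric, centred and flags identical genotypes", {
  set.seed(141)
  M <- random_dosages(30, 200)
  M[2, ] <- M[1, ]  # identical pair
  K <- kinship(M)
  expect_true(isSymmetric(K))
  expect_equal(K[1, 2], K[1, 1])
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))  # positive semidefinite
  expect_gt(mean(diag(K)), mean(K[upper.tri(K)]))
  expect_error(kinship(matrix(2, 5, 4)), "polymorphic")
})

test_that("off-diagonal kinship of unrelated genotypes concentrates at zero", {
  set.seed(151)
  K <- kinship(random_dosages(1000, 500))
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.005)
  expect_lt(abs(mean(diag(K)) - 1), 0.1)  # VanRaden diagonal averages ~1
})

test_that("with identity kinship the scan reduces to ordinary least squares", {
  set.seed(161)
  n <- 80
  M <- random_dosages(n, 25)
  y <- setNames(rnorm(n) + 0.4 * M[, 3], rownames(M))
  scan <- mlm_scan(y, M, K = diag(n), maf = 0)
  for (j in seq_len(ncol(M))) {
    ols <- summary(lm(y ~ M[, j]))$coefficients
    row <- scan[scan$snp_id == colnames(M)[j], ]
    expect_equal(row$p, ols[2, 4], tolerance = 1e-8)
    expect_equal(row$beta, ols[2, 1], tolerance = 1e-8)
  }
})

test_that("the spectral scan matches a direct GLS refit per SNP", {
  set.seed(171)
  n <- 30
  M <- random_dosages(n, 20)
  K <- kinship(M)
  u <- drop(t(chol(K + 1e-6 * diag(n))) %*% rnorm(n))
  y <- setNames(u + rnorm(n), rownames(M))
  scan <- mlm_scan(y, M, K = K, maf = 0)
  delta <- attr(scan, "varcomp")$delta
  for (j in seq_len(ncol(M))) {
    X <- cbind(1, M[, j])
    oracle <- direct_gls(unname(y), X, K, delta)
    row <- scan[scan$snp_id == colnames(M)[j], ]
    expect_equal(row$beta, oracle$beta[2], tolerance = 1e-6)
    expect_equal(row$p, oracle$p[2], tolerance = 1e-6)
  }
})

test_that("per-SNP mixed-model refit agrees with the one-pass scan on null data", {
  set.seed(181)
  n <- 40
  M <- random_dosages(n, 10)
  K <- kinship(M)
  y <- setNames(rnorm(n), rownames(M))
  fast <- mlm_scan(y, M, K = K, maf = 0)
  slow <- mlm_scan(y, M, K = K, maf = 0, refit = TRUE)
  expect_equal(slow$p, fast$p, tolerance = 0.05)
  expect_equal(slow$beta, fast$beta, tolerance = 0.05)
})

test_that("null p-values are uniform and type-I error is nominal", {
  set.seed(191)
  n <- 264
  M <- random_dosages(n, 12000)
  K <- kinship(M)
  V <- 0.5 * K + diag(n)
  y <- setNames(drop(t(chol(V)) %*% rnorm(n)), rownames(M))
  scan <- mlm_scan(y, M, K = K, maf = 0.05)
  m <- nrow(scan)
  expect_gte(m, 10000)
  alpha_hat <- mean(scan$p < 0.05)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / m)
  expect_gt(alpha_hat, ci[1])
  expect_lt(alpha_hat, ci[2])
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("significant-SNP filtering is inclusive, sorted and idempotent", {
  scan <- data.frame(snp_id = c("S01_5", "S02_1", "S01_2"),
                     chrom = c(1L, 2L, 1L), pos = c(5L, 1L, 2L),
                     maf = 0.2, beta = 1, se = 1, stat = 1,
                     p = c(1e-6, 1e-4, 1e-5))
  scan$neglog10p <- -log10(scan$p)
  hits <- significant_snps(scan, 5)
  expect_equal(hits$snp_id, c("S01_2", "S01_5"))  # 1e-5 kept: >= is inclusive
  expect_false("S02_1" %in% hits$snp_id)
  expect_equal(significant_snps(hits, 5)$snp_id, hits$snp_id)
  expect_equal(significant_snps(scan[sample(3), ], 5)$snp_id, hits$snp_id)
})

test_that("PVE is near truth for a planted SNP and monotone in effect size", {
  set.seed(201)
  pves <- replicate(10, {
    n <- 264
    M <- random_dosages(n, 50, maf_lo = 0.3, maf_hi = 0.5)
    s <- M[, 1]
    b <- sqrt(0.1 / 0.9 / var(s))  # SNP explains 10% of trait variance
    y <- setNames(s * b + rnorm(n), rownames(M))
    scan <- mlm_scan(y, M, K = diag(n), maf = 0)
    scan$pve[scan$snp_id == colnames(M)[1]]
  })
  expect_lt(abs(mean(pves) - 10), 4)

  # PVE grows with |beta| at fixed MAF and n
  n <- 200
  M <- random_dosages(n, 5, maf_lo = 0.4, maf_hi = 0.4)
  s <- M[, 1]
  pve_at <- sapply(c(0.1, 0.3, 0.6, 1), function(b) {
    y <- setNames(s * b + rnorm(n), rownames(M))
    scan <- mlm_scan(y, M, K = diag(n), maf = 0)
    scan$pve[scan$snp_id == colnames(M)[1]]
  })
  expect_true(all(diff(pve_at) > 0))
  # a null SNP explains essentially nothing
  y0 <- setNames(rnorm(n), rownames(M))
  scan0 <- mlm_scan(y0, M, K = diag(n), maf = 0)
  expect_lt(max(scan0$pve), 5)
})

test_that("a large-effect planted SNP crosses the threshold in most replicates", {
  set.seed(211)
  hits <- replicate(20, {
    n <- 264
    M <- random_dosages(n, 300, maf_lo = 0.2, maf_hi = 0.5)
    K <- kinship(M)
    s <- M[, 7]
    b <- sqrt(0.18 / 0.82 / var(s))  # ~18% of phenotypic variance
    u <- drop(t(chol(0.3 * K + 1e-6 * diag(n))) %*% rnorm(n))
    y <- setNames(s * b + u + rnorm(n, 0, sqrt(0.7)), rownames(M))
    scan <- mlm_scan(y, M, K = K, maf = 0.05)
    scan$neglog10p[scan$snp_id == colnames(M)[7]] >= 5
  })
  expect_gte(mean(hits), 0.8)
})

test_that("allele-group comparison matches one-way ANOVA and labels stars", {
  set.seed(221)
  g <- simulate_genotypes(sim_config(n_genotypes = 200, n_snps = 10,
                                     maf_range = c(0.4, 0.5), rng_seed = 9))
  snp <- g$map$snp_id[1]
  dos <- g$dosage[, snp]
  y <- setNames(ifelse(dos == 2, 1, 0) + rnorm(200, 0, 0.1), rownames(g$dosage))
  he <- haplotype_compare(snp, y, g)
  expect_lt(he$p, 0.001)
  expect_equal(he$stars, "***")
  expect_equal(sum(he$groups$n), sum(dos != 1))
  expect_setequal(he$groups$allele, c(g$map$ref[1], g$map$alt[1]))

  # identical group means give F ~ 0 and no stars
  y2 <- setNames(rep(c(0.5, 0.5), 100) + 0, names(y))
  y2[] <- 0.5 + rnorm(200, 0, 1e-8)
  he2 <- haplotype_compare(snp, y2, g)
  expect_equal(he2$stars, "")

  # permuting genotype labels within groups leaves p unchanged
  he3 <- haplotype_compare(snp, y, g)
  expect_equal(he3$p, he$p)
  expect_error(haplotype_compare("nope", y, g), "not found")
})

test_that("trait ids absent from the genotype matrix are a hard error", {
  M <- random_dosages(10, 5)
  y <- setNames(rnorm(3), c("G0001", "G0002", "nope"))
  expect_error(mlm_scan(y, M), "missing from the genotype matrix")
})
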