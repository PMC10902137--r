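test_that("descriptive summary matches hand computations", {
  d <- describe(c(0, 1))
  expect_equal(d$mean, 0.5)
  expect_equal(d$sd, sqrt(0.5), tolerance = 1e-12)
  expect_equal(round(d$sd, 4), 0.7071)
  expect_equal(round(d$cv, 2), 141.42)
  expect_equal(d$range, 1)

  const <- describe(rep(4, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$range, 0)

  sym <- describe(c(1, 2, 3, 4, 5))
  expect_equal(sym$skewness, 0)

  expect_true(is.na(describe(c(-1, 1))$cv))  # zero mean
  expect_error(describe(3), "at least 2")
})

test_that("bias-adjusted skewness and kurtosis match the spreadsheet formulas", {
  set.seed(81)
  x <- rnorm(40)
  n <- length(x); m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5; g2 <- m4 / m2^2 - 3
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  d <- describe(x)
  expect_equal(d$skewness, G1, tolerance = 1e-12)
  expect_equal(d$kurtosis, G2, tolerance = 1e-12)
})

test_that("balanced two-way ANOVA matches the brute-force SS oracle", {
  set.seed(91)
  layouts <- list(c(2, 2, 2), c(3, 2, 3), c(3, 2, 2))
  for (L in layouts) {
    d <- simulate_balanced_layout(L[1], L[2], L[3], 1, 0.5, 1)
    dec <- anova_two_way(d, "y")
    oracle <- brute_force_ss(d$y, d$genotype_id, d$environment)
    tab <- dec$table
    expect_equal(tab$SS[tab$source == "G"], oracle$G, tolerance = 1e-10)
    expect_equal(tab$SS[tab$source == "Env"], oracle$Env, tolerance = 1e-10)
    expect_equal(tab$SS[tab$source == "GxEnv"], oracle$GxEnv, tolerance = 1e-10)
    expect_equal(tab$SS[tab$source == "Residual"], oracle$Residual, tolerance = 1e-10)
    expect_equal(sum(tab$SS), oracle$total, tolerance = 1e-10)
    # standard balanced DF
    expect_equal(tab$DF, c(L[1] - 1, L[2] - 1, (L[1] - 1) * (L[2] - 1),
                           L[1] * L[2] * (L[3] - 1)))
  }
})

test_that("degenerate and unbalanced layouts are caught", {
  d <- simulate_balanced_layout(3, 2, 2, 1, 0, 1)
  d$y <- 5
  dec <- anova_two_way(d, "y")
  expect_equal(sum(dec$table$SS), 0)
  expect_error(anova_two_way(d[-1, ], "y"), "unbalanced")
  d1 <- d[d$environment == "E1", ]
  expect_error(anova_two_way(d1, "y"), "2 genotypes and 2 environments")
})

test_that("a pure environment shift loads only the Env stratum", {
  d <- simulate_balanced_layout(4, 2, 3, 0, 0, 0)
  d$y <- ifelse(d$environment == "E1", 0, 2)
  tab <- anova_two_way(d, "y")$table
  expect_equal(tab$SS[tab$source == "G"], 0, tolerance = 1e-12)
  expect_equal(tab$SS[tab$source == "GxEnv"], 0, tolerance = 1e-12)
  expect_gt(tab$SS[tab$source == "Env"], 0)
})

test_that("variance components invert the expected mean squares and clip", {
  # equal mean squares give zero genotype and interaction components
  dec <- structure(list(table = data.frame(
    source = c("G", "Env", "GxEnv", "Residual"),
    DF = c(9, 1, 9, 40), SS = c(20, 2, 20, 80) / 2,
    MS = c(1, 2, 1, 1), F = NA, P = NA), n_env = 2, n_rep = 3,
    response = "y"), class = "variance_decomposition")
  comp <- variance_components(dec)
  expect_equal(unname(comp), c(0, 0, 1), ignore_attr = TRUE)
  # interaction mean square below residual clips with a warning
  dec$table$MS <- c(4, 2, 0.5, 1)
  expect_warning(comp2 <- variance_components(dec), "clipped")
  expect_equal(comp2[["sigma2_ge"]], 0)
  expect_equal(comp2[["sigma2_g"]], (4 - 0.5) / 6)
})

test_that("variance components are recovered from simulated balanced data", {
  set.seed(111)
  truth <- c(1, 0.25, 1)
  est <- matrix(0, 50, 3)
  for (i in 1:50) {
    d <- simulate_balanced_layout(264, 2, 3, truth[1], truth[2], truth[3])
    est[i, ] <- suppressWarnings(variance_components(anova_two_way(d, "y")))
  }
  avg <- colMeans(est)
  expect_true(all(abs(avg - truth) / truth < 0.15))
})

test_that("the heritability formula reproduces worked values and is monotone", {
  expect_equal(heritability(1, 0, 0, n_env = 2, n_rep = 3), 1)
  expect_equal(heritability(1, 1, 1, n_env = 2, n_rep = 3), 0.6)
  expect_equal(heritability(0, 1, 1, n_env = 2, n_rep = 3), 0)
  expect_true(is.na(heritability(0, 0, 0, n_env = 2, n_rep = 3)))
  expect_error(heritability(-1, 0, 0, n_env = 2, n_rep = 3), "non-negative")
  # monotone increasing in genetic variance, decreasing in the noise terms
  h <- sapply(seq(0, 3, by = 0.5), function(s) heritability(s, 1, 1, 2, 3))
  expect_true(all(diff(h) > 0))
  h2 <- sapply(seq(0, 3, by = 0.5), function(s) heritability(1, s, 1, 2, 3))
  expect_true(all(diff(h2) < 0))
  # accepts a variance_components vector directly
  comp <- structure(c(sigma2_g = 1, sigma2_ge = 1, sigma2_e = 1),
                    n_env = 2, n_rep = 3)
  expect_equal(heritability(comp), 0.6)
})

test_that("heritability at the study design is unbiased within Monte-Carlo error", {
  set.seed(121)
  truth <- heritability(1, 0.5, 4, n_env = 2, n_rep = 3)
  h <- replicate(30, {
    d <- simulate_balanced_layout(264, 2, 3, 1, 0.5, 4)
    heritability(suppressWarnings(variance_components(anova_two_way(d, "y"))))
  })
  expect_lt(abs(mean(h) - truth), 0.03)
})

test_that("correlations recover identity, sign flips and a known effect", {
  d <- data.frame(x = rnorm(20))
  d$y <- -d$x
  d$z <- d$x
  ct <- correlate_traits(d, c("x", "y", "z"))
  expect_equal(ct$r["x", "z"], 1)
  expect_equal(ct$r["x", "y"], -1)
  expect_true(isSymmetric(ct$r))

  set.seed(131)
  est <- replicate(20, {
    a <- rnorm(264)
    b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(264)
    correlate_traits(data.frame(a = a, b = b), c("a", "b"))$r["a", "b"]
  })
  expect_lt(abs(mean(est) - 0.9), 0.05)
  expect_error(correlate_traits(data.frame(a = 1:5, b = rep(NA_real_, 5)),
                                c("a", "b")), "complete pairs")
})
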