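#' Descriptive statistics for a trait
#'
#' Max, min, range, mean, sample SD, coefficient of variation (percent),
#' skewness and excess kurtosis for one vector of trait values. Skewness and
#' kurtosis use the bias-adjusted sample formulas
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)} and
#' \eqn{G_2 = ((n+1) g_2 + 6)(n-1)/((n-2)(n-3))}
#' (the SPSS/Excel convention), so values are comparable to spreadsheet
#' output. The CV is undefined for a zero mean and reported as `NA`.
#'
#' @param x Numeric vector, at least 2 non-missing values.
#' @return A one-row data frame: `n`, `max`, `min`, `range`, `mean`, `sd`,
#'   `cv`, `skewness`, `kurtosis`.
#' @examples
#' describe(c(0, 1))
#' @export
describe <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  m <- mean(x)
  s <- stats::sd(x)
  m2 <- mean((x - m)^2)
  g1 <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  skew <- if (n > 2) g1 * sqrt(n * (n - 1)) / (n - 2) else NA_real_
  g2 <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  kurt <- if (n > 3) ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)) else NA_real_
  data.frame(n = n, max = max(x), min = min(x), range = max(x) - min(x),
             mean = m, sd = s,
             cv = if (m == 0) NA_real_ else s / m * 100,
             skewness = skew, kurtosis = kurt)
}

#' Descriptive summary per trait, environment and treatment
#'
#' Applies [describe()] within each trait x environment (x treatment when
#' present) cell of a long or wide trait table.
#'
#' @param data Data frame with an `environment` column, optionally a
#'   `treatment` column, and the trait columns named in `traits`.
#' @param traits Character vector of trait column names.
#' @return A data frame with one row per cell, the grouping keys and the
#'   [describe()] columns.
#' @export
describe_traits <- function(data, traits) {
  keys <- intersect(c("environment", "treatment"), names(data))
  split_keys <- if (length(keys)) data[, keys, drop = FALSE]
                else data.frame(row.names = seq_len(nrow(data)))
  groups <- if (length(keys)) split(data, split_keys, drop = TRUE) else list(all = data)
  rows <- list()
  for (tr in traits) {
    for (g in names(groups)) {
      d <- describe(groups[[g]][[tr]])
      meta <- groups[[g]][1, keys, drop = FALSE]
      rows[[length(rows) + 1L]] <- cbind(data.frame(trait = tr), meta, d,
                                         row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Balanced two-way ANOVA with replication
#'
#' Fits `value ~ genotype * environment` on a balanced layout (equal
#' replicates in every cell) and extracts the standard two-way table:
#' sums of squares, mean squares, F against the residual mean square and
#' p-values for genotype, environment and their interaction.
#'
#' @param data Data frame with columns `genotype_id`, `environment` and the
#'   response named by `response`; one row per replicate observation.
#' @param response Name of the response column.
#' @return A list of class `"variance_decomposition"`: `table` (data frame
#'   with rows G, Env, GxEnv, Residual and columns `DF`, `SS`, `MS`, `F`,
#'   `P`), `n_env`, `n_rep`, `response`.
#' @examples
#' d <- expand.grid(genotype_id = c("a", "b"), environment = c("E1", "E2"),
#'                  rep = 1:2)
#' d$y <- rnorm(nrow(d))
#' anova_two_way(d, "y")
#' @export
anova_two_way <- function(data, response) {
  stopifnot(all(c("genotype_id", "environment", response) %in% names(data)))
  d <- data[!is.na(data[[response]]), ]
  g <- factor(d$genotype_id)
  e <- factor(d$environment)
  if (nlevels(g) < 2 || nlevels(e) < 2)
    stop("need at least 2 genotypes and 2 environments")
  cell_n <- table(g, e)
  if (length(unique(c(cell_n))) != 1 || any(cell_n == 0))
    stop("unbalanced design: every genotype x environment cell needs the ",
         "same number of replicates")
  r <- unname(cell_n[1, 1])
  fit <- stats::aov(d[[response]] ~ g * e)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  pick <- function(term, col) tab[match(term, rn), col]
  out <- data.frame(
    source = c("G", "Env", "GxEnv", "Residual"),
    DF = c(pick("g", "Df"), pick("e", "Df"), pick("g:e", "Df"), pick("Residuals", "Df")),
    SS = c(pick("g", "Sum Sq"), pick("e", "Sum Sq"), pick("g:e", "Sum Sq"),
           pick("Residuals", "Sum Sq")),
    MS = c(pick("g", "Mean Sq"), pick("e", "Mean Sq"), pick("g:e", "Mean Sq"),
           pick("Residuals", "Mean Sq")),
    F = c(pick("g", "F value"), pick("e", "F value"), pick("g:e", "F value"), NA),
    P = c(pick("g", "Pr(>F)"), pick("e", "Pr(>F)"), pick("g:e", "Pr(>F)"), NA)
  )
  structure(list(table = out, n_env = nlevels(e), n_rep = r, response = response),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Two-way ANOVA of %s (%d environments, r = %d)\n",
              x$response, x$n_env, x$n_rep))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Variance components from expected mean squares
#'
#' Method-of-moments estimates on the balanced genotype x environment layout
#' with r replicates: \eqn{\sigma^2 = MS_{res}},
#' \eqn{\sigma^2_{ge} = (MS_{G\times E} - MS_{res})/r},
#' \eqn{\sigma^2_g = (MS_G - MS_{G\times E})/(nr)}. Negative estimates are
#' clipped to zero with a warning.
#'
#' @param decomp A [anova_two_way()] result.
#' @return Named numeric vector `c(sigma2_g, sigma2_ge, sigma2_e)` with
#'   attributes `n_env` and `n_rep`.
#' @export
variance_components <- function(decomp) {
  stopifnot(inherits(decomp, "variance_decomposition"))
  tab <- decomp$table
  ms <- stats::setNames(tab$MS, tab$source)
  n <- decomp$n_env; r <- decomp$n_rep
  s2e <- ms[["Residual"]]
  s2ge <- (ms[["GxEnv"]] - s2e) / r
  s2g <- (ms[["G"]] - ms[["GxEnv"]]) / (n * r)
  clipped <- c(sigma2_g = s2g, sigma2_ge = s2ge, sigma2_e = s2e)
  if (any(clipped < 0)) {
    warning("negative variance component estimate(s) clipped to 0: ",
            paste(names(clipped)[clipped < 0], collapse = ", "))
    clipped <- pmax(clipped, 0)
  }
  attr(clipped, "n_env") <- n
  attr(clipped, "n_rep") <- r
  clipped
}

#' Broad-sense heritability across environments
#'
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ge}/n + \sigma^2/(nr))}
#' for `n` environments and `r` replicates: the fraction of the
#' genotype-mean variance that is genetic.
#'
#' @param sigma2_g,sigma2_ge,sigma2_e Non-negative variance components
#'   (genotype, genotype-by-environment, residual). Alternatively pass a
#'   [variance_components()] vector as the first argument and omit the rest.
#' @param n_env,n_rep Numbers of environments and replicates.
#' @return Heritability in \[0, 1\]; `NA` when all components are zero.
#' @examples
#' heritability(1, 1, 1, n_env = 2, n_rep = 3)  # 0.6
#' @export
heritability <- function(sigma2_g, sigma2_ge = NULL, sigma2_e = NULL,
                         n_env = NULL, n_rep = NULL) {
  if (length(sigma2_g) == 3 && is.null(sigma2_ge)) {
    comp <- sigma2_g
    if (is.null(n_env)) n_env <- attr(comp, "n_env")
    if (is.null(n_rep)) n_rep <- attr(comp, "n_rep")
    sigma2_g <- comp[["sigma2_g"]]
    sigma2_ge <- comp[["sigma2_ge"]]
    sigma2_e <- comp[["sigma2_e"]]
  }
  stopifnot(n_env >= 1, n_rep >= 1)
  if (any(c(sigma2_g, sigma2_ge, sigma2_e) < 0))
    stop("variance components must be non-negative")
  denom <- sigma2_g + sigma2_ge / n_env + sigma2_e / (n_env * n_rep)
  if (denom == 0) return(NA_real_)
  sigma2_g / denom
}

#' Pairwise Pearson correlations with p-values
#'
#' Pearson correlation for every pair of the named columns, with two-sided
#' p-values from [stats::cor.test()]. Pairs are formed on complete
#' observations per pair.
#'
#' @param data Data frame containing the trait columns.
#' @param traits Character vector of column names (>= 2).
#' @return A list with matrices `r` and `p` (traits x traits).
#' @export
correlate_traits <- function(data, traits) {
  stopifnot(length(traits) >= 2, all(traits %in% names(data)))
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- data[[traits[i]]]; y <- data[[traits[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) stop("need at least 3 complete pairs for ", traits[i],
                            " vs ", traits[j])
      ct <- stats::cor.test(x[ok], y[ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Heritability of each relative index from a trial table
#'
#' Convenience wrapper: two-way ANOVA per trait on the genotype x
#' environment relative indices (one observation per replicate is not
#' available for relative indices, so replicate-level relative values are
#' formed per replicate pairing drought replicate r against the control
#' replicate mean), variance components and heritability.
#'
#' @param traits Per-unit trait table from [germination_traits()].
#' @param trait_names Traits to analyse (per-replicate relative values of
#'   GR, GE, GI).
#' @return Data frame: `trait`, `sigma2_g`, `sigma2_ge`, `sigma2_e`, `h2`.
#' @export
heritability_table <- function(traits, trait_names = c("RGR", "RGE", "RGI")) {
  rel <- replicate_relative_values(traits)
  out <- lapply(trait_names, function(tr) {
    dec <- anova_two_way(rel, tr)
    comp <- suppressWarnings(variance_components(dec))
    data.frame(trait = tr,
               sigma2_g = comp[["sigma2_g"]], sigma2_ge = comp[["sigma2_ge"]],
               sigma2_e = comp[["sigma2_e"]],
               h2 = heritability(comp), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Per-replicate relative values: drought replicate value over the control
# replicate mean of the same genotype x environment. Keeps the replicate
# dimension the ANOVA needs while using the stable control mean as the
# denominator.
replicate_relative_values <- function(traits) {
  ctrl <- stats::aggregate(traits[traits$treatment == "control", c("GR", "GE", "GI")],
                           by = traits[traits$treatment == "control",
                                       c("genotype_id", "environment")],
                           FUN = mean)
  names(ctrl)[3:5] <- c("RC", "EC", "IC")
  drt <- traits[traits$treatment == "drought", ]
  m <- merge(drt, ctrl, by = c("genotype_id", "environment"))
  safe <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  m$RGR <- safe(m$GR, m$RC)
  m$RGE <- safe(m$GE, m$EC)
  m$RGI <- safe(m$GI, m$IC)
  m[, c("genotype_id", "environment", "replicate", "RGR", "RGE", "RGI")]
}
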