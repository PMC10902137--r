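#' Simulation configuration for a germination drought trial
#'
#' Builds and validates the configuration object consumed by
#' [simulate_trials()] and [simulate_genotypes()]. The defaults emulate a
#' germination-stage drought screen of a soybean diversity panel: 264
#' accessions grown in 2 environments (years) under a water control and a
#' 15\% PEG-6000 osmotic-stress treatment, 3 replicates of 50 seeds each,
#' counted daily for 7 days with germination energy read on day 4.
#'
#' Each genotype carries a latent drought-response liability
#' \eqn{L_{ge} = g_g + (g\times e)_{ge} + \sum_k (x_{gk} - 2p_k)\beta_k}
#' with genotype effects \eqn{g_g \sim N(0, \sigma^2_g)}, interaction effects
#' \eqn{N(0, \sigma^2_{ge})} and centred additive contributions from planted
#' causal SNPs. Under drought the liability shifts the per-seed germination
#' probability through a logistic link and advances the germination-day
#' distribution; control units germinate at `control_germ_prob` regardless of
#' liability. A replicate-level residual with variance `var_residual` enters
#' the drought linear predictor.
#'
#' @param n_genotypes,n_environments,n_replicates Panel and design sizes.
#' @param seeds_per_replicate Seeds sown per replicate unit.
#' @param n_days Days of daily counting; germination past `n_days` is not
#'   observed.
#' @param energy_day Day on which germination energy is read (must not exceed
#'   `n_days`).
#' @param var_genotype,var_gxe,var_residual Variance components of the latent
#'   liability (genotype, genotype-by-environment, replicate residual).
#' @param control_germ_prob Per-seed germination probability under control,
#'   in (0, 1].
#' @param drought_germ_prob Baseline per-seed germination probability under
#'   drought for a genotype at liability zero.
#' @param n_snps Number of simulated biallelic SNPs.
#' @param maf_range Length-2 numeric, the uniform range minor allele
#'   frequencies are drawn from; each entry in (0, 0.5].
#' @param n_causal Number of SNPs with planted effects on the liability.
#' @param causal_effect_sizes Effect per alternate-allele copy for the causal
#'   SNPs, recycled to length `n_causal`.
#' @param rng_seed Integer seed; identical configurations reproduce
#'   identical data bit-for-bit.
#' @param strict If `TRUE`, a drought germination probability that would
#'   leave (0, 1) is an error; if `FALSE` (default) it is clamped into
#'   `[1e-6, 1 - 1e-6]` with a warning.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_trials()], [simulate_genotypes()], [simulate_study()]
#' @examples
#' cfg <- sim_config(n_genotypes = 10, n_snps = 50, rng_seed = 1)
#' @export
sim_config <- function(n_genotypes = 264,
                       n_environments = 2,
                       n_replicates = 3,
                       seeds_per_replicate = 50,
                       n_days = 7,
                       energy_day = 4,
                       var_genotype = 1,
                       var_gxe = 0.5,
                       var_residual = 4,
                       control_germ_prob = 0.88,
                       drought_germ_prob = 0.5,
                       n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       n_causal = 0,
                       causal_effect_sizes = numeric(0),
                       rng_seed = 1L,
                       strict = FALSE) {
  counts <- c(n_genotypes = n_genotypes, n_environments = n_environments,
              n_replicates = n_replicates, seeds_per_replicate = seeds_per_replicate,
              n_days = n_days, energy_day = energy_day, n_snps = n_snps)
  if (any(counts < 1) || any(counts != as.integer(counts)))
    stop("all counts must be integers >= 1")
  if (energy_day > n_days) stop("energy_day must not exceed n_days")
  vars <- c(var_genotype, var_gxe, var_residual)
  if (any(vars < 0)) stop("variance components must be >= 0")
  if (!(control_germ_prob > 0 && control_germ_prob <= 1))
    stop("control_germ_prob must lie in (0, 1]")
  if (!(drought_germ_prob > 0 && drought_germ_prob < 1))
    stop("drought_germ_prob must lie in (0, 1)")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an ascending pair in (0, 0.5]")
  if (n_causal < 0 || n_causal > n_snps) stop("n_causal must lie in [0, n_snps]")
  if (n_causal > 0 && length(causal_effect_sizes) == 0)
    causal_effect_sizes <- rep(0.5, n_causal)
  if (is.null(rng_seed) || is.na(rng_seed)) stop("rng_seed is mandatory")
  structure(list(
    n_genotypes = as.integer(n_genotypes),
    n_environments = as.integer(n_environments),
    n_replicates = as.integer(n_replicates),
    seeds_per_replicate = as.integer(seeds_per_replicate),
    n_days = as.integer(n_days),
    energy_day = as.integer(energy_day),
    var_genotype = var_genotype, var_gxe = var_gxe, var_residual = var_residual,
    control_germ_prob = control_germ_prob, drought_germ_prob = drought_germ_prob,
    n_snps = as.integer(n_snps), maf_range = maf_range,
    n_causal = as.integer(n_causal),
    causal_effect_sizes = rep_len(causal_effect_sizes, n_causal),
    rng_seed = as.integer(rng_seed), strict = isTRUE(strict)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Germination-trial simulation config\n")
  cat(sprintf("  %d genotypes x %d environments x 2 treatments x %d replicates\n",
              x$n_genotypes, x$n_environments, x$n_replicates))
  cat(sprintf("  %d seeds/replicate, %d days (energy day %d)\n",
              x$seeds_per_replicate, x$n_days, x$energy_day))
  cat(sprintf("  liability variances: g = %g, gxe = %g, residual = %g\n",
              x$var_genotype, x$var_gxe, x$var_residual))
  cat(sprintf("  %d SNPs (MAF %g-%g), %d causal; seed %d\n",
              x$n_snps, x$maf_range[1], x$maf_range[2], x$n_causal, x$rng_seed))
  invisible(x)
}

genotype_ids <- function(n) sprintf("G%03d", seq_len(n))

#' Simulate a biallelic SNP genotype matrix with planted causal variants
#'
#' Draws per-SNP allele frequencies uniformly from `maf_range`, then dosages
#' (alternate-allele counts in \{0, 1, 2\}) per genotype from Binomial(2, p)
#' under Hardy-Weinberg, independently across SNPs. `n_causal` SNPs are
#' flagged as causal with the configured per-allele effect sizes; their
#' contribution to the drought liability in [simulate_trials()] is the
#' centred dosage times the effect.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"genotype_matrix"` with elements `dosage`
#'   (genotypes x SNPs integer matrix), `map` (data frame: `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `maf`), and `causal` (data frame: `snp_id`,
#'   `effect`; zero rows when no causal variants are planted). SNP ids follow
#'   the `S<chrom>_<pos>` convention with 1-based positions.
#' @examples
#' g <- simulate_genotypes(sim_config(n_genotypes = 20, n_snps = 10, rng_seed = 3))
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, {
    m <- config$n_snps
    n <- config$n_genotypes
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    dosage <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    chrom <- sort(sample.int(20L, m, replace = TRUE))
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sort(sample.int(5e7L, length(idx)))
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
    snp_id <- sprintf("S%02d_%d", chrom, pos)
    causal_idx <- if (config$n_causal > 0) sort(sample.int(m, config$n_causal)) else integer(0)
    causal <- data.frame(snp_id = snp_id[causal_idx],
                         effect = config$causal_effect_sizes,
                         stringsAsFactors = FALSE)
  })
  dimnames(dosage) <- list(genotype_ids(n), snp_id)
  structure(list(
    dosage = dosage,
    map = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                     ref = ref, alt = alt, maf = pmin(p, 1 - p),
                     stringsAsFactors = FALSE),
    causal = causal
  ), class = "genotype_matrix")
}

# Discretized-normal germination-day sampler: each germinating seed draws its
# day from days 1..n_days with normal weights centred at `mu`; stress (low
# liability) pushes mu later. Returns an integer vector of daily counts.
draw_daily_counts <- function(n_germ, n_days, mu, sd = 1.2) {
  counts <- integer(n_days)
  if (n_germ == 0) return(counts)
  w <- stats::dnorm(seq_len(n_days), mean = mu, sd = sd)
  if (sum(w) <= 0) w <- rep(1, n_days)
  days <- sample.int(n_days, n_germ, replace = TRUE, prob = w)
  tab <- tabulate(days, nbins = n_days)
  as.integer(tab)
}

#' Simulate germination trials for a genotype panel
#'
#' Generates one trial (daily germination counts) per genotype x environment
#' x treatment x replicate. A genotype's latent drought liability (genotype
#' effect + genotype-by-environment effect + planted causal-SNP
#' contributions) raises its drought germination probability through a
#' logistic link and advances its germination-day distribution; control
#' units use `control_germ_prob` independent of liability.
#'
#' @param config A [sim_config()] object.
#' @param genotypes Optional [simulate_genotypes()] result supplying causal
#'   SNPs. When `config$n_causal > 0` and `genotypes` is `NULL`, genotypes
#'   are simulated internally from the same seed.
#' @return A data frame of class `"germination_trials"` with columns
#'   `genotype_id`, `environment`, `treatment` (`"control"`/`"drought"`),
#'   `replicate`, `total_seeds` and `day1..dayN`. Attributes `liability`
#'   (genotype x environment matrix of latent liabilities) and `config` are
#'   attached for downstream validation.
#' @examples
#' trials <- simulate_trials(sim_config(n_genotypes = 4, n_snps = 10, rng_seed = 2))
#' head(trials)
#' @export
simulate_trials <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genotypes) && config$n_causal > 0)
    genotypes <- simulate_genotypes(config)
  n <- config$n_genotypes
  ne <- config$n_environments
  nr <- config$n_replicates
  ids <- genotype_ids(n)

  causal_term <- rep(0, n)
  if (!is.null(genotypes) && nrow(genotypes$causal) > 0) {
    dos <- genotypes$dosage[, genotypes$causal$snp_id, drop = FALSE]
    centred <- sweep(dos, 2, colMeans(dos))
    causal_term <- drop(centred %*% genotypes$causal$effect)
  }

  units <- expand.grid(replicate = seq_len(nr),
                       treatment = c("control", "drought"),
                       genotype_id = ids,
                       environment = paste0("E", seq_len(ne)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units <- units[, c("genotype_id", "environment", "treatment", "replicate")]
  nu <- nrow(units)
  daily <- matrix(0L, nu, config$n_days)

  withr::with_seed(config$rng_seed + 1L, {
    g_eff <- stats::rnorm(n, 0, sqrt(config$var_genotype))
    ge_eff <- matrix(stats::rnorm(n * ne, 0, sqrt(config$var_gxe)), n, ne)
    liability <- g_eff + ge_eff + causal_term  # n x ne, recycled by column

    base_logit <- stats::qlogis(config$drought_germ_prob)
    clamped <- FALSE
    gi <- match(units$genotype_id, ids)
    ei <- match(units$environment, paste0("E", seq_len(ne)))
    for (u in seq_len(nu)) {
      if (units$treatment[u] == "control") {
        pg <- config$control_germ_prob
        mu_day <- 2.5
      } else {
        lia <- liability[gi[u], ei[u]]
        eta <- base_logit + lia + stats::rnorm(1, 0, sqrt(config$var_residual))
        pg <- stats::plogis(eta)
        if (pg <= 0 || pg >= 1) {
          if (config$strict) stop("drought germination probability left (0, 1)")
          clamped <- TRUE
          pg <- min(max(pg, 1e-6), 1 - 1e-6)
        }
        # stress delays germination; tolerant (high-liability) lines recover
        mu_day <- max(1, 4.5 - 0.8 * lia)
      }
      n_germ <- stats::rbinom(1L, config$seeds_per_replicate, pg)
      daily[u, ] <- draw_daily_counts(n_germ, config$n_days, mu_day)
    }
    if (clamped)
      warning("some drought germination probabilities were clamped into (0, 1)")
  })

  colnames(daily) <- paste0("day", seq_len(config$n_days))
  out <- cbind(units,
               data.frame(total_seeds = rep(config$seeds_per_replicate, nu)),
               as.data.frame(daily))
  dimnames(liability) <- list(ids, paste0("E", seq_len(ne)))
  attr(out, "liability") <- liability
  attr(out, "genotype_effects") <- stats::setNames(g_eff, ids)
  attr(out, "config") <- config
  class(out) <- c("germination_trials", "data.frame")
  out
}

#' Simulate a complete study: genotypes plus matched germination trials
#'
#' Convenience wrapper that simulates the genotype matrix first and feeds its
#' planted causal variants into the trial simulator, so phenotype and
#' genotype share one configuration and seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genotypes` and `trials`.
#' @examples
#' study <- simulate_study(sim_config(n_genotypes = 12, n_snps = 30,
#'                                    n_causal = 2, rng_seed = 7))
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  list(genotypes = geno, trials = simulate_trials(config, geno))
}
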