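#' Run the full screening pipeline
#'
#' Orchestrates simulate (or load) -> germination indices -> membership
#' scoring and screening -> descriptive statistics, ANOVA and heritability
#' -> kinship and MLM association scan, writing every stage's table under
#' `out_dir` together with a machine-readable run report. Identical
#' configuration and seed reproduce byte-identical tabular outputs.
#'
#' @param config Either a [sim_config()] (the study is simulated) or a list
#'   with elements `trials_path` and one of `vcf_path`/`dosage_path`
#'   (existing data are loaded). May also carry `threshold`, `maf`,
#'   `gwas_trait` overrides.
#' @param out_dir Output directory, created if absent.
#' @param stages Character subset of
#'   `c("simulate", "indices", "score", "stats", "gwas")`; later stages
#'   reuse earlier outputs already on disk when a stage is skipped.
#' @param threshold Significance threshold on the \eqn{-\log_{10}(p)} scale.
#' @param maf Minor-allele-frequency filter for the scan.
#' @param gwas_trait Relative index scanned (default `"RGR"`).
#' @param quiet Suppress progress messages.
#' @return A list of class `"run_report"`: per-stage row counts, file paths,
#'   collected warnings, elapsed seconds, and the configuration echo.
#' @examples
#' \donttest{
#' rep <- run_pipeline(sim_config(n_genotypes = 30, n_snps = 100, rng_seed = 9,
#'                                n_causal = 2), out_dir = tempfile())
#' }
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "indices", "score", "stats", "gwas"),
                         threshold = 5, maf = 0.05, gwas_trait = "RGR",
                         quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- union(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  paths <- list(
    trials = file.path(out_dir, "trials.tsv"),
    dosage = file.path(out_dir, "dosage.tsv"),
    map = file.path(out_dir, "snp_map.tsv"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    traits = file.path(out_dir, "traits.tsv"),
    relative = file.path(out_dir, "relative_indices.tsv"),
    scores = file.path(out_dir, "scores.tsv"),
    screen = file.path(out_dir, "screen.json"),
    descriptives = file.path(out_dir, "descriptives.tsv"),
    anova = file.path(out_dir, "anova.tsv"),
    herit = file.path(out_dir, "heritability.tsv"),
    correlations = file.path(out_dir, "correlations.tsv"),
    scan = file.path(out_dir, "gwas_scan.tsv"),
    hits = file.path(out_dir, "gwas_significant.tsv"),
    manhattan = file.path(out_dir, "manhattan.png"),
    report = file.path(out_dir, "run_report.json")
  )
  counts <- list()
  simulated <- inherits(config, "sim_config")

  # --- simulate or load -----------------------------------------------------
  if (simulated && "simulate" %in% stages) {
    say("simulate: %d genotypes x %d environments", config$n_genotypes,
        config$n_environments)
    study <- collect(simulate_study(config))
    geno <- study$genotypes
    trials <- study$trials
    write_trials(trials, paths$trials)
    write_dosage(geno, paths$dosage, paths$map)
    write_vcf(geno, paths$vcf)
  } else if (simulated) {
    trials <- read_trials(paths$trials)
    geno <- read_dosage(paths$dosage, paths$map)
  } else {
    if (is.null(config$trials_path)) stop("config must name trials_path")
    trials <- read_trials(config$trials_path)
    geno <- if (!is.null(config$vcf_path)) read_vcf(config$vcf_path)
            else if (!is.null(config$dosage_path))
              read_dosage(config$dosage_path, config$map_path)
            else NULL
    if (!is.null(geno)) {
      missing_ids <- setdiff(unique(trials$genotype_id), rownames(geno$dosage))
      if (length(missing_ids) > 0)
        stop("genotype id(s) in phenotypes but absent from genotypes: ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    threshold <- config$threshold %||% threshold
    maf <- config$maf %||% maf
    gwas_trait <- config$gwas_trait %||% gwas_trait
  }
  counts$trials <- nrow(trials)

  # --- indices --------------------------------------------------------------
  traits <- collect(germination_traits(trials))
  rel <- collect(relative_indices(traits))
  if ("indices" %in% stages) {
    say("indices: %d units, %d genotype x environment rows", nrow(traits), nrow(rel))
    utils::write.table(traits, paths$traits, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rel, paths$relative, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts$traits <- nrow(traits)

  # --- scoring and screening ------------------------------------------------
  score_tables <- NULL
  if ("score" %in% stages) {
    score_tables <- collect(lapply(split(rel, rel$environment), score_environment))
    all_scores <- do.call(rbind, Map(function(e, st)
      cbind(environment = e, st$scores), names(score_tables), score_tables))
    utils::write.table(all_scores, paths$scores, sep = "\t", quote = FALSE, row.names = FALSE)
    screen <- screen_tolerant(score_tables)
    schemes <- lapply(score_tables, function(st)
      list(boundaries = st$scheme$boundaries,
           boundaries_rounded = round(st$scheme$boundaries, 2),
           range = as.list(st$scheme$range)))
    jsonlite::write_json(list(target_grade = screen$target_grade,
                              per_environment = screen$per_environment,
                              counts = as.list(screen$counts),
                              percent = as.list(screen$percent),
                              union = screen$union,
                              intersection = screen$intersection,
                              schemes = schemes),
                         paths$screen, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("score: %d HDT in union, %d in all environments",
        length(screen$union), length(screen$intersection))
    counts$scored <- nrow(all_scores)
  }

  # --- descriptive stats, ANOVA, heritability, correlations ----------------
  if ("stats" %in% stages) {
    desc <- rbind(describe_traits(traits, c("GR", "GE", "GI")),
                  cbind(treatment = NA,
                        describe_traits(rel, c("RGR", "RGE", "RGI"))[,
                          c("trait", "environment", "n", "max", "min", "range",
                            "mean", "sd", "cv", "skewness", "kurtosis")])[,
                          c("trait", "environment", "treatment", "n", "max", "min",
                            "range", "mean", "sd", "cv", "skewness", "kurtosis")])
    utils::write.table(desc, paths$descriptives, sep = "\t", quote = FALSE, row.names = FALSE)
    relrep <- collect(replicate_relative_values(traits))
    anova_rows <- list(); herit <- NULL
    if (length(unique(rel$environment)) >= 2) {
      herit <- collect(heritability_table(traits))
      for (tr in c("RGR", "RGE", "RGI")) {
        dec <- collect(anova_two_way(relrep, tr))
        anova_rows[[tr]] <- cbind(trait = tr, dec$table)
      }
      utils::write.table(do.call(rbind, anova_rows), paths$anova, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(herit, paths$herit, sep = "\t", quote = FALSE, row.names = FALSE)
      say("stats: h2 = %s",
          paste(sprintf("%s %0.2f", herit$trait, herit$h2), collapse = ", "))
    }
    cors <- correlate_traits(rel, c("RGR", "RGE", "RGI"))
    utils::write.table(data.frame(trait = rownames(cors$r), cors$r),
                       paths$correlations, sep = "\t", quote = FALSE, row.names = FALSE)
    counts$descriptives <- nrow(desc)
  }

  # --- association ----------------------------------------------------------
  if ("gwas" %in% stages && !is.null(geno)) {
    for (env in unique(rel$environment)) {
      rel_e <- rel[rel$environment == env, ]
      y <- stats::setNames(rel_e[[gwas_trait]], rel_e$genotype_id)
      scan <- collect(mlm_scan(y, geno, maf = maf))
      hits <- significant_snps(scan, threshold)
      suffix <- if (env == unique(rel$environment)[1]) "" else paste0("_", env)
      scan_path <- sub("\\.tsv$", paste0(suffix, ".tsv"), paths$scan)
      hits_path <- sub("\\.tsv$", paste0(suffix, ".tsv"), paths$hits)
      utils::write.table(data.frame(environment = rep(env, nrow(scan)), scan),
                         scan_path, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(environment = rep(env, nrow(hits)), hits),
                         hits_path, sep = "\t", quote = FALSE, row.names = FALSE)
      manhattan_path <- sub("\\.png$", paste0(suffix, ".png"), paths$manhattan)
      try(manhattan_plot(scan, threshold, file = manhattan_path,
                         main = sprintf("%s, %s", gwas_trait, env)), silent = TRUE)
      say("gwas %s: %d/%d SNPs at -log10(p) >= %g", env, nrow(hits), nrow(scan),
          threshold)
      counts[[paste0("gwas_", env)]] <- nrow(scan)
      counts[[paste0("hits_", env)]] <- nrow(hits)
    }
  }

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report <- list(counts = counts, warnings = warnings_seen,
                 elapsed_seconds = elapsed, out_dir = out_dir,
                 stages = stages, threshold = threshold, maf = maf,
                 gwas_trait = gwas_trait,
                 simulated = simulated,
                 config = if (simulated) unclass(config)[
                   c("n_genotypes", "n_environments", "n_replicates",
                     "seeds_per_replicate", "n_days", "energy_day", "n_snps",
                     "n_causal", "rng_seed")] else config,
                 version = as.character(utils::packageVersion("droughtscreen")))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  structure(c(report, list(paths = paths)), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (%0.1fs) -> %s\n", x$elapsed_seconds, x$out_dir))
  for (nm in names(x$counts)) cat(sprintf("  %s: %d rows\n", nm, x$counts[[nm]]))
  if (length(x$warnings)) cat("  warnings:\n", paste("   -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
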