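#' Read and write germination trial tables
#'
#' Trials travel as tab-delimited text with columns `genotype_id`,
#' `environment`, `treatment`, `replicate`, `total_seeds`, `day1..dayN`.
#'
#' @param trials A `germination_trials` data frame.
#' @param path File path.
#' @return `read_trials()` returns a `germination_trials` data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("genotype_id", "environment", "treatment", "replicate", "total_seeds")
  if (!all(need %in% names(out)))
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  day_cols <- grep("^day[0-9]+$", names(out), value = TRUE)
  if (length(day_cols) == 0) stop("trial table has no day1..dayN columns")
  bad <- rowSums(out[, day_cols, drop = FALSE]) > out$total_seeds
  if (any(bad)) stop(sum(bad), " row(s) report more germinated seeds than sown")
  class(out) <- c("germination_trials", "data.frame")
  out
}

#' Read and write SNP dosage matrices
#'
#' Plain tab-delimited dosage matrices: first column `genotype_id`, one
#' column per SNP with entries in \{0, 1, 2\} (alternate-allele count). A
#' companion map file (`snp_id`, `chrom`, `pos`, `ref`, `alt`) travels
#' alongside when allele/coordinate metadata is needed.
#'
#' @param G `genotype_matrix` or dosage matrix.
#' @param path Dosage file path.
#' @param map_path Optional map file path.
#' @return `read_dosage()` returns a `genotype_matrix`; writers return
#'   `path` invisibly.
#' @export
write_dosage <- function(G, path, map_path = NULL) {
  M <- dosage_matrix(G)
  df <- data.frame(genotype_id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path) && inherits(G, "genotype_matrix"))
    utils::write.table(G$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path, map_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  if (!all(M %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  storage.mode(M) <- "integer"
  map <- if (!is.null(map_path)) {
    utils::read.delim(map_path, stringsAsFactors = FALSE)
  } else {
    data.frame(snp_id = colnames(M), chrom = NA_integer_, pos = NA_integer_,
               ref = NA_character_, alt = NA_character_,
               maf = pmin(colMeans(M) / 2, 1 - colMeans(M) / 2))
  }
  structure(list(dosage = M, map = map,
                 causal = data.frame(snp_id = character(0), effect = numeric(0))),
            class = "genotype_matrix")
}

#' Write a genotype matrix as minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with CHROM, POS, ID, REF, ALT and
#' per-genotype GT fields; dosage 0/1/2 maps to `0/0`, `0/1`, `1/1`.
#'
#' @param G A `genotype_matrix`.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  M <- G$dosage
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(M)), function(j) {
    paste(c(G$map$chrom[j], G$map$pos[j], G$map$snp_id[j], G$map$ref[j],
            G$map$alt[j], ".", "PASS", ".", "GT", gt[M[, j] + 1]),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(M)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Loads a biallelic-SNP VCF into a `genotype_matrix`, converting GT fields
#' to alternate-allele dosages. Uses the vcfR parser.
#'
#' @param path VCF file path.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(s) {
    a <- strsplit(gsub("\\|", "/", s), "/", fixed = FALSE)
    vapply(a, function(z) sum(z == "1"), integer(1))
  }
  M <- t(apply(gt, 1, alt_count))
  M <- t(M)  # genotypes x SNPs
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(snp_id = fix$ID, chrom = as.integer(fix$CHROM),
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  p <- colMeans(M) / 2
  map$maf <- pmin(p, 1 - p)
  dimnames(M) <- list(colnames(gt), map$snp_id)
  structure(list(dosage = M, map = map,
                 causal = data.frame(snp_id = character(0), effect = numeric(0))),
            class = "genotype_matrix")
}

#' Read a pipeline or simulation configuration file
#'
#' Configurations are YAML (or JSON) mappings of [sim_config()] and
#' [run_pipeline()] arguments. A `rng_seed` entry is mandatory when the
#' configuration asks for simulation.
#'
#' @param path YAML or JSON file.
#' @return A named list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a mapping")
  cfg
}
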