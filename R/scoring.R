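#' Drought-tolerance coefficient
#'
#' The drought-tolerance coefficient (DTC) of a genotype for one trait is
#' the drought-treatment replicate mean over the control replicate mean,
#' times 100. Zero control means give `NA` (shared policy with
#' [relative_indices()]); the ratio is never silently formed.
#'
#' @param treatment_mean,control_mean Numeric vectors of paired replicate
#'   means (one entry per genotype).
#' @return Numeric vector of DTC values on the percent scale.
#' @examples
#' compute_dtc(30, 60)  # 50
#' @export
compute_dtc <- function(treatment_mean, control_mean) {
  if (length(treatment_mean) != length(control_mean))
    stop("treatment and control means must be paired")
  ifelse(control_mean == 0, NA_real_, treatment_mean / control_mean * 100)
}

#' Subordinate (membership) function value
#'
#' Min-max normalization of a DTC column across genotypes:
#' \eqn{F_{ij} = (DTC_{ij} - \min_i DTC_{ij}) / (\max_i DTC_{ij} - \min_i DTC_{ij})}.
#' Invariant to positive affine transforms of its input, so feeding raw
#' relative indices instead of the x100 DTC gives identical scores. Missing
#' values pass through as missing. When all non-missing values are equal the
#' column carries no ranking information: every score is set to 0.5 with a
#' warning.
#'
#' @param x Numeric vector of DTC (or relative-index) values over genotypes
#'   for one trait; at least 2 non-missing values.
#' @return Numeric vector of membership scores in \[0, 1\].
#' @examples
#' compute_sfv(c(20, 60, 100))  # 0, 0.5, 1
#' @export
compute_sfv <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing values to normalize")
  lo <- min(x[ok]); hi <- max(x[ok])
  if (hi == lo) {
    warning("all values equal; membership scores set to 0.5")
    return(ifelse(ok, 0.5, NA_real_))
  }
  (x - lo) / (hi - lo)
}

#' Average subordinate function value
#'
#' Arithmetic mean of the three per-trait membership scores of a genotype.
#' Genotypes missing any score get a missing ASFV (and are later excluded
#' from grading, with a message).
#'
#' @param sfv_matrix Numeric matrix, genotypes x traits (3 columns for
#'   GR/GE/GI-based coefficients).
#' @return Numeric vector of ASFV values in \[0, 1\].
#' @examples
#' compute_asfv(cbind(c(0, 1), c(0.3, 1), c(0.6, 1)))
#' @export
compute_asfv <- function(sfv_matrix) {
  sfv_matrix <- as.matrix(sfv_matrix)
  out <- rowMeans(sfv_matrix)
  n_miss <- sum(is.na(out))
  if (n_miss > 0)
    message(sprintf("%d genotype(s) have a missing membership score and no ASFV", n_miss))
  out
}

#' Equal-interval five-grade tolerance scheme
#'
#' Divides the observed ASFV range into `n_classes` equal intervals and
#' labels them from highly drought-sensitive (lowest) to highly
#' drought-tolerant (highest). Boundaries are reported rounded to 2 decimals
#' for display but classification always uses the unrounded values.
#'
#' @param asfv Numeric vector of ASFV values (at least 2 distinct).
#' @param n_classes Number of grades (default 5: HDS, DS, MDT, DT, HDT).
#' @return A list of class `"grade_scheme"`: `boundaries` (ascending interior
#'   cut points), `labels` (low to high), `range` (observed min/max).
#' @examples
#' build_grade_scheme(c(0, 0.2, 0.94))
#' @export
build_grade_scheme <- function(asfv, n_classes = 5) {
  x <- asfv[!is.na(asfv)]
  if (length(unique(x)) < 2) stop("need at least 2 distinct ASFV values")
  lo <- min(x); hi <- max(x)
  k <- seq_len(n_classes - 1)
  labels <- if (n_classes == 5) c("HDS", "DS", "MDT", "DT", "HDT")
            else paste0("class", seq_len(n_classes))
  structure(list(boundaries = lo + k * (hi - lo) / n_classes,
                 labels = labels, range = c(min = lo, max = hi),
                 n_classes = n_classes),
            class = "grade_scheme")
}

#' @export
print.grade_scheme <- function(x, ...) {
  cat(sprintf("Equal-interval tolerance scheme over ASFV [%0.2f, %0.2f]\n",
              x$range["min"], x$range["max"]))
  b <- round(x$boundaries, 2)
  lab <- rev(x$labels)  # display high to low as grading tables do
  cuts <- rev(c(x$range["min"], x$boundaries))
  tops <- rev(c(x$boundaries, x$range["max"]))
  for (i in seq_along(lab))
    cat(sprintf("  %-4s [%0.2f, %0.2f%s\n", lab[i], cuts[i], tops[i],
                if (i == 1) "]" else ")"))
  invisible(x)
}

#' Assign tolerance grades from a scheme
#'
#' Interval membership: intervals are left-closed, right-open, except the
#' top interval which is closed, so the maximum ASFV grades HDT and higher
#' ASFV never maps to a lower grade. Values outside the scheme range (when
#' one scheme is applied to new data) are clamped, with a warning.
#'
#' @param asfv Numeric vector of ASFV values; `NA` stays `NA`.
#' @param scheme A [build_grade_scheme()] result.
#' @return Ordered factor of grades, levels low to high.
#' @examples
#' s <- build_grade_scheme(c(0, 0.94))
#' assign_grades(c(0.76, 0.10), s)
#' @export
assign_grades <- function(asfv, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  lo <- scheme$range["min"]; hi <- scheme$range["max"]
  out_of_range <- !is.na(asfv) & (asfv < lo | asfv > hi)
  if (any(out_of_range)) {
    warning(sprintf("%d ASFV value(s) outside the scheme range were clamped",
                    sum(out_of_range)))
    asfv <- pmin(pmax(asfv, lo), hi)
  }
  idx <- findInterval(asfv, c(lo, scheme$boundaries, hi),
                      rightmost.closed = TRUE)
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Score genotypes for drought tolerance in one environment
#'
#' Full membership-function scoring of one environment's relative indices:
#' DTC per trait, min-max membership score per trait, their average (ASFV),
#' an equal-interval grade scheme built from the observed ASFV range, and
#' grade assignment.
#'
#' @param rel Relative-index table from [relative_indices()], or any data
#'   frame with `genotype_id` and the columns named in `traits` plus paired
#'   control/drought means `RC/RD`, `EC/ED`, `IC/ID` (when present, DTC is
#'   recomputed from the means; otherwise the relative indices x 100 are
#'   used, which yields identical membership scores by affine invariance).
#' @param traits Character vector of the three relative-index columns.
#' @return A list of class `"score_table"`: `scores` data frame
#'   (genotype_id, DTC x3, SFV x3, ASFV, grade) and `scheme`.
#' @examples
#' trials <- simulate_trials(sim_config(n_genotypes = 8, n_snps = 5, rng_seed = 1))
#' rel <- relative_indices(germination_traits(trials))
#' score_environment(rel[rel$environment == "E1", ])
#' @export
score_environment <- function(rel, traits = c("RGR", "RGE", "RGI")) {
  stopifnot(all(c("genotype_id", traits) %in% names(rel)))
  pairs <- list(RGR = c("RD", "RC"), RGE = c("ED", "EC"), RGI = c("ID", "IC"))
  dtc <- sapply(traits, function(tr) {
    pr <- pairs[[tr]]
    if (!is.null(pr) && all(pr %in% names(rel)))
      compute_dtc(rel[[pr[1]]], rel[[pr[2]]])
    else rel[[tr]] * 100
  })
  sfv <- apply(dtc, 2, compute_sfv)
  asfv <- compute_asfv(sfv)
  scheme <- build_grade_scheme(asfv)
  grade <- assign_grades(asfv, scheme)
  scores <- data.frame(genotype_id = rel$genotype_id,
                       stats::setNames(as.data.frame(dtc), paste0("DTC_", traits)),
                       stats::setNames(as.data.frame(sfv), paste0("SFV_", traits)),
                       ASFV = asfv, grade = grade, stringsAsFactors = FALSE)
  structure(list(scores = scores, scheme = scheme), class = "score_table")
}

#' Screen highly drought-tolerant genotypes across environments
#'
#' Collects the genotypes in the target grade per environment and reports
#' per-environment lists with counts and percentages, plus their union and
#' intersection (genotypes tolerant in every environment).
#'
#' @param score_tables Named list of [score_environment()] results (names =
#'   environment ids), or a single `score_table`.
#' @param target_grade Grade to screen for (default `"HDT"`).
#' @return A list of class `"screen_report"`: `per_environment` (named list
#'   of genotype id vectors), `counts`, `percent`, `union`, `intersection`,
#'   `n_population`.
#' @examples
#' trials <- simulate_trials(sim_config(n_genotypes = 12, n_snps = 5, rng_seed = 1))
#' rel <- relative_indices(germination_traits(trials))
#' st <- lapply(split(rel, rel$environment), score_environment)
#' screen_tolerant(st)
#' @export
screen_tolerant <- function(score_tables, target_grade = "HDT") {
  if (inherits(score_tables, "score_table"))
    score_tables <- list(E1 = score_tables)
  sel <- lapply(score_tables, function(st) {
    sc <- st$scores
    as.character(sc$genotype_id[!is.na(sc$grade) & sc$grade == target_grade])
  })
  n_pop <- max(vapply(score_tables, function(st) nrow(st$scores), integer(1)))
  counts <- vapply(sel, length, integer(1))
  structure(list(
    per_environment = sel,
    counts = counts,
    percent = counts / n_pop * 100,
    union = sort(Reduce(union, sel)),
    intersection = sort(Reduce(intersect, sel)),
    n_population = n_pop,
    target_grade = target_grade
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Screen for grade %s over %d genotypes\n", x$target_grade, x$n_population))
  for (e in names(x$per_environment))
    cat(sprintf("  %s: %d (%0.2f%%): %s\n", e, x$counts[[e]], x$percent[[e]],
                paste(x$per_environment[[e]], collapse = ", ")))
  cat(sprintf("  union: %d; in all environments: %d (%s)\n",
              length(x$union), length(x$intersection),
              paste(x$intersection, collapse = ", ")))
  invisible(x)
}
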