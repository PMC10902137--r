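#' Germination indices from daily counts
#'
#' Three standard germination-stage vigour indices computed from the daily
#' counts of newly germinated seeds in one trial unit:
#' * `compute_gr()` — germination rate: cumulative germination through the
#'   final counting day (conventionally day 7) over seeds sown, in percent.
#' * `compute_ge()` — germination energy: cumulative germination through
#'   `energy_day` (conventionally day 4) over seeds sown, in percent. An
#'   early-vigour measure, so `GE <= GR` always.
#' * `compute_gi()` — germination index: \eqn{GI = \sum_t G_t / D_t}, the sum
#'   over counting days of seeds newly germinated on day \eqn{t} divided by
#'   the day number; weights early germination more heavily. Unitless.
#'
#' @param daily_counts Integer vector of newly germinated seeds per day.
#' @param total_seeds Seeds sown in the unit (must be > 0 for GR/GE).
#' @param energy_day Day through which germination energy is accumulated.
#' @return A single numeric value.
#' @examples
#' compute_gr(c(10, 10, 9, 0, 0, 0, 0), 30)   # 96.67
#' compute_ge(c(5, 5, 5, 5, 5, 0, 0), 50)     # 40
#' compute_gi(c(10, 5, 3, 0, 0, 0, 2))        # 10/1 + 5/2 + 3/3 + 2/7
#' @export
compute_gr <- function(daily_counts, total_seeds) {
  check_counts(daily_counts, total_seeds)
  sum(daily_counts) / total_seeds * 100
}

#' @rdname compute_gr
#' @export
compute_ge <- function(daily_counts, total_seeds, energy_day = 4) {
  check_counts(daily_counts, total_seeds)
  if (energy_day > length(daily_counts))
    stop("energy_day exceeds the number of counting days")
  sum(daily_counts[seq_len(energy_day)]) / total_seeds * 100
}

#' @rdname compute_gr
#' @export
compute_gi <- function(daily_counts) {
  if (any(daily_counts < 0)) stop("daily counts must be non-negative")
  sum(daily_counts / seq_along(daily_counts))
}

check_counts <- function(daily_counts, total_seeds) {
  if (length(total_seeds) != 1 || total_seeds <= 0)
    stop("total_seeds must be a single positive count")
  if (any(daily_counts < 0)) stop("daily counts must be non-negative")
  if (sum(daily_counts) > total_seeds)
    stop("more germinated seeds than seeds sown")
  invisible(TRUE)
}

#' Per-unit germination trait table
#'
#' Computes GR, GE and GI for every trial unit (genotype x environment x
#' treatment x replicate) in a trial table.
#'
#' @param trials A `germination_trials` data frame (from [simulate_trials()]
#'   or [read_trials()]): columns `genotype_id`, `environment`, `treatment`,
#'   `replicate`, `total_seeds`, `day1..dayN`.
#' @param energy_day Day for germination energy; defaults to the trial
#'   configuration's value when present, else 4.
#' @return A data frame with one row per unit and columns `GR`, `GE`, `GI`
#'   appended to the unit keys.
#' @examples
#' trials <- simulate_trials(sim_config(n_genotypes = 3, n_snps = 5, rng_seed = 1))
#' head(germination_traits(trials))
#' @export
germination_traits <- function(trials, energy_day = NULL) {
  day_cols <- grep("^day[0-9]+$", names(trials), value = TRUE)
  if (length(day_cols) == 0) stop("no day1..dayN columns found")
  day_cols <- day_cols[order(as.integer(sub("day", "", day_cols)))]
  if (is.null(energy_day)) {
    cfg <- attr(trials, "config")
    energy_day <- if (!is.null(cfg)) cfg$energy_day else 4L
  }
  counts <- as.matrix(trials[, day_cols])
  cum <- t(apply(counts, 1, cumsum))
  gi <- counts %*% (1 / seq_along(day_cols))
  data.frame(
    trials[, c("genotype_id", "environment", "treatment", "replicate")],
    GR = cum[, length(day_cols)] / trials$total_seeds * 100,
    GE = cum[, energy_day] / trials$total_seeds * 100,
    GI = drop(gi),
    stringsAsFactors = FALSE
  )
}

#' Relative (drought/control) germination indices per genotype and environment
#'
#' Averages each trait over replicates within genotype x environment x
#' treatment, then forms the drought-to-control ratio of those replicate
#' means: RGR = RD/RC, RGE = ED/EC, RGI = ID/IC (ratio of means, not mean of
#' ratios, matching the definition of the drought-tolerance coefficient).
#' Genotype-by-environment rows whose control mean is zero get `NA` for that
#' relative index, with a warning; they are excluded from downstream
#' min-max scans. Ratios above 1 are retained as observed.
#'
#' @param traits Per-unit trait table from [germination_traits()].
#' @return A data frame with one row per genotype x environment and columns
#'   `RC`, `EC`, `IC` (control means), `RD`, `ED`, `ID` (drought means),
#'   `RGR`, `RGE`, `RGI`.
#' @examples
#' trials <- simulate_trials(sim_config(n_genotypes = 3, n_snps = 5, rng_seed = 1))
#' relative_indices(germination_traits(trials))
#' @export
relative_indices <- function(traits) {
  agg <- stats::aggregate(traits[, c("GR", "GE", "GI")],
                          by = traits[, c("genotype_id", "environment", "treatment")],
                          FUN = mean)
  ctrl <- agg[agg$treatment == "control", ]
  drt <- agg[agg$treatment == "drought", ]
  key <- c("genotype_id", "environment")
  m <- merge(ctrl[, c(key, "GR", "GE", "GI")], drt[, c(key, "GR", "GE", "GI")],
             by = key, suffixes = c("_C", "_D"))
  out <- data.frame(
    m[, key],
    RC = m$GR_C, EC = m$GE_C, IC = m$GI_C,
    RD = m$GR_D, ED = m$GE_D, ID = m$GI_D,
    stringsAsFactors = FALSE
  )
  safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  out$RGR <- safe_ratio(out$RD, out$RC)
  out$RGE <- safe_ratio(out$ED, out$EC)
  out$RGI <- safe_ratio(out$ID, out$IC)
  n_bad <- sum(out$RC == 0 | out$EC == 0 | out$IC == 0)
  if (n_bad > 0)
    warning(sprintf("%d genotype x environment row(s) have a zero control mean; %s",
                    n_bad, "the affected relative indices are set to NA"))
  out[order(out$environment, out$genotype_id), , drop = FALSE]
}
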