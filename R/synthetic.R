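#' Simulator configuration for a multi-stratum reporting system
#'
#' Describes a synthetic spontaneous reporting system: drug classes of
#' configurable size, Zipf-skewed drug and ADR popularity (national
#' databases concentrate roughly 60% of reports in the ten most frequent
#' ADRs), a configurable fraction of one-drug-to-many-ADR reports
#' (about a third in practice), a distinct ADR profile for the stratum,
#' planted disproportionate pairs, and a reference database with a known
#' pair fraction. All randomness flows from a single seed.
#'
#' @param n_drugs named integer vector of drugs per class,
#'   `c(TCM=, western=, biological=)`.
#' @param n_adrs number of ADR terms.
#' @param n_reports number of raw reports to draw.
#' @param multi_adr_fraction probability a report lists several ADRs
#'   (default 0.334).
#' @param zipf_exponent popularity skew for drugs and ADRs (default 1,
#'   which puts ~60% of draws in the top ten of 60 ADRs).
#' @param known_pair_fraction probability that a given (drug, ADR) pair
#'   belongs to the reference database (default 0.15).
#' @param signal_pairs optional data.frame `drug_name, adr_name,
#'   relative_risk` of planted disproportionate pairs
#'   (`relative_risk >= 1`).
#' @param stratum_profile_shift in `[0, 1]`: how far the TCM stratum's
#'   ADR distribution departs from the background profile (0 = same
#'   profile).
#' @param serious_fraction probability a report is flagged serious
#'   (default 0.05, matching national proportions).
#' @param seed default RNG seed used by the generators.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_drugs = c(TCM = 30, western = 60, biological = 10),
                       n_adrs = 60, n_reports = 20000,
                       multi_adr_fraction = 0.334, zipf_exponent = 1,
                       known_pair_fraction = 0.15, signal_pairs = NULL,
                       stratum_profile_shift = 0.5, serious_fraction = 0.05,
                       seed = 1L) {
  stopifnot(all(names(n_drugs) %in% DRUG_TYPES), all(n_drugs >= 0),
            sum(n_drugs) > 0, n_adrs >= 1, n_reports >= 1,
            multi_adr_fraction >= 0, multi_adr_fraction <= 1,
            zipf_exponent >= 0,
            known_pair_fraction >= 0, known_pair_fraction <= 1,
            stratum_profile_shift >= 0, stratum_profile_shift <= 1,
            serious_fraction >= 0, serious_fraction <= 1)
  if (!is.null(signal_pairs)) {
    stopifnot(is.data.frame(signal_pairs),
              all(c("drug_name", "adr_name", "relative_risk") %in% names(signal_pairs)),
              all(signal_pairs$relative_risk >= 1))
  }
  structure(list(n_drugs = n_drugs, n_adrs = n_adrs, n_reports = n_reports,
                 multi_adr_fraction = multi_adr_fraction,
                 zipf_exponent = zipf_exponent,
                 known_pair_fraction = known_pair_fraction,
                 signal_pairs = signal_pairs,
                 stratum_profile_shift = stratum_profile_shift,
                 serious_fraction = serious_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic universe implied by a config (no RNG): drug table with
# Zipf popularity interleaved across classes so every class spans the
# popularity range, ADR base weights, and the stratum's shifted profile.
sim_universe <- function(config) {
  types <- rep(names(config$n_drugs), config$n_drugs)
  within_idx <- unlist(lapply(config$n_drugs, seq_len), use.names = FALSE)
  ord <- order(within_idx, match(types, DRUG_TYPES))  # round-robin ranks
  types <- types[ord]
  within_idx <- within_idx[ord]
  d <- length(types)
  drugs <- data.frame(
    name = sprintf("%s_d%03d", tolower(types), within_idx),
    type = types,
    weight = (seq_len(d))^(-config$zipf_exponent),
    stringsAsFactors = FALSE
  )
  drugs$weight <- drugs$weight / sum(drugs$weight)
  adrs <- sprintf("adr%03d", seq_len(config$n_adrs))
  base <- (seq_len(config$n_adrs))^(-config$zipf_exponent)
  base <- base / sum(base)
  # stratum profile: mixture of the base profile and a rotated copy
  rot <- ((seq_len(config$n_adrs) - 1 + config$n_adrs %/% 3) %% config$n_adrs) + 1
  shift <- config$stratum_profile_shift
  stratum <- (1 - shift) * base + shift * base[rot]

  w <- matrix(rep(base, each = d), nrow = d)
  w[drugs$type == "TCM", ] <- matrix(rep(stratum, each = sum(drugs$type == "TCM")),
                                     nrow = sum(drugs$type == "TCM"))
  if (!is.null(config$signal_pairs)) {
    sp <- config$signal_pairs
    di <- match(sp$drug_name, drugs$name)
    ai <- match(sp$adr_name, adrs)
    if (anyNA(di) || anyNA(ai)) stop("signal_pairs refer to drugs/ADRs outside the universe")
    w[cbind(di, ai)] <- w[cbind(di, ai)] * sp$relative_risk
  }
  w <- w / rowSums(w)
  list(drugs = drugs, adrs = adrs, adr_weights = w)
}

#' Generate a synthetic reference database
#'
#' Each (drug, ADR) pair of the universe enters the reference with
#' probability `known_pair_fraction`; when that fraction is positive,
#' every drug is guaranteed at least one known pair (drawn from its own
#' ADR profile), so the reference-drug filter never removes whole drugs.
#' Planted signal pairs are always included, giving recall a known
#' optimum. Deterministic under the seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a [reference_db()].
#' @export
generate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  u <- sim_universe(config)
  d <- nrow(u$drugs)
  if (config$known_pair_fraction == 0 && is.null(config$signal_pairs)) {
    return(reference_db(data.frame(drug_name = character(),
                                   adr_name = character())))
  }
  inc <- matrix(stats::runif(d * config$n_adrs) < config$known_pair_fraction,
                nrow = d)
  if (config$known_pair_fraction > 0) {
    none <- which(rowSums(inc) == 0)
    for (i in none) {
      inc[i, sample.int(config$n_adrs, 1, prob = u$adr_weights[i, ])] <- TRUE
    }
  }
  idx <- which(inc, arr.ind = TRUE)
  pairs <- data.frame(drug_name = u$drugs$name[idx[, 1]],
                      adr_name = u$adrs[idx[, 2]],
                      stringsAsFactors = FALSE)
  if (!is.null(config$signal_pairs)) {
    pairs <- rbind(pairs, config$signal_pairs[c("drug_name", "adr_name")])
  }
  reference_db(pairs)
}

#' Generate raw spontaneous-report rows
#'
#' Draws `n_reports` reports: the drug from the Zipf popularity model,
#' then one ADR (or, with probability `multi_adr_fraction`, several
#' distinct ADRs) from the drug's ADR profile - the background Zipf
#' profile, shifted for the stratum, with planted pairs upweighted by
#' their relative risk and renormalised. Output is in the multi-ADR raw
#' format accepted by [split_multi_adr()] / [read_reports()].
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return data.frame `report_id, drug_name, drug_type, adr_names,
#'   serious`.
#' @export
generate_reports <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  u <- sim_universe(config)
  n <- config$n_reports
  drug_idx <- sample.int(nrow(u$drugs), n, replace = TRUE, prob = u$drugs$weight)
  multi <- stats::runif(n) < config$multi_adr_fraction
  k <- ifelse(multi, pmin(2L + stats::rgeom(n, 0.6), min(6L, config$n_adrs)), 1L)
  serious <- stats::runif(n) < config$serious_fraction
  adr_names <- character(n)
  for (d in unique(drug_idx)) {
    wd <- u$adr_weights[d, ]
    singles <- which(drug_idx == d & k == 1L)
    if (length(singles)) {
      adr_names[singles] <- sample(u$adrs, length(singles), replace = TRUE, prob = wd)
    }
    for (r in which(drug_idx == d & k > 1L)) {
      adr_names[r] <- paste(sample(u$adrs, k[r], replace = FALSE, prob = wd),
                            collapse = ";")
    }
  }
  data.frame(report_id = sprintf("r%07d", seq_len(n)),
             drug_name = u$drugs$name[drug_idx],
             drug_type = u$drugs$type[drug_idx],
             adr_names = adr_names,
             serious = as.integer(serious),
             stringsAsFactors = FALSE)
}
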