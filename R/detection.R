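#' Signal criteria configuration
#'
#' Bundles the tunable cut-offs of the four disproportionality methods.
#' Defaults are the standard published criteria: PRR/MHRA flag a pair when
#' `a >= 3`, `PRR >= 2` and chi-square `>= 4`; ROR when `a >= 3` and the
#' lower 95% confidence bound of the odds ratio exceeds 1; IC when the
#' lower end of the two-standard-deviation credible interval exceeds 0.
#'
#' @param min_count minimum cell-a count for PRR/ROR/MHRA (default 3).
#' @param prr_threshold PRR cut-off (default 2).
#' @param chi2_threshold chi-square cut-off (default 4).
#' @param ci_level confidence level of the ROR interval (default 0.95).
#' @param ic_interval_multiplier standard deviations subtracted from the
#'   IC point value to form its lower bound (default 2).
#' @param yates apply Yates' continuity correction to the chi-square
#'   (default `FALSE`; the MHRA literature quotes the uncorrected form).
#' @param continuity_correction Haldane +0.5 added to all cells for the
#'   ROR statistic (default `FALSE`).
#' @return an object of class `detection_criteria`.
#' @export
detection_criteria <- function(min_count = 3, prr_threshold = 2,
                               chi2_threshold = 4, ci_level = 0.95,
                               ic_interval_multiplier = 2,
                               yates = FALSE, continuity_correction = FALSE) {
  stopifnot(min_count >= 1, prr_threshold > 0, chi2_threshold >= 0,
            ci_level > 0, ci_level < 1, ic_interval_multiplier >= 0)
  structure(list(min_count = min_count, prr_threshold = prr_threshold,
                 chi2_threshold = chi2_threshold, ci_level = ci_level,
                 ic_interval_multiplier = ic_interval_multiplier,
                 yates = yates, continuity_correction = continuity_correction),
            class = "detection_criteria")
}

#' Pearson chi-square of a 2x2 table
#'
#' Closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`; with Yates'
#' correction `|ad - bc|` is reduced by `N/2` (floored at 0) before
#' squaring. A zero margin makes the statistic undefined and returns
#' `NaN`; downstream criteria treat that as no signal.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @param yates logical, apply the continuity correction.
#' @return numeric chi-square value(s).
#' @export
#' @examples
#' chi_square(10, 90, 10, 890)  # 36.281
chi_square <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  m <- (a + b) * (c + d) * (a + c) * (b + d)
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  out <- n * dev^2 / m
  out[m == 0] <- NaN
  out
}

# Vectorised 2x2 cells for every pair of a sample, computed within that
# sample only: a = pair count, b = same drug/other ADRs, c = other
# drugs/same ADR, d = remainder.
contingency_cells <- function(sample) {
  stopifnot(inherits(sample, "pv_sample"))
  p <- sample$pairs
  cnt <- as.numeric(p$count)
  di <- match(p$drug_name, unique(p$drug_name))
  ai <- match(p$adr_name, unique(p$adr_name))
  drug_tot <- as.numeric(rowsum(cnt, di))  # groups 1..k ascending
  adr_tot <- as.numeric(rowsum(cnt, ai))
  a <- cnt
  b <- drug_tot[di] - a
  c <- adr_tot[ai] - a
  d <- sum(cnt) - a - b - c
  data.frame(drug_name = p$drug_name, adr_name = p$adr_name,
             a = a, b = b, c = c, d = d, stringsAsFactors = FALSE)
}

#' 2x2 contingency table for one drug-ADR pair
#'
#' Cells are computed within the given sample only, so a stratum sample
#' yields within-stratum (product-level) tables.
#'
#' @param sample a [pv_sample()].
#' @param drug_name,adr_name the target pair; must be present in the
#'   sample.
#' @return named numeric vector `c(a, b, c, d)`.
#' @export
contingency <- function(sample, drug_name, adr_name) {
  cells <- contingency_cells(sample)
  i <- which(cells$drug_name == drug_name & cells$adr_name == adr_name)
  if (length(i) != 1) {
    stop(sprintf("pair (%s, %s) not present in the sample", drug_name, adr_name))
  }
  c(a = cells$a[i], b = cells$b[i], c = cells$c[i], d = cells$d[i])
}

stat_prr <- function(a, b, c, d, crit) {
  chi2 <- chi_square(a, b, c, d, crit$yates)
  prr <- (a / (a + b)) / (c / (c + d))
  signal <- a >= crit$min_count &
    !is.na(prr) & prr >= crit$prr_threshold &
    !is.na(chi2) & chi2 >= crit$chi2_threshold
  list(statistic = prr, chi2 = chi2,
       interval_low = rep(NA_real_, length(a)), signal = signal)
}

stat_mhra <- function(a, b, c, d, crit) {
  out <- stat_prr(a, b, c, d, crit)
  out$statistic <- rep(NA_real_, length(a))  # criterion-only method
  out
}

stat_ror <- function(a, b, c, d, crit) {
  chi2 <- chi_square(a, b, c, d, crit$yates)
  if (crit$continuity_correction) {
    aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5
  } else {
    aa <- as.numeric(a); bb <- as.numeric(b)
    cc <- as.numeric(c); dd <- as.numeric(d)
  }
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  z <- stats::qnorm(1 - (1 - crit$ci_level) / 2)
  low <- exp(log(ror) - z * se)
  signal <- a >= crit$min_count & is.finite(low) & low > 1
  list(statistic = ror, chi2 = chi2, interval_low = low, signal = signal)
}

# Closed-form posterior variance of the BCPNN information component with
# the classic priors alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1 and
# gamma tuned so the prior IC expectation is 0.
bcpnn_ic_variance <- function(a, b, c, d) {
  n <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  n1. <- a + b
  n.1 <- a + c
  g <- g11 * (n + al) * (n + be) / ((n1. + a1) * (n.1 + b1))
  (1 / log(2))^2 * (
    (n - a + g - g11) / ((a + g11) * (1 + n + g)) +
      (n - n1. + al - a1) / ((n1. + a1) * (1 + n + al)) +
      (n - n.1 + be - b1) / ((n.1 + b1) * (1 + n + be))
  )
}

stat_ic <- function(a, b, c, d, crit) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(n == 0)) stop("IC undefined on an empty table")
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  sdv <- sqrt(bcpnn_ic_variance(a, b, c, d))
  low <- ic - crit$ic_interval_multiplier * sdv
  signal <- !is.na(low) & low > 0
  list(statistic = ic, chi2 = rep(NA_real_, length(a)),
       interval_low = low, signal = signal)
}

DETECTION_METHODS <- c("PRR", "ROR", "MHRA", "IC")

#' Run one disproportionality method over a sample
#'
#' Builds the within-sample 2x2 table of every pair and evaluates the
#' requested method, returning per-pair statistics and binary signal
#' calls. Calls are deterministic functions of the table and the
#' criteria.
#'
#' @param sample a non-empty [pv_sample()].
#' @param method `"PRR"`, `"ROR"`, `"MHRA"` or `"IC"`.
#' @param criteria a [detection_criteria()] configuration.
#' @return an object of class `detection_run` with elements
#'   `sample_label`, `method`, `results` (per-pair data.frame with cells,
#'   `statistic`, `chi2`, `interval_low`, `signal`) and `positives`
#'   (data.frame of flagged pairs).
#' @export
detect <- function(sample, method = DETECTION_METHODS,
                   criteria = detection_criteria()) {
  stopifnot(inherits(sample, "pv_sample"), nrow(sample$pairs) > 0,
            inherits(criteria, "detection_criteria"))
  method <- match.arg(method)
  cells <- contingency_cells(sample)
  fn <- switch(method, PRR = stat_prr, ROR = stat_ror,
               MHRA = stat_mhra, IC = stat_ic)
  st <- fn(cells$a, cells$b, cells$c, cells$d, criteria)
  results <- data.frame(
    method = method,
    drug_name = cells$drug_name, adr_name = cells$adr_name,
    a = cells$a, b = cells$b, c = cells$c, d = cells$d,
    statistic = st$statistic, chi2 = st$chi2,
    interval_low = st$interval_low, signal = st$signal,
    stringsAsFactors = FALSE
  )
  structure(list(
    sample_label = sample$label,
    method = method,
    results = results,
    positives = results[results$signal, c("drug_name", "adr_name"), drop = FALSE]
  ), class = "detection_run")
}

#' @export
print.detection_run <- function(x, ...) {
  cat(sprintf("<detection_run: %s on %s sample> %d pairs, %d positive signals\n",
              x$method, x$sample_label, nrow(x$results), nrow(x$positives)))
  invisible(x)
}

run_keys <- function(run) pair_key(run$results$drug_name, run$results$adr_name)
positive_keys <- function(run) pair_key(run$positives$drug_name, run$positives$adr_name)

#' Phi correlation of two detection runs
#'
#' Pearson correlation of the 0/1 signal indicator vectors of two runs
#' over the same pair universe, ordered by the shared pair list. Constant
#' vectors leave the coefficient undefined (`NaN`, with a warning).
#'
#' @param run_a,run_b `detection_run` objects over the same pairs.
#' @return the phi coefficient, or `NaN`.
#' @export
method_correlation <- function(run_a, run_b) {
  ka <- run_keys(run_a)
  kb <- run_keys(run_b)
  if (length(ka) != length(kb) || !setequal(ka, kb)) {
    stop("detection runs cover different pair universes")
  }
  x <- as.integer(run_a$results$signal)
  y <- as.integer(run_b$results$signal[match(ka, kb)])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant signal vector: correlation undefined")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Write a detection run's per-pair results to CSV
#' @param run a `detection_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(run, path) {
  utils::write.csv(run$results, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
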