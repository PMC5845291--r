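# Independent brute-force oracles (nested loops, no grouping helpers) and
# small fixture builders shared across test files.

# random single-ADR report records over small name universes
random_records <- function(n, n_drugs = 6, n_adrs = 5, seed = 1) {
  set.seed(seed)
  types <- c("TCM", "western", "biological")
  drug <- sprintf("d%02d", sample.int(n_drugs, n, replace = TRUE))
  data.frame(
    report_id = sprintf("r%04d", sample.int(max(1, n %/% 2), n, replace = TRUE)),
    drug_name = drug,
    drug_type = types[(match(drug, sort(unique(drug))) %% 3) + 1],
    adr_name = sprintf("e%02d", sample.int(n_adrs, n, replace = TRUE)),
    serious = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# brute-force aggregation: double loop, order of first appearance
oracle_aggregate <- function(records) {
  drugs <- character(0); types <- character(0); adrs <- character(0)
  counts <- integer(0)
  for (i in seq_len(nrow(records))) {
    hit <- 0L
    for (j in seq_along(drugs)) {
      if (drugs[j] == records$drug_name[i] && adrs[j] == records$adr_name[i]) {
        hit <- j; break
      }
    }
    if (hit == 0L) {
      drugs <- c(drugs, records$drug_name[i])
      types <- c(types, records$drug_type[i])
      adrs <- c(adrs, records$adr_name[i])
      counts <- c(counts, 1L)
    } else {
      counts[hit] <- counts[hit] + 1L
    }
  }
  data.frame(drug_name = drugs, drug_type = types, adr_name = adrs,
             count = counts, known = NA, stringsAsFactors = FALSE)
}

# build a pv_sample straight from a pair count table
toy_sample <- function(drug, adr, count, known = FALSE,
                       type = "western", label = "total") {
  n <- length(drug)
  pv_sample(data.frame(
    drug_name = drug,
    drug_type = rep_len(type, n),
    adr_name = adr,
    count = count,
    known = rep_len(known, n),
    stringsAsFactors = FALSE
  ), label)
}

random_pair_sample <- function(n_drugs = 5, n_adrs = 4, seed = 1,
                               max_count = 9, label = "total") {
  set.seed(seed)
  grid <- expand.grid(drug = sprintf("d%d", seq_len(n_drugs)),
                      adr = sprintf("e%d", seq_len(n_adrs)),
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < 0.8
  grid <- grid[keep | seq_len(nrow(grid)) == 1, ]
  toy_sample(grid$drug, grid$adr,
             count = sample.int(max_count, nrow(grid), replace = TRUE),
             known = runif(nrow(grid)) < 0.4, label = label)
}

# brute-force 2x2 cells for pair i of a sample, by looping over all pairs
oracle_contingency <- function(sample, i) {
  p <- sample$pairs
  a <- b <- c <- d <- 0
  for (j in seq_len(nrow(p))) {
    same_drug <- p$drug_name[j] == p$drug_name[i]
    same_adr <- p$adr_name[j] == p$adr_name[i]
    if (same_drug && same_adr) a <- a + p$count[j]
    else if (same_drug) b <- b + p$count[j]
    else if (same_adr) c <- c + p$count[j]
    else d <- d + p$count[j]
  }
  c(a = a, b = b, c = c, d = d)
}

# scalar reimplementations of the four statistics, written directly from
# their textbook definitions
oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))
oracle_ror <- function(a, b, c, d) (a * d) / (b * c)
oracle_chi2 <- function(a, b, c, d) {
  suppressWarnings(stats::chisq.test(matrix(c(a, c, b, d), 2), correct = FALSE)$statistic)
}
oracle_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  p1 <- (a + b) / n
  p2 <- (a + c) / n
  log((a + 0.5) / (n * p1 * p2 + 0.5)) / log(2)
}
oracle_ic_sd <- function(a, b, c, d) {
  n <- a + b + c + d
  g <- (n + 2) * (n + 2) / ((a + b + 1) * (a + c + 1))
  v <- (n - a + g - 1) / ((a + 1) * (1 + n + g)) +
    (n - (a + b) + 1) / ((a + b + 1) * (n + 3)) +
    (n - (a + c) + 1) / ((a + c + 1) * (n + 3))
  sqrt(v) / log(2)
}

# minimal detection_run stand-in for correlation / fourfold set algebra
fake_run <- function(drug, adr, signal, method = "PRR", label = "total") {
  results <- data.frame(method = method, drug_name = drug, adr_name = adr,
                        a = NA, b = NA, c = NA, d = NA,
                        statistic = NA_real_, chi2 = NA_real_,
                        interval_low = NA_real_, signal = signal,
                        stringsAsFactors = FALSE)
  structure(list(sample_label = label, method = method, results = results,
                 positives = results[results$signal,
                                     c("drug_name", "adr_name"), drop = FALSE]),
            class = "detection_run")
}
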