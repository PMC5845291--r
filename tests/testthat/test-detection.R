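test_that("contingency cells match brute force and conserve the total", {
  # degenerate: one pair only
  s1 <- toy_sample("d1", "e1", 5)
  expect_equal(contingency(s1, "d1", "e1"), c(a = 5, b = 0, c = 0, d = 0))

  # 2 drugs x 2 ADRs with counts 3,4,5,6
  s2 <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                   c(3, 4, 5, 6))
  expect_equal(contingency(s2, "d1", "e1"), c(a = 3, b = 4, c = 5, d = 6))
  expect_error(contingency(s2, "d9", "e1"), "not present")

  for (seed in 1:5) {
    s <- random_pair_sample(seed = seed)
    cells <- pvstrat:::contingency_cells(s)
    n <- sum(s$pairs$count)
    for (i in seq_len(nrow(cells))) {
      expect_equal(unlist(cells[i, c("a", "b", "c", "d")], use.names = FALSE),
                   unname(oracle_contingency(s, i)))
      expect_equal(cells$a[i] + cells$b[i] + cells$c[i] + cells$d[i], n)
    }
  }
})

test_that("chi-square matches the closed form and the standard routine", {
  expect_equal(chi_square(10, 90, 10, 890), 36.281, tolerance = 1e-4)
  expect_equal(chi_square(5, 10, 15, 30), 0)  # ad = bc: independence
  expect_true(is.nan(chi_square(3, 0, 5, 0)))  # zero margin

  set.seed(42)
  for (i in 1:50) {
    t <- sample.int(40, 4) + 1
    expect_equal(chi_square(t[1], t[2], t[3], t[4]),
                 unname(oracle_chi2(t[1], t[2], t[3], t[4])), tolerance = 1e-9)
    yc <- suppressWarnings(stats::chisq.test(matrix(t[c(1, 3, 2, 4)], 2),
                                             correct = TRUE)$statistic)
    expect_equal(chi_square(t[1], t[2], t[3], t[4], yates = TRUE),
                 unname(yc), tolerance = 1e-9)
  }
})

test_that("PRR statistic and criterion follow the standard definition", {
  s <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                  c(10, 90, 10, 890))
  run <- detect(s, "PRR")
  r <- run$results[run$results$drug_name == "d1" & run$results$adr_name == "e1", ]
  expect_equal(r$statistic, 9.0)
  expect_equal(r$chi2, 36.281, tolerance = 1e-4)
  expect_true(r$signal)

  # a = 2 fails the minimum-count sub-criterion whatever the ratio
  s2 <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                   c(2, 5, 1, 400))
  r2 <- detect(s2, "PRR")$results
  expect_false(r2$signal[r2$drug_name == "d1" & r2$adr_name == "e1"])

  # equal reporting proportions: PRR = 1, no signal
  s3 <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                   c(10, 90, 20, 180))
  r3 <- detect(s3, "PRR")$results
  expect_equal(r3$statistic[1], 1)
  expect_false(r3$signal[1])
})

test_that("ROR matches ad/bc, its symmetry identity, and the PRR ordering law", {
  s <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                  c(10, 90, 10, 890))
  r <- detect(s, "ROR")$results
  expect_equal(r$statistic[1], 10 * 890 / (90 * 10))
  # lower bound: exp(ln ROR - 1.96 sqrt(1/a+1/b+1/c+1/d))
  expect_equal(r$interval_low[1],
               exp(log(9.888889) - stats::qnorm(0.975) *
                     sqrt(1 / 10 + 1 / 90 + 1 / 10 + 1 / 890)),
               tolerance = 1e-6)

  # a = d, b = c gives ROR = (a/b)^2
  expect_equal(oracle_ror(12, 4, 4, 12), (12 / 4)^2)

  set.seed(99)
  for (i in 1:100) {
    t <- sample.int(50, 4)
    ror <- oracle_ror(t[1], t[2], t[3], t[4])
    prr <- oracle_prr(t[1], t[2], t[3], t[4])
    expect_equal(ror >= prr,
                 t[4] * (t[1] + t[2]) >= t[2] * (t[3] + t[4]))
  }
})

test_that("MHRA criterion composes min count, PRR and chi-square", {
  s <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                  c(10, 90, 10, 890))
  r <- detect(s, "MHRA")$results
  expect_true(r$signal[1])
  expect_true(is.na(r$statistic[1]))  # criterion-only method

  # PRR below 2 at the boundary is not a signal
  expect_false(with(list(a = 3, b = 97, c = 19, d = 1181), {
    prr <- oracle_prr(a, b, c, d)  # 1.895
    a >= 3 && prr >= 2 && chi_square(a, b, c, d) >= 4
  }))
})

test_that("MHRA positives are nested in PRR positives under shared sub-criteria", {
  for (seed in 1:5) {
    s <- random_pair_sample(n_drugs = 7, n_adrs = 6, seed = seed, max_count = 30)
    prr <- detect(s, "PRR")
    mhra <- detect(s, "MHRA")
    pk <- paste(prr$positives$drug_name, prr$positives$adr_name)
    mk <- paste(mhra$positives$drug_name, mhra$positives$adr_name)
    expect_true(all(mk %in% pk))
  }
})

test_that("IC uses the BCPNN shrinkage form with a credible-interval criterion", {
  # raw (unshrunk) IC for the canonical table is log2(5)
  expect_equal(log2(10 * 1000 / (100 * 20)), log2(5))
  s <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                  c(10, 90, 10, 890))
  r <- detect(s, "IC")$results
  # shrinkage pulls the statistic toward 0 but keeps its sign
  expect_gt(r$statistic[1], 0)
  expect_lt(r$statistic[1], log2(5))
  expect_equal(r$statistic[1], oracle_ic(10, 90, 10, 890), tolerance = 1e-12)
  expect_equal(r$statistic[1] - r$interval_low[1],
               2 * oracle_ic_sd(10, 90, 10, 890), tolerance = 1e-12)

  # balanced table: IC exactly 0, no signal
  sb <- toy_sample(c("d1", "d1", "d2", "d2"), c("e1", "e2", "e1", "e2"),
                   c(7, 7, 7, 7))
  rb <- detect(sb, "IC")$results
  expect_equal(rb$statistic, rep(0, 4))
  expect_false(any(rb$signal))

  # monotonicity: with b, c, d fixed, increasing a never decreases IC while
  # a stays below the other margins (the regime where signals live; once a
  # dominates the table the observed/expected ratio decays back toward 1)
  ic_of <- function(a) {
    n <- a + 50 + 30 + 900
    log2((a + 0.5) / ((a + 50) * (a + 30) / n + 0.5))
  }
  vals <- vapply(1:30, ic_of, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("a planted disproportionate pair is the sole positive for all methods", {
  drugs <- rep(sprintf("d%d", 1:4), each = 4)
  adrs <- rep(sprintf("e%d", 1:4), times = 4)
  counts <- rep(10, 16)
  counts[1] <- 80  # (d1, e1) planted
  s <- toy_sample(drugs, adrs, counts)
  for (m in c("PRR", "ROR", "MHRA", "IC")) {
    run <- detect(s, m)
    expect_equal(nrow(run$positives), 1, info = m)
    expect_equal(run$positives$drug_name, "d1", info = m)
    expect_equal(run$positives$adr_name, "e1", info = m)
  }
})

test_that("detect matches a brute-force per-pair reimplementation", {
  for (seed in c(2, 8)) {
    s <- random_pair_sample(n_drugs = 6, n_adrs = 6, seed = seed, max_count = 25)
    runs <- lapply(c(PRR = "PRR", ROR = "ROR", MHRA = "MHRA", IC = "IC"),
                   function(m) detect(s, m))
    for (i in seq_len(nrow(s$pairs))) {
      t <- oracle_contingency(s, i)
      a <- t["a"]; b <- t["b"]; c <- t["c"]; d <- t["d"]
      chi2 <- if ((a + b) * (c + d) * (a + c) * (b + d) > 0)
        unname(oracle_chi2(a, b, c, d)) else NaN
      prr <- oracle_prr(a, b, c, d)
      expect_equal(runs$PRR$results$statistic[i], unname(prr))
      expect_equal(runs$PRR$results$signal[i],
                   unname(!is.nan(chi2) && a >= 3 && prr >= 2 && chi2 >= 4))
      expect_equal(runs$ROR$results$statistic[i],
                   unname(oracle_ror(a, b, c, d)))
      expect_equal(runs$MHRA$results$signal[i], runs$PRR$results$signal[i])
      expect_equal(runs$IC$results$statistic[i],
                   unname(oracle_ic(a, b, c, d)), tolerance = 1e-12)
      expect_equal(runs$IC$results$signal[i],
                   unname(oracle_ic(a, b, c, d) -
                            2 * oracle_ic_sd(a, b, c, d) > 0))
    }
    # repeated calls are identical (criterion purity)
    expect_identical(detect(s, "PRR")$results, runs$PRR$results)
  }
})

test_that("phi correlation of signal vectors behaves as the 2x2 phi", {
  ra <- fake_run(sprintf("d%d", 1:4), "e1", c(TRUE, TRUE, FALSE, FALSE))
  rb <- fake_run(sprintf("d%d", 1:4), "e1", c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(method_correlation(ra, ra), 1)
  expect_equal(method_correlation(ra, rb), 0)
  rc <- fake_run(sprintf("d%d", 1:4), "e1", rep(TRUE, 4))
  expect_warning(phi <- method_correlation(ra, rc), "constant")
  expect_true(is.nan(phi))
  rd <- fake_run(sprintf("d%d", 1:3), "e1", c(TRUE, FALSE, TRUE))
  expect_error(method_correlation(ra, rd), "universe")
})
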