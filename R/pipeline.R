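#' Full stratification-decision pipeline
#'
#' Chains ingest, detection on the total sample and the stratum, fourfold
#' comparison against the reference, indicator computation and the
#' decision tree. Every stage logs its in/out counts (via `message()`)
#' so the ingest funnel is auditable, and all stage outputs are pure
#' functions of the inputs and configuration: a rerun on identical inputs
#' writes byte-identical artifacts.
#'
#' @param reports raw report rows (data.frame in the multi-ADR or
#'   pre-split format) or a path to a reports CSV.
#' @param reference a [reference_db()] or a path to a reference CSV.
#' @param out_dir optional directory; when given, writes `pairs.csv`,
#'   `signals_<method>_<sample>.csv`, `fourfold_<method>.json`,
#'   `indicators.csv` and `decision.json` there.
#' @param stratum drug class to adjudicate (default `"TCM"`).
#' @param methods detection methods to evaluate (default PRR, MHRA, IC -
#'   ROR is near-duplicate of PRR on 0/1 calls and is omitted from the
#'   decision by default).
#' @param criteria a [detection_criteria()].
#' @param thresholds a [threshold_set()] or `"auto"`.
#' @param min_count minimum pair occurrence (default 3).
#' @param dedupe strict within-report de-duplication (default `FALSE`).
#' @param quiet suppress stage logging (default `FALSE`).
#' @return (invisibly) list with `total`, `stratum` (samples), `runs`,
#'   `fourfolds`, `indicator_sets`, `indicators` (table), `decisions`,
#'   and `record_summary`.
#' @export
run_pipeline <- function(reports, reference, out_dir = NULL, stratum = "TCM",
                         methods = c("PRR", "MHRA", "IC"),
                         criteria = detection_criteria(),
                         thresholds = "auto", min_count = 3,
                         dedupe = FALSE, quiet = FALSE) {
  log <- if (quiet) function(...) invisible() else function(...) message(sprintf(...))

  if (is.character(reports)) reports <- utils::read.csv(
    reports, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
    colClasses = "character")
  if (is.character(reference)) reference <- read_reference(reference)
  stopifnot(inherits(reference, "reference_db"))

  n_raw <- nrow(reports)
  records <- split_multi_adr(reports)
  log("split: %d raw rows -> %d single-ADR records", n_raw, nrow(records))
  n_in <- nrow(records)
  records <- filter_unknown(records)
  log("unknown filter: %d -> %d records", n_in, nrow(records))

  pairs <- aggregate_pairs(records, dedupe = dedupe)
  log("aggregation: %d records -> %d drug-ADR pairs", nrow(records), nrow(pairs))
  n_in <- nrow(pairs)
  pairs <- apply_pair_filters(pairs, reference, min_count = min_count)
  log("count>=%d and reference-drug filters: %d -> %d pairs",
      min_count, n_in, nrow(pairs))
  pairs <- annotate_known(pairs, reference)
  total <- pv_sample(pairs, "total", n_reports = nrow(records))
  log("total sample: %d pairs, %d known", nrow(pairs), sum(pairs$known))

  strat <- extract_stratum(total, stratum)
  log("%s stratum: %d pairs, %d known", stratum, nrow(strat$pairs),
      sum(strat$pairs$known))
  if (nrow(strat$pairs) == 0) stop("empty stratum after filtering")

  runs <- list()
  fourfolds <- list()
  indicator_sets <- list()
  for (m in methods) {
    runs[[m]] <- list(total = detect(total, m, criteria),
                      sub = detect(strat, m, criteria))
    log("%s: %d positives in total sample, %d in stratum", m,
        nrow(runs[[m]]$total$positives), nrow(runs[[m]]$sub$positives))
    fourfolds[[m]] <- build_fourfold(runs[[m]]$total, runs[[m]]$sub, strat)
    indicator_sets[[m]] <- indicators(fourfolds[[m]])
  }
  decisions <- decide_all(indicator_sets, thresholds = thresholds)
  log("verdicts: %s (consensus %s)",
      paste(vapply(decisions$outcomes, function(o)
        paste0(o$method, "=", o$verdict), character(1)), collapse = ", "),
      decisions$consensus)

  out <- list(total = total, stratum = strat, runs = runs,
              fourfolds = fourfolds, indicator_sets = indicator_sets,
              indicators = indicator_table(indicator_sets),
              decisions = decisions,
              record_summary = summarize_records(records))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pairs(total, file.path(out_dir, "pairs.csv"))
    for (m in methods) {
      write_signals(runs[[m]]$total,
                    file.path(out_dir, sprintf("signals_%s_total.csv", m)))
      write_signals(runs[[m]]$sub,
                    file.path(out_dir, sprintf("signals_%s_stratum.csv", m)))
      write_fourfold(fourfolds[[m]], file.path(out_dir, sprintf("fourfold_%s.json", m)))
    }
    utils::write.csv(out$indicators, file.path(out_dir, "indicators.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    write_decision(decisions, file.path(out_dir, "decision.json"))
  }
  invisible(out)
}
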