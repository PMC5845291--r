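#' Construct an analysis sample of drug-ADR pairs
#'
#' A sample bundles an annotated pair table with its label (`"total"` for
#' the whole database, `"stratum"` for a drug-class subset) and the number
#' of single-ADR records it was aggregated from.
#'
#' @param pairs pair table with columns `drug_name`, `drug_type`,
#'   `adr_name`, `count`, `known`.
#' @param label `"total"` or `"stratum"`.
#' @param n_reports record count before aggregation.
#' @return an object of class `pv_sample`.
#' @export
pv_sample <- function(pairs, label = c("total", "stratum"), n_reports = sum(pairs$count)) {
  label <- match.arg(label)
  stopifnot(is.data.frame(pairs),
            all(c("drug_name", "drug_type", "adr_name", "count", "known") %in% names(pairs)))
  if (nrow(pairs) > 0) {
    stopifnot(all(pairs$count >= 0),
              all(pairs$drug_type %in% DRUG_TYPES),
              !anyDuplicated(pair_key(pairs$drug_name, pairs$adr_name)))
  }
  structure(list(pairs = pairs, label = label, n_reports = n_reports),
            class = "pv_sample")
}

#' @export
print.pv_sample <- function(x, ...) {
  cat(sprintf(
    "<pv_sample: %s> %d drug-ADR pairs (%d drugs, %d ADRs), %s known; %d records\n",
    x$label, nrow(x$pairs), length(unique(x$pairs$drug_name)),
    length(unique(x$pairs$adr_name)),
    if (all(is.na(x$pairs$known))) "?" else sprintf("%d", sum(x$pairs$known)),
    x$n_reports
  ))
  invisible(x)
}

#' Full ingest chain: records to annotated total sample
#'
#' Aggregates filtered records to pairs, applies the minimum-count and
#' reference-drug filters, annotates known/unknown status and wraps the
#' result as the total sample.
#'
#' @param records filtered single-ADR report records
#'   (see [filter_unknown()]).
#' @param refdb a [reference_db()].
#' @param min_count minimum occurrence (default 3).
#' @param dedupe strict within-report de-duplication (default `FALSE`),
#'   see [aggregate_pairs()].
#' @return a `pv_sample` labelled `"total"`.
#' @export
build_total_sample <- function(records, refdb, min_count = 3, dedupe = FALSE) {
  pairs <- aggregate_pairs(records, dedupe = dedupe)
  pairs <- apply_pair_filters(pairs, refdb, min_count = min_count)
  pairs <- annotate_known(pairs, refdb)
  pv_sample(pairs, "total", n_reports = nrow(records))
}

#' Extract a drug-class stratum from the total sample
#'
#' Returns the pairs whose `drug_type` matches, labelled as a stratum.
#' The stratum's pair set is by construction a subset of the total's; the
#' union of the three drug-type strata reconstitutes the total exactly.
#'
#' @param total an annotated, filtered `pv_sample`.
#' @param drug_type one of `"TCM"`, `"western"`, `"biological"`.
#' @return a `pv_sample` labelled `"stratum"`.
#' @export
extract_stratum <- function(total, drug_type) {
  stopifnot(inherits(total, "pv_sample"))
  drug_type <- match.arg(drug_type, DRUG_TYPES)
  sub <- total$pairs[total$pairs$drug_type == drug_type, , drop = FALSE]
  rownames(sub) <- NULL
  pv_sample(sub, "stratum", n_reports = sum(sub$count))
}

#' Write a sample's pair table to CSV
#' @param sample a `pv_sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(sample, path) {
  utils::write.csv(sample$pairs, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
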