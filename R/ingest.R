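#' Split one-drug-to-many-ADR rows into single-ADR records
#'
#' Spontaneous reports frequently link one drug to several ADRs. Each raw
#' row is expanded into one record per ADR; all scalar fields are copied
#' unchanged. Rows whose ADR list is empty (after trimming) are dropped
#' with a warning rather than aborting the ingest.
#'
#' @param rows data.frame with columns `report_id`, `drug_name`,
#'   `drug_type` and either `adr_names` (delimited list) or `adr_name`,
#'   plus `serious` (0/1 or logical).
#' @param sep delimiter inside `adr_names` (default `";"`).
#' @return data.frame of report records, one row per (report, ADR):
#'   columns `report_id`, `drug_name`, `drug_type`, `adr_name`, `serious`.
#' @export
#' @examples
#' raw <- data.frame(report_id = "r1", drug_name = "d1", drug_type = "TCM",
#'                   adr_names = "rash;nausea;fever", serious = 0)
#' split_multi_adr(raw)  # 3 records
split_multi_adr <- function(rows, sep = ";") {
  stopifnot(is.data.frame(rows))
  need <- c("report_id", "drug_name", "drug_type", "serious")
  if (!all(need %in% names(rows)) ||
      !any(c("adr_name", "adr_names") %in% names(rows))) {
    stop("malformed report rows: expected columns report_id, drug_name, ",
         "drug_type, adr_name(s), serious")
  }
  adr_col <- if ("adr_names" %in% names(rows)) "adr_names" else "adr_name"
  lists <- strsplit(as.character(rows[[adr_col]]), sep, fixed = TRUE)
  lists <- lapply(lists, function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  n_adr <- lengths(lists)
  if (any(n_adr == 0)) {
    warning(sprintf("dropped %d row(s) with an empty ADR list", sum(n_adr == 0)))
  }
  keep <- which(n_adr > 0)
  idx <- rep(keep, n_adr[keep])
  out <- data.frame(
    report_id = as.character(rows$report_id)[idx],
    drug_name = as.character(rows$drug_name)[idx],
    drug_type = as.character(rows$drug_type)[idx],
    adr_name  = unlist(lists[keep], use.names = FALSE),
    serious   = as_serious(rows$serious)[idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

as_serious <- function(x) {
  if (is.logical(x)) return(x)
  as.character(x) %in% c("1", "TRUE", "true")
}

#' Drop records with sentinel drug or ADR names
#'
#' Records whose drug or ADR name is empty or matches a sentinel (default
#' `"unknown"`) are excluded. Matching trims whitespace and ignores case,
#' so `"  Unknown "` is dropped under the defaults. Idempotent.
#'
#' @param records report records as produced by [split_multi_adr()].
#' @param sentinels character vector of names to exclude; the empty string
#'   catches missing names.
#' @return the surviving records, order preserved.
#' @export
filter_unknown <- function(records, sentinels = c("unknown", "")) {
  norm <- function(x) tolower(trimws(x))
  bad <- norm(records$drug_name) %in% norm(sentinels) |
    norm(records$adr_name) %in% norm(sentinels)
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate records to drug-ADR pairs with occurrence counts
#'
#' Groups records by (drug_name, adr_name) and counts occurrences; the sum
#' of counts equals the number of input records. Pairs appear in order of
#' first appearance. Duplicate (report_id, drug, ADR) rows count as
#' distinct occurrences unless `dedupe = TRUE` (strict mode), since no
#' within-report de-duplication rule is assumed by default.
#'
#' @param records filtered report records.
#' @param dedupe logical; drop exact (report_id, drug_name, adr_name)
#'   duplicates before counting (default `FALSE`).
#' @return data.frame of pairs: `drug_name`, `drug_type`, `adr_name`,
#'   `count`, `known` (initialised `NA`, set by [annotate_known()]).
#' @export
aggregate_pairs <- function(records, dedupe = FALSE) {
  if (dedupe) {
    records <- records[!duplicated(records[c("report_id", "drug_name", "adr_name")]), ,
                       drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(data.frame(drug_name = character(), drug_type = character(),
                      adr_name = character(), count = integer(),
                      known = logical(), stringsAsFactors = FALSE))
  }
  key <- pair_key(records$drug_name, records$adr_name)
  first <- !duplicated(key)
  grp <- match(key, key[first])  # group ids in first-appearance order
  counts <- as.integer(rowsum(rep(1L, length(grp)), grp))
  out <- data.frame(
    drug_name = records$drug_name[first],
    drug_type = records$drug_type[first],
    adr_name  = records$adr_name[first],
    count     = counts,
    known     = NA,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Minimum-count and reference-drug filters
#'
#' Keeps pairs with `count >= min_count` whose drug appears in the
#' reference database. The two filters are row-local, hence
#' order-independent; they are applied in one pass and the input order is
#' preserved.
#'
#' @param pairs pair table from [aggregate_pairs()].
#' @param refdb a [reference_db()].
#' @param min_count minimum occurrence accepted in signal detection
#'   (default 3, the convention for spontaneous-report mining).
#' @return the surviving pairs.
#' @export
apply_pair_filters <- function(pairs, refdb, min_count = 3) {
  stopifnot(inherits(refdb, "reference_db"), min_count >= 1)
  keep <- pairs$count >= min_count & pairs$drug_name %in% ref_drugs(refdb)
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0) message("no pairs survive the count/reference filters")
  rownames(out) <- NULL
  out
}

#' Annotate pairs with known/unknown status
#'
#' Sets `known = TRUE` exactly for pairs present in the reference
#' database. No pair is added or removed; idempotent.
#'
#' @param pairs pair table.
#' @param refdb a [reference_db()].
#' @return `pairs` with the `known` column populated.
#' @export
annotate_known <- function(pairs, refdb) {
  stopifnot(inherits(refdb, "reference_db"))
  pairs$known <- pair_key(pairs$drug_name, pairs$adr_name) %in% ref_keys(refdb)
  pairs
}

#' Read raw spontaneous reports from CSV
#'
#' Accepts either pre-split files (header
#' `report_id,drug_name,drug_type,adr_name,serious`) or multi-ADR files
#' where `adr_name` is replaced by a delimited `adr_names` column; the
#' latter are routed through [split_multi_adr()]. UTF-8 throughout (drug
#' names may be Chinese characters).
#'
#' @param path file path.
#' @param sep_adr delimiter of the `adr_names` column (default `";"`).
#' @return data.frame of single-ADR report records.
#' @export
read_reports <- function(path, sep_adr = ";") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", colClasses = "character")
  need <- c("report_id", "drug_name", "drug_type", "serious")
  if (!all(need %in% names(raw)) ||
      !any(c("adr_name", "adr_names") %in% names(raw))) {
    stop("malformed reports file: expected columns report_id, drug_name, ",
         "drug_type, adr_name(s), serious in ", path)
  }
  bad_type <- setdiff(unique(raw$drug_type), DRUG_TYPES)
  if (length(bad_type)) {
    stop("unknown drug_type value(s): ", paste(bad_type, collapse = ", "))
  }
  split_multi_adr(raw, sep = sep_adr)
}

#' Per-stratum record and seriousness summary
#'
#' Descriptive tallies of the ingest: record and serious-record counts per
#' drug class. The seriousness flag is carried through ingest but plays no
#' role in detection or the decision.
#'
#' @param records report records.
#' @return data.frame with one row per drug type plus a `total` row.
#' @export
summarize_records <- function(records) {
  types <- intersect(DRUG_TYPES, unique(records$drug_type))
  rows <- lapply(c(types, "total"), function(tp) {
    sel <- if (tp == "total") rep(TRUE, nrow(records)) else records$drug_type == tp
    data.frame(drug_type = tp,
               n_records = sum(sel),
               n_serious = sum(records$serious[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
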