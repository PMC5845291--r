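#' Reference database of known drug-ADR associations
#'
#' The evaluation standard for signal detection: a curated set of
#' (drug, ADR) pairs known to be associated, typically extracted from drug
#' product labeling. Duplicate rows are collapsed; names are trimmed.
#'
#' @param pairs data.frame with character columns `drug_name` and
#'   `adr_name`.
#' @return an object of class `reference_db` with element `pairs`
#'   (a de-duplicated data.frame).
#' @seealso [read_reference()], [annotate_known()], [apply_pair_filters()]
#' @export
#' @examples
#' ref <- reference_db(data.frame(
#'   drug_name = c("d1", "d1", "d2"),
#'   adr_name  = c("rash", "rash", "nausea")))
#' nrow(ref$pairs)  # 2: the duplicate is dropped
reference_db <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("drug_name", "adr_name") %in% names(pairs))) {
    stop("reference pairs need columns 'drug_name' and 'adr_name'")
  }
  pairs <- data.frame(
    drug_name = trimws(as.character(pairs$drug_name)),
    adr_name  = trimws(as.character(pairs$adr_name)),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(pairs$drug_name)) || any(!nzchar(pairs$adr_name))) {
    stop("reference pairs must have non-empty drug and ADR names")
  }
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "reference_db")
}

#' Drugs covered by a reference database
#' @param ref a [reference_db()] object.
#' @return character vector of distinct drug names.
#' @export
ref_drugs <- function(ref) unique(ref$pairs$drug_name)

#' ADR terms covered by a reference database
#' @param ref a [reference_db()] object.
#' @return character vector of distinct ADR names.
#' @export
ref_adrs <- function(ref) unique(ref$pairs$adr_name)

ref_keys <- function(ref) pair_key(ref$pairs$drug_name, ref$pairs$adr_name)

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(
    "<reference_db> %d known drug-ADR pairs (%d drugs, %d ADRs)\n",
    nrow(x$pairs), length(ref_drugs(x)), length(ref_adrs(x))
  ))
  invisible(x)
}

#' Read a reference database from CSV
#'
#' Expects a UTF-8 CSV with header `drug_name,adr_name`.
#'
#' @param path file path.
#' @return a [reference_db()] object.
#' @export
read_reference <- function(path) {
  reference_db(utils::read.csv(path, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8",
                               colClasses = "character"))
}

#' Write a reference database to CSV
#' @param ref a [reference_db()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(ref$pairs, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
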