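#' Indicator thresholds for the stratification decision tree
#'
#' @param Rt,Pt,Dt strictly positive thresholds as proportions
#'   (e.g. `0.02` for 2%).
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(Rt, Pt, Dt) {
  stopifnot(Rt > 0, Pt > 0, Dt > 0)
  structure(list(Rt = Rt, Pt = Pt, Dt = Dt), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> Rt = %s, Pt = %s, Dt = %s\n",
              format_percent(x$Rt, 0), format_percent(x$Pt, 0),
              format_percent(x$Dt, 0)))
  invisible(x)
}

# Smallest integer strictly greater than x (percent scale); rounding at
# 1e-9 guards against FP noise on exact integers.
int_above <- function(x) floor(round(x, 9)) + 1

#' Derive decision thresholds from per-method indicator differences
#'
#' Each threshold is "an integer percent slightly larger than the mean":
#' for R the mean over methods of `|R1 - R2|`, for P of `|P1 - P2|`, and
#' for D of the discrepancy values themselves, each taken to the next
#' integer percent under a strictly-greater rule (a mean that is already
#' an integer percent steps up by 1).
#'
#' @param indicator_sets non-empty list of [indicators()] results.
#' @return a [threshold_set()] in proportion units.
#' @export
derive_thresholds <- function(indicator_sets) {
  if (length(indicator_sets) < 1) stop("at least one indicator set is required")
  g <- function(fn) mean(vapply(indicator_sets, fn, numeric(1))) * 100
  threshold_set(
    Rt = int_above(g(function(s) abs(s$R1 - s$R2))) / 100,
    Pt = int_above(g(function(s) abs(s$P1 - s$P2))) / 100,
    Dt = int_above(g(function(s) s$D)) / 100
  )
}

#' Stratification decision for one method's indicators
#'
#' Walks the three-branch decision tree with strict comparisons:
#'
#' 1. `R1 - R2 > Rt` recommends against separate analysis
#'    (non-separation); `R2 - R1 > Rt` recommends separation; a slight
#'    difference falls through.
#' 2. The same rule on precision with `Pt`.
#' 3. Otherwise the discrepancy decides: `D > Dt` yields non-separation,
#'    else separation.
#'
#' The direction of the final branch follows the published rule (large
#' known-signal disagreement blocks separation); set
#' `d_branch_inverted = TRUE` to flip it for sensitivity analysis.
#'
#' @param ind an [indicators()] set.
#' @param th a [threshold_set()].
#' @param d_branch_inverted flip the discrepancy branch (default
#'   `FALSE`).
#' @return an object of class `decision_outcome`: `method`, `verdict`
#'   (`"separation"` or `"non_separation"`), `path` (data.frame of the
#'   branches visited: indicator, difference, threshold, branch) and
#'   `thresholds`.
#' @export
decide <- function(ind, th, d_branch_inverted = FALSE) {
  stopifnot(inherits(ind, "indicator_set"), inherits(th, "threshold_set"))
  step <- function(indicator, difference, threshold, branch) {
    data.frame(indicator = indicator, difference = difference,
               threshold = threshold, branch = branch,
               stringsAsFactors = FALSE)
  }
  path <- NULL
  verdict <- NULL

  dR <- ind$R1 - ind$R2
  if (dR > th$Rt) {
    path <- step("R", dR, th$Rt, "non_separation"); verdict <- "non_separation"
  } else if (-dR > th$Rt) {
    path <- step("R", dR, th$Rt, "separation"); verdict <- "separation"
  } else {
    path <- step("R", dR, th$Rt, "continue")
    dP <- ind$P1 - ind$P2
    if (dP > th$Pt) {
      path <- rbind(path, step("P", dP, th$Pt, "non_separation"))
      verdict <- "non_separation"
    } else if (-dP > th$Pt) {
      path <- rbind(path, step("P", dP, th$Pt, "separation"))
      verdict <- "separation"
    } else {
      path <- rbind(path, step("P", dP, th$Pt, "continue"))
      d_high <- ind$D > th$Dt
      if (d_branch_inverted) d_high <- !d_high
      verdict <- if (d_high) "non_separation" else "separation"
      path <- rbind(path, step("D", ind$D, th$Dt, verdict))
    }
  }
  structure(list(method = ind$method, verdict = verdict,
                 path = path, thresholds = th),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat(sprintf("<decision_outcome%s> verdict: %s\n",
              if (is.na(x$method)) "" else paste0(": ", x$method), x$verdict))
  for (i in seq_len(nrow(x$path))) {
    p <- x$path[i, ]
    cat(sprintf("  %s: difference %s vs threshold %s -> %s\n",
                p$indicator, format_percent(p$difference),
                format_percent(p$threshold, 0), p$branch))
  }
  invisible(x)
}

#' Decide for every method and summarise the consensus
#'
#' With `thresholds = "auto"`, thresholds are first derived from the same
#' indicator sets being judged ([derive_thresholds()]); this circularity
#' matches the published procedure and user-supplied thresholds are
#' supported instead.
#'
#' @param indicator_sets non-empty list of [indicators()] results.
#' @param thresholds a [threshold_set()] or `"auto"`.
#' @param ... passed to [decide()] (e.g. `d_branch_inverted`).
#' @return an object of class `decision_set`: `outcomes` (list of
#'   [decide()] results), `thresholds`, `consensus` (the unanimous
#'   verdict, or `"split"`) and `tally`.
#' @export
decide_all <- function(indicator_sets, thresholds = "auto", ...) {
  if (length(indicator_sets) < 1) stop("at least one indicator set is required")
  if (identical(thresholds, "auto")) thresholds <- derive_thresholds(indicator_sets)
  outcomes <- lapply(indicator_sets, decide, th = thresholds, ...)
  verdicts <- vapply(outcomes, function(o) o$verdict, character(1))
  tally <- c(separation = sum(verdicts == "separation"),
             non_separation = sum(verdicts == "non_separation"))
  consensus <- if (length(unique(verdicts)) == 1) verdicts[[1]] else "split"
  structure(list(outcomes = outcomes, thresholds = thresholds,
                 consensus = consensus, tally = tally),
            class = "decision_set")
}

#' @export
print.decision_set <- function(x, ...) {
  print(x$thresholds)
  for (o in x$outcomes) print(o)
  cat(sprintf("consensus: %s (%d separation : %d non-separation)\n",
              x$consensus, x$tally[["separation"]], x$tally[["non_separation"]]))
  invisible(x)
}

#' Write a decision set as JSON
#' @param dec a `decision_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decision <- function(dec, path) {
  payload <- list(
    thresholds = unclass(dec$thresholds),
    consensus = dec$consensus,
    tally = as.list(dec$tally),
    outcomes = lapply(dec$outcomes, function(o) {
      list(method = o$method, verdict = o$verdict, path = o$path)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
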