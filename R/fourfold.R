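#' Fourfold comparison of two detection runs against a reference
#'
#' Cross-tabulates the positive/negative calls of the total-sample run
#' (rows) and the stratum run (columns) over the stratum's pair universe:
#' `a` = positive in both, `b` = total-only, `c` = stratum-only, `d` =
#' neither. Each cell splits into reference-known (`*1`) and unknown
#' (`*0`) parts; the constructor takes the eight split cells and derives
#' the totals, so the split invariants hold by construction.
#'
#' @param a1,a0,b1,b0,c1,c0,d1,d0 non-negative integer split cells.
#' @param method detection method label carried along for reporting.
#' @return an object of class `fourfold` with the 12 cells,
#'   `universe_size` and `known_total`.
#' @seealso [build_fourfold()], [indicators()]
#' @export
fourfold <- function(a1, a0, b1, b0, c1, c0, d1, d0, method = NA_character_) {
  cells <- c(a1 = a1, a0 = a0, b1 = b1, b0 = b0,
             c1 = c1, c0 = c0, d1 = d1, d0 = d0)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  f <- list(method = method,
            a = a1 + a0, a1 = a1, a0 = a0,
            b = b1 + b0, b1 = b1, b0 = b0,
            c = c1 + c0, c1 = c1, c0 = c0,
            d = d1 + d0, d1 = d1, d0 = d0)
  f$universe_size <- f$a + f$b + f$c + f$d
  f$known_total <- f$a1 + f$b1 + f$c1 + f$d1
  structure(f, class = "fourfold")
}

#' @export
print.fourfold <- function(x, ...) {
  cat(sprintf("<fourfold%s> universe %d pairs, %d known\n",
              if (is.na(x$method)) "" else paste0(": ", x$method),
              x$universe_size, x$known_total))
  cat(sprintf("  a=%d (a1=%d, a0=%d)  b=%d (b1=%d, b0=%d)\n",
              x$a, x$a1, x$a0, x$b, x$b1, x$b0))
  cat(sprintf("  c=%d (c1=%d, c0=%d)  d=%d (d1=%d, d0=%d)\n",
              x$c, x$c1, x$c0, x$d, x$d1, x$d0))
  invisible(x)
}

#' Build the fourfold comparison from two detection runs
#'
#' The comparison universe is the stratum's pair set: the stratum run
#' must cover it exactly, and total-run positives outside it are ignored.
#' Known/unknown splits come from the universe's `known` flags.
#'
#' @param total_run `detection_run` on the total sample.
#' @param sub_run `detection_run` on the stratum.
#' @param universe the stratum [pv_sample()] (annotated).
#' @return a [fourfold()] object labelled with `sub_run`'s method.
#' @export
build_fourfold <- function(total_run, sub_run, universe) {
  stopifnot(inherits(total_run, "detection_run"),
            inherits(sub_run, "detection_run"),
            inherits(universe, "pv_sample"))
  uk <- pair_key(universe$pairs$drug_name, universe$pairs$adr_name)
  sk <- run_keys(sub_run)
  if (length(sk) != length(uk) || !setequal(sk, uk)) {
    stop("stratum run does not cover the comparison universe")
  }
  if (!all(uk %in% run_keys(total_run))) {
    stop("total-sample run does not cover the comparison universe")
  }
  in_total <- uk %in% positive_keys(total_run)
  in_sub <- uk %in% positive_keys(sub_run)
  kn <- universe$pairs$known
  stopifnot(!anyNA(kn))
  fourfold(
    a1 = sum(in_total & in_sub & kn),   a0 = sum(in_total & in_sub & !kn),
    b1 = sum(in_total & !in_sub & kn),  b0 = sum(in_total & !in_sub & !kn),
    c1 = sum(!in_total & in_sub & kn),  c0 = sum(!in_total & in_sub & !kn),
    d1 = sum(!in_total & !in_sub & kn), d0 = sum(!in_total & !in_sub & !kn),
    method = sub_run$method
  )
}

#' Recall ratio of a detection run against the reference
#'
#' Fraction of the universe's reference-known pairs recovered: for the
#' total sample `(a1 + b1) / known_total`, for the stratum
#' `(a1 + c1) / known_total`.
#'
#' @param f a [fourfold()].
#' @param which `"total"` or `"sub"`.
#' @return a proportion in `[0, 1]`.
#' @export
recall <- function(f, which = c("total", "sub")) {
  which <- match.arg(which)
  if (f$known_total == 0) stop("no known pairs in the comparison universe")
  if (which == "total") (f$a1 + f$b1) / f$known_total
  else (f$a1 + f$c1) / f$known_total
}

#' Precision ratio of a detection run against the reference
#'
#' Fraction of a run's positive signals that are reference-known: for the
#' total sample `(a1 + b1) / (a + b)`, for the stratum
#' `(a1 + c1) / (a + c)`.
#'
#' @inheritParams recall
#' @return a proportion in `[0, 1]`.
#' @export
precision <- function(f, which = c("total", "sub")) {
  which <- match.arg(which)
  if (which == "total") {
    if (f$a + f$b == 0) stop("total run has no positive signals: precision undefined")
    (f$a1 + f$b1) / (f$a + f$b)
  } else {
    if (f$a + f$c == 0) stop("stratum run has no positive signals: precision undefined")
    (f$a1 + f$c1) / (f$a + f$c)
  }
}

#' Discrepancy ratio of the two detection runs
#'
#' `|b1 - c1| / (b + c)`: the known-signal disagreement relative to all
#' discordant calls. With no discordant calls at all the ratio is defined
#' as 0 (no disagreement means no diversity), with a warning.
#'
#' @param f a [fourfold()].
#' @return a proportion in `[0, 1]`.
#' @export
discrepancy <- function(f) {
  if (f$b + f$c == 0) {
    warning("no discordant calls between the runs; discrepancy set to 0")
    return(0)
  }
  abs(f$b1 - f$c1) / (f$b + f$c)
}

#' All five evaluation indicators of a fourfold comparison
#'
#' Computes the recall pair (R1 total, R2 stratum), the precision pair
#' (P1, P2) and the discrepancy D. All arithmetic is exact on the integer
#' cells; percent rendering (half-up, 2 decimals) is applied only for
#' display.
#'
#' @param f a [fourfold()].
#' @param method label (defaults to `f`'s method).
#' @return an object of class `indicator_set` with elements `method`,
#'   `R1`, `R2`, `P1`, `P2`, `D` (raw proportions).
#' @export
indicators <- function(f, method = f$method) {
  structure(list(method = method,
                 R1 = recall(f, "total"), R2 = recall(f, "sub"),
                 P1 = precision(f, "total"), P2 = precision(f, "sub"),
                 D = discrepancy(f)),
            class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  cat(sprintf("<indicator_set%s>\n",
              if (is.na(x$method)) "" else paste0(": ", x$method)))
  cat(sprintf("  recall     R1 = %s  R2 = %s  (R1-R2 = %s)\n",
              format_percent(x$R1), format_percent(x$R2),
              format_percent(x$R1 - x$R2)))
  cat(sprintf("  precision  P1 = %s  P2 = %s  (P1-P2 = %s)\n",
              format_percent(x$P1), format_percent(x$P2),
              format_percent(x$P1 - x$P2)))
  cat(sprintf("  discrepancy D = %s\n", format_percent(x$D)))
  invisible(x)
}

#' Tabulate indicator sets
#'
#' @param indicator_sets list of [indicators()] results.
#' @param percent render values as half-up percents at 2 decimals
#'   (default `FALSE`: raw proportions).
#' @return data.frame with columns `method`, `R1`, `R2`, `P1`, `P2`, `D`.
#' @export
indicator_table <- function(indicator_sets, percent = FALSE) {
  rows <- lapply(indicator_sets, function(s) {
    v <- c(s$R1, s$R2, s$P1, s$P2, s$D)
    if (percent) v <- as_percent(v)
    data.frame(method = s$method, R1 = v[1], R2 = v[2],
               P1 = v[3], P2 = v[4], D = v[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a fourfold comparison as JSON
#' @param f a [fourfold()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fourfold <- function(f, path) {
  jsonlite::write_json(unclass(f), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
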