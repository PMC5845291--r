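#' Worked-example fourfold tables from a nationwide TCM analysis
#'
#' Fourfold comparison cells from a published two-year nationwide
#' spontaneous-report analysis in which the Traditional Chinese Medicine
#' stratum (4697 drug-ADR pairs, 830 of them reference-known) was
#' detected both inside the pooled database and on its own, with PRR, the
#' MHRA criteria and the information component. They serve as a frozen
#' worked example for the evaluation and decision stages.
#'
#' @return named list of three [fourfold()] objects (`PRR`, `MHRA`,
#'   `IC`), each with `universe_size` 4697 and `known_total` 830.
#' @export
#' @examples
#' ff <- tcm_fourfolds()
#' as_percent(recall(ff$PRR, "total"))  # 72.41
tcm_fourfolds <- function() {
  list(
    PRR = fourfold(a1 = 561, a0 = 1327, b1 = 40, b0 = 290,
                   c1 = 34, c0 = 287, d1 = 195, d0 = 1963, method = "PRR"),
    MHRA = fourfold(a1 = 456, a0 = 1032, b1 = 56, b0 = 292,
                    c1 = 48, c0 = 284, d1 = 270, d0 = 2259, method = "MHRA"),
    IC = fourfold(a1 = 274, a0 = 305, b1 = 43, b0 = 130,
                  c1 = 31, c0 = 50, d1 = 482, d0 = 3382, method = "IC")
  )
}

#' Reproduce the worked example's decision table
#'
#' Runs the evaluation and decision stages on the bundled
#' [tcm_fourfolds()]: the five indicators per method, the (auto-derived
#' or supplied) thresholds, and the per-method verdicts with consensus.
#'
#' @param thresholds a [threshold_set()] or `"auto"` (default).
#' @return list with `indicators` (raw-proportion table),
#'   `indicators_percent` (half-up 2-decimal rendering) and `decisions`
#'   (a [decide_all()] result).
#' @export
tcm_decision_table <- function(thresholds = "auto") {
  inds <- lapply(tcm_fourfolds(), indicators)
  dec <- decide_all(inds, thresholds = thresholds)
  list(indicators = indicator_table(inds),
       indicators_percent = indicator_table(inds, percent = TRUE),
       decisions = dec)
}
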