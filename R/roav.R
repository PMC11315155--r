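#' Relative odor activity values
#'
#' `ROAV = C / T`: the semi-quantified concentration of a compound divided
#' by its odor threshold in the tasting medium. Values above 1 mark
#' compounds whose concentration exceeds what a human nose can detect, the
#' standard screen for key odorants. One record is produced per
#' (wine, compound) that has both a detected concentration and a known
#' threshold; detected compounds whose thresholds have not been described
#' are unevaluable and reported separately (see [unevaluable_compounds()]).
#'
#' @param matrix Long concentration matrix (`wine`, `compound_id`, `mean`).
#' @param thresholds Threshold table (`compound_id`, `threshold_ug_per_L`);
#'   thresholds must be positive, absent thresholds are `NA`.
#' @return Tibble of ROAV records (`wine`, `compound_id`, `concentration`,
#'   `threshold`, `roav`, `is_key`), with the unevaluable compounds attached
#'   as an attribute. `is_key` uses the strict cutoff `roav > 1`.
#' @export
compute_roav <- function(matrix, thresholds) {
  if (any(thresholds$threshold_ug_per_L <= 0, na.rm = TRUE)) {
    abort("odor thresholds must be positive", class = "aromakit_domain_error")
  }
  joined <- matrix |>
    dplyr::left_join(thresholds[, c("compound_id", "threshold_ug_per_L")], by = "compound_id")
  evaluable <- !is.na(joined$threshold_ug_per_L)
  records <- joined[evaluable, , drop = FALSE] |>
    dplyr::transmute(
      .data$wine,
      .data$compound_id,
      concentration = .data$mean,
      threshold = .data$threshold_ug_per_L,
      roav = .data$mean / .data$threshold_ug_per_L,
      is_key = .data$roav > 1
    )
  attr(records, "unevaluable") <-
    sort(unique(joined$compound_id[!evaluable]))
  records
}

#' @rdname compute_roav
#' @param records ROAV records.
#' @export
unevaluable_compounds <- function(records) attr(records, "unevaluable")

#' Select key odorants per wine
#'
#' Key odorants are compounds whose ROAV strictly exceeds the cutoff
#' (default 1). Comparison uses the unrounded ROAV; reported values are
#' conventionally rounded to two decimals for display only.
#'
#' @param records ROAV records from [compute_roav()].
#' @param cutoff Positive ROAV cutoff; strict inequality.
#' @return Named list (one element per wine) of tibbles sorted by
#'   decreasing ROAV.
#' @export
select_key_odorants <- function(records, cutoff = 1) {
  stopifnot(cutoff > 0)
  keys <- records[records$roav > cutoff, , drop = FALSE]
  keys <- keys[order(keys$wine, -keys$roav), , drop = FALSE]
  out <- split(keys[, c("compound_id", "roav")], keys$wine)
  lapply(out, tibble::as_tibble)
}

#' Format ROAV records the way reference tables print them
#'
#' Rounds half-up to two decimals and renders sub-threshold values as
#' `"<1"`, mirroring the usual presentation of odor-activity tables.
#'
#' @param records ROAV records.
#' @export
format_roav <- function(records) {
  records$printed <- ifelse(
    records$roav < 1, "<1",
    formatC(round_half_up(records$roav, 2), format = "f", digits = 2)
  )
  records
}
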