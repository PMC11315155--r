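#' Internal-standard configuration
#'
#' The internal standard (2-octanol in the reference panel) is spiked into
#' every vial at a known final concentration; analyte concentrations are
#' estimated from the analyte/IS peak-area ratio.
#'
#' @param name Compound name of the internal standard.
#' @param final_concentration Spiked final concentration, micrograms per litre.
#' @export
is_config <- function(name = "2-octanol", final_concentration = 328.8) {
  stopifnot(is.numeric(final_concentration), final_concentration > 0)
  structure(list(name = name, final_concentration = final_concentration),
            class = "aroma_is_config")
}

#' Internal-standard semi-quantification
#'
#' For each annotated analyte peak, `C = (A_c / A_is) * C_is`, where `A_c`
#' is the analyte peak area, `A_is` the internal-standard peak area of the
#' same replicate injection, and `C_is` the spiked IS concentration. The
#' ratio makes the estimate invariant to injection-to-injection sensitivity
#' changes that scale all areas of a replicate equally.
#'
#' @param peaks Annotated peak table; every replicate must contain exactly
#'   one internal-standard peak.
#' @param is_config An [is_config()].
#' @return Tibble of concentration records (`sample_id`, `compound_id`,
#'   `concentration` in ug/L).
#' @export
semi_quantify <- function(peaks, is_config = aromakit::is_config()) {
  stopifnot(inherits(is_config, "aroma_is_config"))
  is_rows <- peaks[peaks$is_internal_standard, , drop = FALSE]
  analytes <- peaks[!peaks$is_internal_standard & !is.na(peaks$compound_id), , drop = FALSE]
  missing_is <- setdiff(unique(analytes$sample_id), is_rows$sample_id)
  if (length(missing_is)) {
    abort(
      paste0("replicate(s) lacking an internal-standard peak: ",
             paste(missing_is, collapse = ", ")),
      class = "aromakit_quantification_error"
    )
  }
  ais <- stats::setNames(is_rows$peak_area, is_rows$sample_id)
  tibble::tibble(
    sample_id = analytes$sample_id,
    compound_id = analytes$compound_id,
    concentration = analytes$peak_area / unname(ais[analytes$sample_id]) *
      is_config$final_concentration
  )
}

#' Aggregate replicate concentrations to a wine-level matrix
#'
#' Per (wine, compound): mean and sample standard deviation over the
#' replicates in which the compound was detected. A compound detected in a
#' single replicate is still reported (SD 0, flagged `low_support`); a
#' compound detected in no replicate of a wine is a missing cell (absent
#' row), never zero.
#'
#' @param records Concentration records from [semi_quantify()].
#' @param meta Sample metadata mapping `sample_id` to `wine_label`.
#' @return Long-format concentration matrix: `wine`, `compound_id`, `mean`,
#'   `sd`, `n_replicates`, `low_support`.
#' @export
aggregate_replicates <- function(records, meta) {
  records |>
    dplyr::inner_join(meta[, c("sample_id", "wine_label")], by = "sample_id") |>
    dplyr::group_by(wine = .data$wine_label, .data$compound_id) |>
    dplyr::summarise(
      mean = mean(.data$concentration),
      sd = if (dplyr::n() > 1) stats::sd(.data$concentration) else 0,
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(low_support = .data$n_replicates < 2L)
}

#' Chemical-class totals per wine
#'
#' Sums mean concentrations over each chemical class (acids, alcohols,
#' aldehydes, esters, other). Missing cells contribute zero, matching the
#' convention of per-class totals that sum only detected compounds; classes
#' with no detected member in a wine get an explicit zero row.
#'
#' @param matrix Long concentration matrix ([aggregate_replicates()] or the
#'   `concentrations` element of [load_paper_fixture()]).
#' @param library Compound library supplying `chem_class`.
#' @return Tibble `wine`, `chem_class`, `total`.
#' @export
class_totals <- function(matrix, library) {
  unclassified <- setdiff(unique(matrix$compound_id), library$compound_id)
  if (length(unclassified)) {
    abort(paste0("compound(s) without a chemical class: ",
                 paste(unclassified, collapse = ", ")),
          class = "aromakit_classification_error")
  }
  matrix |>
    dplyr::inner_join(library[, c("compound_id", "chem_class")], by = "compound_id") |>
    dplyr::group_by(.data$wine, .data$chem_class) |>
    dplyr::summarise(total = sum(.data$mean), .groups = "drop") |>
    tidyr::complete(
      wine = unique(matrix$wine),
      chem_class = sort(unique(library$chem_class)),
      fill = list(total = 0)
    )
}

#' Presence/absence sets of detected compounds per group
#'
#' A compound is "present" in a group iff it is detected (non-missing) in at
#' least one wine of that group. Returns the per-group sets together with
#' the cardinalities of all exclusive Venn regions (compounds present in
#' exactly that combination of groups), the data behind Venn diagrams of
#' shared and unique aroma compounds.
#'
#' @param matrix Long concentration matrix.
#' @param grouping Named character vector mapping wine -> group.
#' @return List with `sets` (named list of compound id vectors) and
#'   `regions` (tibble `groups`, `n`, `compounds`).
#' @export
presence_sets <- function(matrix, grouping) {
  matrix <- matrix[matrix$wine %in% names(grouping), , drop = FALSE]
  groups <- sort(unique(unname(grouping)))
  sets <- lapply(groups, function(g) {
    sort(unique(matrix$compound_id[grouping[matrix$wine] == g]))
  })
  names(sets) <- groups
  all_compounds <- sort(unique(matrix$compound_id))
  membership <- vapply(sets, function(s) all_compounds %in% s, logical(length(all_compounds)))
  membership <- matrix(membership, nrow = length(all_compounds),
                       dimnames = list(all_compounds, groups))
  key <- apply(membership, 1, function(m) paste(groups[m], collapse = "&"))
  regions <- tibble::tibble(
    groups = names(split(all_compounds, key)),
    compounds = unname(split(all_compounds, key))
  )
  regions$n <- lengths(regions$compounds)
  list(sets = sets, regions = regions[, c("groups", "n", "compounds")])
}
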