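#' Build a sample metadata table
#'
#' Describes the panel design: which replicate injections belong to which
#' wine, and which wines belong to which comparison group (for example the
#' short-cellar-time vs long-cellar-time vs modern rice wine vs grape wine
#' partition used in the discriminant analyses).
#'
#' @param sample_id Character, unique identifier of a replicate injection.
#' @param wine_label Character, wine the replicate was drawn from.
#' @param group_label Character, comparison group of the wine.
#' @param replicate_index Positive integer, replicate number within the wine.
#' @return A tibble with one row per replicate injection.
#' @export
sample_meta <- function(sample_id, wine_label, group_label, replicate_index) {
  meta <- tibble::tibble(
    sample_id = as.character(sample_id),
    wine_label = as.character(wine_label),
    group_label = as.character(group_label),
    replicate_index = as.integer(replicate_index)
  )
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicated sample_id in metadata", class = "aromakit_validation_error")
  }
  dup <- duplicated(meta[, c("wine_label", "replicate_index")])
  if (any(dup)) {
    abort(
      paste0(
        "duplicated (wine_label, replicate_index) pairs: ",
        paste(unique(meta$wine_label[dup]), collapse = ", ")
      ),
      class = "aromakit_validation_error"
    )
  }
  if (any(meta$replicate_index < 1L)) {
    abort("replicate_index must be a positive integer", class = "aromakit_validation_error")
  }
  meta
}

#' Read an integrated peak table
#'
#' Reads a delimited text file of integrated chromatographic peaks (one row
#' per peak). The file must name at least `retention_time` (minutes) and
#' `peak_area` columns together with `sample_id`; `compound_id` and
#' `is_internal_standard` are optional and filled with `NA`/`FALSE` when
#' absent. Rows with non-positive peak areas carry no usable signal and are
#' dropped; the number of dropped rows is recorded in the load report
#' (see [load_report()]).
#'
#' @param path Path to a CSV/TSV file (delimiter inferred by [readr::read_delim()]
#'   heuristics via [readr::read_csv()] for `.csv`, tab otherwise).
#' @param meta Sample metadata from [sample_meta()]; every `sample_id` in the
#'   file must resolve here.
#' @return A validated peak-table tibble with columns `sample_id`,
#'   `retention_time`, `peak_area`, `compound_id`, `is_internal_standard`,
#'   carrying a `load_report` attribute.
#' @export
read_peak_table <- function(path, meta) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "retention_time", "peak_area")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(
      paste0("peak table is missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "aromakit_format_error"
    )
  }
  if (!"compound_id" %in% names(raw)) raw$compound_id <- NA_character_
  if (!"is_internal_standard" %in% names(raw)) raw$is_internal_standard <- FALSE
  peaks <- tibble::as_tibble(raw[, c(required, "compound_id", "is_internal_standard")])
  peaks$sample_id <- as.character(peaks$sample_id)
  peaks$compound_id <- as.character(peaks$compound_id)
  peaks$is_internal_standard <- isTRUE_vec(peaks$is_internal_standard)
  as_peak_table(peaks, meta)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  as.logical(x) %in% TRUE
}

#' Validate an in-memory peak table
#'
#' Applies the same validation as [read_peak_table()] to a data frame built
#' in code: drops non-positive areas (counted in the load report), checks
#' that sample ids resolve in `meta`, and that no replicate carries more
#' than one internal-standard peak.
#'
#' @inheritParams read_peak_table
#' @param peaks Data frame with the peak-table columns.
#' @export
as_peak_table <- function(peaks, meta) {
  unknown <- setdiff(unique(peaks$sample_id), meta$sample_id)
  if (length(unknown)) {
    abort(
      paste0("sample id(s) not present in metadata: ", paste(unknown, collapse = ", ")),
      class = "aromakit_validation_error"
    )
  }
  keep <- is.finite(peaks$peak_area) & peaks$peak_area > 0
  dropped <- sum(!keep)
  peaks <- peaks[keep, , drop = FALSE]
  n_is <- tapply(peaks$is_internal_standard, peaks$sample_id, sum)
  dup_is <- names(n_is)[!is.na(n_is) & n_is > 1]
  if (length(dup_is)) {
    abort(
      paste0("more than one internal-standard peak in replicate(s): ", paste(dup_is, collapse = ", ")),
      class = "aromakit_validation_error"
    )
  }
  peaks <- tibble::as_tibble(peaks)
  attr(peaks, "load_report") <- list(n_dropped_nonpositive_area = dropped)
  class(peaks) <- c("aroma_peak_table", class(peaks))
  peaks
}

#' @rdname read_peak_table
#' @param x A peak table.
#' @export
load_report <- function(x) attr(x, "load_report")

#' Write a peak table in canonical order
#'
#' Writes CSV sorted by sample id and retention time, so that write/read
#' round trips are byte-stable.
#'
#' @param peaks Peak table.
#' @param path Output path.
#' @export
write_peak_table <- function(peaks, path) {
  out <- peaks[order(peaks$sample_id, peaks$retention_time), , drop = FALSE]
  # 12 significant digits: decimal -> double -> decimal is then an exact
  # identity, making repeated write/read round trips byte-stable
  for (col in c("retention_time", "peak_area")) {
    out[[col]] <- formatC(out[[col]], format = "g", digits = 12)
  }
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Read a compound reference library
#'
#' A library row describes one identifiable compound: a stable `compound_id`,
#' human-readable name, CAS registry string, chemical class (one of
#' `acid`, `alcohol`, `aldehyde`, `ester`, `other`), an optional reference
#' retention index, the identification evidence and an odor description.
#'
#' @param path CSV file with at least `compound_id` and `chem_class` columns.
#' @export
read_compound_library <- function(path) {
  lib <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_library(lib)
}

validate_library <- function(lib) {
  if (!all(c("compound_id", "chem_class") %in% names(lib))) {
    abort("compound library needs compound_id and chem_class columns",
          class = "aromakit_format_error")
  }
  if (anyDuplicated(lib$compound_id)) {
    abort("duplicated compound_id in library", class = "aromakit_validation_error")
  }
  bad <- setdiff(unique(lib$chem_class), c("acid", "alcohol", "aldehyde", "ester", "other"))
  if (length(bad)) {
    abort(paste0("unknown chem_class value(s): ", paste(bad, collapse = ", ")),
          class = "aromakit_validation_error")
  }
  if (!"reference_ri" %in% names(lib)) lib$reference_ri <- NA_real_
  tibble::as_tibble(lib)
}

#' Read an odor-threshold table
#'
#' @param path CSV with columns `compound_id`, `threshold_ug_per_L` and
#'   optionally `medium` (aqueous/ethanol/unspecified). Absent thresholds
#'   (compounds whose threshold has not been described) are `NA`, never zero.
#' @export
read_threshold_table <- function(path) {
  thr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("compound_id", "threshold_ug_per_L") %in% names(thr))) {
    abort("threshold table needs compound_id and threshold_ug_per_L columns",
          class = "aromakit_format_error")
  }
  if (any(thr$threshold_ug_per_L <= 0, na.rm = TRUE)) {
    abort("odor thresholds must be positive", class = "aromakit_domain_error")
  }
  if (!"medium" %in% names(thr)) thr$medium <- "unspecified"
  tibble::as_tibble(thr[, c("compound_id", "threshold_ug_per_L", "medium")])
}

# md5 digests of the packaged fixture files; guards against silent corruption
# of the transcribed reference tables.
.fixture_md5 <- c(
  xijiao_table1_concentrations.csv = "8db82561bc13b6e415ba8bc25e3c0612",
  xijiao_table2_thresholds.csv = "7eaf7132153f6c4fd81bf2b3444b1135"
)

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "aromakit")
  if (!nzchar(path)) abort(paste0("packaged fixture not found: ", file))
  path
}

#' Load the packaged nine-wine reference panel
#'
#' Returns the transcribed reference data of a nine-wine
#' HS-SPME-GC-MS aroma survey: semi-quantified concentrations
#' (mean and SD of three replicate injections, micrograms per litre) of 128
#' volatile compounds across the wines YJ, JJ, NEH, GLS, SKM, KJS, XH, CC
#' and ZY, plus odor thresholds for the 38 compounds whose thresholds are
#' described, and the odor-activity values as printed in the source tables
#' (numeric, `<1`, or not detected). Missing cells mean "not detected" and
#' are `NA`, never zero.
#'
#' @return A list of class `aroma_panel_fixture` with elements
#'   `concentrations` (long tibble: `wine`, `compound_id`, `mean`, `sd`,
#'   `n_replicates`), `library` (compound metadata), `thresholds`, and
#'   `printed_oav` (long tibble of the printed odor-activity cells, kept for
#'   regression tests).
#' @export
load_paper_fixture <- function() {
  files <- names(.fixture_md5)
  for (f in files) {
    got <- unname(tools::md5sum(fixture_path(f)))
    if (!identical(got, unname(.fixture_md5[[f]]))) {
      abort(paste0("packaged fixture ", f, " failed its checksum; reinstall the package"),
            class = "aromakit_corrupted_resource_error")
    }
  }
  t1 <- readr::read_csv(fixture_path(files[[1]]), show_col_types = FALSE, progress = FALSE)
  t2 <- readr::read_csv(fixture_path(files[[2]]), show_col_types = FALSE, progress = FALSE)

  lib <- validate_library(
    t1[, c("compound_id", "name", "cas", "chem_class", "evidence", "odor_description")]
  )
  conc <- t1 |>
    dplyr::select("compound_id", dplyr::ends_with("_mean"), dplyr::ends_with("_sd")) |>
    tidyr::pivot_longer(
      -"compound_id",
      names_to = c("wine", ".value"),
      names_pattern = "^([A-Z]+)_(mean|sd)$"
    ) |>
    dplyr::filter(!is.na(.data$mean)) |>
    dplyr::mutate(n_replicates = 3L)

  printed <- t2 |>
    dplyr::select("compound_id", dplyr::starts_with("oav_")) |>
    tidyr::pivot_longer(-"compound_id", names_to = "wine", values_to = "printed_oav") |>
    dplyr::mutate(wine = sub("^oav_", "", .data$wine))

  out <- list(
    concentrations = conc,
    library = lib,
    thresholds = tibble::as_tibble(t2[, c("compound_id", "threshold_ug_per_L")]) |>
      dplyr::mutate(medium = t2$medium %||% "unspecified"),
    printed_oav = printed,
    wines = c("YJ", "JJ", "NEH", "GLS", "SKM", "KJS", "XH", "CC", "ZY")
  )
  class(out) <- "aroma_panel_fixture"
  out
}

#' Validate a panel against its compound library
#'
#' Report-only check used before quantification: lists compound annotations
#' that do not resolve in the library, replicates that lack an
#' internal-standard peak, and retention-time anomalies (non-finite or
#' non-positive retention times). The panel passes iff all lists are empty.
#'
#' @param peaks Peak table.
#' @param library Compound library.
#' @param meta Sample metadata; defines the expected set of replicates.
#' @return A list with `passed` plus the three anomaly lists.
#' @export
validate_panel <- function(peaks, library, meta) {
  annotated <- peaks$compound_id[!is.na(peaks$compound_id) & !peaks$is_internal_standard]
  unresolved <- sort(setdiff(unique(annotated), library$compound_id))
  with_is <- unique(peaks$sample_id[peaks$is_internal_standard])
  missing_is <- sort(setdiff(meta$sample_id, with_is))
  bad_rt <- !is.finite(peaks$retention_time) | peaks$retention_time <= 0
  rt_anomalies <- sort(unique(peaks$sample_id[bad_rt]))
  report <- list(
    unresolved_compounds = unresolved,
    replicates_missing_is = missing_is,
    rt_anomalies = rt_anomalies
  )
  report$passed <- all(lengths(report[1:3]) == 0L)
  report
}
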