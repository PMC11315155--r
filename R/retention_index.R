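#' Calibrate an n-alkane ladder
#'
#' Builds the carbon-number to retention-time calibration backing
#' temperature-programmed (van den Dool-Kratz) retention indices. Rungs are
#' sorted by carbon number; both carbon numbers and retention times must
#' then be strictly increasing, otherwise the injection is unusable for
#' calibration.
#'
#' @param carbon_number Integer vector of alkane carbon numbers (e.g. 7:30).
#' @param retention_time Retention times of the alkane peaks, minutes.
#' @return An `alkane_ladder` tibble.
#' @export
fit_ladder <- function(carbon_number, retention_time) {
  if (length(carbon_number) != length(retention_time)) {
    abort("carbon_number and retention_time lengths differ", class = "aromakit_calibration_error")
  }
  if (length(carbon_number) < 2) {
    abort("an alkane ladder needs at least two rungs", class = "aromakit_calibration_error")
  }
  ord <- order(carbon_number)
  ladder <- tibble::tibble(
    carbon_number = as.integer(carbon_number[ord]),
    retention_time = as.numeric(retention_time[ord])
  )
  if (any(diff(ladder$carbon_number) <= 0)) {
    abort("carbon numbers must be distinct", class = "aromakit_calibration_error")
  }
  if (any(diff(ladder$retention_time) <= 0)) {
    abort("alkane retention times must increase strictly with carbon number",
          class = "aromakit_calibration_error")
  }
  class(ladder) <- c("alkane_ladder", class(ladder))
  ladder
}

#' @rdname fit_ladder
#' @param path Two-column CSV (`carbon_number`, `retention_time_min`).
#' @export
read_alkane_ladder <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rt_col <- intersect(c("retention_time_min", "retention_time"), names(x))[1]
  if (!"carbon_number" %in% names(x) || is.na(rt_col)) {
    abort("ladder file needs carbon_number and retention_time_min columns",
          class = "aromakit_format_error")
  }
  fit_ladder(x$carbon_number, x[[rt_col]])
}

#' Temperature-programmed retention index
#'
#' For a peak eluting at `rt` between the alkanes with carbon numbers Z and
#' Z+1, the retention index is
#' `RI = 100 * (Z + (rt - RT_Z) / (RT_{Z+1} - RT_Z))`,
#' the linear interpolation used with linear oven-temperature programs.
#' Retention times outside the ladder span are extrapolated from the first
#' or last rung pair and flagged.
#'
#' @param rt Numeric vector of retention times, minutes; must be positive.
#' @param ladder An [fit_ladder()] calibration.
#' @return Tibble with `value` (the index), `bracketing_z` (carbon number of
#'   the lower rung used) and `extrapolated`.
#' @export
compute_ri <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  if (any(!is.finite(rt) | rt <= 0)) {
    abort("retention times must be positive", class = "aromakit_domain_error")
  }
  z <- ladder$carbon_number
  t <- ladder$retention_time
  # index of the lower rung of the bracketing pair, clamped to the end pairs;
  # the carbon-number step is usually 1 but a sparse ladder is handled too
  i <- findInterval(rt, t, rightmost.closed = FALSE, all.inside = TRUE)
  value <- 100 * (z[i] + (z[i + 1] - z[i]) * (rt - t[i]) / (t[i + 1] - t[i]))
  tibble::tibble(
    value = value,
    bracketing_z = z[i],
    extrapolated = rt < t[1] | rt > t[length(t)]
  )
}

#' Annotate peaks by retention-index proximity
#'
#' Assigns each unannotated, non-internal-standard peak the library compound
#' whose reference retention index is nearest to the peak's computed index,
#' provided the distance is at most `tolerance` index units. Within each
#' replicate, assignments are injective: when several peaks compete for one
#' compound (or one peak for several compounds) the closest pair wins and
#' the loser stays unannotated. An exact tie between two library entries at
#' equal distance leaves the peak unannotated with a warning, since no
#' spectral evidence is available to break it.
#'
#' @param peaks Peak table.
#' @param library Compound library with a `reference_ri` column.
#' @param ladder Alkane ladder for [compute_ri()].
#' @param tolerance Maximum |RI difference| in index units; default 10.
#' @return The peak table with `compound_id` filled in and a `peak_ri` column.
#' @export
annotate_peaks <- function(peaks, library, ladder, tolerance = 10) {
  stopifnot(tolerance > 0)
  lib <- library[!is.na(library$reference_ri), , drop = FALSE]
  if (nrow(lib) == 0) {
    abort("library has no reference_ri values to annotate against",
          class = "aromakit_annotation_error")
  }
  peaks$peak_ri <- compute_ri(peaks$retention_time, ladder)$value
  for (sid in unique(peaks$sample_id)) {
    rows <- which(peaks$sample_id == sid & !peaks$is_internal_standard & is.na(peaks$compound_id))
    if (!length(rows)) next
    d <- abs(outer(peaks$peak_ri[rows], lib$reference_ri, "-"))
    d[d > tolerance] <- NA_real_
    taken <- peaks$compound_id[peaks$sample_id == sid]
    d[, lib$compound_id %in% taken] <- NA_real_  # already-annotated compounds stay assigned
    while (any(is.finite(d))) {
      best <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)
      if (nrow(best) > 1 && length(unique(best[, 1])) < nrow(best)) {
        # one peak equidistant from two compounds: ambiguous, leave unannotated
        amb <- best[duplicated(best[, 1]) | duplicated(best[, 1], fromLast = TRUE), 1]
        warn(paste0("ambiguous RI tie for peak(s) in replicate ", sid, "; left unannotated"))
        d[unique(amb), ] <- NA_real_
        next
      }
      pi <- best[1, 1]; ci <- best[1, 2]
      peaks$compound_id[rows[pi]] <- lib$compound_id[ci]
      d[pi, ] <- NA_real_
      d[, ci] <- NA_real_
    }
  }
  peaks
}
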