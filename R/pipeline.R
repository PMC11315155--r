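#' Configure an end-to-end pipeline run
#'
#' Collects input paths and stage options for [run_pipeline()]. All
#' referenced paths must exist at run start.
#'
#' @param peaks,meta,ladder,library,thresholds Input CSV paths (peak table,
#'   sample metadata, alkane ladder, compound library, odor thresholds).
#' @param out_dir Output directory (created if needed).
#' @param is_config Internal-standard configuration.
#' @param ri_tolerance Retention-index match tolerance for annotation.
#' @param roav_cutoff Key-odorant ROAV cutoff.
#' @param chemometrics List of multivariate options: `metric`, `folds`,
#'   `permutations`, `n_components`, `reference_sample` (optional sample id
#'   for quotient normalization), or `NULL` to skip the multivariate stage.
#' @param seed Integer seed recorded in the manifest and used by the
#'   validation stage.
#' @export
pipeline_config <- function(peaks, meta, ladder, library, thresholds, out_dir,
                            is_config = aromakit::is_config(),
                            ri_tolerance = 10, roav_cutoff = 1,
                            chemometrics = list(metric = "bray", folds = 5,
                                                permutations = 100,
                                                n_components = 2,
                                                reference_sample = NULL),
                            seed = 1) {
  cfg <- list(
    peaks = peaks, meta = meta, ladder = ladder, library = library,
    thresholds = thresholds, out_dir = out_dir, is_config = is_config,
    ri_tolerance = ri_tolerance, roav_cutoff = roav_cutoff,
    chemometrics = chemometrics, seed = seed
  )
  paths <- unlist(cfg[c("peaks", "meta", "ladder", "library", "thresholds")])
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")),
          class = "aromakit_configuration_error")
  }
  structure(cfg, class = "aroma_pipeline_config")
}

stage <- function(name, written, code) {
  tryCatch(code, error = function(e) {
    unlink(written$files)  # no partial outputs on failure
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
          class = "aromakit_pipeline_error", parent = e)
  })
}

#' Run the full pipeline
#'
#' Stages, in order: load and validate inputs, retention-index annotation,
#' internal-standard semi-quantification with replicate aggregation,
#' chemical-class totals, ROAV scoring with key-odorant selection, and
#' (when configured and at least two groups are present) the multivariate
#' stage (imputation, optional quotient normalization, Pareto scaling,
#' Spearman matrix, PCoA, PLS-DA with VIP, cross-validation and permutation
#' test). Any stage failure aborts with the stage name and removes files
#' written so far. A manifest records the configuration hash and seed, so
#' identical configurations reproduce identical numeric outputs.
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, a list of the main in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "aroma_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- new.env(); written$files <- character()
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    readr::write_csv(df, path, na = "NA")
    written$files <- c(written$files, path)
    path
  }

  inputs <- stage("load", written, {
    meta <- readr::read_csv(config$meta, show_col_types = FALSE, progress = FALSE)
    meta <- sample_meta(meta$sample_id, meta$wine_label, meta$group_label,
                        meta$replicate_index)
    list(
      meta = meta,
      peaks = read_peak_table(config$peaks, meta),
      ladder = read_alkane_ladder(config$ladder),
      library = read_compound_library(config$library),
      thresholds = read_threshold_table(config$thresholds)
    )
  })

  stage("validate", written, {
    report <- validate_panel(inputs$peaks, inputs$library, inputs$meta)
    if (!report$passed) {
      abort(paste0(
        "panel validation failed; missing IS in [",
        paste(report$replicates_missing_is, collapse = ", "),
        "], unresolved compounds [",
        paste(report$unresolved_compounds, collapse = ", "), "]"
      ), class = "aromakit_validation_error")
    }
  })

  annotated <- stage("ri_annotation", written,
    annotate_peaks(inputs$peaks, inputs$library, inputs$ladder,
                   tolerance = config$ri_tolerance))

  quant <- stage("quantify", written, {
    records <- semi_quantify(annotated, config$is_config)
    mat <- aggregate_replicates(records, inputs$meta)
    emit(mat, "concentration_matrix.csv")
    totals <- class_totals(mat, inputs$library)
    emit(totals, "class_totals.csv")
    list(records = records, matrix = mat, totals = totals)
  })

  roav_out <- stage("roav", written, {
    rec <- compute_roav(quant$matrix, inputs$thresholds)
    emit(format_roav(rec), "roav.csv")
    keys <- select_key_odorants(rec, cutoff = config$roav_cutoff)
    key_path <- file.path(config$out_dir, "key_odorants.json")
    jsonlite::write_json(lapply(keys, function(k) k$compound_id), key_path,
                         auto_unbox = FALSE)
    written$files <- c(written$files, key_path)
    list(records = rec, key_odorants = keys)
  })

  chem <- NULL
  co <- config$chemometrics
  if (!is.null(co) && length(unique(inputs$meta$group_label)) >= 2) {
    chem <- stage("chemometrics", written, {
      X <- as_data_matrix(quant$records)
      X <- impute_missing(X)
      if (!is.null(co$reference_sample)) {
        X <- normalize_to_reference(X, co$reference_sample)
      }
      pc <- pcoa(X, metric = co$metric %||% "bray")
      emit(tibble::as_tibble(pc$coordinates, rownames = "sample_id"), "pcoa_coordinates.csv")
      emit(tibble::as_tibble(spearman_matrix(X), rownames = "sample_id"),
           "spearman_matrix.csv")
      Xs <- pareto_scale(X)
      groups <- inputs$meta$group_label[match(rownames(Xs), inputs$meta$sample_id)]
      spec <- plsda_spec(n_components = co$n_components %||% 2)
      model <- fit_plsda(Xs, groups, n_components = co$n_components %||% 2)
      vip <- compute_vip(model)
      emit(tibble::tibble(compound_id = names(vip), vip = unname(vip)), "vip.csv")
      emit(tibble::as_tibble(model$T, .name_repair = "minimal") |>
             dplyr::mutate(sample_id = rownames(Xs), .before = 1), "plsda_scores.csv")
      val <- permutation_test(Xs, groups, spec,
                              n_permutations = co$permutations %||% 100,
                              folds = co$folds %||% 5, seed = config$seed)
      val_path <- file.path(config$out_dir, "validation.json")
      jsonlite::write_json(
        list(r2 = val$r2, q2 = val$q2, permutation_p = val$permutation_p,
             n_permutations = val$n_permutations, folds = val$folds),
        val_path, auto_unbox = TRUE, digits = NA)
      written$files <- c(written$files, val_path)
      list(pcoa = pc, model = model, vip = vip, validation = val)
    })
  }

  manifest <- list(
    package = "aromakit",
    version = as.character(utils::packageVersion("aromakit")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    outputs = basename(written$files)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(
    quantification = quant, roav = roav_out, chemometrics = chem,
    manifest = manifest, files = written$files
  ))
}

#' Reproduce the reference odor-activity report from the packaged panel
#'
#' Fixture mode: no inputs needed. Recomputes every ROAV from the packaged
#' concentrations and thresholds, writes the formatted table and the
#' per-wine key-odorant lists.
#'
#' @param out_dir Output directory.
#' @export
fixture_report <- function(out_dir) {
  fx <- load_paper_fixture()
  rec <- compute_roav(fx$concentrations, fx$thresholds)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(format_roav(rec), file.path(out_dir, "roav.csv"), na = "NA")
  keys <- select_key_odorants(rec)
  jsonlite::write_json(
    list(
      key_odorants = lapply(keys, function(k) k$compound_id),
      counts = lapply(keys, nrow),
      unevaluable = unevaluable_compounds(rec)
    ),
    file.path(out_dir, "key_odorants.json"), auto_unbox = TRUE
  )
  invisible(list(records = rec, key_odorants = keys))
}
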