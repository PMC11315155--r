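#' Default alkane ladder of the synthetic panels
#'
#' C7-C30 rungs placed by the same affine retention model the generator
#' uses, spanning roughly a 46-minute temperature-programmed run.
#'
#' @param rt_model Affine retention model (see [panel_spec()]).
#' @export
default_alkane_ladder <- function(rt_model = default_rt_model()) {
  z <- 7:30
  fit_ladder(z, rt_model$intercept + rt_model$slope * 100 * z)
}

#' @rdname default_alkane_ladder
#' @export
default_rt_model <- function() {
  # maps retention index to minutes: RI 700 elutes at ~2 min, RI 3000 at ~45.7
  list(intercept = -11.3, slope = 0.019, jitter_sd = 0.02)
}

#' Specify a synthetic SPME-GC-MS panel
#'
#' Defines the study design a synthetic panel emulates: wines organized in
#' comparison groups with replicate injections, a compound panel with
#' reference retention indices, per-wine mean concentrations, multiplicative
#' log-normal noise (parameterized by a coefficient of variation), a
#' detection floor below which peaks are censored, an internal standard
#' spiked at fixed concentration, and an affine retention-time model with
#' Gaussian jitter. Defaults mirror the reference study design: three
#' replicate injections per wine and an internal standard at 328.8 ug/L.
#'
#' @param groups Data frame (`group_label`, `n_wines`, `n_replicates`).
#' @param compounds Data frame (`compound_id`, `chem_class`, `reference_ri`).
#' @param means Matrix of true mean concentrations (ug/L), compounds x
#'   groups (columns named by group) or compounds x wines.
#' @param cv Coefficient of variation of the log-normal replicate noise;
#'   scalar, per-compound vector, or compounds x wines matrix.
#' @param lod Detection floor (ug/L); concentrations below it are censored.
#' @param rt_model List (`intercept`, `slope`, `jitter_sd`): retention time
#'   in minutes = intercept + slope * reference_ri + jitter.
#' @param is_config Internal-standard configuration.
#' @param ladder Alkane ladder shipped with the panel.
#' @param seed Integer seed; generation is byte-identical for equal seeds.
#' @return A `panel_spec` object.
#' @export
panel_spec <- function(groups, compounds, means, cv = 0.25, lod = 0,
                       rt_model = default_rt_model(),
                       is_config = aromakit::is_config(),
                       ladder = default_alkane_ladder(rt_model),
                       seed = 1) {
  groups <- tibble::as_tibble(groups)
  compounds <- tibble::as_tibble(compounds)
  stopifnot(all(c("group_label", "n_wines", "n_replicates") %in% names(groups)),
            all(c("compound_id", "reference_ri") %in% names(compounds)),
            lod >= 0, all(cv >= 0))
  wines <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    tibble::tibble(
      wine_label = paste0(g$group_label, "_w", seq_len(g$n_wines)),
      group_label = g$group_label,
      n_replicates = g$n_replicates
    )
  }))
  means <- as.matrix(means)
  if (identical(sort(colnames(means)), sort(groups$group_label))) {
    means <- means[, wines$group_label, drop = FALSE]
    colnames(means) <- wines$wine_label
  }
  stopifnot(nrow(means) == nrow(compounds), ncol(means) == nrow(wines),
            all(means >= 0, na.rm = TRUE))
  if (is.null(dim(cv))) {
    cv <- matrix(cv, nrow(compounds), nrow(wines))
  }
  dimnames(cv) <- dimnames(means) <- list(compounds$compound_id, wines$wine_label)
  structure(
    list(groups = groups, wines = wines, compounds = compounds, means = means,
         cv = cv, lod = lod, rt_model = rt_model, is_config = is_config,
         ladder = ladder, seed = seed,
         markers = tibble::tibble(compound_id = character(),
                                  fold_change = numeric(),
                                  target_group = character())),
    class = "panel_spec"
  )
}

#' Plant discriminant markers into a panel specification
#'
#' Multiplies the mean concentrations of the named compounds by
#' `fold_change` in every wine of `target_group` and records the marker
#' identities, so that downstream marker-recovery experiments have known
#' ground truth.
#'
#' @param spec A [panel_spec()].
#' @param compound_ids Compounds to perturb.
#' @param fold_change Positive multiplicative effect.
#' @param target_group Group whose wines receive the effect.
#' @export
plant_markers <- function(spec, compound_ids, fold_change, target_group) {
  stopifnot(inherits(spec, "panel_spec"), fold_change > 0)
  unknown <- setdiff(compound_ids, spec$compounds$compound_id)
  if (length(unknown)) {
    abort(paste0("unknown compound id(s): ", paste(unknown, collapse = ", ")),
          class = "aromakit_configuration_error")
  }
  if (!target_group %in% spec$groups$group_label) {
    abort(paste0("unknown group: ", target_group), class = "aromakit_configuration_error")
  }
  cols <- spec$wines$wine_label[spec$wines$group_label == target_group]
  spec$means[compound_ids, cols] <- spec$means[compound_ids, cols] * fold_change
  spec$markers <- rbind(
    spec$markers,
    tibble::tibble(compound_id = compound_ids, fold_change = fold_change,
                   target_group = target_group)
  )
  spec
}

# log-normal draw with arithmetic mean m and coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0 || m == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic replicate-level panel
#'
#' Draws, per replicate injection: a log-normal internal-standard peak area
#' (5% CV around 1e6 counts, so that the area-ratio invariance of
#' semi-quantification is actually exercised), log-normal true
#' concentrations around the wine means with the specified CV, censoring
#' below the detection floor, peak areas `A = (C / C_is) * A_is`, and
#' retention times from the affine model with Gaussian jitter. The internal
#' standard is always present. Output is byte-identical for equal seeds.
#'
#' @param spec A [panel_spec()].
#' @return List of class `synthetic_panel`: `peaks` (annotated peak table;
#'   strip `compound_id` to test annotation), `meta`, `truth` (tibble of
#'   true concentrations with an `emitted` flag), `ladder`, `markers`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    meta_rows <- list(); peak_rows <- list(); truth_rows <- list()
    is_ri <- 1096  # nominal index of the 2-octanol internal standard
    for (wi in seq_len(nrow(spec$wines))) {
      w <- spec$wines[wi, ]
      for (r in seq_len(w$n_replicates)) {
        sid <- paste0(w$wine_label, "_r", r)
        meta_rows[[sid]] <- tibble::tibble(
          sample_id = sid, wine_label = w$wine_label,
          group_label = w$group_label, replicate_index = r
        )
        a_is <- rlnorm_cv(1, 1e6, 0.05)
        m <- spec$means[, w$wine_label]
        cvs <- spec$cv[, w$wine_label]
        conc <- vapply(seq_along(m), function(j) rlnorm_cv(1, m[j], cvs[j]), numeric(1))
        emitted <- conc >= spec$lod & conc > 0
        rt <- spec$rt_model$intercept + spec$rt_model$slope * spec$compounds$reference_ri +
          stats::rnorm(length(m), 0, spec$rt_model$jitter_sd)
        truth_rows[[sid]] <- tibble::tibble(
          sample_id = sid, compound_id = spec$compounds$compound_id,
          true_concentration = conc, emitted = emitted, true_rt = rt
        )
        is_rt <- spec$rt_model$intercept + spec$rt_model$slope * is_ri +
          stats::rnorm(1, 0, spec$rt_model$jitter_sd)
        peak_rows[[sid]] <- tibble::tibble(
          sample_id = sid,
          retention_time = c(is_rt, rt[emitted]),
          peak_area = c(a_is, conc[emitted] / spec$is_config$final_concentration * a_is),
          compound_id = c(NA_character_, spec$compounds$compound_id[emitted]),
          is_internal_standard = c(TRUE, rep(FALSE, sum(emitted)))
        )
      }
    }
    meta <- dplyr::bind_rows(meta_rows)
    panel <- list(
      peaks = as_peak_table(dplyr::bind_rows(peak_rows), meta),
      meta = meta,
      truth = dplyr::bind_rows(truth_rows),
      ladder = spec$ladder,
      markers = spec$markers
    )
    class(panel) <- "synthetic_panel"
    panel
  })
}

#' Panel specification seeded from the packaged reference panel
#'
#' Builds a [panel_spec()] whose per-wine mean concentrations equal the
#' packaged nine-wine reference values, with per-cell CVs taken as sd/mean
#' (cells with undefined CV fall back to 0.1) and three replicates per
#' wine. Reference retention indices are synthetic (evenly spaced across
#' the ladder span) since the reference tables do not print them.
#'
#' @param seed Seed passed to the spec.
#' @export
fixture_spec <- function(seed = 1) {
  fx <- load_paper_fixture()
  wines <- fx$wines
  group_of <- c(YJ = "Xijiao_SCT", JJ = "Xijiao_SCT", NEH = "Xijiao_LCT",
                GLS = "MCRW", SKM = "MCRW", KJS = "MCRW", XH = "MCRW",
                CC = "GW", ZY = "GW")
  ids <- fx$library$compound_id
  means <- matrix(0, length(ids), length(wines), dimnames = list(ids, wines))
  cvs <- matrix(0.1, length(ids), length(wines), dimnames = list(ids, wines))
  for (k in seq_len(nrow(fx$concentrations))) {
    row <- fx$concentrations[k, ]
    means[row$compound_id, row$wine] <- row$mean
    if (is.finite(row$sd) && row$mean > 0) {
      cvs[row$compound_id, row$wine] <- row$sd / row$mean
    }
  }
  compounds <- tibble::tibble(
    compound_id = ids,
    chem_class = fx$library$chem_class,
    reference_ri = seq(720, 2980, length.out = length(ids))
  )
  spec <- panel_spec(
    groups = tibble::tibble(group_label = wines, n_wines = 1L, n_replicates = 3L),
    compounds = compounds, means = means, cv = cvs, seed = seed
  )
  # wines keep their real labels and the four-group partition
  spec$wines$wine_label <- wines
  spec$wines$group_label <- unname(group_of[wines])
  colnames(spec$means) <- colnames(spec$cv) <- wines
  spec$groups <- dplyr::count(spec$wines, group_label = .data$group_label,
                              name = "n_wines") |>
    dplyr::mutate(n_replicates = 3L)
  spec
}
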