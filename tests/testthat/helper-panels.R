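# Shared builders for small in-code fixtures.

tiny_meta <- function(n_rep = 2, wines = c("W1", "W2")) {
  grid <- expand.grid(rep = seq_len(n_rep), wine = wines,
                      stringsAsFactors = FALSE)
  sample_meta(
    sample_id = paste0(grid$wine, "_r", grid$rep),
    wine_label = grid$wine,
    group_label = "G",
    replicate_index = grid$rep
  )
}

# peak table for one replicate: IS peak + annotated analytes
tiny_peaks <- function(sample_id, areas, compounds, is_area = 1000) {
  tibble::tibble(
    sample_id = sample_id,
    retention_time = seq(2, by = 1, length.out = length(areas) + 1),
    peak_area = c(is_area, areas),
    compound_id = c(NA_character_, compounds),
    is_internal_standard = c(TRUE, rep(FALSE, length(areas)))
  )
}

tiny_library <- function(ids, ri = NULL, class = "ester") {
  tibble::tibble(
    compound_id = ids,
    chem_class = class,
    reference_ri = ri %||% rep(NA_real_, length(ids))
  )
}

# two-group spec used across generator / chemometrics tests
two_group_spec <- function(n_compounds = 10, n_wines = 1, n_replicates = 3,
                           mean = 100, cv = 0.25, seed = 1, ...) {
  ids <- paste0("c", seq_len(n_compounds))
  panel_spec(
    groups = data.frame(group_label = c("A", "B"), n_wines = n_wines,
                        n_replicates = n_replicates),
    compounds = data.frame(compound_id = ids, chem_class = "ester",
                           reference_ri = seq(750, 2900, length.out = n_compounds)),
    means = matrix(mean, n_compounds, 2, dimnames = list(ids, c("A", "B"))),
    cv = cv, seed = seed, ...
  )
}

panel_matrix <- function(panel) {
  X <- as_data_matrix(semi_quantify(panel$peaks))
  pareto_scale(impute_missing(X))
}

panel_groups <- function(panel, X) {
  panel$meta$group_label[match(rownames(X), panel$meta$sample_id)]
}

withr_local_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "NA")
  path
}

# per-class totals as printed in the reference survey (ug/L)
printed_class_totals <- function() {
  wines <- c("YJ", "JJ", "NEH", "GLS", "SKM", "KJS", "XH", "CC", "ZY")
  vals <- rbind(
    acid = c(933.38, 671.03, 6.58, 31.58, 11.02, 16.84, 21.25, 86.97, 767.10),
    alcohol = c(7844.28, 6859.95, 5859.07, 15105.31, 16575.76, 22909.24,
                14689.63, 16731.91, 24290.54),
    aldehyde = c(31.74, 592.92, 3131.71, 7762.23, 5709.46, 5954.80,
                 1387.48, 68.58, 110.53),
    ester = c(4910.12, 8092.48, 4228.98, 5482.05, 3302.94, 8379.61,
              6449.53, 12350.18, 9516.72),
    other = c(205.30, 576.55, 888.30, 494.34, 359.82, 526.29,
              451.82, 501.40, 404.75)
  )
  colnames(vals) <- wines
  out <- as.data.frame.table(vals, stringsAsFactors = FALSE)
  names(out) <- c("chem_class", "wine", "printed")
  out
}
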