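test_that("semi-quantification is the IS area ratio times the spike concentration", {
  meta <- tiny_meta(1, "W1")
  peaks <- as_peak_table(tiny_peaks("W1_r1", areas = c(1000, 2000),
                                    compounds = c("a", "b"),
                                    is_area = 1000), meta)
  # areas equal to IS area recover C_is; 2000/500 scales accordingly
  rec <- semi_quantify(peaks, is_config(final_concentration = 328.8))
  expect_equal(rec$concentration[rec$compound_id == "a"], 328.8)
  peaks2 <- as_peak_table(tiny_peaks("W1_r1", areas = 2000, compounds = "a",
                                     is_area = 500), meta)
  expect_equal(semi_quantify(peaks2)$concentration, 1315.2)

  no_is <- peaks[!peaks$is_internal_standard, ]
  expect_error(semi_quantify(no_is), class = "aromakit_quantification_error",
               regexp = "W1_r1")
})

test_that("concentrations are invariant to replicate-wide area scaling only when the IS scales too", {
  meta <- tiny_meta(1, "W1")
  base <- as_peak_table(tiny_peaks("W1_r1", areas = c(400, 900),
                                   compounds = c("a", "b")), meta)
  all_scaled <- base; all_scaled$peak_area <- base$peak_area * 7.3
  expect_equal(semi_quantify(as_peak_table(all_scaled, meta))$concentration,
               semi_quantify(base)$concentration)
  analytes_only <- base
  analytes_only$peak_area[!analytes_only$is_internal_standard] <-
    analytes_only$peak_area[!analytes_only$is_internal_standard] * 7.3
  expect_false(isTRUE(all.equal(
    semi_quantify(as_peak_table(analytes_only, meta))$concentration,
    semi_quantify(base)$concentration)))
})

test_that("noiseless generate -> quantify recovers truth to machine precision", {
  panel <- generate_panel(two_group_spec(n_compounds = 8, cv = 0, seed = 3))
  rec <- semi_quantify(panel$peaks)
  truth <- panel$truth[panel$truth$emitted, ]
  key <- paste(truth$sample_id, truth$compound_id)
  expect_equal(rec$concentration,
               truth$true_concentration[match(paste(rec$sample_id, rec$compound_id), key)],
               tolerance = 1e-12)
})

test_that("replicate aggregation uses detected replicates and flags single-replicate support", {
  meta <- tiny_meta(3, "W1")
  recs <- tibble::tibble(
    sample_id = c("W1_r1", "W1_r2", "W1_r3", "W1_r2"),
    compound_id = c("a", "a", "a", "solo"),
    concentration = c(10, 12, 14, 10)
  )
  agg <- aggregate_replicates(recs, meta)
  a <- agg[agg$compound_id == "a", ]
  expect_equal(a$mean, 12)
  expect_equal(a$sd, 2)
  expect_false(a$low_support)
  solo <- agg[agg$compound_id == "solo", ]
  expect_equal(solo$mean, 10)
  expect_equal(solo$sd, 0)
  expect_true(solo$low_support)
  # compound absent from every replicate of the wine: no row at all
  expect_false("ghost" %in% agg$compound_id)
})

test_that("class totals sum detected means, zero-fill empty classes, and partition the grand total", {
  fx <- load_paper_fixture()
  totals <- class_totals(fx$concentrations, fx$library)
  get <- function(w, cl) totals$total[totals$wine == w & totals$chem_class == cl]
  expect_equal(get("YJ", "aldehyde"), 31.74, tolerance = 0.05 / 31.74)
  expect_equal(get("JJ", "ester"), 8092.48, tolerance = 0.5 / 8092.48)

  # per wine, class totals sum to the total over all compounds
  by_wine <- tapply(fx$concentrations$mean, fx$concentrations$wine, sum)
  agg <- tapply(totals$total, totals$wine, sum)
  expect_equal(agg[names(by_wine)], by_wine)

  # a wine with no detected acids gets an explicit zero
  no_acid <- fx$concentrations[fx$concentrations$wine == "NEH" &
    fx$concentrations$compound_id != "2_methylbutanoic_acid", ]
  t2 <- class_totals(no_acid, fx$library)
  expect_equal(t2$total[t2$wine == "NEH" & t2$chem_class == "acid"], 0)

  expect_error(class_totals(fx$concentrations, tiny_library("nope")),
               class = "aromakit_classification_error")
})

test_that("presence sets and their Venn regions match brute-force set algebra", {
  mat <- tibble::tibble(
    wine = c("w1", "w1", "w2", "w3"),
    compound_id = c("a", "b", "a", "c"),
    mean = 1
  )
  ps <- presence_sets(mat, c(w1 = "G1", w2 = "G2", w3 = "G2"))
  expect_equal(ps$sets$G1, c("a", "b"))
  expect_equal(ps$sets$G2, c("a", "c"))
  expect_equal(ps$regions$n[ps$regions$groups == "G1&G2"], 1)

  # identical groups: empty symmetric difference
  ps2 <- presence_sets(mat[1:3, ], c(w1 = "G1", w2 = "G1"))
  expect_equal(names(ps2$sets), "G1")

  # fixture 3-way partition cross-checked by explicit enumeration
  fx <- load_paper_fixture()
  grouping <- c(YJ = "Xijiao", JJ = "Xijiao", NEH = "Xijiao",
                GLS = "MCRW", SKM = "MCRW", KJS = "MCRW", XH = "MCRW",
                CC = "GW", ZY = "GW")
  ps3 <- presence_sets(fx$concentrations, grouping)
  in_group <- function(g) {
    sort(unique(fx$concentrations$compound_id[
      grouping[fx$concentrations$wine] == g]))
  }
  for (g in c("Xijiao", "MCRW", "GW")) expect_equal(ps3$sets[[g]], in_group(g))
  brute_exclusive <- function(inside) {
    all_ids <- sort(unique(fx$concentrations$compound_id))
    keep <- rep(TRUE, length(all_ids))
    for (g in c("Xijiao", "MCRW", "GW")) {
      member <- all_ids %in% in_group(g)
      keep <- keep & (if (g %in% inside) member else !member)
    }
    sum(keep)
  }
  for (combo in list("Xijiao", "GW", c("MCRW", "Xijiao"), c("GW", "MCRW", "Xijiao"))) {
    label <- paste(sort(combo), collapse = "&")
    got <- ps3$regions$n[ps3$regions$groups == label]
    expect_equal(if (length(got)) got else 0L, brute_exclusive(combo))
  }
  expect_equal(sum(ps3$regions$n), 128)
})
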