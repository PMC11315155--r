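#' Assemble a samples-by-compounds data matrix
#'
#' Converts replicate-level concentration records into the numeric matrix
#' consumed by the multivariate stage (rows = replicate injections,
#' columns = compounds). Undetected cells are `NA` until [impute_missing()].
#'
#' @param records Concentration records (`sample_id`, `compound_id`,
#'   `concentration`).
#' @return Numeric matrix with sample ids as row names, compound ids as
#'   column names, and a `provenance` attribute tracking transformations.
#' @export
as_data_matrix <- function(records) {
  wide <- records |>
    tidyr::pivot_wider(
      id_cols = "sample_id", names_from = "compound_id",
      values_from = "concentration"
    )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  add_provenance(m, "assembled")
}

add_provenance <- function(m, step, from = m) {
  attr(m, "provenance") <- c(attr(from, "provenance"), step)
  m
}

#' @rdname as_data_matrix
#' @param m A data matrix.
#' @export
provenance <- function(m) attr(m, "provenance")

#' Impute missing cells
#'
#' Each missing cell is replaced by one fifth of the minimum positive value
#' of its compound column, the usual surrogate for concentrations censored
#' below the detection limit. Columns with no observed value at all carry no
#' information and are dropped (recorded in the `dropped_columns` attribute).
#'
#' @param m Data matrix.
#' @export
impute_missing <- function(m) {
  all_missing <- colSums(!is.na(m)) == 0
  dropped <- colnames(m)[all_missing]
  m2 <- m[, !all_missing, drop = FALSE]
  for (j in seq_len(ncol(m2))) {
    miss <- is.na(m2[, j])
    if (any(miss)) {
      pos <- m2[!miss, j]
      pos <- pos[pos > 0]
      m2[miss, j] <- if (length(pos)) min(pos) / 5 else 0
    }
  }
  m2 <- add_provenance(m2, "imputed_min5", from = m)
  attr(m2, "dropped_columns") <- dropped
  m2
}

#' Probabilistic quotient normalization against a reference sample
#'
#' Divides each sample row by the median of its element-wise quotients
#' against the designated reference row, correcting sample-to-sample
#' dilution/extraction differences while leaving the reference unchanged.
#'
#' @param m Imputed data matrix (the reference row must contain no zeros).
#' @param reference_sample Row name of the reference sample.
#' @export
normalize_to_reference <- function(m, reference_sample) {
  if (!reference_sample %in% rownames(m)) {
    abort(paste0("reference sample not found: ", reference_sample),
          class = "aromakit_configuration_error")
  }
  ref <- m[reference_sample, ]
  if (any(!is.finite(ref) | ref == 0)) {
    abort("reference row contains zeros or missing values; impute first",
          class = "aromakit_configuration_error")
  }
  quotients <- sweep(m, 2, ref, "/")
  f <- apply(quotients, 1, stats::median, na.rm = TRUE)
  add_provenance(sweep(m, 1, f, "/"), paste0("pqn:", reference_sample), from = m)
}

#' Pareto scaling
#'
#' Mean-centers each column and divides by the square root of its standard
#' deviation — a compromise between no scaling (dominated by abundant
#' compounds) and unit-variance scaling (inflates noise of trace
#' compounds). Constant columns become all-zero and are flagged in the
#' `constant_columns` attribute.
#'
#' @param m Data matrix with at least two rows.
#' @export
pareto_scale <- function(m) {
  stopifnot(nrow(m) >= 2)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  centered <- sweep(m, 2, mu, "-")
  scl <- sqrt(s)
  scl[s == 0] <- 1  # centered column is already all zero
  out <- sweep(centered, 2, scl, "/")
  out <- add_provenance(out, "pareto", from = m)
  attr(out, "constant_columns") <- colnames(m)[s == 0]
  out
}

#' Sample-to-sample Spearman correlation matrix
#'
#' Rank correlations between sample rows (average ranks on ties); a
#' monotone-transform-invariant view of sample similarity.
#'
#' @param m Data matrix with at least three columns.
#' @export
spearman_matrix <- function(m) {
  stopifnot(ncol(m) >= 3)
  stats::cor(t(m), method = "spearman")
}

#' Principal coordinate analysis
#'
#' Classical metric multidimensional scaling: a distance matrix is
#' Gower-double-centered and eigendecomposed; coordinates on the
#' positive-eigenvalue axes are eigenvectors scaled by the square root of
#' their eigenvalues, so Euclidean distances among coordinates reproduce
#' the input distances whenever those are Euclidean-embeddable. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported and their axes dropped.
#'
#' @param m Data matrix (>= 3 samples).
#' @param metric Distance measure passed to [vegan::vegdist()]; default
#'   `"bray"`, with `"euclidean"` the common alternative.
#' @return List of class `aroma_pcoa`: `coordinates`, `eigenvalues`
#'   (all, descending), `negative_eigenvalues`, `variance_explained`
#'   (share of the positive eigenvalue sum), `metric`.
#' @export
pcoa <- function(m, metric = "bray") {
  stopifnot(nrow(m) >= 3)
  ok_metrics <- c("manhattan", "euclidean", "canberra", "clark", "bray",
                  "kulczynski", "jaccard", "gower", "altGower", "morisita",
                  "horn", "mountford", "raup", "binomial", "chao", "cao",
                  "mahalanobis", "chisq", "chord", "hellinger", "aitchison",
                  "robust.aitchison")
  if (!metric %in% ok_metrics) {
    abort(paste0("unknown distance metric: ", metric),
          class = "aromakit_configuration_error")
  }
  d <- vegan::vegdist(m, method = metric)
  # all n-1 axes are requested and the non-positive ones dropped below, so
  # cmdscale's note about fewer positive eigenvalues is expected
  fit <- withCallingHandlers(
    stats::cmdscale(d, k = nrow(m) - 1, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  eig <- fit$eig
  pos <- eig > max(eig) * 1e-12
  coords <- fit$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = coords,
      eigenvalues = eig,
      negative_eigenvalues = eig[eig < 0],
      variance_explained = eig[pos] / sum(eig[pos]),
      metric = metric
    ),
    class = "aroma_pcoa"
  )
}
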