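## Multi-sample per-patient analysis: which variants are shared between a
## primary tumor and its metastases, which metastases look polyphyletic,
## what was acquired during progression, and the cluster-retention rule
## applied to clonal-deconvolution output.

#' Per-patient variant sets
#'
#' Bundles the variant keys of each of a patient's samples with their
#' roles. Variant identity across samples is `(chrom, pos, ref, alt)`
#' only — depths never enter (see [variant_keys()]).
#'
#' @param patient_id Patient identifier.
#' @param sets Named list of character vectors of variant keys, one per
#'   sample (duplicates within a sample are collapsed).
#' @param roles Named character vector mapping each sample to `"primary"`
#'   or `"metastasis"`; at most one primary.
#' @return An object of class `patient_variant_sets`.
#' @export
patient_variant_sets <- function(patient_id, sets, roles) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            setequal(names(sets), names(roles)),
            all(roles %in% c("primary", "metastasis")))
  if (sum(roles == "primary") > 1)
    stop("at most one primary sample per patient")
  sets <- lapply(sets, unique)
  structure(list(patient_id = patient_id, sets = sets,
                 roles = roles[names(sets)]),
            class = "patient_variant_sets")
}

#' Pairwise shared-variant matrix
#'
#' Entry `(i, j)` is the number of variant keys shared by samples `i` and
#' `j`; the diagonal holds the set sizes. Symmetric, with the diagonal
#' dominating its row.
#'
#' @param sets A [patient_variant_sets()], or a named list of key
#'   vectors.
#' @return Symmetric integer matrix with sample names on both dims.
#' @export
shared_matrix <- function(sets) {
  if (inherits(sets, "patient_variant_sets")) sets <- sets$sets
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, unique)
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n))
    for (j in i:n)
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
  m
}

#' Polyphyly consistency check per metastasis
#'
#' A metastasis is flagged consistent with polyphyletic seeding when it
#' shares strictly more variants with the primary tumor than with every
#' other metastasis. Ties are conservative: a tie with any sibling
#' metastasis yields `FALSE` and sets the tie flag (no polyphyly claim on
#' ties). With a single metastasis the condition is vacuously `TRUE`.
#'
#' @param m Shared matrix from [shared_matrix()].
#' @param roles Named role vector (`"primary"`/`"metastasis"`) covering
#'   the matrix dimnames; exactly one primary.
#' @return `data.frame` with columns `sample_id`, `polyphyletic`, `tie`.
#' @export
polyphyly_check <- function(m, roles) {
  stopifnot(is.matrix(m), setequal(rownames(m), names(roles)))
  roles <- roles[rownames(m)]
  primary <- names(roles)[roles == "primary"]
  if (length(primary) != 1)
    stop("polyphyly_check() requires exactly one primary sample")
  mets <- names(roles)[roles == "metastasis"]
  res <- lapply(mets, function(met) {
    others <- setdiff(mets, met)
    with_primary <- m[met, primary]
    with_others <- if (length(others)) m[met, others] else integer(0)
    tie <- any(with_others == with_primary)
    data.frame(sample_id = met,
               polyphyletic = all(with_primary > with_others) && !tie,
               tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Variants acquired by a metastasis, and their CpG>TpG fraction
#'
#' Computes the set difference `met \ reference` — the variants private
#' to the metastasis relative to a reference set (by default the primary
#' tumor's variants, a proxy for the founding clone; an explicit founder
#' variant list may be supplied instead) — and, when a variant table and
#' reference sequence are given, the CpG>TpG fraction of the acquired
#' variants via [compute_spectrum()].
#'
#' @param met_keys Variant keys of the metastasis.
#' @param reference_keys Variant keys of the reference set (primary
#'   sample or explicit founder list).
#' @param variants Optional variant table containing (at least) the
#'   acquired variants, used to compute the acquired spectrum.
#' @param reference Optional reference sequence (required with
#'   `variants`).
#' @return List with `n_acquired`, `acquired_keys`, and (when spectra
#'   inputs are given) `cpg_tpg_fraction`, `fraction_undefined` and
#'   `spectrum`.
#' @export
acquired_snvs <- function(met_keys, reference_keys,
                          variants = NULL, reference = NULL) {
  acquired <- setdiff(unique(met_keys), unique(reference_keys))
  out <- list(n_acquired = length(acquired), acquired_keys = acquired)
  if (!is.null(variants)) {
    stopifnot(!is.null(reference))
    sub <- variants[variant_keys(variants) %in% acquired, , drop = FALSE]
    sub$sample_id <- "acquired"
    spec <- compute_spectrum(sub, reference)
    st <- cpg_tpg_stat(spec)
    out$cpg_tpg_fraction <- st$fraction
    out$fraction_undefined <- st$undefined
    out$spectrum <- spec
  }
  out
}

#' Retain clonal clusters by size and cancer-cell fraction
#'
#' Applies the retention rule used on clonal-deconvolution output: a
#' cluster is kept iff it holds at least `min_snvs` variants and its mean
#' cancer-cell fraction reaches at least `min_ccf` in at least one sample
#' (both boundaries inclusive). Cluster inference itself is out of scope;
#' clusters arrive as input.
#'
#' @param clusters List of clusters; each a list with `cluster_id`,
#'   `variant_keys` (character) and `ccf` (named numeric, mean CCF per
#'   sample, in `[0, 1]`).
#' @param min_snvs Minimum cluster size (default 5).
#' @param min_ccf Minimum mean CCF in at least one sample (default 0.10).
#' @return The retained subset of `clusters`, order preserved.
#' @export
filter_clusters <- function(clusters, min_snvs = 5L, min_ccf = 0.10) {
  stopifnot(is.list(clusters))
  keep <- vapply(clusters, function(cl) {
    stopifnot(length(cl$variant_keys) >= 1,
              all(cl$ccf >= 0 & cl$ccf <= 1))
    length(cl$variant_keys) >= min_snvs && max(cl$ccf) >= min_ccf
  }, logical(1))
  clusters[keep]
}

#' Write a per-patient lineage report
#'
#' JSON report with the shared matrix, per-metastasis polyphyly flags and
#' acquired-variant summaries. The report records that the reference set
#' for "acquired" is a proxy (the primary sample's variants or a supplied
#' founder list), not an inferred founding clone.
#'
#' @param pvs A [patient_variant_sets()].
#' @param path Output JSON path.
#' @param variants Optional cohort variant table for acquired-spectrum
#'   computation.
#' @param reference Optional reference sequence.
#' @param matrix_tsv Optional path for a TSV copy of the shared matrix.
#' @return `path`, invisibly.
#' @export
write_lineage_report <- function(pvs, path, variants = NULL,
                                 reference = NULL, matrix_tsv = NULL) {
  m <- shared_matrix(pvs)
  poly <- polyphyly_check(m, pvs$roles)
  primary <- names(pvs$roles)[pvs$roles == "primary"]
  acq <- lapply(poly$sample_id, function(met) {
    a <- acquired_snvs(pvs$sets[[met]], pvs$sets[[primary]],
                       variants, reference)
    c(list(sample_id = met), a[setdiff(names(a),
                                       c("acquired_keys", "spectrum"))])
  })
  jsonlite::write_json(
    list(patient_id = pvs$patient_id,
         reference_set = "primary-sample proxy for founding clone",
         shared = as.data.frame(m),
         polyphyly = poly,
         acquired = acq),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(matrix_tsv))
    write.table(m, matrix_tsv, sep = "\t", quote = FALSE)
  invisible(path)
}
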