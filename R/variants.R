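## Variant tables: the package-wide representation of somatic calls.
## A variant table is a plain data.frame with one row per call and a fixed
## column set; all readers normalize to it and all downstream modules
## consume it.

VARIANT_COLUMNS <- c(
  "sample_id", "patient_id", "chrom", "pos", "ref_allele", "alt_allele",
  "variant_class", "callers", "germline_depth", "somatic_depth",
  "allele_depth", "pop_freq", "functional_class"
)

VARIANT_CLASSES <- c("SNV", "INS", "DEL", "other")
FUNCTIONAL_CLASSES <- c("synonymous", "nonsynonymous", "other", "missing")

#' Construct a somatic variant table
#'
#' Builds the canonical variant table used throughout the package: one row
#' per somatic call, with 1-based inclusive coordinates (MAF/VCF native),
#' caller provenance as a comma-separated label set, and the depth and
#' population-frequency annotations consumed by [apply_filters()].
#' Missing annotations are `NA`, never zero.
#'
#' @param sample_id,patient_id Character; sample and patient identifiers.
#' @param chrom Character contig names.
#' @param pos Integer 1-based positions (`pos >= 1`).
#' @param ref_allele,alt_allele Alleles. For `variant_class = "SNV"` both
#'   must be a single base in `A`,`C`,`G`,`T` and differ.
#' @param variant_class One of `"SNV"`, `"INS"`, `"DEL"`, `"other"`.
#' @param callers Comma-separated caller labels (e.g. `"mutect2,mpileup"`).
#' @param germline_depth,somatic_depth,allele_depth Read counts (`NA` when
#'   unknown). `allele_depth` may not exceed `somatic_depth`.
#' @param pop_freq Population allele frequency in `[0, 1]`, or `NA`.
#' @param functional_class One of `"synonymous"`, `"nonsynonymous"`,
#'   `"other"`, `"missing"`.
#' @return A `data.frame` with the 13 canonical columns.
#' @examples
#' variant_table(sample_id = "S1", chrom = "chr1", pos = 100,
#'               ref_allele = "C", alt_allele = "T")
#' @export
variant_table <- function(sample_id = character(), patient_id = sample_id,
                          chrom = character(), pos = integer(),
                          ref_allele = character(), alt_allele = character(),
                          variant_class = "SNV", callers = "",
                          germline_depth = NA_integer_,
                          somatic_depth = NA_integer_,
                          allele_depth = NA_integer_,
                          pop_freq = NA_real_,
                          functional_class = "missing") {
  n <- max(length(sample_id), length(chrom), length(pos),
           length(ref_allele), length(alt_allele))
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    patient_id = rep_len(as.character(patient_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    ref_allele = rep_len(toupper(as.character(ref_allele)), n),
    alt_allele = rep_len(toupper(as.character(alt_allele)), n),
    variant_class = rep_len(as.character(variant_class), n),
    callers = rep_len(as.character(callers), n),
    germline_depth = rep_len(as.integer(germline_depth), n),
    somatic_depth = rep_len(as.integer(somatic_depth), n),
    allele_depth = rep_len(as.integer(allele_depth), n),
    pop_freq = rep_len(as.numeric(pop_freq), n),
    functional_class = rep_len(as.character(functional_class), n),
    stringsAsFactors = FALSE
  )
  validate_variant_table(df)
}

## Internal consistency checks shared by the constructor and the readers.
validate_variant_table <- function(df) {
  stopifnot(is.data.frame(df), all(VARIANT_COLUMNS %in% names(df)))
  df <- df[, VARIANT_COLUMNS]
  if (nrow(df) == 0) return(df)
  if (any(df$pos < 1, na.rm = TRUE))
    stop("variant positions must be >= 1 (1-based coordinates)")
  bad_class <- setdiff(unique(df$variant_class), VARIANT_CLASSES)
  if (length(bad_class))
    stop("unknown variant_class: ", paste(bad_class, collapse = ", "))
  bad_fun <- setdiff(unique(df$functional_class), FUNCTIONAL_CLASSES)
  if (length(bad_fun))
    stop("unknown functional_class: ", paste(bad_fun, collapse = ", "))
  snv <- df$variant_class == "SNV"
  if (any(snv)) {
    ok <- df$ref_allele[snv] %in% c("A", "C", "G", "T") &
      df$alt_allele[snv] %in% c("A", "C", "G", "T") &
      df$ref_allele[snv] != df$alt_allele[snv]
    if (!all(ok))
      stop("SNV records must have single, distinct A/C/G/T ref and alt alleles")
  }
  ad_gt_dp <- !is.na(df$allele_depth) & !is.na(df$somatic_depth) &
    df$allele_depth > df$somatic_depth
  if (any(ad_gt_dp))
    stop("allele_depth exceeds somatic_depth in ", sum(ad_gt_dp), " record(s)")
  if (any(!is.na(df$pop_freq) & (df$pop_freq < 0 | df$pop_freq > 1)))
    stop("pop_freq must lie in [0, 1]")
  df
}

#' Variant identity keys
#'
#' Identity of a variant across samples and callers is defined by
#' `(chrom, pos, ref, alt)` only; depths and annotations never enter the
#' key. Used for caller merging and for shared/private analysis across a
#' patient's samples.
#'
#' @param variants A variant table (see [variant_table()]).
#' @return Character vector of `chrom:pos:ref>alt` keys, one per row.
#' @export
variant_keys <- function(variants) {
  paste0(variants$chrom, ":", variants$pos, ":",
         variants$ref_allele, ">", variants$alt_allele)
}

## Reverse complement of plain character DNA (vectorized over strings).
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(
    strsplit(x, NULL),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  ))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)
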