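#' Filter thresholds for the somatic call cascade
#'
#' The cascade rejects a call when any of five rules fires, each phrased
#' as a strict inequality: germline position depth below
#' `min_germline_depth`, somatic position depth below `min_somatic_depth`,
#' allele depth below `min_allele_depth`, allele fraction (AD/DP against
#' the somatic depth) below `min_allele_fraction`, or population allele
#' frequency above `max_pop_freq`. Records exactly at a threshold are
#' retained (an AD/DP ratio of exactly 0.05 passes; a population
#' frequency of exactly 0.01 passes). A sixth, configurable rule rejects
#' calls seen by fewer than `min_callers` callers; the default of 1
#' mirrors a union merge.
#'
#' @param min_germline_depth Minimum germline DP, reads (default 10).
#' @param min_somatic_depth Minimum somatic DP, reads (default 10).
#' @param min_allele_depth Minimum allele depth AD, reads (default 6).
#' @param min_allele_fraction Minimum AD/DP fraction (default 0.05).
#' @param max_pop_freq Maximum population frequency (default 0.01).
#' @param min_callers Minimum number of supporting callers (default 1).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_germline_depth = 10L,
                              min_somatic_depth = 10L,
                              min_allele_depth = 6L,
                              min_allele_fraction = 0.05,
                              max_pop_freq = 0.01,
                              min_callers = 1L) {
  th <- list(min_germline_depth = min_germline_depth,
             min_somatic_depth = min_somatic_depth,
             min_allele_depth = min_allele_depth,
             min_allele_fraction = min_allele_fraction,
             max_pop_freq = max_pop_freq,
             min_callers = min_callers)
  stopifnot(all(vapply(th, function(x) is.numeric(x) && x >= 0, logical(1))),
            min_allele_fraction <= 1, max_pop_freq <= 1)
  structure(th, class = "filter_thresholds")
}

## Number of caller labels in a comma-separated callers field.
n_callers <- function(callers) {
  vapply(strsplit(callers, ",", fixed = TRUE),
         function(x) length(unique(x[nzchar(x)])), integer(1))
}

#' Merge per-caller somatic call sets by union
#'
#' Unions call sets from multiple callers for one sample. Records
#' identical on `(chrom, pos, ref, alt)` collapse into a single record
#' whose `callers` field is the union of labels. Depths are resolved by
#' keeping the annotations of the contributing record with the highest
#' somatic depth (ties broken by allele depth): callers disagree on
#' depths, and the union merge is deliberately permissive. `pop_freq` and
#' `functional_class` are taken from the first record that has them.
#' Output is sorted by `(chrom, pos, alt_allele)`.
#'
#' @param call_sets List of variant tables, all for the same sample.
#' @return A merged variant table.
#' @export
merge_callers <- function(call_sets) {
  stopifnot(is.list(call_sets), length(call_sets) >= 1)
  all_calls <- do.call(rbind, call_sets)
  if (nrow(all_calls) == 0) return(validate_variant_table(all_calls))
  if (length(unique(all_calls$sample_id)) > 1)
    stop("merge_callers() requires a single sample_id; got: ",
         paste(unique(all_calls$sample_id), collapse = ", "))
  key <- variant_keys(all_calls)
  merged <- lapply(split(all_calls, key), function(grp) {
    # best-supported depths win; annotations fall back to first non-missing
    o <- order(-ifelse(is.na(grp$somatic_depth), -1, grp$somatic_depth),
               -ifelse(is.na(grp$allele_depth), -1, grp$allele_depth))
    rec <- grp[o[1], , drop = FALSE]
    labels <- unique(unlist(strsplit(grp$callers, ",", fixed = TRUE)))
    rec$callers <- paste(sort(labels[nzchar(labels)]), collapse = ",")
    if (is.na(rec$pop_freq)) rec$pop_freq <- first_non_na(grp$pop_freq)
    if (rec$functional_class == "missing") {
      fc <- grp$functional_class[grp$functional_class != "missing"]
      if (length(fc)) rec$functional_class <- fc[1]
    }
    rec
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$pos, out$alt_allele), , drop = FALSE]
  rownames(out) <- NULL
  validate_variant_table(out)
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) x[1] else x[NA_integer_]
}

FILTER_RULES <- c("germline_depth", "somatic_depth", "allele_depth",
                  "allele_fraction", "pop_freq", "min_callers")

#' Apply the somatic filter cascade
#'
#' Evaluates every rule on every record (see [filter_thresholds()] for
#' the rule definitions and boundary semantics) and splits the input into
#' retained and rejected calls. The audit counts each record once under
#' every rule it fails, so audit totals can exceed the number of rejected
#' records. Missing annotations cannot fire a rule: a record with `NA`
#' population frequency is not frequency-filtered, and likewise for
#' missing depths.
#'
#' @param variants A variant table.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with elements `retained` (variant table), `rejected`
#'   (variant table), and `audit` (data.frame with columns `rule`,
#'   `n_failed`).
#' @export
apply_filters <- function(variants, thresholds = filter_thresholds()) {
  variants <- validate_variant_table(variants)
  th <- thresholds
  inconsistent <- !is.na(variants$somatic_depth) &
    variants$somatic_depth == 0 &
    !is.na(variants$allele_depth) & variants$allele_depth > 0
  if (any(inconsistent))
    stop("somatic_depth = 0 with allele_depth > 0 in ",
         sum(inconsistent), " record(s)")
  lt <- function(x, cut) !is.na(x) & x < cut
  ratio <- variants$allele_depth / variants$somatic_depth
  fails <- cbind(
    germline_depth = lt(variants$germline_depth, th$min_germline_depth),
    somatic_depth = lt(variants$somatic_depth, th$min_somatic_depth),
    allele_depth = lt(variants$allele_depth, th$min_allele_depth),
    allele_fraction = lt(ratio, th$min_allele_fraction),
    pop_freq = !is.na(variants$pop_freq) &
      variants$pop_freq > th$max_pop_freq,
    min_callers = n_callers(variants$callers) < th$min_callers &
      th$min_callers > 1
  )
  rejected <- if (nrow(variants)) rowSums(fails) > 0 else logical(0)
  audit <- data.frame(rule = FILTER_RULES,
                      n_failed = if (nrow(variants)) colSums(fails)
                                 else rep(0L, length(FILTER_RULES)),
                      row.names = NULL, stringsAsFactors = FALSE)
  ret <- variants[!rejected, , drop = FALSE]
  rej <- variants[rejected, , drop = FALSE]
  rownames(ret) <- rownames(rej) <- NULL
  list(retained = ret, rejected = rej, audit = audit)
}

#' Write a filter audit table
#'
#' @param audit The `audit` element returned by [apply_filters()].
#' @param path Output TSV path (columns `rule`, `n_failed`).
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
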