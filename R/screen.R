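#' Configuration of the hypermutator cohort screen
#'
#' A sample is a screen hit when it is both hypermutated (more than
#' `min_snv` SNVs; strict) and CpG>TpG-enriched (CpG>TpG/SNVs above
#' `min_fraction`; strict). Fold-changes of the SNV burden are computed
#' against a cohort baseline: by default the arithmetic mean of the other
#' samples' SNV counts (excluding the index sample avoids an outlier
#' inflating its own baseline); the median is available as an
#' alternative.
#'
#' @param min_snv Hypermutation cut, SNVs per tumor (default 200,
#'   strict `>`).
#' @param min_fraction CpG>TpG enrichment cut (default 0.6, strict `>`).
#' @param baseline_statistic `"mean"` or `"median"`.
#' @param baseline_excludes_self Exclude the index sample from its own
#'   baseline (default `TRUE`).
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(min_snv = 200L, min_fraction = 0.6,
                          baseline_statistic = c("mean", "median"),
                          baseline_excludes_self = TRUE) {
  stopifnot(min_snv >= 0, min_fraction > 0, min_fraction < 1)
  structure(list(min_snv = min_snv, min_fraction = min_fraction,
                 baseline_statistic = match.arg(baseline_statistic),
                 baseline_excludes_self = isTRUE(baseline_excludes_self)),
            class = "screen_config")
}

#' Summarize one sample for the cohort screen
#'
#' Derives the per-sample screen quantities from its spectrum: SNV count,
#' CpG>TpG fraction, the fraction of C>T outside CpG contexts (the second
#' axis of the cohort scatter), and the strict hypermutation/enrichment
#' flags. `is_hit` is their conjunction. Fold-change is filled in later
#' by [screen_cohort()], once the whole cohort is known.
#'
#' @param spectrum A `mutation_spectrum` from [compute_spectrum()].
#' @param config A [screen_config()].
#' @param sample_id,cohort_id Identifiers carried into the summary.
#' @param n_nonsynonymous Optional non-synonymous SNV count (input
#'   metadata; the package never computes functional consequences).
#' @return One-row `data.frame` with columns `sample_id`, `cohort_id`,
#'   `n_snv`, `n_nonsynonymous`, `cpg_tpg_fraction`, `ct_other_fraction`,
#'   `fraction_undefined`, `is_hypermutated`, `is_enriched`, `is_hit`,
#'   `fold_change` (`NA` until cohort context is available).
#' @export
summarize_sample <- function(spectrum, config = screen_config(),
                             sample_id = "sample", cohort_id = "cohort",
                             n_nonsynonymous = NA_integer_) {
  stopifnot(inherits(spectrum, "mutation_spectrum"),
            inherits(config, "screen_config"))
  st <- cpg_tpg_stat(spectrum)
  ct_all <- sum(spectrum$counts[grepl("\\[C>T\\]", names(spectrum$counts))])
  ct_other <- ct_all - st$n_cpg_tpg
  hyper <- st$n_snv > config$min_snv
  enriched <- !st$undefined && st$fraction > config$min_fraction
  data.frame(
    sample_id = sample_id,
    cohort_id = cohort_id,
    n_snv = st$n_snv,
    n_nonsynonymous = as.integer(n_nonsynonymous),
    cpg_tpg_fraction = st$fraction,
    ct_other_fraction = if (st$n_snv > 0) ct_other / st$n_snv else 0,
    fraction_undefined = st$undefined,
    is_hypermutated = hyper,
    is_enriched = enriched,
    is_hit = hyper && enriched,
    fold_change = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Fold-change of a sample's SNV burden over the cohort baseline
#'
#' @param sample_n_snv SNV count of the index sample.
#' @param cohort_counts SNV counts of the cohort (excluding the index
#'   sample if `config$baseline_excludes_self` was applied by the
#'   caller).
#' @param config A [screen_config()]; selects mean or median baseline.
#' @return `sample_n_snv / baseline`, or `NA` with a warning-free
#'   undefined result when the baseline is 0 or the cohort is empty.
#' @export
fold_change <- function(sample_n_snv, cohort_counts,
                        config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (length(cohort_counts) == 0) return(NA_real_)
  base <- switch(config$baseline_statistic,
                 mean = mean(cohort_counts),
                 median = median(cohort_counts))
  if (!is.finite(base) || base <= 0) return(NA_real_)
  sample_n_snv / base
}

#' Screen a cohort for hypermutated CpG>TpG-enriched outliers
#'
#' Takes the per-sample summaries of one or more cohorts, fills in each
#' sample's fold-change against its cohort baseline, and assembles the
#' ordered hit list: samples with `is_hit = TRUE`, sorted by descending
#' CpG>TpG fraction, then descending SNV count. The full per-sample table
#' retains the 2D screen coordinates (CpG>TpG fraction vs C>T-other
#' fraction) for plotting.
#'
#' @param summaries A `data.frame` of rows from [summarize_sample()]
#'   (or a list of such rows), one per sample; duplicate `sample_id`s
#'   within a cohort are an error.
#' @param config A [screen_config()].
#' @return An object of class `cohort_screen_report`: list with
#'   `summaries` (per-sample table), `hits` (ordered subset) and
#'   `config`.
#' @export
screen_cohort <- function(summaries, config = screen_config()) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  stopifnot(is.data.frame(summaries), inherits(config, "screen_config"))
  key <- paste(summaries$cohort_id, summaries$sample_id)
  if (anyDuplicated(key))
    stop("duplicate sample_id within a cohort: ",
         summaries$sample_id[duplicated(key)][1])
  summaries <- summaries[order(summaries$cohort_id, summaries$sample_id), ,
                         drop = FALSE]
  for (i in seq_len(nrow(summaries))) {
    same <- summaries$cohort_id == summaries$cohort_id[i]
    if (config$baseline_excludes_self) same[i] <- FALSE
    summaries$fold_change[i] <-
      fold_change(summaries$n_snv[i], summaries$n_snv[same], config)
  }
  hits <- summaries[summaries$is_hit, , drop = FALSE]
  hits <- hits[order(-hits$cpg_tpg_fraction, -hits$n_snv), , drop = FALSE]
  rownames(summaries) <- rownames(hits) <- NULL
  structure(list(summaries = summaries, hits = hits, config = config),
            class = "cohort_screen_report")
}

#' @export
print.cohort_screen_report <- function(x, ...) {
  cat("Cohort hypermutator screen\n")
  cat(sprintf("  samples: %d in %d cohort(s)\n", nrow(x$summaries),
              length(unique(x$summaries$cohort_id))))
  cat(sprintf("  thresholds: > %d SNVs and CpG>TpG/SNVs > %.2f\n",
              x$config$min_snv, x$config$min_fraction))
  cat(sprintf("  hypermutated: %d; enriched: %d; hits: %d\n",
              sum(x$summaries$is_hypermutated),
              sum(x$summaries$is_enriched), nrow(x$hits)))
  if (nrow(x$hits)) {
    cat("  hit list (descending CpG>TpG fraction):\n")
    h <- x$hits
    for (i in seq_len(nrow(h)))
      cat(sprintf("    %s [%s]: %d SNVs, CpG>TpG %.3f, fold-change %s\n",
                  h$sample_id[i], h$cohort_id[i], h$n_snv[i],
                  h$cpg_tpg_fraction[i],
                  ifelse(is.na(h$fold_change[i]), "NA",
                         sprintf("%.1f", h$fold_change[i]))))
  }
  invisible(x)
}

#' @export
plot.cohort_screen_report <- function(x, ...) {
  s <- x$summaries
  graphics::plot(s$cpg_tpg_fraction, s$ct_other_fraction,
                 col = ifelse(s$is_hit, "red", "grey40"),
                 pch = 19, xlim = c(0, 1),
                 xlab = "C>T in CpG context / SNVs",
                 ylab = "C>T in other contexts / SNVs", ...)
  graphics::abline(v = x$config$min_fraction, lty = 2, col = "grey70")
  invisible(x)
}

#' Write a screen report as JSON (plus optional per-sample TSV)
#'
#' @param report A `cohort_screen_report`.
#' @param path Output JSON path.
#' @param tsv_path Optional path for a per-sample TSV mirror.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path, tsv_path = NULL) {
  jsonlite::write_json(
    list(config = unclass(report$config),
         n_samples = nrow(report$summaries),
         n_hits = nrow(report$hits),
         hits = report$hits,
         samples = report$summaries),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  if (!is.null(tsv_path))
    write.table(report$summaries, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}
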