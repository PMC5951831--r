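## Worked examples and validation experiments built from the package's
## own simulator. These are the entry points the acceptance checks and
## the vignette use; they contain no logic of their own beyond driving
## the pipeline and scoring the result against planted truth.

#' Build a single hypermutated-case fixture with exact totals
#'
#' Constructs a synthetic reference and a single-sample variant table
#' with exactly `n_cpg` CpG>TpG SNVs (spread over the four `N[C>T]G`
#' channels) and `n_other` SNVs spread over non-CpG channels. The
#' defaults reproduce the mutation load characteristic of an
#' MBD4-deficient uveal melanoma: 474 SNVs of which 460 (97%) are
#' CpG>TpG.
#'
#' @param n_cpg Number of CpG>TpG SNVs (default 460).
#' @param n_other Number of non-CpG>TpG SNVs (default 14).
#' @param seed Seed for reference simulation and variant placement.
#' @return List with `variants` (variant table), `reference`, and
#'   `sample_id`.
#' @export
hypermutator_case <- function(n_cpg = 460L, n_other = 14L, seed = 1L) {
  cfg <- simulation_config(seed = seed, contig_length = 50000L)
  reference <- simulate_reference(cfg)
  set.seed(cfg$seed + 3L)
  cpg <- cpg_tpg_channels()
  other <- setdiff(seq_len(96), cpg)
  channels <- c(rep(cpg, length.out = n_cpg),
                sample(other, n_other, replace = TRUE))
  variants <- plant_snvs(reference, channels, "case_01", cfg)
  list(variants = variants, reference = reference, sample_id = "case_01")
}

#' Germline carrier frequency of a cohort
#'
#' @param n_carriers Number of carriers observed.
#' @param n_total Cohort size.
#' @return Carrier percentage (`100 * n_carriers / n_total`).
#' @export
carrier_frequency <- function(n_carriers, n_total) {
  stopifnot(n_total > 0, n_carriers >= 0, n_carriers <= n_total)
  100 * n_carriers / n_total
}

#' Hypermutator-recovery experiment over seeded synthetic cohorts
#'
#' Runs the full simulate -> spectrum -> screen pipeline on
#' `n_replicates` independent cohorts and scores the screen's hit list
#' against the planted truth. With the default study conditions
#' (background CpG>TpG weight 0.25 at ~15 SNVs per tumor versus planted
#' hypermutators at weight 0.95 carrying 300-1500 SNVs) the separation
#' is wide and both sensitivity and specificity are expected to be 1.
#'
#' @param n_replicates Number of independent cohorts.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param config Template [simulation_config()]; its seed is overridden
#'   per replicate. The reference contig is simulated once from `seed`.
#' @param screen_cfg A [screen_config()].
#' @return List with `sensitivity`, `specificity`, `tp`, `fp`, `fn`,
#'   `tn`, `n_replicates` and `n_samples_per_cohort`.
#' @export
screen_recovery <- function(n_replicates = 100L, seed = 1L,
                            config = simulation_config(),
                            screen_cfg = screen_config()) {
  ref_cfg <- config
  ref_cfg$seed <- as.integer(seed)
  reference <- simulate_reference(ref_cfg)
  tp <- fp <- fn <- tn <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- simulate_cohort(cfg, reference,
                           cohort_id = sprintf("rep%03d", r))
    sums <- do.call(rbind, lapply(
      split(sim$variants, sim$variants$sample_id),
      function(v) summarize_sample(compute_spectrum(v, reference),
                                   screen_cfg, sample_id = v$sample_id[1])))
    # samples whose planted count is zero emit no variants at all
    missing <- setdiff(sim$truth$samples$sample_id, sums$sample_id)
    if (length(missing)) {
      empty <- compute_spectrum(variant_table(), reference)
      sums <- rbind(sums, do.call(rbind, lapply(missing, function(id)
        summarize_sample(empty, screen_cfg, sample_id = id))))
    }
    report <- screen_cohort(sums, screen_cfg)
    truth <- sim$truth$samples
    is_hit <- truth$sample_id %in% report$hits$sample_id
    tp <- tp + sum(is_hit & truth$is_hypermutator)
    fp <- fp + sum(is_hit & !truth$is_hypermutator)
    fn <- fn + sum(!is_hit & truth$is_hypermutator)
    tn <- tn + sum(!is_hit & !truth$is_hypermutator)
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn,
       n_replicates = n_replicates,
       n_samples_per_cohort = config$n_samples)
}

#' Bias of the recovered CpG>TpG fraction against the planted weight
#'
#' Simulates `n_samples` tumors, each with exactly `n_snv` SNVs drawn at
#' CpG>TpG weight `weight`, recomputes each spectrum through the full
#' classification path and reports the mean absolute error of the
#' recovered fraction against the planted weight.
#'
#' @param n_samples Number of simulated samples.
#' @param n_snv SNVs per sample.
#' @param weight Planted CpG>TpG weight.
#' @param seed Seed.
#' @return List with `mae`, `bias` (mean signed error), `fractions` and
#'   the experiment parameters.
#' @export
estimator_recovery <- function(n_samples = 200L, n_snv = 1000L,
                               weight = 0.95, seed = 1L) {
  cfg <- simulation_config(seed = as.integer(seed),
                           n_samples = as.integer(n_samples),
                           hypermutator_fraction = 1,
                           hypermutator_count_range = c(n_snv, n_snv),
                           hypermutator_cpg_weight = weight)
  reference <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, reference)
  fractions <- vapply(split(sim$variants, sim$variants$sample_id),
                      function(v)
                        cpg_tpg_stat(compute_spectrum(v, reference))$fraction,
                      numeric(1))
  list(mae = mean(abs(fractions - weight)),
       bias = mean(fractions - weight),
       fractions = unname(fractions),
       n_samples = n_samples, n_snv = n_snv, weight = weight)
}
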