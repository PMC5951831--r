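## Seeded synthetic-data generation. Everything the pipeline consumes can
## be simulated: a reference contig, cohorts of low-burden tumors with
## planted CpG>TpG-dominated hypermutators, and per-caller call tables
## with planted filter-rule violations — each with a machine-readable
## truth table. All randomness flows from the single seed in the config.

CALLER_LABELS <- c("haplotypecaller", "mutect2", "mpileup")

#' Configuration of the synthetic-data generator
#'
#' Defaults describe the study conditions the generator emulates: a
#' low-burden uveal-melanoma-like background (negative-binomial SNV
#' counts, mean 15; CpG>TpG weight 0.25, below the <30% seen in
#' non-hypermutated tumors) against planted hypermutators carrying
#' 300-1500 SNVs at CpG>TpG weight 0.95 (within the 91-97% band of
#' MBD4-deficient tumors).
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_samples Cohort size.
#' @param hypermutator_fraction Fraction of samples planted as
#'   hypermutators (the planted number is `round(fraction * n_samples)`).
#' @param background_count_mean,background_count_dispersion Negative
#'   binomial mean and size for background per-sample SNV counts.
#' @param hypermutator_count_range Integer interval for hypermutator SNV
#'   counts (uniform).
#' @param background_cpg_weight,hypermutator_cpg_weight Planted
#'   probability that a simulated SNV is CpG>TpG.
#' @param contig_length Simulated contig length in bases (>= 1000).
#' @param gc_content GC fraction in (0, 1); realized exactly (rounded to
#'   a base count).
#' @param depth_mean Mean sequencing depth (Poisson) for germline and
#'   somatic position depth.
#' @param allele_fraction_shape1,allele_fraction_shape2 Beta parameters
#'   of the simulated variant allele fraction (defaults give mean 0.4).
#' @param violation_rates Named numeric vector of planted filter-rule
#'   violation rates over `c("germline_depth", "somatic_depth",
#'   "allele_depth", "allele_fraction", "pop_freq")`; the planted number
#'   per rule is `round(rate * n_variants)`, each violating exactly that
#'   one rule.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 20L,
                              hypermutator_fraction = 0.1,
                              background_count_mean = 15,
                              background_count_dispersion = 10,
                              hypermutator_count_range = c(300L, 1500L),
                              background_cpg_weight = 0.25,
                              hypermutator_cpg_weight = 0.95,
                              contig_length = 100000L,
                              gc_content = 0.4,
                              depth_mean = 80,
                              allele_fraction_shape1 = 8,
                              allele_fraction_shape2 = 12,
                              violation_rates = c(germline_depth = 0,
                                                  somatic_depth = 0,
                                                  allele_depth = 0,
                                                  allele_fraction = 0,
                                                  pop_freq = 0)) {
  probs <- c(hypermutator_fraction, background_cpg_weight,
             hypermutator_cpg_weight, violation_rates)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and rates must lie in [0, 1]")
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie strictly within (0, 1)")
  if (any(hypermutator_count_range < 1) ||
      hypermutator_count_range[1] > hypermutator_count_range[2])
    stop("hypermutator_count_range must be a positive, ordered interval")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 hypermutator_fraction = hypermutator_fraction,
                 background_count_mean = background_count_mean,
                 background_count_dispersion = background_count_dispersion,
                 hypermutator_count_range = as.integer(hypermutator_count_range),
                 background_cpg_weight = background_cpg_weight,
                 hypermutator_cpg_weight = hypermutator_cpg_weight,
                 contig_length = as.integer(contig_length),
                 gc_content = gc_content,
                 depth_mean = depth_mean,
                 allele_fraction_shape1 = allele_fraction_shape1,
                 allele_fraction_shape2 = allele_fraction_shape2,
                 violation_rates = violation_rates),
            class = "simulation_config")
}

#' Simulate a reference contig
#'
#' Generates a single contig named `chr_sim` with the requested GC
#' content realized exactly (the G+C base count is `round(gc * length)`;
#' placements are random). Reproducible: the same config yields a
#' byte-identical sequence.
#'
#' @param config A [simulation_config()].
#' @return Named character vector of length 1 (usable directly as a
#'   reference, or written with [write_reference()]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$contig_length
  if (L < 1000L)
    stop("contig_length must be at least 1000 bases")
  set.seed(config$seed)
  n_gc <- round(config$gc_content * L)
  bases <- rep("x", L)
  gc_pos <- sample.int(L, n_gc)
  bases[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  bases[bases == "x"] <- sample(c("A", "T"), L - n_gc, replace = TRUE)
  seq <- paste(bases, collapse = "")
  if (!grepl("CG", seq, fixed = TRUE))
    stop("simulated contig contains no CpG dinucleotide; ",
         "increase contig_length or gc_content")
  c(chr_sim = seq)
}

## Index of trinucleotide contexts: maps each 3-mer to the 1-based
## positions (of the center base) where it occurs on the forward strand.
context_index <- function(reference) {
  lapply(reference, function(seq) {
    L <- nchar(seq)
    pos <- 2:(L - 1L)
    tri <- substring(seq, pos - 1L, pos + 1L)
    split(pos, tri)
  })
}

## Candidate center positions for one SBS96 channel: forward-strand
## occurrences of the pyrimidine-centered context, plus forward-strand
## occurrences of its reverse complement (where the mutation is planted
## as the complementary purine substitution).
channel_positions <- function(cidx_contig, channel_label) {
  ctx <- paste0(substr(channel_label, 1, 1), substr(channel_label, 3, 3),
                substr(channel_label, 7, 7))
  fwd <- cidx_contig[[ctx]]
  rev <- cidx_contig[[revcomp(ctx)]]
  list(fwd = if (is.null(fwd)) integer(0) else fwd,
       rev = if (is.null(rev)) integer(0) else rev)
}

#' Plant SNVs with exact per-channel counts
#'
#' Places one SNV per requested channel occurrence at a reference
#' position whose trinucleotide context matches the channel — on either
#' strand, so a CpG>TpG variant may appear as plus-strand C>T or
#' minus-strand G>A at a genuine CpG site. Positions are sampled without
#' replacement within the sample, so the planted spectrum is exact by
#' construction. Depth annotations are drawn from the config's depth
#' model and always pass the default filter cascade.
#'
#' @param reference Reference sequence (e.g. [simulate_reference()]).
#' @param channel_idx Integer vector of SBS96 channel indices, one per
#'   SNV to plant.
#' @param sample_id Sample identifier for the emitted records.
#' @param config A [simulation_config()] (depth model parameters).
#' @param cidx Optional precomputed [context index][context_index]
#'   (reused across samples for speed).
#' @return A variant table with `length(channel_idx)` SNV rows.
#' @export
plant_snvs <- function(reference, channel_idx, sample_id,
                       config = simulation_config(), cidx = NULL) {
  if (is.null(cidx)) cidx <- context_index(reference)
  contig <- names(reference)[1]
  labels <- sbs96_channels()
  n <- length(channel_idx)
  if (n == 0) return(variant_table())
  used <- integer(0)
  pos <- integer(n)
  strand <- character(n)
  for (ch in unique(channel_idx)) {
    rows <- which(channel_idx == ch)
    pool <- channel_positions(cidx[[contig]], labels[ch])
    cand_pos <- c(pool$fwd, pool$rev)
    cand_strand <- rep(c("+", "-"), c(length(pool$fwd), length(pool$rev)))
    free <- !(cand_pos %in% used)
    if (sum(free) < length(rows))
      stop("insufficient ", labels[ch], " context sites: need ",
           length(rows), ", have ", sum(free),
           " free; increase contig_length")
    pick <- sample(which(free), length(rows))
    pos[rows] <- cand_pos[pick]
    strand[rows] <- cand_strand[pick]
    used <- c(used, cand_pos[pick])
  }
  pyr_ref <- substr(labels[channel_idx], 3, 3)
  pyr_alt <- substr(labels[channel_idx], 5, 5)
  minus <- strand == "-"
  ref_allele <- ifelse(minus, comp_base(pyr_ref), pyr_ref)
  alt_allele <- ifelse(minus, comp_base(pyr_alt), pyr_alt)
  dp <- rpois(n, config$depth_mean) + 10L  # comfortably above filter cuts
  gdp <- rpois(n, config$depth_mean) + 10L
  vaf <- stats::rbeta(n, config$allele_fraction_shape1,
                      config$allele_fraction_shape2)
  ad <- rbinom(n, dp, vaf)
  ad <- pmin(pmax(ad, 6L, ceiling(0.05 * dp)), dp)
  variant_table(sample_id = sample_id, patient_id = sample_id,
                chrom = contig, pos = pos,
                ref_allele = ref_allele, alt_allele = alt_allele,
                variant_class = "SNV", callers = "",
                germline_depth = gdp, somatic_depth = dp,
                allele_depth = ad, pop_freq = 0,
                functional_class = "missing")
}

## Draw per-variant channel indices for one sample: CpG>TpG with
## probability `cpg_weight` (uniform over the four N[C>T]G channels),
## otherwise uniform over the remaining 92 channels.
draw_channels <- function(n, cpg_weight) {
  cpg <- cpg_tpg_channels()
  other <- setdiff(seq_len(96), cpg)
  is_cpg <- runif(n) < cpg_weight
  idx <- integer(n)
  idx[is_cpg] <- sample(cpg, sum(is_cpg), replace = TRUE)
  idx[!is_cpg] <- sample(other, sum(!is_cpg), replace = TRUE)
  idx
}

#' Simulate a tumor cohort with planted hypermutators
#'
#' Draws per-sample SNV counts (negative-binomial background;
#' uniform-in-range hypermutators), plants each variant at a reference
#' position matching its drawn SBS96 channel, and returns both the
#' cohort variant table and the ground truth. `round(fraction * n)`
#' samples are hypermutators; which ones is random.
#'
#' @param config A [simulation_config()].
#' @param reference Reference from [simulate_reference()] (or any
#'   single-contig reference).
#' @param cohort_id Cohort label recorded in the truth table.
#' @return List with `variants` (cohort variant table, valid MAF content
#'   for [write_maf()]) and `truth` (list with per-sample data.frame
#'   `samples`: `sample_id`, `is_hypermutator`, `planted_count`,
#'   `planted_cpg_weight`; and per-variant data.frame `variants`:
#'   `sample_id`, `key`, `channel`).
#' @export
simulate_cohort <- function(config, reference, cohort_id = "sim_cohort") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  n <- config$n_samples
  n_hyper <- round(config$hypermutator_fraction * n)
  hyper <- rep(FALSE, n)
  if (n_hyper > 0) hyper[sample.int(n, n_hyper)] <- TRUE
  counts <- integer(n)
  counts[!hyper] <- rnbinom(sum(!hyper),
                            mu = config$background_count_mean,
                            size = config$background_count_dispersion)
  rng <- config$hypermutator_count_range
  counts[hyper] <- rng[1] +
    sample.int(rng[2] - rng[1] + 1L, sum(hyper), replace = TRUE) - 1L
  weights <- ifelse(hyper, config$hypermutator_cpg_weight,
                    config$background_cpg_weight)
  ids <- sprintf("%s_S%02d", cohort_id, seq_len(n))
  cidx <- context_index(reference)
  labels <- sbs96_channels()
  per_sample <- vector("list", n)
  truth_var <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- draw_channels(counts[i], weights[i])
    v <- plant_snvs(reference, ch, ids[i], config, cidx = cidx)
    per_sample[[i]] <- v
    truth_var[[i]] <- data.frame(sample_id = rep(ids[i], counts[i]),
                                 key = variant_keys(v),
                                 channel = labels[ch],
                                 stringsAsFactors = FALSE)
  }
  list(
    variants = do.call(rbind, per_sample),
    truth = list(
      cohort_id = cohort_id,
      samples = data.frame(sample_id = ids, is_hypermutator = hyper,
                           planted_count = counts,
                           planted_cpg_weight = weights,
                           stringsAsFactors = FALSE),
      variants = do.call(rbind, truth_var)
    )
  )
}

#' Split a call set into three per-caller tables with planted violations
#'
#' Assigns every variant to a random non-empty subset of the three
#' caller labels (`haplotypecaller`, `mutect2`, `mpileup`), then rewrites
#' the depth/frequency annotations of a configured fraction of variants
#' so that each violates exactly one filter rule (disjoint sets of
#' variants per rule; annotations are rewritten consistently across all
#' of a variant's callers). The truth table records every planted
#' violation, so a downstream [apply_filters()] audit can be checked
#' exactly.
#'
#' @param variants A variant table (e.g. from [simulate_cohort()]).
#' @param config A [simulation_config()]; `violation_rates` drives the
#'   planting.
#' @return List with `calls` (named list of three per-caller variant
#'   tables), `merged_input` (the annotated table before splitting) and
#'   `truth` (data.frame `key`, `sample_id`, `violated_rule`).
#' @export
simulate_caller_outputs <- function(variants, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  n <- nrow(variants)
  rates <- config$violation_rates
  n_violate <- round(rates * n)
  if (sum(n_violate) > n)
    stop("violation rates sum to more than one violation per record")
  victim <- sample.int(n, sum(n_violate))
  rule_of <- rep(names(n_violate), n_violate)
  for (j in seq_along(victim)) {
    i <- victim[j]
    dp <- variants$somatic_depth[i]
    switch(rule_of[j],
      germline_depth = {
        variants$germline_depth[i] <- sample(0:9, 1)
      },
      somatic_depth = {
        dp <- sample(6:9, 1)
        variants$somatic_depth[i] <- dp
        variants$allele_depth[i] <- 6L + sample.int(dp - 5L, 1) - 1L
      },
      allele_depth = {
        ad <- sample(3:5, 1)
        variants$allele_depth[i] <- ad
        variants$somatic_depth[i] <- min(dp, 20L * ad)
      },
      allele_fraction = {
        variants$somatic_depth[i] <- sample(150:300, 1)
        variants$allele_depth[i] <- 6L
      },
      pop_freq = {
        variants$pop_freq[i] <- runif(1, 0.02, 0.5)
      })
  }
  # random non-empty caller subsets, encoded as rows of a 7-pattern table
  patterns <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                          c = c(TRUE, FALSE))
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  pick <- patterns[sample.int(nrow(patterns), n, replace = TRUE), ,
                   drop = FALSE]
  calls <- lapply(seq_along(CALLER_LABELS), function(k) {
    sub <- variants[pick[[k]], , drop = FALSE]
    sub$callers <- CALLER_LABELS[k]
    rownames(sub) <- NULL
    sub
  })
  names(calls) <- CALLER_LABELS
  truth <- data.frame(key = variant_keys(variants)[victim],
                      sample_id = variants$sample_id[victim],
                      violated_rule = rule_of,
                      stringsAsFactors = FALSE)
  merged_input <- variants
  merged_input$callers <- apply(pick, 1, function(p)
    paste(CALLER_LABELS[unlist(p)], collapse = ","))
  list(calls = calls, merged_input = merged_input, truth = truth)
}

#' Write a full synthetic data bundle to a directory
#'
#' Emits everything an end-to-end run needs: `reference.fa`,
#' `cohort.maf`, one VCF per caller and `truth.json`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  sim <- simulate_cohort(config, reference)
  paths <- list(reference = file.path(dir, "reference.fa"),
                maf = file.path(dir, "cohort.maf"),
                truth = file.path(dir, "truth.json"))
  write_reference(reference, paths$reference)
  write_maf(sim$variants, paths$maf)
  callers <- simulate_caller_outputs(sim$variants, config)
  for (lab in names(callers$calls)) {
    p <- file.path(dir, paste0(lab, ".vcf"))
    write_vcf(callers$calls[[lab]], p)
    paths[[lab]] <- p
  }
  jsonlite::write_json(
    list(samples = sim$truth$samples,
         variants = sim$truth$variants,
         violations = callers$truth),
    paths$truth, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
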