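spec_from_counts <- function(n_cpg, n_other) {
  # deterministic spectrum builder: CpG>TpG into A[C>T]G, rest into T>A
  counts <- setNames(integer(96), sbs96_channels())
  counts["A[C>T]G"] <- n_cpg
  counts["A[T>A]A"] <- n_other
  structure(list(counts = counts, n_snv = n_cpg + n_other,
                 n_unclassifiable = 0L, n_non_snv = 0L),
            class = "mutation_spectrum")
}

test_that("hypermutation and enrichment thresholds are strict", {
  cfg <- screen_config()
  s <- summarize_sample(spec_from_counts(150, 50), cfg)  # exactly 200 SNVs
  expect_false(s$is_hypermutated)
  s <- summarize_sample(spec_from_counts(150, 51), cfg)
  expect_true(s$is_hypermutated)
  s <- summarize_sample(spec_from_counts(600, 400), cfg)  # fraction 0.6
  expect_false(s$is_enriched)
  s <- summarize_sample(spec_from_counts(601, 399), cfg)
  expect_true(s$is_enriched)
  expect_equal(s$is_hit, s$is_hypermutated && s$is_enriched)
})

test_that("the 2D screen coordinates separate CpG and non-CpG C>T", {
  counts <- setNames(integer(96), sbs96_channels())
  counts["A[C>T]G"] <- 40  # CpG>TpG
  counts["A[C>T]T"] <- 10  # C>T outside CpG
  counts["A[T>C]A"] <- 50
  spec <- structure(list(counts = counts, n_snv = 100L,
                         n_unclassifiable = 0L, n_non_snv = 0L),
                    class = "mutation_spectrum")
  s <- summarize_sample(spec)
  expect_equal(s$cpg_tpg_fraction, 0.4)
  expect_equal(s$ct_other_fraction, 0.1)
})

test_that("fold-change matches arithmetic oracles for mean and median", {
  expect_equal(fold_change(100, c(10, 10, 10)), 10)
  expect_equal(fold_change(50, 50), 1)
  expect_true(is.na(fold_change(50, c(0, 0))))
  expect_true(is.na(fold_change(50, integer(0))))
  set.seed(81)
  for (rep in 1:20) {
    cohort <- sample(1:500, sample(2:30, 1))
    x <- sample(1:2000, 1)
    expect_equal(fold_change(x, cohort, screen_config()),
                 x / (sum(cohort) / length(cohort)))
    med_cfg <- screen_config(baseline_statistic = "median")
    s <- sort(cohort)
    n <- length(s)
    oracle_median <- if (n %% 2 == 1) s[(n + 1) / 2]
                     else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(fold_change(x, cohort, med_cfg), x / oracle_median)
  }
})

test_that("a cohort with no planted hypermutators yields no hits", {
  cfg <- simulation_config(seed = 91, n_samples = 12,
                           hypermutator_fraction = 0)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, ref)
  sums <- do.call(rbind, lapply(split(sim$variants, sim$variants$sample_id),
    function(v) summarize_sample(compute_spectrum(v, ref),
                                 sample_id = v$sample_id[1])))
  rep <- screen_cohort(sums)
  expect_equal(nrow(rep$hits), 0)
  expect_false(any(sim$truth$samples$is_hypermutator))
})

test_that("planted hypermutators are recovered exactly, in fraction order", {
  cfg <- simulation_config(seed = 101, n_samples = 15,
                           hypermutator_fraction = 0.2)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, ref)
  sums <- do.call(rbind, lapply(split(sim$variants, sim$variants$sample_id),
    function(v) summarize_sample(compute_spectrum(v, ref),
                                 sample_id = v$sample_id[1])))
  rep <- screen_cohort(sums)
  truth_ids <- sim$truth$samples$sample_id[sim$truth$samples$is_hypermutator]
  expect_setequal(rep$hits$sample_id, truth_ids)
  expect_equal(rep$hits$cpg_tpg_fraction,
               sort(rep$hits$cpg_tpg_fraction, decreasing = TRUE))
  # fold-change of a planted hypermutator dwarfs the background burden
  expect_true(all(rep$hits$fold_change > 5))
})

test_that("the report is invariant to input order and rejects duplicates", {
  set.seed(111)
  sums <- do.call(rbind, lapply(1:8, function(i)
    summarize_sample(spec_from_counts(sample(0:800, 1), sample(0:400, 1)),
                     sample_id = sprintf("S%02d", i))))
  a <- screen_cohort(sums)
  b <- screen_cohort(sums[sample(nrow(sums)), ])
  expect_equal(a$summaries, b$summaries)
  expect_equal(a$hits, b$hits)
  expect_error(screen_cohort(rbind(sums, sums[1, ])), "duplicate")
})

test_that("raising thresholds never adds hits", {
  set.seed(121)
  sums <- do.call(rbind, lapply(1:20, function(i)
    summarize_sample(spec_from_counts(sample(0:900, 1), sample(0:500, 1)),
                     sample_id = sprintf("S%02d", i))))
  base_hits <- screen_cohort(sums)$hits$sample_id
  for (cfg in list(screen_config(min_snv = 500),
                   screen_config(min_fraction = 0.8))) {
    sums2 <- do.call(rbind, lapply(seq_len(nrow(sums)), function(i) {
      s <- spec_from_counts(
        round(sums$cpg_tpg_fraction[i] * sums$n_snv[i]),
        sums$n_snv[i] - round(sums$cpg_tpg_fraction[i] * sums$n_snv[i]))
      summarize_sample(s, cfg, sample_id = sums$sample_id[i])
    }))
    expect_true(all(screen_cohort(sums2, cfg)$hits$sample_id %in% base_hits))
  }
})

test_that("screen JSON report round-trips its headline numbers", {
  sums <- rbind(
    summarize_sample(spec_from_counts(460, 14), sample_id = "HIT"),
    summarize_sample(spec_from_counts(5, 10), sample_id = "BG1"),
    summarize_sample(spec_from_counts(3, 12), sample_id = "BG2"))
  rep <- screen_cohort(sums)
  path <- withr::local_tempfile(fileext = ".json")
  write_screen_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_samples, 3)
  expect_equal(back$n_hits, 1)
  expect_equal(back$hits$sample_id, "HIT")
})
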