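mk_rec <- function(..., sample_id = "S1") {
  defaults <- list(sample_id = sample_id, chrom = "chr1", pos = 100L,
                   ref_allele = "C", alt_allele = "T",
                   germline_depth = 60L, somatic_depth = 120L,
                   allele_depth = 30L, pop_freq = 0.001)
  do.call(variant_table, utils::modifyList(defaults, list(...)))
}

test_that("identical calls from three callers merge to one record", {
  sets <- lapply(c("haplotypecaller", "mutect2", "mpileup"), function(lab)
    mk_rec(callers = lab))
  m <- merge_callers(sets)
  expect_equal(nrow(m), 1)
  expect_equal(sort(strsplit(m$callers, ",")[[1]]),
               c("haplotypecaller", "mpileup", "mutect2"))
})

test_that("disjoint call sets union without loss and sort stably", {
  a <- mk_rec(pos = c(10L, 20L), callers = "mutect2")
  b <- mk_rec(pos = c(30L, 40L, 50L), callers = "mpileup")
  m <- merge_callers(list(a, b))
  expect_equal(nrow(m), 5)
  expect_equal(m$pos, c(10L, 20L, 30L, 40L, 50L))
})

test_that("merge resolves depths to the best-supported caller record", {
  a <- mk_rec(callers = "mutect2", somatic_depth = 100L, allele_depth = 40L)
  b <- mk_rec(callers = "mpileup", somatic_depth = 140L, allele_depth = 35L)
  m <- merge_callers(list(a, b))
  expect_equal(m$somatic_depth, 140L)
  expect_equal(m$allele_depth, 35L)
})

test_that("mixed sample_ids are a usage error", {
  expect_error(merge_callers(list(mk_rec(sample_id = "S1"),
                                  mk_rec(sample_id = "S2"))),
               "sample_id")
})

test_that("randomized overlapping call sets merge to the brute-force key union", {
  set.seed(31)
  for (rep in 1:5) {
    pool_pos <- sample(100:999, 60)
    sets <- lapply(c("a", "b", "c"), function(lab) {
      pos <- sample(pool_pos, 30)
      mk_rec(pos = sort(pos), callers = lab)
    })
    m <- merge_callers(sets)
    oracle_keys <- sort(unique(unlist(lapply(sets, variant_keys))))
    expect_equal(sort(variant_keys(m)), oracle_keys)
    # caller label sets match per-key brute force
    all_rows <- do.call(rbind, sets)
    for (k in sample(oracle_keys, 5)) {
      expect_equal(sort(strsplit(m$callers[variant_keys(m) == k], ",")[[1]]),
                   sort(unique(all_rows$callers[variant_keys(all_rows) == k])))
    }
  }
})

test_that("each cascade rule rejects strictly below (above) its threshold", {
  res <- apply_filters(mk_rec(germline_depth = 9L))
  expect_equal(nrow(res$retained), 0)
  expect_equal(res$audit$n_failed[res$audit$rule == "germline_depth"], 1L)

  expect_equal(nrow(apply_filters(mk_rec(somatic_depth = 9L,
                                         allele_depth = 9L))$retained), 0)
  expect_equal(nrow(apply_filters(mk_rec(allele_depth = 5L))$retained), 0)
  expect_equal(nrow(apply_filters(
    mk_rec(somatic_depth = 200L, allele_depth = 9L))$retained), 0)
  expect_equal(nrow(apply_filters(mk_rec(pop_freq = 0.02))$retained), 0)
})

test_that("records exactly at a threshold are retained", {
  at_boundary <- list(
    mk_rec(germline_depth = 10L),
    mk_rec(somatic_depth = 10L, allele_depth = 6L),  # DP=10; AD/DP=0.6
    mk_rec(allele_depth = 6L, somatic_depth = 120L), # ratio 0.05 exactly
    mk_rec(pop_freq = 0.01)
  )
  for (rec in at_boundary) {
    res <- apply_filters(rec)
    expect_equal(nrow(res$retained), 1)
    expect_equal(sum(res$audit$n_failed), 0L)
  }
})

test_that("missing annotations never fire a rule", {
  rec <- mk_rec(germline_depth = NA_integer_, pop_freq = NA_real_)
  expect_equal(nrow(apply_filters(rec)$retained), 1)
})

test_that("somatic depth zero with supporting reads is a consistency error", {
  rec <- mk_rec(somatic_depth = 0L, allele_depth = 0L)
  rec$allele_depth <- 3L  # bypass constructor to simulate corrupt input
  rec$somatic_depth <- 0L
  expect_error(apply_filters(rec), "somatic_depth")
})

test_that("filtering is idempotent and counts balance", {
  set.seed(41)
  v <- mk_rec(pos = 1:50,
              germline_depth = sample(c(5L, 60L), 50, replace = TRUE),
              allele_depth = sample(c(4L, 30L), 50, replace = TRUE))
  res <- apply_filters(v)
  expect_equal(nrow(res$retained) + nrow(res$rejected), nrow(v))
  again <- apply_filters(res$retained)
  expect_equal(again$retained, res$retained)
  expect_equal(sum(again$audit$n_failed), 0L)
})

test_that("tightening any single threshold never increases retention", {
  set.seed(51)
  v <- mk_rec(pos = 1:200,
              germline_depth = sample(5:40, 200, replace = TRUE),
              somatic_depth = sample(5:200, 200, replace = TRUE),
              allele_depth = 3L)
  v$allele_depth <- pmin(sample(3:30, 200, replace = TRUE), v$somatic_depth)
  v$pop_freq <- runif(200, 0, 0.05)
  base <- nrow(apply_filters(v)$retained)
  tighter <- list(
    filter_thresholds(min_germline_depth = 20),
    filter_thresholds(min_somatic_depth = 20),
    filter_thresholds(min_allele_depth = 10),
    filter_thresholds(min_allele_fraction = 0.2),
    filter_thresholds(max_pop_freq = 0.001)
  )
  for (th in tighter)
    expect_lte(nrow(apply_filters(v, th)$retained), base)
})

test_that("audit counts equal planted per-rule violations exactly", {
  rates <- c(germline_depth = 0.05, somatic_depth = 0.03,
             allele_depth = 0.04, allele_fraction = 0.03, pop_freq = 0.02)
  cfg <- simulation_config(seed = 61, n_samples = 8,
                           hypermutator_fraction = 0.25,
                           violation_rates = rates)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, ref)
  co <- simulate_caller_outputs(sim$variants, cfg)
  res <- apply_filters(co$merged_input)
  planted <- table(co$truth$violated_rule)
  for (rule in names(planted))
    expect_equal(res$audit$n_failed[res$audit$rule == rule],
                 as.integer(planted[[rule]]), info = rule)
  expect_equal(nrow(res$rejected), nrow(co$truth))
})
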