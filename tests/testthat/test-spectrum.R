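test_that("pyrimidine-centered classification matches hand-worked cases", {
  ch <- sbs96_channels()
  expect_equal(ch[classify_channel("C", "T", "ACG")], "A[C>T]G")
  # minus-strand G>A at a CpG collapses onto the same channel
  expect_equal(ch[classify_channel("G", "A", "CGT")], "A[C>T]G")
  expect_equal(ch[classify_channel("T", "G", "TTT")], "T[T>G]T")
  expect_equal(ch[classify_channel("A", "C", "AAA")], "T[T>G]T")
  expect_error(classify_channel("C", "T", "AAG"), "center")
  expect_error(classify_channel("C", "C", "ACA"), "distinct")
})

test_that("every valid (ref, alt, context) input matches the brute-force oracle", {
  # 16 flank pairs x 4 reference bases x 3 alternate bases
  grid <- all_snv_combinations()
  expect_equal(nrow(grid), 192)
  got <- sbs96_channels()[classify_channel(grid$ref, grid$alt, grid$ctx)]
  want <- mapply(oracle_sbs96_label, grid$ref, grid$alt, grid$ctx)
  expect_equal(unname(got), unname(want))
  # the channel ordering itself matches an independently built table
  expect_equal(sbs96_channels(), oracle_sbs96_order())
  # bijection: the 96 channels are all reachable
  expect_setequal(unique(got), sbs96_channels())
})

test_that("classification is invariant under strand involution", {
  grid <- all_snv_combinations()
  fwd <- classify_channel(grid$ref, grid$alt, grid$ctx)
  rc <- function(x) chartr("ACGT", "TGCA", x)
  rc3 <- vapply(strsplit(grid$ctx, NULL), function(p)
    paste(rc(rev(p)), collapse = ""), character(1))
  rev_idx <- classify_channel(rc(grid$ref), rc(grid$alt), rc3)
  expect_equal(fwd, rev_idx)
})

test_that("CpG>TpG detection covers both strands and only CpG contexts", {
  expect_true(is_cpg_tpg("C", "T", "TCG"))
  expect_false(is_cpg_tpg("C", "T", "TCA"))
  expect_true(is_cpg_tpg("G", "A", "CGA"))   # minus-strand CpG
  expect_false(is_cpg_tpg("C", "G", "TCG"))  # not a transition
  expect_false(is_cpg_tpg("C", "T", "GCC"))
  # the four flagged channels are exactly N[C>T]G
  expect_equal(sbs96_channels()[cpg_tpg_channels()],
               c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G"))
})

test_that("an empty variant table yields the zero spectrum", {
  spec <- compute_spectrum(variant_table(), toy_reference())
  expect_equal(sum(spec$counts), 0)
  expect_equal(spec$n_snv, 0)
  st <- cpg_tpg_stat(spec)
  expect_true(st$undefined)
  expect_equal(st$fraction, 0)
})

test_that("planted CpG>TpG variants land in the four CpG channels", {
  ref <- toy_reference()
  cpg <- cpg_tpg_channels()
  set.seed(5)
  v <- plant_snvs(ref, rep(cpg, length.out = 10), "S1")
  spec <- compute_spectrum(v, ref)
  expect_equal(sum(spec$counts[cpg]), 10)
  expect_equal(spec$n_snv, 10)
  expect_equal(cpg_tpg_stat(spec)$fraction, 1)
})

test_that("mixed planted spectra reproduce per-channel truth tallies", {
  ref <- toy_reference()
  set.seed(15)
  channels <- sample(96, 400, replace = TRUE)
  v <- plant_snvs(ref, channels, "S1")
  spec <- compute_spectrum(v, ref)
  truth <- tabulate(channels, nbins = 96)
  expect_equal(unname(spec$counts), truth)
  expect_equal(spec$n_unclassifiable, 0)
})

test_that("spectra are order-invariant and additive over partitions", {
  ref <- toy_reference()
  set.seed(25)
  v <- plant_snvs(ref, sample(96, 120, replace = TRUE), "S1")
  shuffled <- v[sample(nrow(v)), ]
  expect_equal(compute_spectrum(shuffled, ref)$counts,
               compute_spectrum(v, ref)$counts)
  a <- v[1:50, ]
  b <- v[51:120, ]
  expect_equal((compute_spectrum(a, ref) + compute_spectrum(b, ref))$counts,
               compute_spectrum(v, ref)$counts)
})

test_that("non-SNV records are tallied, never classified", {
  ref <- toy_reference()
  set.seed(35)
  v <- plant_snvs(ref, c(33, 35), "S1")
  indel <- variant_table(sample_id = "S1", chrom = names(ref), pos = 50L,
                         ref_allele = "CA", alt_allele = "C",
                         variant_class = "DEL")
  spec <- compute_spectrum(rbind(v, indel), ref)
  expect_equal(spec$n_snv, 2)
  expect_equal(spec$n_non_snv, 1)
})

test_that("a mismatched reference allele is a loud error", {
  ref <- toy_reference()
  set.seed(45)
  v <- plant_snvs(ref, 33, "S1")
  v$ref_allele <- ifelse(v$ref_allele == "C", "T", "C")
  v$alt_allele <- "A"
  expect_error(compute_spectrum(v, ref), "does not match")
})

test_that("recovered CpG>TpG fraction sits inside the exact binomial band", {
  cfg <- simulation_config(seed = 71, n_samples = 1,
                           hypermutator_fraction = 1,
                           hypermutator_count_range = c(1000L, 1000L),
                           hypermutator_cpg_weight = 0.95)
  ref <- simulate_reference(cfg)
  sim <- simulate_cohort(cfg, ref)
  spec <- compute_spectrum(sim$variants, ref)
  frac <- cpg_tpg_stat(spec)$fraction
  ci <- stats::binom.test(round(0.95 * 1000), 1000,
                          conf.level = 0.99)$conf.int
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("spectrum TSV serialization is canonical and complete", {
  ref <- toy_reference()
  set.seed(55)
  v <- plant_snvs(ref, sample(96, 60, replace = TRUE), "S1")
  spec <- compute_spectrum(v, ref)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(spec, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 96)
  expect_equal(tab$channel, sbs96_channels())
  expect_equal(sum(tab$count), 60)
  expect_equal(sum(tab$proportion), 1)
})
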