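# Shared fixtures, built in code at test time.

# A tiny deterministic reference: every 3-mer over ACGT appears, plus CpG
# sites on both strands.
toy_reference <- function() {
  set.seed(424242)
  bases <- sample(c("A", "C", "G", "T"), 5000, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  c(chr_toy = paste(bases, collapse = ""))
}

# Minimal GDC-style MAF text: 2 SNP rows and 1 DEL row.
write_toy_maf <- function(path) {
  writeLines(c(
    paste("Chromosome", "Start_Position", "Reference_Allele",
          "Tumor_Seq_Allele2", "Variant_Type", "Variant_Classification",
          "Tumor_Sample_Barcode", "t_depth", "t_alt_count", "n_depth",
          sep = "\t"),
    paste("chr1", "100", "C", "T", "SNP", "Missense_Mutation", "S1",
          "80", "30", "60", sep = "\t"),
    paste("chr1", "200", "G", "A", "SNP", "Silent", "S1",
          "90", "40", "70", sep = "\t"),
    paste("chr2", "300", "CT", "C", "DEL", "Frame_Shift_Del", "S1",
          "85", "20", "65", sep = "\t")
  ), path)
  path
}

# Small single-sample variant table planted on the toy reference.
toy_variants <- function(channels = c(33, 36, 1, 50),
                         sample_id = "S1", seed = 7) {
  set.seed(seed)
  ref <- toy_reference()
  plant_snvs(ref, channels, sample_id, simulation_config(seed = seed))
}

# Independent brute-force SBS96 oracle, sharing no code with the package:
# builds the channel label by explicit reverse complementation and looks
# it up in an explicitly constructed label table.
oracle_sbs96_label <- function(ref, alt, ctx) {
  rc1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
  rc3 <- function(s) {
    p <- strsplit(s, "")[[1]]
    paste0(rc1(p[3]), rc1(p[2]), rc1(p[1]))
  }
  if (ref %in% c("A", "G")) {
    new_ctx <- rc3(ctx)
    new_ref <- rc1(ref)
    new_alt <- rc1(alt)
  } else {
    new_ctx <- ctx
    new_ref <- ref
    new_alt <- alt
  }
  paste0(substr(new_ctx, 1, 1), "[", new_ref, ">", new_alt, "]",
         substr(new_ctx, 3, 3))
}

oracle_sbs96_order <- function() {
  out <- character(0)
  for (sub in c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
    for (f5 in c("A", "C", "G", "T"))
      for (f3 in c("A", "C", "G", "T"))
        out <- c(out, paste0(f5, "[", sub, "]", f3))
  out
}

# All 576 valid (ref, alt, context) combinations.
all_snv_combinations <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f5 = bases, ref = bases, f3 = bases, alt = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  grid$ctx <- paste0(grid$f5, grid$ref, grid$f3)
  grid
}
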