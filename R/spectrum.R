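## The 96-channel pyrimidine-centered trinucleotide spectrum (SBS96).
## Channel order is fixed: substitution-major (C>A, C>G, C>T, T>A, T>C,
## T>G), then the 16 flank pairs per substitution, 5' flank varying
## slowest, both flanks alphabetical. Serialized spectra are therefore
## bit-comparable across runs.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 SBS channel labels in canonical order
#'
#' Labels have the COSMIC form `5'[ref>alt]3'`, e.g. `"A[C>T]G"`.
#' Substitutions are pyrimidine-centered: purine-reference mutations are
#' reverse-complemented onto these channels by [classify_channel()].
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(sub) {
    ref <- substr(sub, 1, 1)
    as.vector(t(outer(BASES, BASES, function(f5, f3)
      paste0(f5, "[", sub, "]", f3))))
  }))
}

#' Classify an SNV into its SBS96 channel
#'
#' Maps `(ref, alt, trinucleotide context)` to a channel index. When the
#' reference base is a purine (`A` or `G`) the substitution and context
#' are reverse-complemented first, so every channel is pyrimidine-centered
#' (strand collapse): a minus-strand `G>A` at a CpG lands in the same
#' channel as its plus-strand `C>T` mate. The mapping is a bijection from
#' the 96 collapsed `(substitution, context)` pairs to `1:96`.
#'
#' @param ref_allele,alt_allele Single bases in `A`,`C`,`G`,`T`;
#'   `ref != alt`. Vectorized.
#' @param context Trinucleotide string whose center base equals
#'   `ref_allele`.
#' @return Integer channel indices in `1:96` (see [sbs96_channels()] for
#'   the label at each index).
#' @examples
#' ch <- sbs96_channels()
#' ch[classify_channel("C", "T", "ACG")]  # "A[C>T]G"
#' ch[classify_channel("G", "A", "CGT")]  # also "A[C>T]G" (strand collapse)
#' @export
classify_channel <- function(ref_allele, alt_allele, context) {
  n <- max(length(ref_allele), length(alt_allele), length(context))
  ref <- toupper(rep_len(ref_allele, n))
  alt <- toupper(rep_len(alt_allele, n))
  ctx <- toupper(rep_len(context, n))
  ok_base <- ref %in% BASES & alt %in% BASES & ref != alt
  if (!all(ok_base))
    stop("ref/alt must be distinct single bases in A/C/G/T")
  if (any(nchar(ctx) != 3))
    stop("context must be a trinucleotide")
  if (any(substr(ctx, 2, 2) != ref))
    stop("context center base does not match ref_allele")
  # collapse purine-reference records onto the pyrimidine strand
  purine <- ref %in% c("A", "G")
  ref[purine] <- comp_base(ref[purine])
  alt[purine] <- comp_base(alt[purine])
  ctx[purine] <- revcomp(ctx[purine])
  sub_idx <- match(paste0(ref, ">", alt), SBS_SUBSTITUTIONS)
  f5 <- match(substr(ctx, 1, 1), BASES)
  f3 <- match(substr(ctx, 3, 3), BASES)
  (sub_idx - 1L) * 16L + (f5 - 1L) * 4L + f3
}

#' Is an SNV a CpG>TpG transition?
#'
#' `TRUE` iff the strand-collapsed channel is C>T with a 3' flank of G,
#' i.e. one of `A[C>T]G`, `C[C>T]G`, `G[C>T]G`, `T[C>T]G` — a C>T at a
#' CpG dinucleotide on either strand, the footprint of 5-methylcytosine
#' deamination.
#'
#' @inheritParams classify_channel
#' @return Logical vector.
#' @export
is_cpg_tpg <- function(ref_allele, alt_allele, context) {
  classify_channel(ref_allele, alt_allele, context) %in% cpg_tpg_channels()
}

#' Indices of the four CpG>TpG channels
#' @return Integer vector of length 4 (positions of `N[C>T]G` in
#'   [sbs96_channels()]).
#' @export
cpg_tpg_channels <- function() {
  which(grepl("\\[C>T\\]G$", sbs96_channels()))
}

#' Compute the 96-channel mutation spectrum of a sample
#'
#' Classifies every SNV in a single-sample variant table into its SBS96
#' channel using trinucleotide contexts from the reference. Non-SNV
#' records are ignored (tallied separately); SNVs whose context is
#' unavailable (contig edge, or `N` in the 3-mer) are excluded from the
#' spectrum and counted as unclassifiable. SNVs whose reference allele
#' contradicts the reference sequence raise an error.
#'
#' @param variants A variant table for one sample.
#' @param reference Named character vector from [read_reference()].
#' @return An object of class `mutation_spectrum`: list with `counts`
#'   (named integer vector of length 96 summing to `n_snv`), `n_snv`,
#'   `n_unclassifiable` and `n_non_snv`.
#' @export
compute_spectrum <- function(variants, reference) {
  variants <- validate_variant_table(variants)
  if (length(unique(variants$sample_id)) > 1)
    stop("compute_spectrum() expects variants from a single sample")
  snvs <- variants[variants$variant_class == "SNV", , drop = FALSE]
  counts <- setNames(integer(96), sbs96_channels())
  n_unclass <- 0L
  if (nrow(snvs)) {
    ctx <- extract_context(reference, snvs$chrom, snvs$pos)
    usable <- !is.na(ctx)
    n_unclass <- sum(!usable)
    if (any(usable)) {
      mism <- substr(ctx[usable], 2, 2) != snvs$ref_allele[usable]
      if (any(mism))
        stop("reference base does not match ref_allele for ",
             sum(mism), " SNV(s), e.g. ",
             variant_keys(snvs[usable, ][mism, ])[1])
      chan <- classify_channel(snvs$ref_allele[usable],
                               snvs$alt_allele[usable], ctx[usable])
      tab <- tabulate(chan, nbins = 96)
      counts[] <- as.integer(tab)
    }
  }
  structure(list(counts = counts,
                 n_snv = sum(counts),
                 n_unclassifiable = n_unclass,
                 n_non_snv = nrow(variants) - nrow(snvs)),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("SBS96 mutation spectrum\n")
  cat("  classifiable SNVs :", x$n_snv, "\n")
  cat("  unclassifiable    :", x$n_unclassifiable, "\n")
  cat("  non-SNV records   :", x$n_non_snv, "\n")
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  if (length(top)) {
    top <- utils::head(top, 5)
    cat("  top channels      :",
        paste(names(top), top, sep = "=", collapse = ", "), "\n")
  }
  st <- cpg_tpg_stat(x)
  if (!st$undefined)
    cat(sprintf("  CpG>TpG fraction  : %.3f (%d/%d)\n",
                st$fraction, st$n_cpg_tpg, st$n_snv))
  invisible(x)
}

#' @export
plot.mutation_spectrum <- function(x, main = "SBS96 spectrum", ...) {
  cols <- rep(c("#03BCEE", "#010101", "#E32926",
                "#CAC9C9", "#A1CE63", "#EBC6C4"), each = 16)
  graphics::barplot(x$counts, col = cols, border = NA, names.arg = NA,
                    ylab = "count", main = main, ...)
  mids <- (seq_len(6) - 0.5) * 16 * 1.2  # barplot default spacing
  graphics::mtext(SBS_SUBSTITUTIONS, side = 1, at = mids, line = 0.5,
                  cex = 0.8)
  invisible(x)
}

#' Sum spectra
#'
#' Spectra are additive over disjoint variant partitions:
#' `spectrum(A) + spectrum(B) == spectrum(A union B)` for disjoint A, B.
#' @param e1,e2 `mutation_spectrum` objects.
#' @export
`+.mutation_spectrum` <- function(e1, e2) {
  structure(list(counts = e1$counts + e2$counts,
                 n_snv = e1$n_snv + e2$n_snv,
                 n_unclassifiable = e1$n_unclassifiable + e2$n_unclassifiable,
                 n_non_snv = e1$n_non_snv + e2$n_non_snv),
            class = "mutation_spectrum")
}

#' CpG>TpG enrichment statistic of a spectrum
#'
#' Sums the four `N[C>T]G` channels and divides by the classifiable SNV
#' count. The denominator excludes indels and unclassifiable SNVs. An
#' empty spectrum yields `fraction = 0` with `undefined = TRUE`.
#'
#' @param spectrum A `mutation_spectrum`.
#' @return List of class `cpg_tpg_stat` with `n_cpg_tpg`, `n_snv`,
#'   `fraction` and `undefined`.
#' @export
cpg_tpg_stat <- function(spectrum) {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  n_cpg <- sum(spectrum$counts[cpg_tpg_channels()])
  n <- spectrum$n_snv
  structure(list(n_cpg_tpg = n_cpg, n_snv = n,
                 fraction = if (n > 0) n_cpg / n else 0,
                 undefined = n == 0),
            class = "cpg_tpg_stat")
}

#' @export
print.cpg_tpg_stat <- function(x, ...) {
  if (x$undefined) {
    cat("CpG>TpG fraction: undefined (no classifiable SNVs)\n")
  } else {
    cat(sprintf("CpG>TpG fraction: %.4f (%d/%d SNVs)\n",
                x$fraction, x$n_cpg_tpg, x$n_snv))
  }
  invisible(x)
}

#' Write a spectrum as a 96-row TSV
#'
#' Columns: `channel`, `count`, `proportion` (of classifiable SNVs; 0
#' when the spectrum is empty), in canonical channel order.
#'
#' @param spectrum A `mutation_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  prop <- if (spectrum$n_snv > 0) spectrum$counts / spectrum$n_snv
          else rep(0, 96)
  out <- data.frame(channel = names(spectrum$counts),
                    count = as.integer(spectrum$counts),
                    proportion = as.numeric(prop))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
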