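#' Read a reference sequence from FASTA
#'
#' Loads a FASTA file (via \pkg{Biostrings}) into the simple named
#' character representation used for trinucleotide context extraction.
#' Soft-masked (lowercase) bases are uppercased; anything outside
#' `A`,`C`,`G`,`T`,`N` is rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per contig.
#' @seealso [extract_context()], [write_reference()]
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("contig(s) contain non-ACGTN characters: ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Write a reference sequence to FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  stopifnot(is.character(reference), !is.null(names(reference)))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path, width = 70L
  )
  invisible(path)
}

#' Extract the trinucleotide context around a position
#'
#' Returns the uppercase reference 3-mer centered on `pos` (1-based):
#' bases `pos - 1` through `pos + 1`. Positions at a contig edge, or whose
#' 3-mer contains `N`, have no usable context: they are returned as `NA`
#' so callers can exclude the record from spectra and tally it as
#' unclassifiable.
#'
#' @param reference Named character vector from [read_reference()].
#' @param chrom Contig name(s).
#' @param pos 1-based position(s); recycled against `chrom`.
#' @return Character vector of 3-mers, `NA` where no context is available.
#' @examples
#' ref <- c(ctg = "ACGT")
#' extract_context(ref, "ctg", 2)  # "ACG"
#' extract_context(ref, "ctg", 1)  # NA: no 5' flank
#' @export
extract_context <- function(reference, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  missing_ctg <- !(chrom %in% names(reference))
  if (any(missing_ctg))
    stop("contig(s) not in reference: ",
         paste(unique(chrom[missing_ctg]), collapse = ", "))
  len <- nchar(reference)[chrom]
  out_of_range <- pos < 1L | pos > len
  if (any(out_of_range))
    stop("position(s) outside contig bounds: ",
         paste(utils::head(paste0(chrom, ":", pos)[out_of_range], 5),
               collapse = ", "))
  ok <- pos >= 2L & pos <= len - 1L
  ctx <- rep(NA_character_, n)
  if (any(ok))
    ctx[ok] <- substr(reference[chrom[ok]], pos[ok] - 1L, pos[ok] + 1L)
  ctx[!is.na(ctx) & grepl("N", ctx)] <- NA_character_
  ctx
}
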