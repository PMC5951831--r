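## VCF I/O for per-caller somatic call sets. Depth and frequency
## annotations live in INFO fields whose keys are configurable, since
## different callers name them differently.

#' Default INFO keys for depth/frequency annotations
#'
#' Maps the canonical annotation fields to the VCF INFO keys used by
#' [read_vcf()] and [write_vcf()]: germline depth (`GDP`), somatic depth
#' (`DP`), allele depth (`AD`, one value per ALT allele) and population
#' allele frequency (`PAF`).
#'
#' @return Named list of INFO keys.
#' @export
vcf_depth_keys <- function() {
  list(germline_depth = "GDP", somatic_depth = "DP",
       allele_depth = "AD", pop_freq = "PAF")
}

#' Read a per-caller VCF into a variant table
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into the canonical variant
#' table, labelling every record with `caller_label`. Biallelic SNVs map
#' to `variant_class = "SNV"`; multi-allelic sites are split into one
#' record per alternate allele (per-allele `AD` values are matched to
#' their allele). Insertions/deletions are typed by allele length.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_id Sample identifier to assign to all records.
#' @param caller_label Caller name stored in the `callers` field.
#' @param patient_id Patient identifier; defaults to `sample_id`.
#' @param depth_keys Named list of INFO keys, as [vcf_depth_keys()]. Keys
#'   configured here must be declared in the VCF header.
#' @return A variant table (see [variant_table()]).
#' @export
read_vcf <- function(path, sample_id, caller_label,
                     patient_id = sample_id, depth_keys = vcf_depth_keys()) {
  stopifnot(setequal(names(depth_keys), names(vcf_depth_keys())))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(variant_table())
  declared <- vcfR::queryMETA(vcf, element = "INFO")
  declared_ids <- unique(unlist(lapply(declared, function(m)
    sub(".*\\bID=", "", grep("ID=", m, value = TRUE)))))
  missing_keys <- setdiff(unlist(depth_keys), declared_ids)
  if (length(missing_keys))
    stop("configured INFO key(s) not declared in VCF header: ",
         paste(missing_keys, collapse = ", "))
  info_get <- function(key) vcfR::extract.info(vcf, element = key)

  gdp <- suppressWarnings(as.integer(info_get(depth_keys$germline_depth)))
  dp <- suppressWarnings(as.integer(info_get(depth_keys$somatic_depth)))
  paf <- suppressWarnings(as.numeric(info_get(depth_keys$pop_freq)))
  ad_raw <- info_get(depth_keys$allele_depth)

  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("malformed VCF record at data line ", bad[1], ": unparseable POS '",
         fix$POS[bad[1]], "'")

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  ads <- strsplit(ifelse(is.na(ad_raw), "", ad_raw), ",", fixed = TRUE)
  # per-allele AD: recycle a single value across alleles, else match 1:1
  ad_for <- function(i, j) {
    v <- ads[[i]]
    if (length(v) == 0) return(NA_integer_)
    if (length(v) == 1) return(suppressWarnings(as.integer(v)))
    if (length(v) != n_alt[i])
      stop("malformed VCF record at data line ", i, ": ", length(v),
           " AD values for ", n_alt[i], " ALT allele(s)")
    suppressWarnings(as.integer(v[j]))
  }

  idx <- rep(seq_len(nrow(fix)), n_alt)
  allele_j <- unlist(lapply(n_alt, seq_len))
  ref <- toupper(fix$REF[idx])
  alt <- toupper(unlist(alts))
  vclass <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
            ifelse(nchar(ref) < nchar(alt), "INS",
            ifelse(nchar(ref) > nchar(alt), "DEL", "other")))
  validate_variant_table(data.frame(
    sample_id = sample_id,
    patient_id = patient_id,
    chrom = fix$CHROM[idx],
    pos = pos[idx],
    ref_allele = ref,
    alt_allele = alt,
    variant_class = vclass,
    callers = caller_label,
    germline_depth = gdp[idx],
    somatic_depth = dp[idx],
    allele_depth = mapply(ad_for, idx, allele_j),
    pop_freq = paf[idx],
    functional_class = "missing",
    stringsAsFactors = FALSE
  ))
}

#' Write a variant table as a minimal VCF v4.2
#'
#' One record per row (no multi-allelic collapsing); depth and frequency
#' annotations are stored in the INFO fields named by `depth_keys` and
#' declared in the header. Suitable for round-tripping with [read_vcf()].
#'
#' @param variants A variant table (single caller label per file).
#' @param path Output path.
#' @param depth_keys Named list of INFO keys, as [vcf_depth_keys()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, depth_keys = vcf_depth_keys()) {
  variants <- validate_variant_table(variants)
  k <- depth_keys
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Germline position depth\">", k$germline_depth),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Somatic position depth\">", k$somatic_depth),
    sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"Somatic allele depth\">", k$allele_depth),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population allele frequency\">", k$pop_freq),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  info_field <- function(key, val) ifelse(is.na(val), NA,
                                          paste0(key, "=", val))
  info <- apply(cbind(info_field(k$germline_depth, variants$germline_depth),
                      info_field(k$somatic_depth, variants$somatic_depth),
                      info_field(k$allele_depth, variants$allele_depth),
                      info_field(k$pop_freq, variants$pop_freq)),
                1, function(r) {
                  r <- r[!is.na(r)]
                  if (length(r)) paste(r, collapse = ";") else "."
                })
  body <- paste(variants$chrom, variants$pos, ".", variants$ref_allele,
                variants$alt_allele, ".", "PASS", info, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
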