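## MAF (Mutation Annotation Format) I/O. MAF is the tab-separated somatic
## mutation table used by TCGA/GDC; coordinates are 1-based inclusive and
## are kept that way internally.

## Column dialects: each canonical field maps to the names accepted in a
## MAF header, in priority order. The GDC names come first, then the
## minimal generic header emitted by write_maf().
MAF_DIALECT <- list(
  chrom = c("Chromosome", "chrom"),
  pos = c("Start_Position", "Start_position", "pos"),
  ref_allele = c("Reference_Allele", "ref_allele"),
  alt_allele = c("Tumor_Seq_Allele2", "alt_allele"),
  variant_type = c("Variant_Type", "variant_type"),
  variant_classification = c("Variant_Classification", "variant_classification"),
  sample_id = c("Tumor_Sample_Barcode", "sample_id"),
  patient_id = c("Patient_ID", "patient_id"),
  callers = c("callers"),
  germline_depth = c("n_depth", "germline_depth"),
  somatic_depth = c("t_depth", "somatic_depth"),
  allele_depth = c("t_alt_count", "allele_depth"),
  pop_freq = c("popfreq_all", "pop_freq")
)

MAF_MANDATORY <- c("chrom", "pos", "ref_allele", "alt_allele",
                   "variant_type", "variant_classification", "sample_id")

## Map a MAF Variant_Classification string to the coarse functional class.
classify_functional <- function(vc) {
  nonsyn <- c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
              "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
              "In_Frame_Del", "In_Frame_Ins", "Translation_Start_Site",
              "nonsynonymous")
  syn <- c("Silent", "synonymous")
  out <- rep("other", length(vc))
  out[vc %in% nonsyn] <- "nonsynonymous"
  out[vc %in% syn] <- "synonymous"
  out[is.na(vc) | vc == "" | vc == "missing"] <- "missing"
  out
}

#' Read a MAF somatic mutation table
#'
#' Parses a tab-separated MAF into the canonical variant table. Both the
#' TCGA/GDC header (`Chromosome`, `Start_Position`, `Tumor_Seq_Allele2`,
#' ...) and the minimal generic header written by [write_maf()] are
#' accepted; additional synonyms can be supplied through `dialect`.
#' `Variant_Type` drives `variant_class` (`SNP` maps to `SNV`); missing
#' depth or frequency columns become `NA`, never zero. Rows with an
#' unparseable position raise an error naming the offending line.
#'
#' @param path Path to a MAF file (plain TSV, `#` comment lines ignored).
#' @param dialect Named list of accepted column names per canonical field,
#'   merged over the built-in dialect (see `deaminoscan:::MAF_DIALECT`).
#' @return A variant table (see [variant_table()]).
#' @export
read_maf <- function(path, dialect = list()) {
  dia <- utils::modifyList(MAF_DIALECT, dialect)
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  col_for <- function(field) {
    hit <- intersect(dia[[field]], names(raw))
    if (length(hit)) hit[1] else NA_character_
  }
  cols <- vapply(names(dia), col_for, character(1))
  absent <- MAF_MANDATORY[is.na(cols[MAF_MANDATORY])]
  if (length(absent))
    stop("MAF is missing mandatory column(s): ",
         paste(absent, " (accepted names: ",
               vapply(absent, function(f) paste(dia[[f]], collapse = "/"),
                      character(1)), ")", sep = "", collapse = "; "))
  get <- function(field, default = NA_character_) {
    if (is.na(cols[[field]])) rep(default, nrow(raw)) else raw[[cols[[field]]]]
  }
  pos_raw <- get("pos")
  pos <- suppressWarnings(as.integer(pos_raw))
  bad <- which(is.na(pos) & !is.na(pos_raw))
  if (length(bad))
    stop("unparseable position '", pos_raw[bad[1]], "' at MAF data row ",
         bad[1])
  vt <- toupper(get("variant_type"))
  vclass <- ifelse(vt %in% c("SNP", "SNV"), "SNV",
            ifelse(vt == "INS", "INS",
            ifelse(vt == "DEL", "DEL", "other")))
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  sample_id <- get("sample_id")
  patient <- get("patient_id")
  patient[is.na(patient)] <- sample_id[is.na(patient)]
  callers <- get("callers")
  callers[is.na(callers)] <- ""
  validate_variant_table(data.frame(
    sample_id = sample_id,
    patient_id = patient,
    chrom = get("chrom"),
    pos = pos,
    ref_allele = toupper(get("ref_allele")),
    alt_allele = toupper(get("alt_allele")),
    variant_class = vclass,
    callers = callers,
    germline_depth = as.integer(num_or_na(get("germline_depth"))),
    somatic_depth = as.integer(num_or_na(get("somatic_depth"))),
    allele_depth = as.integer(num_or_na(get("allele_depth"))),
    pop_freq = num_or_na(get("pop_freq")),
    functional_class = classify_functional(get("variant_classification")),
    stringsAsFactors = FALSE
  ))
}

#' Write a variant table as MAF
#'
#' Emits a GDC-compatible MAF (tab-separated, 1-based inclusive
#' coordinates) that [read_maf()] round-trips losslessly for every field
#' the pipeline consumes.
#'
#' @param variants A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  variants <- validate_variant_table(variants)
  vc_out <- c(synonymous = "Silent", nonsynonymous = "Missense_Mutation",
              other = "other", missing = "")
  out <- data.frame(
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref_allele,
    Tumor_Seq_Allele2 = variants$alt_allele,
    Variant_Type = ifelse(variants$variant_class == "SNV", "SNP",
                          variants$variant_class),
    Variant_Classification = vc_out[variants$functional_class],
    Tumor_Sample_Barcode = variants$sample_id,
    Patient_ID = variants$patient_id,
    callers = variants$callers,
    n_depth = variants$germline_depth,
    t_depth = variants$somatic_depth,
    t_alt_count = variants$allele_depth,
    popfreq_all = variants$pop_freq,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
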