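#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses genotypes with `VariantAnnotation::readVcf()`. Multi-allelic records
#' are decomposed into bi-allelic variants keyed `chrom:pos:ref:alt`
#' (1-based coordinates; no left-normalisation is performed, inputs are
#' assumed normalised). Genotype calls are mapped to alternate-allele dosage:
#' 0 = hom-ref, 1 = het, 2 = hom-alt; any call containing `.` (including
#' half-calls) is missing (`NA`). Phase separators are ignored.
#'
#' @param path Path to a VCF file (plain, gzip or bgzip).
#' @return Integer matrix, patients in rows (rownames = sample ids), variants
#'   in columns (colnames = variant keys).
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  if (!("GT" %in% names(g))) stop("VCF has no GT genotype field")
  gt <- g$GT
  if (all(is.na(gt) | gt == ".")) {
    stop("VCF has no GT genotype field (no genotype calls present)")
  }
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicate sample id in VCF header")

  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  chrom <- as.character(rr$seqnames)
  pos <- rr$start
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- lapply(VariantAnnotation::alt(vcf), as.character)
  n_alt <- lengths(alt_list)

  # dosage lookup per alternate-allele index over the distinct GT strings
  u <- unique(as.vector(gt))
  parse_gt <- function(s, a) {
    if (is.na(s)) return(NA_integer_)
    toks <- strsplit(s, "[/|]")[[1]]
    if (length(toks) == 0 || any(toks == ".")) return(NA_integer_)
    min(sum(toks == as.character(a)), 2L)
  }
  lookup <- lapply(seq_len(max(n_alt)), function(a) {
    v <- vapply(u, parse_gt, integer(1), a = a)
    names(v) <- u
    v
  })

  keys <- character(sum(n_alt))
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = sum(n_alt),
                  dimnames = list(samples, NULL))
  j <- 0L
  for (i in seq_along(chrom)) {
    for (a in seq_len(n_alt[i])) {
      j <- j + 1L
      keys[j] <- paste(chrom[i], pos[i], ref[i], alt_list[[i]][a], sep = ":")
      calls[, j] <- lookup[[a]][gt[i, ]]
    }
  }
  colnames(calls) <- keys
  if (anyDuplicated(keys)) stop("duplicate variant key after decomposition")
  calls
}

#' Write a genotype matrix (plus annotations) as VCF
#'
#' Minimal VCF 4.2 writer emitting GT only, in the dialect [read_vcf()]
#' accepts; a write/read round trip reproduces the calls.
#'
#' @param genotypes Integer patient x variant matrix as from [read_vcf()].
#' @param annotations Annotation table carrying `chrom`, `pos`, `ref`, `alt`
#'   and `filter_status` for every variant column (see [read_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, annotations, path) {
  keys <- colnames(genotypes)
  ann <- annotations[match(keys, annotations$variant_key), ]
  if (anyNA(ann$variant_key)) stop("annotations missing for some variants")
  ord <- order(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann <- ann[ord, ]
  gmap <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(ann)), function(i) {
    calls <- genotypes[, ann$variant_key[i]]
    gt <- ifelse(is.na(calls), "./.", gmap[calls + 1L])
    paste(c(ann$chrom[i], ann$pos[i], ".", ann$ref[i], ann$alt[i], ".",
            ann$filter_status[i], ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read the per-variant annotation table
#'
#' Expects a TSV with header columns `chrom, pos, ref, alt, gene, gnomad_ac,
#' gnomad_an, gnomad_hom, cadd_phred, filter, coding_distance`. An empty
#' `gnomad_an` encodes "not covered in gnomAD" (stored as `NA`; such variants
#' are later removed by [filter_variants()]). Row-level invariants
#' (AC <= AN, 2 HOM <= AC, non-negative counts) are validated with the
#' offending line number reported.
#'
#' @param path Path to the TSV (optionally gzip-compressed).
#' @return `data.frame` keyed by `variant_key`, one row per variant.
#' @export
read_annotations <- function(path) {
  need <- c("chrom", "pos", "ref", "alt", "gene", "gnomad_ac", "gnomad_an",
            "gnomad_hom", "cadd_phred", "filter", "coding_distance")
  hdr <- names(data.table::fread(path, sep = "\t", header = TRUE, nrows = 0))
  miss <- setdiff(need, hdr)
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  ann <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("chrom", "ref",
                                                           "alt", "gene",
                                                           "filter")),
                           na.strings = c("", "NA"), data.table = FALSE)
  ann$variant_key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  names(ann)[names(ann) == "filter"] <- "filter_status"
  bad <- which(!is.na(ann$gnomad_an) &
                 (ann$gnomad_ac > ann$gnomad_an |
                    2 * ann$gnomad_hom > ann$gnomad_ac |
                    ann$gnomad_ac < 0 | ann$gnomad_hom < 0))
  if (length(bad)) {
    stop("annotation invariant violated (AC <= AN, 2*HOM <= AC) at line ",
         bad[1] + 1L)
  }
  if (any(ann$cadd_phred < 0, na.rm = TRUE) ||
      any(ann$coding_distance < 0, na.rm = TRUE)) {
    stop("cadd_phred and coding_distance must be non-negative")
  }
  if (anyDuplicated(ann$variant_key)) stop("duplicate variant in annotations")
  ann
}

#' Write an annotation table
#' @param annotations Annotation `data.frame` (see [read_annotations()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "gnomad_ac", "gnomad_an",
            "gnomad_hom", "cadd_phred", "filter_status", "coding_distance")
  out <- annotations[cols]
  names(out)[names(out) == "filter_status"] <- "filter"
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read the patient phenotype table
#'
#' UTF-8 TSV with a header row and two columns: `patient_id` and a
#' comma-separated list of HPO term ids. Patients with no terms are dropped
#' with a warning.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with `patient_id` and list column `hpo`.
#' @export
read_phenotypes <- function(path) {
  ph <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (!all(c("patient_id", "hpo") %in% names(ph))) {
    stop("phenotype table must have header columns patient_id, hpo")
  }
  if (anyDuplicated(ph$patient_id)) stop("duplicate patient_id")
  hpo <- lapply(strsplit(ph$hpo, ","), function(tt) {
    tt <- trimws(tt)
    tt[nzchar(tt)]
  })
  keep <- lengths(hpo) > 0
  if (!all(keep)) {
    warning(sum(!keep), " patient(s) with no HPO terms dropped")
  }
  data.frame(patient_id = ph$patient_id[keep], hpo = I(hpo[keep]),
             stringsAsFactors = FALSE)
}

#' Write a patient phenotype table
#' @param patients Patient `data.frame` (`patient_id`, list column `hpo`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(patients, path) {
  out <- data.frame(
    patient_id = patients$patient_id,
    hpo = vapply(patients$hpo, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Assemble a cohort object
#'
#' Bundles patients, genotypes and annotations; computes per-variant
#' missingness from the genotype matrix when the annotation table does not
#' carry it; builds the gene -> variants index (a variant may be assigned to
#' several genes via a comma- or semicolon-separated `gene` field).
#'
#' @param patients Patient table (`patient_id`, list column `hpo`).
#' @param genotypes Integer patient x variant matrix ([read_vcf()]).
#' @param annotations Annotation table ([read_annotations()]); must cover
#'   every genotyped variant.
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(patients, genotypes, annotations) {
  keys <- colnames(genotypes)
  if (!all(keys %in% annotations$variant_key)) {
    stop("every genotyped variant needs an annotation; missing: ",
         paste(utils::head(setdiff(keys, annotations$variant_key), 3),
               collapse = ", "))
  }
  annotations <- annotations[match(keys, annotations$variant_key), ]
  if (!("missing_rate" %in% names(annotations)) ||
      anyNA(annotations$missing_rate)) {
    annotations$missing_rate <- colMeans(is.na(genotypes))
  }
  genes <- strsplit(annotations$gene, "[,;]")
  gene_index <- split(rep(annotations$variant_key, lengths(genes)),
                      trimws(unlist(genes)))
  structure(
    list(patients = patients, genotypes = genotypes,
         annotations = annotations, gene_index = gene_index),
    class = "cohort_data"
  )
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d patients, %d variants, %d genes\n",
              nrow(x$patients), ncol(x$genotypes), length(x$gene_index)))
  invisible(x)
}

#' Apply the variant quality filters
#'
#' Retains exactly the variants that (1) pass the caller filters
#' (`filter_status == "PASS"`), (2) are covered in gnomAD (AN present and
#' positive), (3) lie within 5 bp of a coding region
#' (`coding_distance <= 5`), and (4) have cohort missingness below 20%.
#' The input cohort is unmodified; per-rule removal counts are logged.
#' Filtering is idempotent.
#'
#' @param cohort A [cohort_data()] object.
#' @param config A [genon_config()] (reserved for future rule parameters).
#' @return A new, filtered `cohort_data`.
#' @export
filter_variants <- function(cohort, config = genon_config()) {
  ann <- cohort$annotations
  fail_pass <- ann$filter_status != "PASS"
  fail_cov <- is.na(ann$gnomad_an) | ann$gnomad_an <= 0
  fail_cod <- is.na(ann$coding_distance) | ann$coding_distance > 5
  fail_mis <- ann$missing_rate >= 0.20
  keep <- !(fail_pass | fail_cov | fail_cod | fail_mis)
  genon_log("filter",
            "removed %d non-PASS, %d gnomAD-uncovered, %d non-coding, %d high-missingness; %d/%d retained",
            sum(fail_pass), sum(fail_cov), sum(fail_cod), sum(fail_mis),
            sum(keep), length(keep))
  if (!any(keep)) warning("no variants survive the filters")
  cohort_data(cohort$patients,
              cohort$genotypes[, keep, drop = FALSE],
              ann[keep, , drop = FALSE])
}
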