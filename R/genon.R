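#' Mode-of-inheritance-dependent genotype frequency
#'
#' Under dominant inheritance the genotype frequency (GF) of a variant is its
#' gnomAD allele frequency AC / AN; under recessive inheritance it is the
#' estimated homozygote frequency 2 HOM / AN. The comparator convention
#' `gf_convention = "allele_frequency_for_recessive"` uses AC / AN for both
#' branches.
#'
#' @param annotations Annotation table rows (needs `gnomad_ac`, `gnomad_an`,
#'   `gnomad_hom`).
#' @param moi `"dominant"` or `"recessive"`.
#' @param config A [genon_config()].
#' @return Numeric vector of GF values in \[0, 1\].
#' @export
genotype_frequency <- function(annotations, moi = c("dominant", "recessive"),
                               config = genon_config()) {
  moi <- match.arg(moi)
  an <- annotations$gnomad_an
  if (any(is.na(an) | an <= 0)) {
    stop("undefined genotype frequency: gnomAD AN missing or zero ",
         "(variant should have been filtered)")
  }
  if (moi == "dominant" ||
      config$gf_convention == "allele_frequency_for_recessive") {
    annotations$gnomad_ac / an
  } else {
    2 * annotations$gnomad_hom / an
  }
}

#' Assign variants to grid bins
#'
#' Half-open bins: CADD row r covers `[r*h, (r+1)*h)` and GF column c covers
#' `[c*w, (c+1)*w)`. CADD at or above `cadd_max` clamps into the top row; GF
#' at or above `gf_max` is excluded (both indices `NA`). Column 0 is the rare
#' column.
#'
#' @param gf,cadd Numeric vectors (recycled to common length).
#' @param config A [genon_config()].
#' @return `data.frame` with integer columns `cadd_row` and `gf_col`
#'   (0-based; `NA` = excluded).
#' @export
assign_bin <- function(gf, cadd, config = genon_config()) {
  stopifnot(all(gf >= 0), all(cadd >= 0))
  n <- max(length(gf), length(cadd))
  gf <- rep_len(gf, n); cadd <- rep_len(cadd, n)
  row <- pmin(as.integer(floor(cadd / config$cadd_bin_height)),
              config$n_cadd_rows - 1L)
  col <- as.integer(floor(gf / config$gf_bin_width))
  excl <- gf >= config$gf_max
  row[excl] <- NA_integer_
  col[excl] <- NA_integer_
  data.frame(cadd_row = row, gf_col = col)
}

#' One-sided Fisher exact test for case enrichment
#'
#' Upper-tail p of the 2x2 table
#' `[[case_carriers, n_cases - case_carriers],
#'   [control_carriers, n_controls - control_carriers]]`,
#' i.e. the hypergeometric probability of at least `case_carriers` carriers
#' among the cases. `p = 1` whenever `case_carriers = 0`. Vectorised.
#'
#' @param case_carriers,n_cases,control_carriers,n_controls Non-negative
#'   integer vectors.
#' @return Numeric vector of p-values in (0, 1\].
#' @export
bin_fisher <- function(case_carriers, n_cases, control_carriers, n_controls) {
  if (any(case_carriers < 0 | control_carriers < 0 | n_cases < 0 |
            n_controls < 0)) {
    stop("negative count in contingency table")
  }
  if (any(case_carriers > n_cases | control_carriers > n_controls)) {
    stop("carrier count exceeds group size")
  }
  if (any(n_cases + n_controls <= 0)) stop("empty cohort")
  exp(.lp_fisher(case_carriers, n_cases, control_carriers, n_controls))
}

# log upper-tail hypergeometric p, kept in log space for precision
.lp_fisher <- function(a, n_cases, c, n_controls) {
  stats::phyper(a - 1, a + c, n_cases + n_controls - (a + c), n_cases,
                lower.tail = FALSE, log.p = TRUE)
}

# z = Phi^-1(1 - p) with p clipped into config$p_clip; takes log p. For p
# near 1 the log.p upper-tail quantile loses precision, so that branch goes
# through the accurately complemented lower-tail probability -expm1(lp).
.z_from_lp <- function(lp, config) {
  lp <- pmin(pmax(lp, log(config$p_clip[1])), log(config$p_clip[2]))
  out <- lp
  hi <- lp > log(0.5)
  out[hi] <- stats::qnorm(-expm1(lp[hi]))
  out[!hi] <- stats::qnorm(lp[!hi], lower.tail = FALSE, log.p = TRUE)
  out
}

# Core per-gene binning machinery shared by build_heatmap() and the screen.
# Computes, for one gene and MOI: the non-empty cells (>= 1 qualifying
# carrier), their member variants and carrier patient-index sets.
.gene_cells <- function(cohort, gene, moi, config) {
  keys <- cohort$gene_index[[gene]]
  if (is.null(keys)) stop("unknown gene: ", gene)
  ann <- cohort$annotations[match(keys, cohort$annotations$variant_key), ]
  if (nrow(ann) == 0) {
    return(list(cells = data.frame(), variants = list(), carriers = list()))
  }
  gf <- genotype_frequency(ann, moi, config)
  bins <- assign_bin(gf, ann$cadd_phred, config)
  G <- cohort$genotypes[, keys, drop = FALSE]
  G[is.na(G)] <- 0L  # missing genotype counts as non-carrier

  if (moi == "dominant") {
    qualifies <- G >= 1L
  } else {
    m <- length(keys)
    # recessive GF is used for both sides of the compound-het comparison
    gfr <- gf
    partner_ok <- outer(ann$cadd_phred, ann$cadd_phred, ">=") &
      outer(gfr, gfr, "<=")
    diag(partner_ok) <- FALSE
    # partner_ok[u, v]: u is an acceptable second hit for anchor v
    has_partner <- ((G >= 1L) %*% partner_ok) >= 1L
    qualifies <- (G == 2L) | (G == 1L & has_partner)
  }

  inbin <- !is.na(bins$cadd_row)
  cell_id <- ifelse(inbin, paste(bins$cadd_row, bins$gf_col, sep = "_"), NA)
  groups <- split(which(inbin), cell_id[inbin])
  carriers <- lapply(groups, function(ix) {
    which(rowSums(qualifies[, ix, drop = FALSE]) > 0)
  })
  nonempty <- lengths(carriers) > 0
  groups <- groups[nonempty]
  carriers <- carriers[nonempty]
  if (length(groups) == 0) {
    return(list(cells = data.frame(), variants = list(), carriers = list()))
  }
  rc <- do.call(rbind, strsplit(names(groups), "_", fixed = TRUE))
  cells <- data.frame(cadd_row = as.integer(rc[, 1]),
                      gf_col = as.integer(rc[, 2]),
                      n_variants = lengths(groups))
  cells$is_rare <- cells$gf_col == 0L
  ord <- order(cells$cadd_row, cells$gf_col)
  list(cells = cells[ord, , drop = FALSE],
       variants = lapply(groups[ord], function(ix) keys[ix]),
       carriers = carriers[ord])
}

#' Identify carriers of a bin's variants
#'
#' Dominant: patients with at least one non-missing alternate call on any of
#' the cell variants. Recessive: patients homozygous-alternate for a cell
#' variant, or heterozygous for a cell variant `v` while carrying a second,
#' distinct variant `u` in the same gene with `cadd(u) >= cadd(v)` and
#' `GF(u) <= GF(v)` (GF under the recessive definition; the pair is presumed
#' in trans -- phasing is not assessed). Missing genotypes never qualify.
#'
#' @param cohort A filtered [cohort_data()].
#' @param gene Gene symbol (compound-het partners are searched gene-wide).
#' @param variant_keys Variant keys of the cell.
#' @param moi `"dominant"` or `"recessive"`.
#' @param config A [genon_config()].
#' @return Character vector of carrier patient ids.
#' @export
find_carriers <- function(cohort, gene, variant_keys,
                          moi = c("dominant", "recessive"),
                          config = genon_config()) {
  moi <- match.arg(moi)
  if (is.null(cohort$gene_index[[gene]])) stop("unknown gene: ", gene)
  bad <- setdiff(variant_keys, cohort$gene_index[[gene]])
  if (length(bad)) stop("variant(s) not in gene ", gene, ": ",
                        paste(bad, collapse = ", "))
  idx <- .gene_cells_carriers_subset(cohort, gene, variant_keys, moi, config)
  sort(cohort$patients$patient_id[idx])
}

# carriers over an arbitrary variant subset (same qualification rule)
.gene_cells_carriers_subset <- function(cohort, gene, keys, moi, config) {
  all_keys <- cohort$gene_index[[gene]]
  ann <- cohort$annotations[match(all_keys, cohort$annotations$variant_key), ]
  gf <- genotype_frequency(ann, moi, config)
  G <- cohort$genotypes[, all_keys, drop = FALSE]
  G[is.na(G)] <- 0L
  sel <- match(keys, all_keys)
  if (moi == "dominant") {
    return(which(rowSums(G[, sel, drop = FALSE] >= 1L) > 0))
  }
  partner_ok <- outer(ann$cadd_phred, ann$cadd_phred, ">=") &
    outer(gf, gf, "<=")
  diag(partner_ok) <- FALSE
  has_partner <- ((G >= 1L) %*% partner_ok) >= 1L
  qual <- (G == 2L) | (G == 1L & has_partner)
  which(rowSums(qual[, sel, drop = FALSE]) > 0)
}

#' Build the Fisher-test heatmap for one gene, term and MOI
#'
#' Splits the cohort on the term (term or any descendant = case), bins every
#' retained gene variant on the GF x CADD grid, finds per-bin carriers under
#' the MOI, and applies the one-sided Fisher test to each non-empty bin. A
#' bin is non-empty when at least one patient qualifies as a carrier of it;
#' bins without member variants, and bins whose variants no patient qualifies
#' for under the MOI, are omitted (they carry no genotype evidence).
#'
#' @param cohort A filtered [cohort_data()].
#' @param ontology An `hpo_ontology` (for the case/control split).
#' @param gene Gene symbol.
#' @param term_id HPO term id (or several; conjunction).
#' @param moi `"dominant"` or `"recessive"`.
#' @param config A [genon_config()].
#' @return Object of class `genon_heatmap`: list with `gene`, `term_id`,
#'   `moi`, `cells` (data frame: `cadd_row`, `gf_col`, `cadd_low`, `gf_low`,
#'   `is_rare`, `n_variants`, `case_carriers`, `control_carriers`, `p`,
#'   `minus_ln_p`, `z`; row-major order), `variants` (list of member variant
#'   keys per cell), `n_cases`, `n_controls`, `k_rare`, `k_nonrare`.
#' @export
build_heatmap <- function(cohort, ontology, gene, term_id,
                          moi = c("dominant", "recessive"),
                          config = genon_config()) {
  moi <- match.arg(moi)
  part <- split_cases(ontology, cohort$patients, term_id)
  case <- cohort$patients$patient_id %in% part$cases
  gc <- .gene_cells(cohort, gene, moi, config)
  .heatmap_from_cells(gc, case, gene, term_id, moi, config)
}

.heatmap_from_cells <- function(gc, case, gene, term_id, moi, config) {
  n_cases <- sum(case)
  n_controls <- sum(!case)
  cells <- gc$cells
  if (nrow(cells) == 0) {
    hm <- list(gene = gene, term_id = term_id, moi = moi,
               cells = data.frame(), variants = list(),
               n_cases = n_cases, n_controls = n_controls,
               k_rare = 0L, k_nonrare = 0L)
    class(hm) <- "genon_heatmap"
    return(hm)
  }
  a <- vapply(gc$carriers, function(ix) sum(case[ix]), integer(1))
  tot <- lengths(gc$carriers)
  lp <- .lp_fisher(a, n_cases, tot - a, n_controls)
  cells$cadd_low <- cells$cadd_row * config$cadd_bin_height
  cells$gf_low <- cells$gf_col * config$gf_bin_width
  cells$case_carriers <- a
  cells$control_carriers <- tot - a
  cells$p <- exp(lp)
  cells$minus_ln_p <- -lp
  cells$z <- .z_from_lp(lp, config)
  hm <- list(gene = gene, term_id = term_id, moi = moi, cells = cells,
             variants = gc$variants,
             n_cases = n_cases, n_controls = n_controls,
             k_rare = sum(cells$is_rare),
             k_nonrare = sum(!cells$is_rare))
  class(hm) <- "genon_heatmap"
  hm
}

#' @export
print.genon_heatmap <- function(x, ...) {
  cat(sprintf("<genon_heatmap> %s / %s / %s: %d cell(s) (%d rare), %d cases vs %d controls\n",
              x$gene, paste(x$term_id, collapse = "+"), x$moi,
              nrow(x$cells), x$k_rare, x$n_cases, x$n_controls))
  if (nrow(x$cells)) {
    print(x$cells[c("cadd_low", "gf_low", "n_variants", "case_carriers",
                    "control_carriers", "p")], row.names = FALSE)
  }
  invisible(x)
}

#' Export a heatmap as TSV or JSON
#'
#' TSV columns: `cadd_row_low, gf_col_low, n_variants, case_carriers,
#' control_carriers, p, z, minus_ln_p`, in deterministic row-major order.
#' The JSON document nests the same cells under the pair metadata.
#'
#' @param heatmap A `genon_heatmap`.
#' @param path Output path; when `NULL` the formatted object is returned.
#' @param format `"tsv"` or `"json"`.
#' @return The exported table (TSV) or JSON string, invisibly when written.
#' @export
export_heatmap <- function(heatmap, path = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  cells <- heatmap$cells
  if (nrow(cells)) {
    cells <- cells[order(cells$cadd_row, cells$gf_col), , drop = FALSE]
  }
  tab <- if (nrow(cells)) {
    data.frame(cadd_row_low = cells$cadd_low, gf_col_low = cells$gf_low,
               n_variants = cells$n_variants,
               case_carriers = cells$case_carriers,
               control_carriers = cells$control_carriers,
               p = cells$p, z = cells$z, minus_ln_p = cells$minus_ln_p)
  } else {
    data.frame(cadd_row_low = numeric(0), gf_col_low = numeric(0),
               n_variants = integer(0), case_carriers = integer(0),
               control_carriers = integer(0), p = numeric(0), z = numeric(0),
               minus_ln_p = numeric(0))
  }
  if (format == "tsv") {
    if (is.null(path)) return(tab)
    data.table::fwrite(tab, path, sep = "\t", quote = FALSE)
    return(invisible(tab))
  }
  doc <- list(gene = heatmap$gene, term_id = heatmap$term_id,
              moi = heatmap$moi, n_cases = heatmap$n_cases,
              n_controls = heatmap$n_controls, k_rare = heatmap$k_rare,
              k_nonrare = heatmap$k_nonrare, cells = tab)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
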