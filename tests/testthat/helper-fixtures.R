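# In-code fixtures shared across the test files.

# three-level chain plus a sibling branch:
# root <- A <- B, root <- C; O is obsolete, replaced by A
toy_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: root", "",
    "[Term]", "id: HP:0000002", "name: A", "is_a: HP:0000001 ! root", "",
    "[Term]", "id: HP:0000003", "name: B", "is_a: HP:0000002", "",
    "[Term]", "id: HP:0000004", "name: C", "is_a: HP:0000001", "",
    "[Term]", "id: HP:0000099", "name: O", "is_obsolete: true",
    "replaced_by: HP:0000002", "")
}

toy_ontology <- function() parse_obo(toy_obo())

# annotation row builder with sane defaults (PASS, covered, coding, CADD 30)
make_ann <- function(pos, gene = "G1", ac = 5, an = 200000, hom = 0,
                     cadd = 30, filter = "PASS", coding_distance = 0,
                     ref = "A", alt = "T", chrom = "1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             gnomad_ac = ac, gnomad_an = an, gnomad_hom = hom,
             cadd_phred = cadd, filter_status = filter,
             coding_distance = coding_distance,
             variant_key = paste(chrom, pos, ref, alt, sep = ":"),
             stringsAsFactors = FALSE)
}

# cohort from a genotype matrix (patients x variants), annotation rows and a
# named list patient_id -> character vector of HPO ids
make_cohort <- function(geno, ann, terms) {
  patients <- data.frame(patient_id = rownames(geno),
                         hpo = I(unname(terms[rownames(geno)])),
                         stringsAsFactors = FALSE)
  cohort_data(patients, geno, ann)
}

# small planted end-to-end fixture used by screen/cli tests: 300 patients,
# 20 background genes, one recessive plant with 8 carriers
small_sim <- function(seed = 1, moi = "recessive", contaminant = NULL,
                      n_carriers = 8) {
  pl <- planted_association("GENE_PLANT", "HP:0000005", moi,
                            n_carriers_in_cases = n_carriers,
                            contaminant_af = contaminant)
  simulate_cohort(simulation_params(
    n_patients = 300, n_background_genes = 20, planted = list(pl),
    seed = seed))
}

# synthetic heatmap with prescribed cells (bypasses the cohort machinery);
# p, cadd_row, gf_col vectors of equal length
make_heatmap <- function(p, cadd_row, gf_col, config = genon_config(),
                         gene = "G", term_id = "HP:0000002",
                         moi = "dominant") {
  if (length(p) == 0) {
    return(structure(list(gene = gene, term_id = term_id, moi = moi,
                          cells = data.frame(), variants = list(),
                          n_cases = 10L, n_controls = 90L,
                          k_rare = 0L, k_nonrare = 0L),
                     class = "genon_heatmap"))
  }
  lp <- log(p)
  lpc <- pmin(pmax(lp, log(config$p_clip[1])), log(config$p_clip[2]))
  cells <- data.frame(
    cadd_row = as.integer(cadd_row), gf_col = as.integer(gf_col),
    n_variants = 1L, is_rare = gf_col == 0,
    cadd_low = cadd_row * config$cadd_bin_height,
    gf_low = gf_col * config$gf_bin_width,
    case_carriers = 1L, control_carriers = 1L,
    p = p, minus_ln_p = -lp,
    z = stats::qnorm(lpc, lower.tail = FALSE, log.p = TRUE))
  structure(list(gene = gene, term_id = term_id, moi = moi, cells = cells,
                 variants = list(), n_cases = 10L, n_controls = 90L,
                 k_rare = sum(cells$is_rare),
                 k_nonrare = sum(!cells$is_rare)),
            class = "genon_heatmap")
}

write_tmp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
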