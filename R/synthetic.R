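#' Simulate a balanced phenotype ontology
#'
#' Builds a balanced is_a tree (a valid, if simple, stand-in for the real
#' phenotype DAG): one synthetic root with `branching` children per node down
#' to the given depth. Term ids are deterministic (`HP:0000001` onwards,
#' breadth-first); term labels are drawn from a seeded generator, so two
#' seeds give different labels on the same topology.
#'
#' @param depth Number of levels including the root (>= 2).
#' @param branching Children per internal node.
#' @param seed Integer seed for the labels; `NULL` uses the current RNG
#'   state.
#' @param path Optional OBO output path ([write_obo()] dialect).
#' @return An `hpo_ontology`.
#' @examples
#' ont <- simulate_ontology(depth = 3, branching = 2, seed = 1)
#' length(ont$ids)  # 1 + 2 + 4
#' @export
simulate_ontology <- function(depth = 3, branching = 3, seed = 1,
                              path = NULL) {
  stopifnot(depth >= 2, branching >= 1)
  build <- function() {
    n_per_level <- branching^(0:(depth - 1))
    n <- sum(n_per_level)
    ids <- sprintf("HP:%07d", seq_len(n))
    parents <- rep(list(character(0)), n)
    # breadth-first numbering: node i's children are branching*(i-1)+2 ...
    for (i in seq_len(n - 1) + 1L) {
      parents[[i]] <- ids[(i - 2L) %/% branching + 1L]
    }
    names(parents) <- ids
    syll <- c("reti", "nal", "myo", "card", "neuro", "derm", "osse", "ocul",
              "audi", "gastro", "pulmo", "renal", "hepat", "ost", "chondro")
    nm <- c("All (synthetic root)",
            paste0(
              vapply(seq_len(n - 1), function(i) {
                paste0(toupper(substr(s <- paste(sample(syll, 3), collapse = ""),
                                      1, 1)), substr(s, 2, nchar(s)))
              }, character(1)),
              " abnormality"))
    names(nm) <- ids
    children <- rep(list(character(0)), n)
    names(children) <- ids
    for (id in ids[-1]) {
      p <- parents[[id]]
      children[[p]] <- c(children[[p]], id)
    }
    structure(list(ids = ids, name = nm, parents = parents,
                   children = children, alias = character(0),
                   root_id = ids[1]),
              class = "hpo_ontology")
  }
  ont <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  if (!is.null(path)) write_obo(ont, path)
  ont
}

#' Describe a planted gene-phenotype association
#'
#' Encodes the causal structure the simulator realises exactly: ultra-rare,
#' high-CADD causal variants whose carriers receive the phenotype term with
#' probability `penetrance`, while non-carriers receive it at
#' `phenocopy_rate`. Recessive carriers get two distinct heterozygous causal
#' variants (compound het) or, for a `hom_fraction` of them, one homozygous
#' call, so they satisfy the recessive carrier rule by construction. An
#' optional common contaminant variant (non-rare under the dominant GF,
#' rare under the recessive homozygote-frequency GF) can be enriched in
#' cases to emulate frequency-driven confounding.
#'
#' @param gene Gene symbol the association is planted into.
#' @param term_id Phenotype term assigned to carriers.
#' @param moi `"dominant"` or `"recessive"`.
#' @param n_carriers_in_cases Exact number of carrier patients.
#' @param cadd_range CADD interval of the causal variants (default
#'   \[25, 35)).
#' @param causal_gf Target genotype frequency of each causal variant under
#'   the planted mode of inheritance; must be below the rare threshold
#'   0.00025. For a dominant plant this is the gnomAD allele frequency; for
#'   a recessive plant it is the estimated homozygote frequency (realised as
#'   a gnomAD homozygote count of 0, the ultra-rare convention, so the
#'   recessive GF is exactly 0).
#' @param causal_af gnomAD allele frequency of the causal variants. Defaults
#'   to `causal_gf` for dominant plants. For recessive plants the default is
#'   1e-3 (a carrier frequency of about 1/500, typical of recessive disease
#'   alleles): rare under the recessive homozygote-frequency GF but non-rare
#'   under the dominant allele-frequency GF, which is the frequency
#'   signature the signal ratio exploits.
#' @param penetrance Fraction of carriers given the term.
#' @param phenocopy_rate Fraction of non-carriers given the term.
#' @param n_causal_variants Size of the causal allelic series.
#' @param hom_fraction Recessive only: fraction of carriers homozygous for
#'   one causal variant instead of compound heterozygous.
#' @param contaminant_af When non-`NULL`, plant one extra variant at this
#'   gnomAD allele frequency.
#' @param contaminant_cadd CADD of the contaminant.
#' @param contaminant_case_rate Heterozygous-carriage probability of the
#'   contaminant among case patients (non-cases follow Hardy-Weinberg).
#' @return A list of class `planted_association`.
#' @export
planted_association <- function(gene, term_id,
                                moi = c("dominant", "recessive"),
                                n_carriers_in_cases = 15,
                                cadd_range = c(25, 35),
                                causal_gf = 1e-5,
                                causal_af = NULL,
                                penetrance = 1,
                                phenocopy_rate = 0.01,
                                n_causal_variants = 4,
                                hom_fraction = 0.2,
                                contaminant_af = NULL,
                                contaminant_cadd = 30,
                                contaminant_case_rate = 0.3) {
  moi <- match.arg(moi)
  if (is.null(causal_af)) {
    causal_af <- if (moi == "dominant") causal_gf else 1e-3
  }
  stopifnot(causal_gf < 0.00025, penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            n_causal_variants >= ifelse(moi == "recessive", 2, 1))
  if (moi == "dominant" && causal_af >= 0.00025) {
    stop("dominant plant: causal_af is the GF and must be < 0.00025")
  }
  structure(list(gene = gene, term_id = term_id, moi = moi,
                 n_carriers_in_cases = n_carriers_in_cases,
                 cadd_range = cadd_range, causal_gf = causal_gf,
                 causal_af = causal_af,
                 penetrance = penetrance, phenocopy_rate = phenocopy_rate,
                 n_causal_variants = n_causal_variants,
                 hom_fraction = hom_fraction,
                 contaminant_af = contaminant_af,
                 contaminant_cadd = contaminant_cadd,
                 contaminant_case_rate = contaminant_case_rate),
            class = "planted_association")
}

#' Simulation parameters
#'
#' Defaults emulate, at desk scale, an unrelated rare-disease exome cohort:
#' 2,000 patients, 200 background genes with a Poisson(30) candidate variant
#' count each, a gnomAD-like frequency spectrum dominated by rare alleles
#' (log-uniform mixture: 60% in 1e-6..2e-4, 25% in 2e-4..1e-3, 15% in
#' 1e-3..1e-2), a bimodal CADD distribution (80% benign N(8, 4), 20%
#' damaging N(28, 5), truncated to \[0, 40)), Hardy-Weinberg genotypes,
#' per-variant missingness uniform in \[0, 0.1\], and gnomAD annotations
#' derived from the simulated frequency at a nominal AN of 500,000 so that
#' GF binning is exactly controllable. Only cohort-observed variants (at
#' least one alternate call) enter the emitted call set, as in a real
#' joint-called VCF.
#'
#' @param n_patients Cohort size (>= 2).
#' @param n_background_genes Number of null genes.
#' @param variants_per_gene Poisson mean of candidate variants per gene.
#' @param af_mix Mixture weights of the rare / low / common frequency bands
#'   (must sum to 1).
#' @param af_ranges List of the three log-uniform AF bands.
#' @param cadd_mix Mixture weights of the benign / damaging CADD components.
#' @param cadd_benign,cadd_damaging `c(mean, sd)` of the two components.
#' @param missing_rate_range Per-variant missingness range.
#' @param an_nominal Nominal gnomAD allele number.
#' @param frac_nonpass,frac_noncoding,frac_uncovered Fractions of background
#'   variants failing the caller filter, lying > 5 bp from coding sequence,
#'   or lacking gnomAD coverage (exercise the variant filters).
#' @param planted List of [planted_association()] objects.
#' @param ontology_depth,ontology_branching Shape of the simulated ontology.
#' @param terms_per_patient Range of background terms drawn per patient.
#' @param seed Integer seed; the whole simulation is a deterministic function
#'   of the parameter object.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_patients = 2000,
                              n_background_genes = 200,
                              variants_per_gene = 30,
                              af_mix = c(rare = 0.6, low = 0.25,
                                         common = 0.15),
                              af_ranges = list(rare = c(1e-6, 2e-4),
                                               low = c(2e-4, 1e-3),
                                               common = c(1e-3, 1e-2)),
                              cadd_mix = c(benign = 0.8, damaging = 0.2),
                              cadd_benign = c(8, 4),
                              cadd_damaging = c(28, 5),
                              missing_rate_range = c(0, 0.1),
                              an_nominal = 500000,
                              frac_nonpass = 0.03,
                              frac_noncoding = 0.02,
                              frac_uncovered = 0.01,
                              planted = list(),
                              ontology_depth = 3,
                              ontology_branching = 3,
                              terms_per_patient = c(1, 3),
                              seed = 1) {
  if (n_patients < 2) stop("n_patients must be at least 2")
  if (abs(sum(af_mix) - 1) > 1e-9 || abs(sum(cadd_mix) - 1) > 1e-9) {
    stop("mixture weights must sum to 1")
  }
  if (inherits(planted, "planted_association")) planted <- list(planted)
  for (pl in planted) {
    if (pl$n_carriers_in_cases > n_patients) {
      stop("infeasible plant: n_carriers_in_cases > n_patients")
    }
  }
  structure(
    list(n_patients = n_patients, n_background_genes = n_background_genes,
         variants_per_gene = variants_per_gene, af_mix = af_mix,
         af_ranges = af_ranges, cadd_mix = cadd_mix,
         cadd_benign = cadd_benign, cadd_damaging = cadd_damaging,
         missing_rate_range = missing_rate_range, an_nominal = an_nominal,
         frac_nonpass = frac_nonpass, frac_noncoding = frac_noncoding,
         frac_uncovered = frac_uncovered, planted = planted,
         ontology_depth = ontology_depth,
         ontology_branching = ontology_branching,
         terms_per_patient = terms_per_patient, seed = seed),
    class = "simulation_params")
}

# truncated normal via the inverse-CDF of the conditioned interval
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a cohort
#'
#' Generates a complete, self-consistent cohort: ontology, patients with
#' phenotype terms, genotype matrix, gnomAD/CADD-style annotations, and the
#' truth records of the planted associations. Planted carrier counts are
#' exact, not expected: carriers are chosen patients whose causal genotypes
#' are written directly (and never masked as missing), then phenotype terms
#' are assigned by penetrance / phenocopy. Background terms exclude the
#' planted terms and their descendants so phenocopy rates stay controlled.
#'
#' @param params A [simulation_params()] object.
#' @param dir Optional output directory; when given, the cohort is written as
#'   `cohort.vcf`, `annotations.tsv`, `phenotypes.tsv`, `ontology.obo`,
#'   `truth.tsv` and `manifest.json` (the dialects the package readers
#'   accept).
#' @return List of class `genon_simulation`: `cohort` (a [cohort_data()]),
#'   `ontology`, `truth` (data frame `gene, hpo_id, moi`), `planted_carriers`
#'   (patient ids per plant) and `params`.
#' @export
simulate_cohort <- function(params = simulation_params(), dir = NULL) {
  sim <- withr::with_seed(params$seed, .simulate_cohort_impl(params))
  if (!is.null(dir)) write_simulation(sim, dir)
  sim
}

.simulate_cohort_impl <- function(params) {
  p <- params
  ont <- simulate_ontology(p$ontology_depth, p$ontology_branching,
                           seed = NULL)
  n <- p$n_patients
  patient_ids <- sprintf("P%05d", seq_len(n))

  genes <- sprintf("GENE%04d", seq_len(p$n_background_genes))
  planted_genes <- vapply(p$planted, `[[`, character(1), "gene")
  genes <- union(genes, planted_genes)

  ann_list <- list()
  geno_list <- list()
  pos_base <- 0L
  bases <- c("A", "C", "G", "T")
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    m <- max(1L, stats::rpois(1, p$variants_per_gene))
    band <- sample(names(p$af_mix), m, replace = TRUE, prob = p$af_mix)
    af <- vapply(band, function(b) {
      r <- p$af_ranges[[b]]
      exp(stats::runif(1, log(r[1]), log(r[2])))
    }, numeric(1))
    comp <- sample(names(p$cadd_mix), m, replace = TRUE, prob = p$cadd_mix)
    cadd <- numeric(m)
    cadd[comp == "benign"] <- .rtruncnorm(sum(comp == "benign"),
                                          p$cadd_benign[1], p$cadd_benign[2],
                                          0, 40)
    cadd[comp == "damaging"] <- .rtruncnorm(sum(comp == "damaging"),
                                            p$cadd_damaging[1],
                                            p$cadd_damaging[2], 0, 40)
    G <- matrix(stats::rbinom(n * m, 2, rep(af, each = n)), nrow = n)
    observed <- colSums(G) > 0
    if (!any(observed)) next
    G <- G[, observed, drop = FALSE]
    af <- af[observed]; cadd <- cadd[observed]; m <- sum(observed)
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    ann_list[[g]] <- data.frame(
      chrom = "1", pos = pos_base + 10L * seq_len(m),
      ref = ref, alt = alt, gene = g,
      gnomad_ac = round(af * p$an_nominal),
      gnomad_an = ifelse(stats::runif(m) < p$frac_uncovered, NA_real_,
                         p$an_nominal),
      gnomad_hom = round(af^2 * p$an_nominal / 2),
      cadd_phred = cadd,
      filter_status = ifelse(stats::runif(m) < p$frac_nonpass,
                             "LowQual", "PASS"),
      coding_distance = ifelse(stats::runif(m) < p$frac_noncoding,
                               sample(6:500, m, replace = TRUE), 0L),
      simulated_af = af,
      planted = FALSE,
      stringsAsFactors = FALSE
    )
    geno_list[[g]] <- G
    pos_base <- pos_base + 10L * m + 10000L
  }

  # realise the planted associations exactly
  planted_carriers <- list()
  for (pl in p$planted) {
    g <- pl$gene
    nc <- pl$n_causal_variants
    cadd <- stats::runif(nc, pl$cadd_range[1], pl$cadd_range[2])
    ref <- sample(bases, nc, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    causal_ann <- data.frame(
      chrom = "1", pos = pos_base + 10L * seq_len(nc),
      ref = ref, alt = alt, gene = g,
      gnomad_ac = pmax(1, round(pl$causal_af * p$an_nominal)),
      gnomad_an = p$an_nominal,
      gnomad_hom = 0,  # ultra-rare convention: recessive GF is exactly 0
      cadd_phred = cadd,
      filter_status = "PASS", coding_distance = 0L,
      simulated_af = pl$causal_af, planted = TRUE,
      stringsAsFactors = FALSE
    )
    pos_base <- pos_base + 10L * nc + 10000L
    carriers <- sample.int(n, pl$n_carriers_in_cases)
    Gc <- matrix(0L, nrow = n, ncol = nc)
    if (pl$moi == "dominant") {
      v <- rep_len(seq_len(nc), length(carriers))
      Gc[cbind(carriers, v)] <- 1L
    } else {
      hom <- stats::runif(length(carriers)) < pl$hom_fraction
      v1 <- rep_len(seq_len(nc), length(carriers))
      Gc[cbind(carriers[hom], v1[hom])] <- 2L
      het <- carriers[!hom]
      v1h <- v1[!hom]
      v2h <- (v1h %% nc) + 1L  # a second, distinct causal variant
      Gc[cbind(het, v1h)] <- 1L
      Gc[cbind(het, v2h)] <- 1L
    }
    if (!is.null(pl$contaminant_af)) {
      caf <- pl$contaminant_af
      cont_ann <- data.frame(
        chrom = "1", pos = pos_base, ref = "A", alt = "G", gene = g,
        gnomad_ac = round(caf * p$an_nominal), gnomad_an = p$an_nominal,
        gnomad_hom = round(caf^2 * p$an_nominal / 2),
        cadd_phred = pl$contaminant_cadd,
        filter_status = "PASS", coding_distance = 0L,
        simulated_af = caf, planted = TRUE, stringsAsFactors = FALSE
      )
      pos_base <- pos_base + 10010L
      gcont <- stats::rbinom(n, 2, caf)
      causal_ann <- rbind(causal_ann, cont_ann)
      Gc <- cbind(Gc, gcont)  # case enrichment applied after term assignment
    }
    ann_list[[g]] <- rbind(ann_list[[g]], causal_ann)
    geno_list[[g]] <- cbind(geno_list[[g]], Gc)
    planted_carriers[[paste(g, pl$term_id, sep = "/")]] <-
      patient_ids[sort(carriers)]
  }

  ann <- do.call(rbind, ann_list)
  ann$variant_key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  G <- do.call(cbind, geno_list)
  colnames(G) <- ann$variant_key
  rownames(G) <- patient_ids

  # phenotype assignment: background terms (excluding planted closures), then
  # penetrance / phenocopy for each plant
  excluded <- unique(unlist(lapply(p$planted, function(pl) {
    hpo_descendants(ont, pl$term_id)
  })))
  pool <- setdiff(ont$ids[-1], excluded)
  k <- sample(seq(p$terms_per_patient[1], p$terms_per_patient[2]),
              n, replace = TRUE)
  hpo <- lapply(k, function(ki) sample(pool, min(ki, length(pool))))
  case_of_plant <- list()
  for (pl in p$planted) {
    key <- paste(pl$gene, pl$term_id, sep = "/")
    is_carrier <- patient_ids %in% planted_carriers[[key]]
    gets_term <- ifelse(is_carrier,
                        stats::runif(n) < pl$penetrance,
                        stats::runif(n) < pl$phenocopy_rate)
    hpo[gets_term] <- lapply(hpo[gets_term], function(tt)
      unique(c(tt, pl$term_id)))
    case_of_plant[[key]] <- gets_term
  }
  patients <- data.frame(patient_id = patient_ids, hpo = I(hpo),
                         stringsAsFactors = FALSE)

  # contaminant case enrichment (needs the term assignment above)
  for (pl in p$planted) {
    if (is.null(pl$contaminant_af)) next
    key <- paste(pl$gene, pl$term_id, sep = "/")
    ckey <- ann$variant_key[ann$gene == pl$gene & ann$planted &
                              ann$simulated_af == pl$contaminant_af]
    is_case <- case_of_plant[[key]]
    enrich <- is_case & stats::runif(n) < pl$contaminant_case_rate
    G[enrich, ckey[length(ckey)]] <- pmax(G[enrich, ckey[length(ckey)]], 1L)
  }

  # per-variant missingness; planted carrier calls are never masked
  miss_rate <- stats::runif(ncol(G), p$missing_rate_range[1],
                            p$missing_rate_range[2])
  mask <- matrix(stats::runif(length(G)) < rep(miss_rate, each = n),
                 nrow = n)
  mask[G > 0 & matrix(ann$planted, nrow = n, ncol = ncol(G),
                      byrow = TRUE)] <- FALSE
  G[mask] <- NA_integer_
  # masking can silence a variant's only carriers; a joint call set would
  # not contain such a site, so drop it
  live <- colSums(G > 0, na.rm = TRUE) > 0
  G <- G[, live, drop = FALSE]
  ann <- ann[live, , drop = FALSE]

  truth <- if (length(p$planted)) {
    data.frame(gene = vapply(p$planted, `[[`, character(1), "gene"),
               hpo_id = vapply(p$planted, `[[`, character(1), "term_id"),
               moi = vapply(p$planted, `[[`, character(1), "moi"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), hpo_id = character(0),
               moi = character(0), stringsAsFactors = FALSE)
  }

  structure(list(cohort = cohort_data(patients, G, ann),
                 ontology = ont, truth = truth,
                 planted_carriers = planted_carriers, params = p),
            class = "genon_simulation")
}

#' @export
print.genon_simulation <- function(x, ...) {
  cat(sprintf("<genon_simulation> seed %s: %d patients, %d variants, %d genes, %d planted association(s)\n",
              format(x$params$seed), nrow(x$cohort$patients),
              ncol(x$cohort$genotypes), length(x$cohort$gene_index),
              nrow(x$truth)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the dialects the package readers accept, plus a manifest
#' JSON recording the parameters and seed for reproducibility.
#'
#' @param sim A `genon_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$cohort$genotypes, sim$cohort$annotations,
            file.path(dir, "cohort.vcf"))
  write_annotations(sim$cohort$annotations, file.path(dir, "annotations.tsv"))
  write_phenotypes(sim$cohort$patients, file.path(dir, "phenotypes.tsv"))
  write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE)
  manifest <- list(
    generator = "phenogenon::simulate_cohort",
    version = as.character(utils::packageVersion("phenogenon")),
    seed = sim$params$seed,
    params = sim$params[setdiff(names(sim$params), "planted")],
    planted = lapply(sim$params$planted, function(pl) unclass(pl))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
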