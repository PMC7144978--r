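# Per-gene, per-MOI scoring of every term at once. Pmat is the patient x term
# logical case matrix; gc is the .gene_cells() result. Returns per-term
# vectors. Cell occupancy does not depend on the term, so the Fisher tests
# vectorise across the cells x terms grid.
.score_terms_for_gene <- function(gc, Pmat, config) {
  n_terms <- ncol(Pmat)
  n_pat <- nrow(Pmat)
  zero <- rep(0, n_terms)
  out <- list(hgf = zero, sr = zero, m = zero, np = rep(0L, n_terms),
              fisher_mlp = zero, k_rare = rep(0L, n_terms))
  cells <- gc$cells
  if (nrow(cells) == 0) return(out)

  n_cases_t <- colSums(Pmat)
  A <- t(vapply(gc$carriers, function(ix) colSums(Pmat[ix, , drop = FALSE]),
                numeric(n_terms)))
  A <- matrix(A, nrow = nrow(cells))  # guard the 1-term / 1-cell collapses
  tot <- lengths(gc$carriers)
  TOT <- matrix(tot, nrow(cells), n_terms)
  NCASE <- matrix(n_cases_t, nrow(cells), n_terms, byrow = TRUE)
  lp <- stats::phyper(A - 1, TOT, n_pat - TOT, NCASE,
                      lower.tail = FALSE, log.p = TRUE)
  lp <- matrix(lp, nrow(cells), n_terms)
  z <- matrix(.z_from_lp(lp, config), nrow(cells), n_terms)
  mlp <- -lp

  rare <- cells$is_rare
  w <- config$weights[cells$cadd_row + 1L]
  use <- if (config$stouffer_cells == "rare") rare else rep(TRUE, nrow(cells))
  k <- sum(use)
  if (k > 0) {
    sumwz <- colSums(w[use] * z[use, , drop = FALSE])
    denom <- switch(config$stouffer_denominator,
                    k_rare = k,
                    sqrt_k_rare = sqrt(k),
                    sqrt_sum_w2 = sqrt(sum(w[use]^2)))
    out$hgf <- -stats::pnorm(sumwz / denom, lower.tail = FALSE, log.p = TRUE)
  }
  num <- colSums(mlp[rare, , drop = FALSE])
  den <- if (config$sr_denominator == "all") {
    colSums(mlp)
  } else {
    colSums(mlp[!rare, , drop = FALSE])
  }
  out$sr <- ifelse(den > 0, num / den, 0)
  out$m <- out$hgf * out$sr
  if (any(rare)) {
    out$fisher_mlp <- -stats::pchisq(2 * num, df = 2 * sum(rare),
                                     lower.tail = FALSE, log.p = TRUE)
    rare_union <- sort(unique(unlist(gc$carriers[rare])))
    out$np <- as.integer(colSums(Pmat[rare_union, , drop = FALSE]))
  }
  out$k_rare <- rep(sum(rare), n_terms)
  out
}

#' Number of case patients carrying qualifying rare variants
#'
#' NP for a gene-term-MOI triple: the count of case patients (term or any
#' descendant) who carry at least one rare-column bin of the gene under the
#' MOI's carrier rule (dominant carriage, or the recessive
#' biallelic / compound-het rule). Used as the sample-size statistic gating
#' the screen.
#'
#' @param cohort A filtered [cohort_data()].
#' @param ontology An `hpo_ontology`.
#' @param gene Gene symbol.
#' @param term_id HPO term id (or several; conjunction).
#' @param moi `"dominant"` or `"recessive"`.
#' @param config A [genon_config()].
#' @return Integer NP, never exceeding the number of cases.
#' @export
count_np <- function(cohort, ontology, gene, term_id,
                     moi = c("dominant", "recessive"),
                     config = genon_config()) {
  moi <- match.arg(moi)
  part <- split_cases(ontology, cohort$patients, term_id)
  gc <- .gene_cells(cohort, gene, moi, config)
  if (nrow(gc$cells) == 0) return(0L)
  rare <- which(gc$cells$is_rare)
  if (length(rare) == 0) return(0L)
  carriers <- unique(unlist(gc$carriers[rare]))
  sum(cohort$patients$patient_id[carriers] %in% part$cases)
}

#' Score one gene-term pair under both modes of inheritance
#'
#' Builds the dominant and recessive heatmaps, computes HGF, SR and M for
#' both branches, counts NP, and calls the mode of inheritance from the M
#' scores. A gene with no scorable bins under a branch gets all-zero scores
#' for that branch; if both branches are empty the prediction is
#' `"undetermined"`.
#'
#' @inheritParams count_np
#' @return Object of class `genon_result`: list with `gene`, `term_id`,
#'   `n_cases`, `np_dom`, `np_rec`, `hgf_dom`, `hgf_rec`, `sr_dom`, `sr_rec`,
#'   `m_dom`, `m_rec`, `predicted_moi`, and the two `genon_heatmap`s
#'   (`heatmap_dom`, `heatmap_rec`).
#' @export
score_pair <- function(cohort, ontology, gene, term_id,
                       config = genon_config()) {
  branch <- function(moi) {
    hm <- build_heatmap(cohort, ontology, gene, term_id, moi, config)
    if (nrow(hm$cells) == 0 || hm$k_rare == 0) {
      return(list(hm = hm, hgf = 0, sr = 0, m = 0))
    }
    z <- scaled_stouffer_z(hm, config)
    h <- hgf(z)
    s <- signal_ratio(hm, config)
    list(hm = hm, hgf = h, sr = s, m = m_score(h, s))
  }
  d <- branch("dominant")
  r <- branch("recessive")
  res <- list(
    gene = gene, term_id = paste(term_id, collapse = "+"),
    n_cases = d$hm$n_cases,
    np_dom = count_np(cohort, ontology, gene, term_id, "dominant", config),
    np_rec = count_np(cohort, ontology, gene, term_id, "recessive", config),
    hgf_dom = d$hgf, hgf_rec = r$hgf,
    sr_dom = d$sr, sr_rec = r$sr,
    m_dom = d$m, m_rec = r$m,
    predicted_moi = predict_moi(d$m, r$m),
    heatmap_dom = d$hm, heatmap_rec = r$hm
  )
  class(res) <- "genon_result"
  res
}

#' @export
print.genon_result <- function(x, ...) {
  cat(sprintf("<genon_result> %s / %s: HGF dom %.3f rec %.3f, M dom %.3f rec %.3f -> %s (NP %d/%d, %d cases)\n",
              x$gene, x$term_id, x$hgf_dom, x$hgf_rec, x$m_dom, x$m_rec,
              x$predicted_moi, x$np_dom, x$np_rec, x$n_cases))
  invisible(x)
}

#' Screen every gene-term pair of a cohort
#'
#' Runs the full scoring pipeline over all genes and terms, keeping the pairs
#' whose NP (under the predicted mode of inheritance; the larger NP on a tie)
#' reaches `config$np_cutoff`, and ranks them by HGF (the larger branch)
#' descending, ties broken lexicographically by gene then term.
#'
#' @param cohort A filtered [cohort_data()].
#' @param ontology An `hpo_ontology`.
#' @param config A [genon_config()]; `np_cutoff` and `np_source` control the
#'   gating.
#' @param terms Optional allow-list: character vector of term ids, or a list
#'   whose elements may be multi-id character vectors (conjunction queries:
#'   cases must carry all listed terms). Default: every ontology term with at
#'   least one case.
#' @param genes Optional gene allow-list.
#' @param comparators When `TRUE`, also computes the benchmark comparator
#'   columns: Fisher's-method `-ln p` for both branches and the
#'   allele-frequency-for-recessive branch (`af_*` columns), as required by
#'   [genon_benchmark()].
#' @param keep_all Keep pairs failing the NP cutoff (used when sweeping
#'   cutoffs downstream).
#' @return `data.frame` of class `genon_screen`, one row per evaluated pair.
#' @export
screen_cohort <- function(cohort, ontology, config = genon_config(),
                          terms = NULL, genes = NULL, comparators = FALSE,
                          keep_all = FALSE) {
  if (is.null(terms)) terms <- as.list(ontology$ids)
  if (!is.list(terms)) terms <- as.list(terms)
  labels <- vapply(terms, paste, character(1), collapse = "+")

  # patient x term case matrix (conjunction = row-wise AND)
  single <- unique(unlist(terms))
  cm <- .case_matrix(ontology, cohort$patients, single)
  Pmat <- vapply(terms, function(tt) {
    apply(matrix(cm[tt, , drop = FALSE], ncol = ncol(cm)), 2, all)
  }, logical(ncol(cm)))
  colnames(Pmat) <- labels
  has_case <- colSums(Pmat) >= 1
  Pmat <- Pmat[, has_case, drop = FALSE]
  labels <- labels[has_case]
  if (length(labels) == 0) {
    warning("no term with at least one case")
    return(.empty_screen())
  }

  if (is.null(genes)) genes <- sort(names(cohort$gene_index))
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    sd_ <- .score_terms_for_gene(.gene_cells(cohort, g, "dominant", config),
                                 Pmat, config)
    sr_ <- .score_terms_for_gene(.gene_cells(cohort, g, "recessive", config),
                                 Pmat, config)
    df <- data.frame(
      gene = g, term_id = labels, n_cases = as.integer(colSums(Pmat)),
      np_dom = sd_$np, np_rec = sr_$np,
      hgf_dom = sd_$hgf, hgf_rec = sr_$hgf,
      sr_dom = sd_$sr, sr_rec = sr_$sr,
      m_dom = sd_$m, m_rec = sr_$m,
      fisher_mlp_dom = sd_$fisher_mlp, fisher_mlp_rec = sr_$fisher_mlp,
      stringsAsFactors = FALSE
    )
    if (comparators) {
      af_cfg <- config
      af_cfg$gf_convention <- "allele_frequency_for_recessive"
      sa_ <- .score_terms_for_gene(
        .gene_cells(cohort, g, "recessive", af_cfg), Pmat, af_cfg)
      df$af_hgf_rec <- sa_$hgf
      df$af_sr_rec <- sa_$sr
      df$af_m_rec <- sa_$m
      df$af_np_rec <- sa_$np
      df$af_fisher_mlp_rec <- sa_$fisher_mlp
    }
    rows[[gi]] <- df
  }
  res <- do.call(rbind, rows)
  res$predicted_moi <- predict_moi(res$m_dom, res$m_rec)
  res$hgf <- pmax(res$hgf_dom, res$hgf_rec)
  res$term_name <- vapply(strsplit(res$term_id, "+", fixed = TRUE),
                          function(tt) {
                            paste(ontology$name[vapply(tt, resolve_term,
                                                       character(1),
                                                       ontology = ontology)],
                                  collapse = "+")
                          }, character(1))
  np_sel <- ifelse(res$predicted_moi == "dominant", res$np_dom,
                   ifelse(res$predicted_moi == "recessive", res$np_rec,
                          pmax(res$np_dom, res$np_rec)))
  if (config$np_source == "n_cases") np_sel <- res$n_cases
  res$np <- np_sel
  if (!keep_all) {
    res <- res[np_sel >= config$np_cutoff, , drop = FALSE]
    if (nrow(res) == 0) {
      warning("no gene-term pair reaches np_cutoff = ", config$np_cutoff)
    }
  }
  res <- res[order(-res$hgf, res$gene, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("genon_screen", "data.frame")
  res
}

.empty_screen <- function() {
  res <- data.frame(gene = character(0), term_id = character(0),
                    n_cases = integer(0), np_dom = integer(0),
                    np_rec = integer(0), hgf_dom = numeric(0),
                    hgf_rec = numeric(0), sr_dom = numeric(0),
                    sr_rec = numeric(0), m_dom = numeric(0),
                    m_rec = numeric(0), fisher_mlp_dom = numeric(0),
                    fisher_mlp_rec = numeric(0),
                    predicted_moi = character(0), hgf = numeric(0),
                    term_name = character(0), np = integer(0))
  class(res) <- c("genon_screen", "data.frame")
  res
}

#' Write ranked screen results as TSV
#'
#' Column order follows the results contract: gene, term_id, term_name,
#' n_cases, np_dom, np_rec, hgf_dom, hgf_rec, sr_dom, sr_rec, m_dom, m_rec,
#' predicted_moi (comparator columns, when present, follow).
#'
#' @param results A `genon_screen` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen <- function(results, path) {
  lead <- c("gene", "term_id", "term_name", "n_cases", "np_dom", "np_rec",
            "hgf_dom", "hgf_rec", "sr_dom", "sr_rec", "m_dom", "m_rec",
            "predicted_moi")
  rest <- setdiff(names(results), lead)
  data.table::fwrite(results[c(lead, rest)], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Select a gene's positive phenotype terms
#'
#' Given the per-term HGF scores of one gene, returns the terms scoring at
#' least `sd_multiplier` sample standard deviations above the mean. With
#' fewer than two scored terms the spread is undefined and the selection is
#' empty (with a warning). When all scores are equal (s = 0) every term
#' passes the threshold; this usually signals too few terms and is flagged.
#'
#' @param hgf_values Named numeric vector: term id -> HGF.
#' @param config A [genon_config()] (`sd_multiplier`).
#' @return Character vector of selected term ids.
#' @examples
#' select_positive_terms(c(a = 2, b = 2, c = 2, d = 8))  # "d"
#' @export
select_positive_terms <- function(hgf_values, config = genon_config()) {
  if (length(hgf_values) < 2) {
    warning("fewer than two scored terms; positive-term selection undefined")
    return(character(0))
  }
  s <- stats::sd(hgf_values)
  if (s == 0) {
    warning("zero spread in HGF scores; every term passes the threshold")
  }
  thr <- mean(hgf_values) + config$sd_multiplier * s
  names(hgf_values)[hgf_values >= thr]
}
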