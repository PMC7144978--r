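#' Read a truth-set table
#'
#' TSV with header columns `gene`, `hpo_id`, `moi` (dominant / recessive /
#' x-linked); one row per known gene-phenotype-MOI relationship.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with those three columns.
#' @export
read_truth <- function(path) {
  tr <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  miss <- setdiff(c("gene", "hpo_id", "moi"), names(tr))
  if (length(miss)) {
    stop("truth table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tr[c("gene", "hpo_id")])) {
    stop("duplicate (gene, hpo_id) in truth table")
  }
  tr
}

# does (gene, term) match a truth record? Ontology-aware matching accepts the
# truth term itself or any ancestor/descendant of it; returns the matched
# truth MOI or NA. Conjunction labels ("a+b") match if any component does.
.truth_match <- function(gene, term_label, truth, ontology, config) {
  rows <- truth[truth$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0) return(NA_character_)
  terms <- strsplit(term_label, "+", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(rows))) {
    tt <- rows$hpo_id[i]
    if (any(terms == tt)) return(rows$moi[i])
    if (config$truth_matching == "ontology") {
      for (t in terms) {
        t_res <- resolve_term(ontology, t, error = FALSE)
        tt_res <- resolve_term(ontology, tt, error = FALSE)
        if (is.na(t_res) || is.na(tt_res)) next
        if (tt_res %in% hpo_descendants(ontology, t_res) ||
            t_res %in% hpo_descendants(ontology, tt_res)) {
          return(rows$moi[i])
        }
      }
    }
  }
  NA_character_
}

# model-specific view of a screen row set: predicted MOI, the selection
# statistic (the model's HGF analogue under that MOI), and the NP gate
.model_view <- function(results, model) {
  pick <- function(moi, dom, rec) {
    ifelse(moi == "dominant", dom, ifelse(moi == "recessive", rec,
                                          pmax(dom, rec)))
  }
  switch(model,
    phenogenon = {
      moi <- predict_moi(results$m_dom, results$m_rec)
      list(moi = moi,
           stat = pick(moi, results$hgf_dom, results$hgf_rec),
           np = pick(moi, results$np_dom, results$np_rec))
    },
    fisher_method = {
      mf_dom <- results$fisher_mlp_dom * results$sr_dom
      mf_rec <- results$fisher_mlp_rec * results$sr_rec
      moi <- predict_moi(mf_dom, mf_rec)
      list(moi = moi,
           stat = pick(moi, results$fisher_mlp_dom, results$fisher_mlp_rec),
           np = pick(moi, results$np_dom, results$np_rec))
    },
    hgf_only = {
      moi <- hgf_only_moi(results$hgf_dom, results$hgf_rec)
      list(moi = moi,
           stat = pick(moi, results$hgf_dom, results$hgf_rec),
           np = pick(moi, results$np_dom, results$np_rec))
    },
    recessive_af = {
      if (is.null(results$af_m_rec)) {
        stop("recessive_af comparator needs screen_cohort(comparators = TRUE)")
      }
      moi <- predict_moi(results$m_dom, results$af_m_rec)
      list(moi = moi,
           stat = pick(moi, results$hgf_dom, results$af_hgf_rec),
           np = pick(moi, results$np_dom, results$af_np_rec))
    },
    stop("unknown model: ", model)
  )
}

#' Benchmark screen results against a truth set
#'
#' Reproduces the two benchmarking curves for four prediction models
#' (`phenogenon`, `fisher_method`, `hgf_only`, `recessive_af`), all evaluated
#' on identical pair sets:
#'
#' * HPO-selection error versus NP cutoff: at each cutoff, genes with at
#'   least two pairs passing the model's NP gate have their positive terms
#'   selected by the mean-plus-SD rule ([select_positive_terms()]) on the
#'   model's score; the error rate is the fraction of positive terms not
#'   supported by the truth set (a precision complement). Term matching is
#'   ontology-aware by default (a term matches a truth term that is identical
#'   or an ancestor/descendant of it).
#' * MOI error versus HGF cutoff: among truth-supported pairs whose model
#'   score exceeds the cutoff, the fraction with a wrong MOI call
#'   (`undetermined` counts as wrong; x-linked truth makes any dominant or
#'   recessive call wrong).
#'
#' Cutoffs with no evaluable pairs get `NA`, not 0.
#'
#' @param results A `genon_screen` data frame from
#'   [screen_cohort()] (with `comparators = TRUE`, typically `keep_all =
#'   TRUE` so cutoffs can be swept here).
#' @param truth Truth `data.frame` ([read_truth()]).
#' @param ontology An `hpo_ontology` (for term matching).
#' @param np_cutoffs Integer vector of NP cutoffs for the HPO curve.
#' @param hgf_cutoffs Numeric vector of HGF cutoffs for the MOI curve.
#' @param config A [genon_config()].
#' @param models Character vector of model names to evaluate.
#' @return Object of class `genon_benchmark`: list of two data frames,
#'   `hpo` (`cutoff, model, error_rate, n_positive, n_evaluated`) and
#'   `moi` (`cutoff, model, error_rate, n_predicted`).
#' @export
genon_benchmark <- function(results, truth, ontology,
                            np_cutoffs = c(5, 10, 20, 40, 60),
                            hgf_cutoffs = c(0, 1, 2, 3, 5),
                            config = genon_config(),
                            models = c("phenogenon", "fisher_method",
                                       "hgf_only", "recessive_af")) {
  if (!any(results$gene %in% truth$gene)) {
    warning("truth set and results share no genes; error rates will be absent or 1")
  }
  # truth MOI (or NA) per result row, shared by every model
  match_moi <- mapply(.truth_match, results$gene, results$term_id,
                      MoreArgs = list(truth = truth, ontology = ontology,
                                      config = config))
  hpo_rows <- list()
  moi_rows <- list()
  for (model in models) {
    mv <- .model_view(results, model)
    for (cut in np_cutoffs) {
      keep <- mv$np >= cut
      n_eval <- sum(keep)
      pos_true <- logical(0)
      if (n_eval > 0) {
        sub <- which(keep)
        for (g in unique(results$gene[sub])) {
          gi <- sub[results$gene[sub] == g]
          if (length(gi) < 2) next
          hg <- mv$stat[gi]
          names(hg) <- results$term_id[gi]
          sel <- suppressWarnings(select_positive_terms(hg, config))
          if (length(sel)) {
            pos_true <- c(pos_true, !is.na(match_moi[gi][names(hg) %in% sel]))
          }
        }
      }
      hpo_rows[[length(hpo_rows) + 1L]] <- data.frame(
        cutoff = cut, model = model,
        error_rate = if (length(pos_true)) mean(!pos_true) else NA_real_,
        n_positive = length(pos_true), n_evaluated = n_eval)
    }
    in_truth <- !is.na(match_moi)
    for (cut in hgf_cutoffs) {
      keep <- in_truth & mv$stat > cut
      n_pred <- sum(keep)
      err <- if (n_pred > 0) {
        truth_moi <- match_moi[keep]
        called <- mv$moi[keep]
        mean(called == "undetermined" | truth_moi == "x-linked" |
               called != truth_moi)
      } else NA_real_
      moi_rows[[length(moi_rows) + 1L]] <- data.frame(
        cutoff = cut, model = model, error_rate = err, n_predicted = n_pred)
    }
  }
  structure(list(hpo = do.call(rbind, hpo_rows),
                 moi = do.call(rbind, moi_rows)),
            class = "genon_benchmark")
}

#' @export
print.genon_benchmark <- function(x, ...) {
  cat("<genon_benchmark>\nHPO-selection error by NP cutoff:\n")
  print(x$hpo, row.names = FALSE)
  cat("MOI error by HGF cutoff:\n")
  print(x$moi, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report (long TSV + JSON)
#'
#' @param report A `genon_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- rbind(
    data.frame(curve = "hpo_error", report$hpo[c("cutoff", "model",
                                                 "error_rate")],
               n = report$hpo$n_evaluated),
    data.frame(curve = "moi_error", report$moi[c("cutoff", "model",
                                                 "error_rate")],
               n = report$moi$n_predicted)
  )
  data.table::fwrite(long, file.path(dir, "benchmark.tsv"), sep = "\t",
                     quote = FALSE, na = "NA")
  jsonlite::write_json(list(hpo = report$hpo, moi = report$moi),
                       file.path(dir, "benchmark.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(dir)
}
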