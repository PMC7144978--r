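#' Analysis configuration
#'
#' Builds the configuration object consumed by the binning, scoring and
#' screening functions. Defaults reproduce the method's canonical settings: CADD bins of
#' height 5, genotype-frequency (GF) bins of width 1/4000 = 0.00025 with the
#' first column (< 0.00025) treated as the rare column, a weighted Stouffer
#' combination over rare bins scaled by the number of non-empty rare bins, and
#' natural-log HGF scores.
#'
#' @param cadd_bin_height Height of a CADD Phred bin (default 5).
#' @param gf_bin_width Width of a GF bin (default 0.00025 = 1/4000).
#' @param rare_threshold GF below which a variant is rare (default equals
#'   `gf_bin_width`, so the rare column is exactly column 0).
#' @param cadd_max CADD scores at or above this clamp into the top row
#'   (default 40, i.e. 8 rows).
#' @param gf_max Variants with GF at or above this are excluded from the grid
#'   (default 0.01).
#' @param weights Per-CADD-row weights, lowest row first; must be
#'   non-negative, non-decreasing and of length `cadd_max / cadd_bin_height`.
#'   The default is a linear ramp 0.2, 0.4, 0.6, 0.8 and then 1.0 for every
#'   row at or above CADD 20, so damaging bins dominate the combined Z.
#' @param p_clip Two-sided clip applied to per-bin p-values before the normal
#'   quantile transform, keeping z finite (default `c(1e-300, 1 - 1e-16)`;
#'   p = 1 maps to z ~ -8.21 rather than -Inf).
#' @param stouffer_denominator Scale for the combined Z: `"k_rare"` (the
#'   canonical scaling; divide by the number of non-empty rare bins),
#'   `"sqrt_k_rare"`, or `"sqrt_sum_w2"` (classical weighted Stouffer).
#' @param stouffer_cells Which cells feed the combined Z: `"rare"` (default,
#'   first GF column only) or `"all"` (sensitivity analysis).
#' @param sr_denominator Denominator of the signal ratio: `"all"` (default;
#'   every non-empty cell, so SR is bounded in \[0, 1\]) or `"nonrare"`
#'   (the literal text reading; unbounded).
#' @param gf_convention `"homozygote"` (default: recessive GF is the estimated
#'   homozygote frequency 2 HOM / AN) or
#'   `"allele_frequency_for_recessive"` (comparator model: AC / AN for both
#'   modes of inheritance).
#' @param np_cutoff Minimum number of case patients carrying qualifying rare
#'   variants for a gene-term pair to be screened (default 60).
#' @param sd_multiplier Multiplier on the per-gene HGF standard deviation when
#'   selecting positive terms (default 1).
#' @param np_source `"np"` (default: rare-carrier case count, per the
#'   benchmark tables) or `"n_cases"` (raw case count) as the sample-size
#'   statistic gating screening.
#' @param truth_matching `"ontology"` (default: a predicted term matches a
#'   truth term if identical or related by ancestry) or `"exact"`.
#' @param seed Optional integer seed recorded in run manifests.
#' @return A list of class `genon_config`.
#' @examples
#' cfg <- genon_config(np_cutoff = 10)
#' cfg$weights
#' @export
genon_config <- function(cadd_bin_height = 5,
                         gf_bin_width = 0.00025,
                         rare_threshold = gf_bin_width,
                         cadd_max = 40,
                         gf_max = 0.01,
                         weights = NULL,
                         p_clip = c(1e-300, 1 - 1e-16),
                         stouffer_denominator = c("k_rare", "sqrt_k_rare",
                                                  "sqrt_sum_w2"),
                         stouffer_cells = c("rare", "all"),
                         sr_denominator = c("all", "nonrare"),
                         gf_convention = c("homozygote",
                                           "allele_frequency_for_recessive"),
                         np_cutoff = 60,
                         sd_multiplier = 1,
                         np_source = c("np", "n_cases"),
                         truth_matching = c("ontology", "exact"),
                         seed = NULL) {
  stopifnot(gf_bin_width > 0, cadd_bin_height > 0, gf_max > 0, cadd_max > 0)
  n_rows <- as.integer(ceiling(cadd_max / cadd_bin_height))
  if (is.null(weights)) {
    ramp <- pmin(0.2 * seq_len(n_rows), 1)
    weights <- ramp
  }
  if (length(weights) != n_rows) {
    stop("`weights` must have one entry per CADD row (", n_rows, ")")
  }
  if (any(weights < 0) || is.unsorted(weights)) {
    stop("`weights` must be non-negative and non-decreasing with CADD row")
  }
  if (length(p_clip) != 2 || p_clip[1] <= 0 || p_clip[2] >= 1 ||
      p_clip[1] >= p_clip[2]) {
    stop("`p_clip` must be c(low, high) with 0 < low < high < 1")
  }
  cfg <- list(
    cadd_bin_height = cadd_bin_height,
    gf_bin_width = gf_bin_width,
    rare_threshold = rare_threshold,
    cadd_max = cadd_max,
    gf_max = gf_max,
    n_cadd_rows = n_rows,
    n_gf_cols = as.integer(ceiling(gf_max / gf_bin_width)),
    weights = as.numeric(weights),
    p_clip = as.numeric(p_clip),
    stouffer_denominator = match.arg(stouffer_denominator),
    stouffer_cells = match.arg(stouffer_cells),
    sr_denominator = match.arg(sr_denominator),
    gf_convention = match.arg(gf_convention),
    np_cutoff = np_cutoff,
    sd_multiplier = sd_multiplier,
    np_source = match.arg(np_source),
    truth_matching = match.arg(truth_matching),
    seed = seed
  )
  class(cfg) <- "genon_config"
  cfg
}

#' @export
print.genon_config <- function(x, ...) {
  cat("<genon_config>\n")
  cat(sprintf("  grid: %d CADD rows (height %g, max %g) x %d GF cols (width %g, max %g)\n",
              x$n_cadd_rows, x$cadd_bin_height, x$cadd_max,
              x$n_gf_cols, x$gf_bin_width, x$gf_max))
  cat(sprintf("  rare GF threshold: %g\n", x$rare_threshold))
  cat(sprintf("  weights: %s\n", paste(x$weights, collapse = ", ")))
  cat(sprintf("  stouffer: cells=%s denominator=%s\n",
              x$stouffer_cells, x$stouffer_denominator))
  cat(sprintf("  SR denominator=%s, GF convention=%s\n",
              x$sr_denominator, x$gf_convention))
  cat(sprintf("  np_cutoff=%g (source=%s), sd_multiplier=%g\n",
              x$np_cutoff, x$np_source, x$sd_multiplier))
  invisible(x)
}

# stage-prefixed progress line on stderr
genon_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
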