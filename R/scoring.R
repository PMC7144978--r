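#' Scaled weighted Stouffer Z over rare bins
#'
#' Combines the per-bin z scores of the rare (first) GF column into one Z:
#' `Z = sum(w_i * z_i) / D`, where `w_i` is the weight of the bin's CADD row
#' and `D` is, by default, `k_rare` -- the number of non-empty rare bins
#' (the canonical scaling; `sqrt(k_rare)` and the classical
#' `sqrt(sum(w_i^2))` are available through the config). An empty heatmap
#' yields `Z = 0` with a warning.
#'
#' @param heatmap A `genon_heatmap` from [build_heatmap()].
#' @param config A [genon_config()].
#' @return The combined Z (scalar).
#' @export
scaled_stouffer_z <- function(heatmap, config = genon_config()) {
  cells <- heatmap$cells
  if (config$stouffer_cells == "rare" && nrow(cells)) {
    cells <- cells[cells$is_rare, , drop = FALSE]
  }
  if (nrow(cells) == 0) {
    warning("empty heatmap: combined Z defined as 0")
    return(0)
  }
  if (max(cells$cadd_row) + 1L > length(config$weights)) {
    stop("weight vector shorter than the occupied CADD rows")
  }
  w <- config$weights[cells$cadd_row + 1L]
  denom <- switch(config$stouffer_denominator,
                  k_rare = nrow(cells),
                  sqrt_k_rare = sqrt(nrow(cells)),
                  sqrt_sum_w2 = sqrt(sum(w^2)))
  sum(w * cells$z) / denom
}

#' HPO goodness-of-fit score from a combined Z
#'
#' `HGF = -ln(1 - Phi(Z))`, evaluated through the log survival function of
#' the standard normal so that large Z (e.g. Z ~ 12, HGF ~ 70) does not
#' underflow. Negative Z gives a small positive HGF.
#'
#' @param z Combined Z (finite numeric vector).
#' @return Non-negative HGF value(s).
#' @examples
#' hgf(0)                       # -ln(0.5)
#' hgf(stats::qnorm(0.95))      # -ln(0.05)
#' @export
hgf <- function(z) {
  stopifnot(all(is.finite(z)))
  -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
}

#' Signal ratio of a heatmap
#'
#' `SR = sum(-ln p_i, rare cells) / sum(-ln p_j, all non-empty cells)`
#' (default denominator; the literal non-rare-only reading is available via
#' `sr_denominator = "nonrare"`). When every p equals 1 the ratio is defined
#' as 0 with a warning. Wrong-MOI profiles shift -ln(p) mass into non-rare
#' columns, so SR down-weights them.
#'
#' @param heatmap A non-empty `genon_heatmap`.
#' @param config A [genon_config()].
#' @return SR, in \[0, 1\] under the default denominator.
#' @export
signal_ratio <- function(heatmap, config = genon_config()) {
  cells <- heatmap$cells
  if (nrow(cells) == 0) stop("signal ratio undefined for an empty heatmap")
  num <- sum(cells$minus_ln_p[cells$is_rare])
  den <- if (config$sr_denominator == "all") {
    sum(cells$minus_ln_p)
  } else {
    sum(cells$minus_ln_p[!cells$is_rare])
  }
  if (den == 0) {
    warning("all bin p-values are 1; SR defined as 0")
    return(0)
  }
  num / den
}

#' M score
#'
#' `M = HGF x SR` for the corresponding MOI branch; the branch with the
#' larger M is the predicted mode of inheritance.
#'
#' @param hgf_value Non-negative HGF.
#' @param sr Signal ratio.
#' @return The M score.
#' @export
m_score <- function(hgf_value, sr) {
  stopifnot(all(hgf_value >= 0))
  hgf_value * sr
}

#' Predict mode of inheritance from M scores
#'
#' @param m_dom,m_rec M scores of the dominant and recessive branches.
#' @return `"dominant"`, `"recessive"`, or `"undetermined"` on an exact tie.
#' @export
predict_moi <- function(m_dom, m_rec) {
  ifelse(m_dom > m_rec, "dominant",
         ifelse(m_rec > m_dom, "recessive", "undetermined"))
}

#' HGF-only mode-of-inheritance comparator
#'
#' Benchmark comparator that ignores the signal ratio and compares the two
#' HGF branches directly.
#'
#' @param hgf_dom,hgf_rec HGF scores of the two branches.
#' @return `"dominant"`, `"recessive"`, or `"undetermined"` on a tie.
#' @export
hgf_only_moi <- function(hgf_dom, hgf_rec) {
  ifelse(hgf_dom > hgf_rec, "dominant",
         ifelse(hgf_rec > hgf_dom, "recessive", "undetermined"))
}

#' Fisher's-method comparator over rare bins
#'
#' Combines the rare-bin p-values with Fisher's method:
#' `X^2 = -2 sum(ln p_i)` referred to a chi-squared distribution with
#' `2 k_rare` degrees of freedom. Unlike the weighted Stouffer combination it
#' cannot favour high-CADD bins. With a single bin it returns the input p
#' exactly.
#'
#' @param heatmap A `genon_heatmap` with at least one rare cell.
#' @return List with `p` (combined upper-tail p), `minus_ln_p`, `statistic`
#'   and `df`.
#' @export
fisher_combine <- function(heatmap) {
  cells <- heatmap$cells
  cells <- cells[cells$is_rare, , drop = FALSE]
  if (nrow(cells) == 0) stop("Fisher's method undefined for an empty heatmap")
  x2 <- 2 * sum(cells$minus_ln_p)
  df <- 2L * nrow(cells)
  lp <- stats::pchisq(x2, df = df, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(lp), minus_ln_p = -lp, statistic = x2, df = df)
}
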