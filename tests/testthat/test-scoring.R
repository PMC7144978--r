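# random synthetic heatmap: cells with random p over random grid positions
rand_heatmap <- function() {
  n <- sample(1:12, 1)
  make_heatmap(p = exp(-stats::rexp(n, rate = 0.3)),
               cadd_row = sample(0:7, n, replace = TRUE),
               gf_col = sample(0:39, n, replace = TRUE) *
                 rbinom(n, 1, 0.6))
}

test_that("scaled Stouffer Z follows the k_rare scaling", {
  cfg <- genon_config()
  # one rare cell, unit weight (row >= 4), denominator k_rare = 1
  hm1 <- make_heatmap(0.05, cadd_row = 6, gf_col = 0)
  expect_equal(scaled_stouffer_z(hm1, cfg), 1.6448536269514722,
               tolerance = 1e-9)  # Phi^-1(0.95)
  # two identical unit-weight rare cells: (z + z) / 2 = z
  hm2 <- make_heatmap(c(0.05, 0.05), cadd_row = c(5, 6), gf_col = c(0, 0))
  expect_equal(scaled_stouffer_z(hm2, cfg), scaled_stouffer_z(hm1, cfg),
               tolerance = 1e-12)
  # non-rare cells do not feed the default combination
  hm3 <- make_heatmap(c(0.05, 1e-10), cadd_row = c(6, 6), gf_col = c(0, 5))
  expect_equal(scaled_stouffer_z(hm3, cfg), scaled_stouffer_z(hm1, cfg))
  # row weights scale the contributions
  hm4 <- make_heatmap(0.05, cadd_row = 0, gf_col = 0)
  expect_equal(scaled_stouffer_z(hm4, cfg),
               0.2 * scaled_stouffer_z(hm1, cfg))
  # empty heatmap
  hm0 <- make_heatmap(numeric(0), integer(0), integer(0))
  expect_warning(z0 <- scaled_stouffer_z(hm0, cfg), "empty")
  expect_identical(z0, 0)
  # alternative denominators
  expect_equal(scaled_stouffer_z(hm2, genon_config(
    stouffer_denominator = "sqrt_k_rare")),
    sqrt(2) * scaled_stouffer_z(hm2, cfg))
  expect_equal(scaled_stouffer_z(hm2, genon_config(
    stouffer_denominator = "sqrt_sum_w2")),
    sqrt(2) * scaled_stouffer_z(hm2, cfg))
})

test_that("HGF is the log survival of Z and never underflows", {
  expect_equal(hgf(0), log(2), tolerance = 1e-12)
  # closed form: single unit-weight rare cell => HGF = -ln p
  for (p in c(0.5, 0.05, 1e-6, 1e-30)) {
    hm <- make_heatmap(p, cadd_row = 6, gf_col = 0)
    expect_equal(hgf(scaled_stouffer_z(hm)), -log(p), tolerance = 1e-9,
                 label = sprintf("p = %g", p))
  }
  # large-Z path: finite, > 60, and close to the Mills-ratio expansion
  expect_true(is.finite(hgf(12)) && hgf(12) > 60)
  expect_equal(hgf(12), -normal_log_sf_mills(12), tolerance = 1e-4)
  # strictly increasing in Z
  zs <- seq(-6, 12, by = 0.5)
  expect_true(all(diff(hgf(zs)) > 0))
})

test_that("signal ratio partitions the -ln p mass", {
  cfg <- genon_config()
  # rare mass 3, non-rare mass 1 -> SR = 0.75
  hm <- make_heatmap(p = exp(-c(3, 1)), cadd_row = c(6, 6), gf_col = c(0, 4))
  expect_equal(signal_ratio(hm, cfg), 0.75, tolerance = 1e-12)
  # all signal rare -> SR = 1
  expect_equal(signal_ratio(make_heatmap(0.05, 6, 0), cfg), 1)
  # every p = 1 -> SR = 0 with warning
  expect_warning(
    sr0 <- signal_ratio(make_heatmap(c(1, 1), c(2, 3), c(0, 4)), cfg), "SR")
  expect_identical(sr0, 0)
  expect_error(signal_ratio(make_heatmap(numeric(0), integer(0),
                                         integer(0)), cfg), "empty")
  # literal non-rare-only denominator reading
  expect_equal(signal_ratio(hm, genon_config(sr_denominator = "nonrare")), 3)
})

test_that("M score and the MOI calls are consistent", {
  expect_equal(m_score(10, 0.8), 8)
  expect_equal(m_score(10, 0), 0)
  expect_equal(m_score(0, 0.8), 0)
  expect_identical(predict_moi(5, 3), "dominant")
  expect_identical(predict_moi(3, 5), "recessive")
  expect_identical(predict_moi(4, 4), "undetermined")
  expect_identical(hgf_only_moi(6, 2), "dominant")
  expect_identical(hgf_only_moi(2, 6), "recessive")
  expect_identical(hgf_only_moi(2, 2), "undetermined")
})

test_that("Fisher's method matches the even-df chi-squared oracle", {
  # identity with one cell
  for (p in c(0.9, 0.05, 1e-8)) {
    fc <- fisher_combine(make_heatmap(p, 6, 0))
    expect_equal(fc$p, p, tolerance = 1e-10, label = sprintf("p = %g", p))
  }
  # two p = 1 cells: X^2 = 0, combined p = 1
  fc1 <- fisher_combine(make_heatmap(c(1, 1), c(5, 6), c(0, 0)))
  expect_equal(fc1$statistic, 0)
  expect_equal(fc1$p, 1)
  # df = 4 case against the closed-form series
  fc2 <- fisher_combine(make_heatmap(c(0.01, 0.5), c(5, 6), c(0, 0)))
  expect_identical(fc2$df, 4L)
  expect_equal(fc2$p,
               chisq_sf_even_oracle(-2 * log(0.01 * 0.5), 4),
               tolerance = 1e-10)
  # non-rare cells are excluded from the combination
  fc3 <- fisher_combine(make_heatmap(c(0.01, 0.5, 1e-9), c(5, 6, 6),
                                     c(0, 0, 7)))
  expect_equal(fc3$p, fc2$p)
})

test_that("randomized heatmaps satisfy the SR/M/MOI algebra", {
  cfg <- genon_config()
  withr::with_seed(4, {
    for (i in 1:400) {
      hm_d <- rand_heatmap()
      hm_r <- rand_heatmap()
      score <- function(hm) {
        if (hm$k_rare == 0) return(c(0, 0, 0))
        h <- hgf(scaled_stouffer_z(hm, cfg))
        s <- suppressWarnings(signal_ratio(hm, cfg))
        c(h, s, m_score(h, s))
      }
      d <- score(hm_d); r <- score(hm_r)
      expect_gte(d[2], 0); expect_lte(d[2], 1)
      expect_equal(d[3], d[1] * d[2], tolerance = 1e-12)
      moi <- predict_moi(d[3], r[3])
      expect_identical(moi,
                       if (d[3] > r[3]) "dominant"
                       else if (r[3] > d[3]) "recessive" else "undetermined")
    }
  })
})

test_that("the recessive-AF convention only rebins the recessive branch", {
  sim <- small_sim(seed = 5)
  cohort <- suppressMessages(filter_variants(sim$cohort))
  ont <- sim$ontology
  cfg <- genon_config()
  cfg_af <- genon_config(gf_convention = "allele_frequency_for_recessive")
  hm_dom <- build_heatmap(cohort, ont, "GENE_PLANT", "HP:0000005",
                          "dominant", cfg)
  hm_dom_af <- build_heatmap(cohort, ont, "GENE_PLANT", "HP:0000005",
                             "dominant", cfg_af)
  expect_identical(hm_dom$cells, hm_dom_af$cells)  # dominant path untouched
  hm_rec <- build_heatmap(cohort, ont, "GENE_PLANT", "HP:0000005",
                          "recessive", cfg)
  hm_rec_af <- build_heatmap(cohort, ont, "GENE_PLANT", "HP:0000005",
                             "recessive", cfg_af)
  # the planted causal alleles (AF 1e-3, HOM 0) are rare under the
  # homozygote-frequency GF but non-rare under the allele-frequency GF
  expect_gt(hm_rec$k_rare, 0)
  expect_true(any(hm_rec_af$cells$gf_col >= 4))
  # switch off -> identical results
  expect_identical(build_heatmap(cohort, ont, "GENE_PLANT", "HP:0000005",
                                 "recessive", genon_config())$cells,
                   hm_rec$cells)
})
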