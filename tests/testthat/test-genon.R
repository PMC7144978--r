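# two-variant gene fixture for carrier-rule tests:
# v = 1:100:A:T (CADD 30, recessive GF 1e-4), u = 1:200:A:T (CADD 32, GF 5e-5)
carrier_fixture <- function(genos) {
  ann <- rbind(make_ann(100, cadd = 30, an = 200000, hom = 10, ac = 100),
               make_ann(200, cadd = 32, an = 200000, hom = 5, ac = 50))
  geno <- do.call(rbind, genos)
  dimnames(geno) <- list(names(genos), ann$variant_key)
  make_cohort(geno, ann,
              setNames(as.list(rep("HP:0000002", length(genos))),
                       names(genos)))
}

test_that("genotype_frequency follows the MOI and the config convention", {
  ann <- make_ann(100, ac = 5, an = 10000, hom = 1)
  expect_equal(genotype_frequency(ann, "dominant"), 5e-4)
  expect_equal(genotype_frequency(ann, "recessive"), 2e-4)
  af_cfg <- genon_config(gf_convention = "allele_frequency_for_recessive")
  expect_equal(genotype_frequency(ann, "recessive", af_cfg), 5e-4)
  expect_error(genotype_frequency(make_ann(1, an = 0), "dominant"),
               "undefined")
})

test_that("assign_bin uses half-open intervals with clamp and cap", {
  cfg <- genon_config()
  expect_identical(assign_bin(0.0001, 22, cfg),
                   data.frame(cadd_row = 4L, gf_col = 0L))
  # exact bin boundary goes to the upper column
  expect_identical(assign_bin(0.00025, 22, cfg)$gf_col, 1L)
  # cap: GF >= gf_max excluded; clamp: CADD >= cadd_max into the top row
  expect_identical(assign_bin(0.02, 22, cfg)$gf_col, NA_integer_)
  expect_identical(assign_bin(0.0001, 45, cfg)$cadd_row, 7L)
  expect_identical(assign_bin(0, 0, cfg),
                   data.frame(cadd_row = 0L, gf_col = 0L))
})

test_that("carrier rules: dominant carriage and recessive second hits", {
  cohort <- carrier_fixture(list(
    P1 = c(1L, 1L),   # het at v + het at u (u: higher CADD, lower GF)
    P2 = c(1L, 0L),   # single het -> not a recessive carrier
    P3 = c(2L, 0L),   # hom-alt -> recessive carrier, dominant carrier
    P4 = c(0L, 1L),   # het at u only
    P5 = c(NA, 1L)))  # missing never qualifies
  v <- "1:100:A:T"; u <- "1:200:A:T"
  expect_setequal(find_carriers(cohort, "G1", v, "dominant"),
                  c("P1", "P2", "P3"))
  # compound het: anchor v accepts u (CADD 32 >= 30, GF 5e-5 <= 1e-4) ...
  expect_setequal(find_carriers(cohort, "G1", v, "recessive"),
                  c("P1", "P3"))
  # ... but anchor u does not accept v (lower CADD, higher GF)
  expect_length(find_carriers(cohort, "G1", u, "recessive"), 0)
  expect_error(find_carriers(cohort, "NOPE", v, "dominant"), "unknown gene")
  expect_error(find_carriers(cohort, "G1", "1:9:A:T", "dominant"),
               "not in gene")
})

test_that("bin_fisher matches the factorial enumeration oracle", {
  expect_equal(bin_fisher(0, 10, 0, 100), 1)
  expect_equal(bin_fisher(10, 10, 0, 100),
               hyper_tail_oracle(10, 10, 0, 100), tolerance = 1e-12)
  expect_equal(bin_fisher(3, 10, 1, 100),
               hyper_tail_oracle(3, 10, 1, 100), tolerance = 1e-12)
  expect_error(bin_fisher(-1, 10, 0, 100), "negative")
  expect_error(bin_fisher(11, 10, 0, 100), "exceeds")

  withr::with_seed(1, {
    for (i in 1:200) {
      n_cases <- sample(1:50, 1); n_controls <- sample(1:50, 1)
      a <- sample(0:n_cases, 1); c <- sample(0:n_controls, 1)
      expect_equal(bin_fisher(a, n_cases, c, n_controls),
                   hyper_tail_oracle(a, n_cases, c, n_controls),
                   tolerance = 1e-12,
                   label = sprintf("table (%d,%d,%d,%d)", a, n_cases, c,
                                   n_controls))
    }
  })
})

test_that("moving a control carrier into the cases never increases p", {
  withr::with_seed(2, {
    for (i in 1:100) {
      n_cases <- sample(2:40, 1); n_controls <- sample(2:80, 1)
      a <- sample(0:(n_cases - 1), 1); c <- sample(1:n_controls, 1)
      p0 <- bin_fisher(a, n_cases, c, n_controls)
      p1 <- bin_fisher(a + 1, n_cases + 1, c - 1, n_controls - 1)
      expect_lte(p1, p0 + 1e-12)
    }
  })
})

test_that("build_heatmap bins carriers and tests each occupied cell", {
  # one rare CADD-30 variant carried by 3 of 10 cases and 1 of 100 controls
  ann <- make_ann(100, cadd = 30, ac = 10, an = 200000, hom = 0)
  ids <- sprintf("P%03d", 1:110)
  geno <- matrix(0L, 110, 1, dimnames = list(ids, ann$variant_key))
  geno[c(1, 2, 3, 15), 1] <- 1L  # P001-P003 cases, P015 control
  terms <- setNames(as.list(rep("HP:0000004", 110)), ids)
  terms[sprintf("P%03d", 1:10)] <- "HP:0000002"  # 10 cases for term A
  cohort <- make_cohort(geno, ann, terms)
  ont <- toy_ontology()
  hm <- build_heatmap(cohort, ont, "G1", "HP:0000002", "dominant")
  expect_identical(nrow(hm$cells), 1L)
  expect_identical(hm$cells$cadd_row, 6L)  # CADD 30 -> [30, 35)
  expect_identical(hm$cells$gf_col, 0L)    # GF 5e-5 -> rare column
  expect_identical(hm$k_rare, 1L)
  expect_identical(c(hm$cells$case_carriers, hm$cells$control_carriers),
                   c(3L, 1L))
  expect_equal(hm$cells$p, hyper_tail_oracle(3, 10, 1, 100),
               tolerance = 1e-12)
  # querying a term with no cases leaves no case carriers: p = 1
  hm_null <- build_heatmap(cohort, ont, "G1", "HP:0000003", "dominant")
  expect_equal(hm_null$cells$p, 1)
  expect_lt(hm_null$cells$z, -8)  # clipped, finite
  # all variants at or above gf_max -> empty heatmap
  ann2 <- make_ann(100, ac = 10000, an = 200000)
  geno2 <- matrix(1L, 110, 1, dimnames = list(ids, ann2$variant_key))
  hm_empty <- build_heatmap(make_cohort(geno2, ann2, terms), ont, "G1",
                            "HP:0000002", "dominant")
  expect_identical(nrow(hm_empty$cells), 0L)
  expect_identical(hm_empty$k_rare, 0L)
})

test_that("heatmap exports are deterministic and re-readable", {
  hm <- make_heatmap(p = c(0.01, 0.5, 1), cadd_row = c(6, 1, 4),
                     gf_col = c(0, 0, 3))
  tab <- export_heatmap(hm, format = "tsv")
  expect_identical(names(tab)[1:2], c("cadd_row_low", "gf_col_low"))
  # row-major order ascending
  expect_identical(order(tab$cadd_row_low, tab$gf_col_low), 1:3)
  f <- tempfile(fileext = ".json")
  export_heatmap(hm, f, format = "json")
  doc <- jsonlite::fromJSON(f)
  expect_identical(doc$k_rare, 2L)
  expect_equal(doc$cells$p, tab$p)
})

test_that("per-bin carrier sets stay within the case/control partition", {
  sim <- small_sim(seed = 9)
  cohort <- suppressMessages(filter_variants(sim$cohort))
  ont <- sim$ontology
  for (moi in c("dominant", "recessive")) {
    hm <- build_heatmap(cohort, ont, "GENE_PLANT", "HP:0000005", moi)
    if (nrow(hm$cells) == 0) next
    expect_true(all(hm$cells$case_carriers <= hm$n_cases))
    expect_true(all(hm$cells$control_carriers <= hm$n_controls))
    expect_true(all(hm$cells$case_carriers + hm$cells$control_carriers >= 1))
    expect_identical(hm$k_rare + hm$k_nonrare, nrow(hm$cells))
    expect_identical(hm$cells$is_rare, hm$cells$gf_col == 0L)
  }
})
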