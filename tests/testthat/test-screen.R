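test_that("count_np counts case patients carrying rare bins", {
  # rare recessive gene: 3 biallelic cases, 5 single-het cases
  ann <- rbind(make_ann(100, cadd = 28, ac = 2, an = 200000, hom = 0),
               make_ann(200, cadd = 30, ac = 2, an = 200000, hom = 0))
  ids <- sprintf("P%02d", 1:30)
  geno <- matrix(0L, 30, 2, dimnames = list(ids, ann$variant_key))
  geno[1:3, ] <- 1L          # compound het
  geno[4:8, 1] <- 1L         # single het
  terms <- setNames(as.list(rep("HP:0000004", 30)), ids)
  terms[ids[1:10]] <- "HP:0000002"
  cohort <- make_cohort(geno, ann, terms)
  ont <- toy_ontology()
  expect_identical(count_np(cohort, ont, "G1", "HP:0000002", "recessive"), 3L)
  expect_identical(count_np(cohort, ont, "G1", "HP:0000002", "dominant"), 8L)
  # no case carries anything for the sibling branch that excludes carriers
  expect_identical(count_np(cohort, ont, "G1", "HP:0000003", "dominant"), 0L)
  expect_lte(count_np(cohort, ont, "G1", "HP:0000001", "dominant"), 30L)
})

test_that("score_pair agrees with the vectorised screen", {
  sim <- small_sim(seed = 21)
  cohort <- suppressMessages(filter_variants(sim$cohort))
  cfg <- genon_config(np_cutoff = 0)
  res <- suppressWarnings(screen_cohort(cohort, sim$ontology, cfg,
                                        keep_all = TRUE))
  for (i in c(1, 5, 25)) {
    sp <- score_pair(cohort, sim$ontology, res$gene[i], res$term_id[i], cfg)
    expect_equal(sp$hgf_dom, res$hgf_dom[i], tolerance = 1e-10)
    expect_equal(sp$hgf_rec, res$hgf_rec[i], tolerance = 1e-10)
    expect_equal(sp$sr_dom, res$sr_dom[i], tolerance = 1e-10)
    expect_equal(sp$m_rec, res$m_rec[i], tolerance = 1e-10)
    expect_identical(sp$predicted_moi, res$predicted_moi[i])
    expect_identical(sp$np_dom, as.integer(res$np_dom[i]))
    expect_identical(sp$np_rec, as.integer(res$np_rec[i]))
  }
})

test_that("screening recovers the planted association end to end", {
  sim <- small_sim(seed = 21)
  cohort <- suppressMessages(filter_variants(sim$cohort))
  cfg <- genon_config(np_cutoff = 5)
  res <- suppressWarnings(screen_cohort(cohort, sim$ontology, cfg))
  expect_identical(res$gene[1], "GENE_PLANT")
  expect_identical(res$term_id[1], "HP:0000005")
  expect_identical(res$predicted_moi[1], "recessive")
  # ranking is by max-branch HGF, non-increasing
  expect_true(all(diff(res$hgf) <= 1e-12))
  # gene whose variants all fall off the grid scores zero / undetermined
  ann0 <- make_ann(100, ac = 10000, an = 200000, hom = 2000)  # GF >= gf_max
  ids <- sprintf("Q%02d", 1:20)
  geno0 <- matrix(1L, 20, 1, dimnames = list(ids, ann0$variant_key))
  cohort0 <- make_cohort(geno0, ann0, setNames(
    as.list(rep(c("HP:0000002", "HP:0000004"), 10)), ids))
  sp0 <- score_pair(cohort0, toy_ontology(), "G1", "HP:0000002")
  expect_identical(c(sp0$hgf_dom, sp0$hgf_rec, sp0$m_dom, sp0$m_rec),
                   c(0, 0, 0, 0))
  expect_identical(sp0$predicted_moi, "undetermined")
})

test_that("term allow-lists and conjunctions restrict the case set", {
  sim <- small_sim(seed = 13)
  cohort <- suppressMessages(filter_variants(sim$cohort))
  ont <- sim$ontology
  cfg <- genon_config(np_cutoff = 0)
  one <- suppressWarnings(screen_cohort(cohort, ont, cfg,
                                        terms = "HP:0000005",
                                        keep_all = TRUE))
  expect_setequal(unique(one$term_id), "HP:0000005")
  conj <- suppressWarnings(screen_cohort(
    cohort, ont, cfg, terms = list(c("HP:0000005", "HP:0000006")),
    genes = "GENE_PLANT", keep_all = TRUE))
  both <- split_cases(ont, cohort$patients, c("HP:0000005", "HP:0000006"))
  a <- split_cases(ont, cohort$patients, "HP:0000005")
  b <- split_cases(ont, cohort$patients, "HP:0000006")
  expect_setequal(both$cases, intersect(a$cases, b$cases))
  expect_identical(conj$n_cases[1], length(both$cases))
  # a cutoff above every NP yields an empty result with a warning
  expect_warning(
    empty <- screen_cohort(cohort, ont, genon_config(np_cutoff = 1000)),
    "np_cutoff")
  expect_identical(nrow(empty), 0L)
})

test_that("select_positive_terms implements the mean + SD rule", {
  # mu = 3.5, s = 3 (sum of squares 27, n - 1 = 3): threshold 6.5
  hgfs <- c(t1 = 2, t2 = 2, t3 = 2, t4 = 8)
  expect_identical(select_positive_terms(hgfs), "t4")
  expect_warning(all_eq <- select_positive_terms(c(a = 3, b = 3, c = 3)),
                 "spread")
  expect_setequal(all_eq, c("a", "b", "c"))
  expect_warning(none <- select_positive_terms(c(a = 3)), "fewer than two")
  expect_length(none, 0)
  # sd_multiplier moves the threshold
  expect_setequal(select_positive_terms(hgfs,
                                        genon_config(sd_multiplier = 0.5)),
                  "t4")
})

test_that("benchmark error rates hit the trivial endpoints", {
  sim <- small_sim(seed = 21)
  cohort <- suppressMessages(filter_variants(sim$cohort))
  cfg <- genon_config(np_cutoff = 0)
  res <- suppressWarnings(screen_cohort(cohort, sim$ontology, cfg,
                                        comparators = TRUE,
                                        keep_all = TRUE))
  # truth = everything predicted: HPO error 0 wherever terms are selected
  all_truth <- data.frame(gene = res$gene, hpo_id = res$term_id,
                          moi = "recessive", stringsAsFactors = FALSE)
  all_truth <- all_truth[!duplicated(all_truth[1:2]), ]
  rep_all <- genon_benchmark(res, all_truth, sim$ontology,
                             np_cutoffs = c(1, 5), hgf_cutoffs = 0,
                             config = cfg)
  expect_true(all(rep_all$hpo$error_rate[rep_all$hpo$n_positive > 0] == 0))
  # empty truth: every positive term is an error
  empty_truth <- data.frame(gene = character(0), hpo_id = character(0),
                            moi = character(0))
  rep_none <- suppressWarnings(
    genon_benchmark(res, empty_truth, sim$ontology, np_cutoffs = c(1, 5),
                    hgf_cutoffs = 0, config = cfg))
  expect_true(all(rep_none$hpo$error_rate[rep_none$hpo$n_positive > 0] == 1))
  # MOI errors counted where predictions exist, NA where none
  expect_true(all(is.na(rep_none$moi$error_rate)))
  # n_evaluated never increases with the cutoff
  for (m in unique(rep_all$hpo$model)) {
    sub <- rep_all$hpo[rep_all$hpo$model == m, ]
    expect_true(all(diff(sub$n_evaluated[order(sub$cutoff)]) <= 0))
  }
  # ontology-aware matching accepts ancestors; exact matching does not
  parent_truth <- data.frame(gene = "GENE_PLANT", hpo_id = "HP:0000002",
                             moi = "recessive", stringsAsFactors = FALSE)
  expect_identical(
    phenogenon:::.truth_match("GENE_PLANT", "HP:0000005", parent_truth,
                              sim$ontology, cfg),
    "recessive")
  expect_true(is.na(
    phenogenon:::.truth_match("GENE_PLANT", "HP:0000005", parent_truth,
                              sim$ontology,
                              genon_config(truth_matching = "exact"))))
})

test_that("screening is deterministic for fixed inputs", {
  sim1 <- small_sim(seed = 33)
  sim2 <- small_sim(seed = 33)
  c1 <- suppressMessages(filter_variants(sim1$cohort))
  c2 <- suppressMessages(filter_variants(sim2$cohort))
  cfg <- genon_config(np_cutoff = 5)
  r1 <- suppressWarnings(screen_cohort(c1, sim1$ontology, cfg))
  r2 <- suppressWarnings(screen_cohort(c2, sim2$ontology, cfg))
  expect_identical(r1, r2)
})
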