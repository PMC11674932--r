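test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(ms_fraction = 0), "ms_fraction")
  expect_error(cohort_config(ms_fraction = 1.2), "ms_fraction")
  expect_error(cohort_config(conservation_coupling = -2), "coupling")
  expect_error(cohort_config(site_scale_sd = -1), "sd")
  expect_error(cohort_config(n_subjects = 0), "counts")
  expect_error(cohort_config(noise_sd = NaN), "non-finite")
  expect_error(cohort_config(n_subjects = 10, ms_fraction = 0.05),
               "no MS subject")
})

test_that("the same config and seed reproduce the cohort bitwise", {
  cfg <- cohort_config(n_subjects = 12, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$connectomes, b$connectomes)
  expect_identical(a$ground_truth, b$ground_truth)
  # a different seed changes the draw but not the schema
  c <- generate_cohort(cohort_config(n_subjects = 12, seed = 100))
  expect_false(identical(a$records$age, c$records$age))
  expect_identical(names(a$records), names(c$records))
})

test_that("generated connectomes satisfy the matrix invariants", {
  coh <- generate_cohort(cohort_config(n_subjects = 8, seed = 3))
  gt <- coh$ground_truth
  for (id in names(coh$connectomes)) {
    cn <- coh$connectomes[[id]]
    expect_length(validate_connectome(cn), 0)
    # allocation conservation: unordered weight mass equals the streamline
    # budget once the per-center batch scale is divided out
    scale_c <- gt$centers$scale[match(
      coh$records$center[coh$records$id == id], gt$centers$center)]
    total <- sum(cn$weights[upper.tri(cn$weights)]) / scale_c
    expect_lt(abs(total - 10000) / 10000, 0.001)
    # midline regions carry no streamline weight
    m <- cn$hemisphere == "M"
    expect_true(all(cn$weights[m, ] == 0))
  }
  # with batch effects disabled the budget holds exactly as generated
  coh0 <- generate_cohort(cohort_config(n_subjects = 4, seed = 3,
                                        site_shift_sd = 0,
                                        site_scale_sd = 0))
  for (cn in coh0$connectomes)
    expect_lt(abs(sum(cn$weights[upper.tri(cn$weights)]) - 10000) / 10000,
              0.001)
})

test_that("intra-hemispheric subgraphs are connected by construction", {
  coh <- generate_cohort(cohort_config(n_subjects = 4, seed = 21))
  for (cn in coh$connectomes) {
    b <- hemisphere_blocks(cortical_subgraph(normalize_by_length(cn)))
    for (blk in list(b$left, b$right)) {
      spl <- mean_spl(to_distance_graph(blk))
      expect_equal(attr(spl, "n_unreachable"), 0)
    }
  }
})

test_that("subject records follow the instrument ranges and cohort structure", {
  coh <- generate_cohort(cohort_config(n_subjects = 300, seed = 5))
  rec <- coh$records
  ms <- rec$diagnosis == "MS"
  # EDSS on the half-point grid in [0, 10], MS only
  expect_true(all(is.na(rec$edss[!ms])))
  expect_true(all(rec$edss[ms] * 2 == round(rec$edss[ms] * 2)))
  expect_true(all(rec$edss[ms] >= 0 & rec$edss[ms] <= 10))
  # SDMT non-negative integers, MS only
  expect_true(all(rec$sdmt[ms] >= 0))
  expect_true(all(rec$sdmt[ms] == round(rec$sdmt[ms])))
  expect_true(all(is.na(rec$sdmt[!ms])))
  # proportions and scalars
  expect_true(all(rec$gmf > 0 & rec$gmf < 1))
  expect_true(all(rec$wmf > 0 & rec$wmf < 1))
  expect_true(all(rec$lvf >= 0 & rec$lvf < 1))
  expect_true(all(rec$lvf[!ms] == 0))
  expect_true(all(rec$cc_area > 0))
  expect_true(all(rec$sex %in% c(0, 1)))
  expect_true(all(table(rec$center) > 0))
  expect_equal(length(unique(rec$center)), 7)
  # ground truth covers every subject and center
  expect_setequal(coh$ground_truth$subjects$id, rec$id)
  expect_setequal(coh$ground_truth$centers$center, unique(rec$center))
})

test_that("the planted inter/intra coupling is realized in the latents", {
  coh <- generate_cohort(cohort_config(n_subjects = 500, seed = 17,
                                       conservation_coupling = -0.4))
  gt <- coh$ground_truth$subjects
  r <- cor(gt$p_inter_bio, gt$intra_strength)
  expect_gt(r, -0.5)
  expect_lt(r, -0.3)
})

test_that("without a disease effect HC and MS commissural ratios coincide", {
  tstats <- vapply(1:5, function(s) {
    coh <- generate_cohort(cohort_config(
      n_subjects = 300, seed = 1000 + s, disease_effect_inter = 0,
      site_shift_sd = 0, site_scale_sd = 0))
    cr <- quick_commissural(coh)
    ms <- coh$records$diagnosis == "MS"
    unname(t.test(cr[ms], cr[!ms])$statistic)
  }, numeric(1))
  expect_lt(median(abs(tstats)), 2)
  expect_lt(max(abs(tstats)), 4)
})

test_that("site effects create, and only they create, center differences", {
  # with default batch magnitudes the raw commissural ratio separates centers
  coh <- generate_cohort(cohort_config(n_subjects = 300, seed = 23))
  cr <- quick_commissural(coh)
  p_on <- summary(aov(cr ~ factor(coh$records$center)))[[1]][["Pr(>F)"]][1]
  expect_lt(p_on, 0.01)
  # with batch effects off, center is not significant in most draws
  p_off <- vapply(1:6, function(s) {
    coh0 <- generate_cohort(cohort_config(n_subjects = 250, seed = 400 + s,
                                          site_shift_sd = 0,
                                          site_scale_sd = 0))
    cr0 <- quick_commissural(coh0)
    summary(aov(cr0 ~ factor(coh0$records$center)))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_gte(sum(p_off > 0.05), 4)
})

test_that("interhemispheric fibers are longer than intrahemispheric ones", {
  coh <- generate_cohort(cohort_config(n_subjects = 6, seed = 31))
  for (cn in coh$connectomes) {
    hemi <- cn$hemisphere
    inter <- outer(hemi, hemi, function(a, b)
      (a == "L" & b == "R") | (a == "R" & b == "L"))
    ut <- upper.tri(cn$weights)
    conn <- cn$weights > 0
    expect_gt(mean(cn$lengths[ut & conn & inter]),
              mean(cn$lengths[ut & conn & !inter]))
  }
})

test_that("cohorts round-trip through the on-disk format", {
  coh <- generate_cohort(cohort_config(n_subjects = 4, seed = 8))
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_equal(man$n_subjects, 4)
  back <- read_cohort(dir)
  expect_equal(names(back$connectomes), names(coh$connectomes))
  for (id in names(coh$connectomes)) {
    expect_equal(back$connectomes[[id]]$weights,
                 coh$connectomes[[id]]$weights, tolerance = 1e-14)
    expect_equal(back$connectomes[[id]]$lengths,
                 coh$connectomes[[id]]$lengths, tolerance = 1e-14)
    expect_identical(back$connectomes[[id]]$hemisphere,
                     coh$connectomes[[id]]$hemisphere)
  }
  expect_equal(back$records$age, coh$records$age, tolerance = 1e-12)
  # subject table columns are exactly the record schema
  expect_identical(names(back$records), names(coh$records))
  expect_equal(back$ground_truth$subjects$p_inter,
               coh$ground_truth$subjects$p_inter, tolerance = 1e-12)
})

test_that("an empty cohort writes a zero-subject manifest without error", {
  dir <- withr::local_tempdir()
  empty <- structure(list(connectomes = list(),
                          records = data.frame(), ground_truth = NULL),
                     class = "synthetic_cohort")
  man <- write_cohort(empty, dir)
  expect_equal(man$n_subjects, 0)
})

test_that("parcellation label table matches the shipped fixture", {
  fixture <- read.table(system.file("extdata",
                                    "desikan_killiany_labels.tsv",
                                    package = "hemiconn"),
                        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_identical(parcellation_labels(30, 16), fixture)
  # generic sizes keep the paired-plus-midline structure
  small <- parcellation_labels(5, 7)
  expect_equal(sum(small$cortical), 10)
  expect_equal(sum(small$hemisphere == "M"), 3)
  expect_equal(sum(small$hemisphere == "L"), sum(small$hemisphere == "R"))
})
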