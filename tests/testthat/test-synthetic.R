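test_that("distribution table covers all 36 reference cells", {
  d <- marker_distributions()
  expect_equal(nrow(d), 36)
  expect_true(all(d$mean >= 0 & d$mean <= 100))
  expect_true(all(d$sd >= 0))
  expect_true(all(d$n_ref >= 1))
  # spot checks against the reference table
  expect_equal(d$mean[d$group == "sperm_secretion" & d$marker == "N27SE"],
               90.39)
  expect_equal(d$sd[d$group == "nasal" & d$marker == "NB21"], 17.55)
  expect_equal(d$n_ref[d$group == "menstrual_blood" & d$marker == "MB4"], 23)
})

test_that("sd = 0 draws return the configured mean exactly", {
  d <- zero_sd_distributions()
  expect_equal(draw_single_source("sperm_secretion", "N27SE", 5, d),
               rep(90.39, 5))
  expect_equal(draw_single_source("saliva", "SA4", 3, d), rep(38.98, 3))
  # nasal_blood maps onto the shared nasal group
  expect_equal(draw_single_source("nasal_blood", "NB21", 1, d), 75.13)
})

test_that("draws are bounded and a missing cell errors", {
  set.seed(42)
  for (g in group_fluids) {
    x <- draw_single_source(g, "B7", 10000)
    expect_true(all(x >= 0 & x <= 100))
  }
  expect_error(draw_single_source("saliva", "XX9"), "no distribution")
})

test_that("cohort moments converge to the configured parameters", {
  # law-of-large-numbers check over all 36 cells, 3 SEM tolerance
  set.seed(20260901)
  d <- marker_distributions()
  n <- 10000
  for (i in seq_len(nrow(d))) {
    x <- draw_single_source(d$group[i], d$marker[i], n)
    sem <- d$sd[i] / sqrt(n)
    expect_lt(abs(mean(x) - d$mean[i]), 3 * sem + 1e-12,
              label = sprintf("mean of %s/%s", d$group[i], d$marker[i]))
    sem_sd <- d$sd[i] / sqrt(2 * n)
    expect_lt(abs(stats::sd(x) - d$sd[i]), 4 * sem_sd,
              label = sprintf("sd of %s/%s", d$group[i], d$marker[i]))
  }
})

test_that("outlier components reach the documented extremes", {
  set.seed(99)
  b7 <- draw_single_source("peripheral_blood", "B7", 20000)
  expect_gt(mean(b7 < 80), 0.10)   # ~1/6 outliers below the core range
  expect_gte(min(b7), 60)
  n27 <- draw_single_source("sperm_secretion", "N27SE", 20000)
  expect_true(any(n27 == 73) && any(n27 == 81))
  # with outliers disabled the discrete displacement points never occur
  core <- draw_single_source("sperm_secretion", "N27SE", 20000,
                             outliers = FALSE)
  expect_false(any(core %in% c(73, 81)))
})

test_that("mixture specs validate their weights", {
  expect_error(mixture_spec(c(saliva = 0.5, vaginal_secretion = 0.4)),
               "sum to 1")
  expect_error(mixture_spec(c(tears = 1)), "unknown fluid")
  expect_error(mixture_spec(numeric(0)), "at least one")
  expect_silent(mixture_spec(c(saliva = 1)))
})

test_that("mixture values are weighted means of component draws", {
  d <- zero_sd_distributions()
  # equal-weight nasal + vaginal at N27SE: (31.40 + 14.62) / 2
  mx <- mix_profile(mixture_spec(c(nasal_secretion = 0.5,
                                   vaginal_secretion = 0.5)), "N27SE", 3, d)
  expect_equal(mx, rep(23.01, 3))
  # degenerate single-component mixture equals the single-source draw
  expect_equal(mix_profile(mixture_spec(c(saliva = 1)), "SA4", 2, d),
               draw_single_source("saliva", "SA4", 2, d))
  # 70/30 sperm + menstrual blood
  expect_equal(
    mix_profile(mixture_spec(c(sperm_secretion = 0.7,
                               menstrual_blood = 0.3)), "N27SE", 1, d),
    0.7 * 90.39 + 0.3 * 23.65)
})

test_that("derived pre-tests reflect composition and detection floor", {
  expect_equal(
    unclass(derive_pretests(mixture_spec(c(menstrual_blood = 0.5,
                                           sperm_secretion = 0.5)))),
    c(blood = "positive", saliva = "negative", sperm = "positive"),
    ignore_attr = TRUE)
  expect_equal(
    unclass(derive_pretests(mixture_spec(c(saliva = 0.5,
                                           vaginal_secretion = 0.5)))),
    c(blood = "negative", saliva = "positive", sperm = "negative"),
    ignore_attr = TRUE)
  all_neg <- derive_pretests(mixture_spec(c(vaginal_secretion = 1)))
  expect_true(all(all_neg == "negative"))
  # a trace component below the floor stays undetected
  trace <- mixture_spec(c(saliva = 0.96, peripheral_blood = 0.04))
  expect_equal(derive_pretests(trace, detection_floor = 0.05)[["blood"]],
               "negative")
  expect_equal(derive_pretests(trace)[["blood"]], "positive")
})

test_that("adding a blood component never flips the blood test negative", {
  set.seed(5)
  for (i in 1:25) {
    base_fluids <- sample(c("saliva", "vaginal_secretion", "nasal_secretion",
                            "sperm_secretion"), 2)
    w <- stats::runif(1, 0.2, 0.8)
    base <- mixture_spec(stats::setNames(c(w, 1 - w), base_fluids))
    blood_fluid <- sample(c("peripheral_blood", "menstrual_blood",
                            "nasal_blood"), 1)
    shrink <- 0.6
    augmented <- mixture_spec(stats::setNames(
      c(as.numeric(base) * shrink, 1 - shrink),
      c(names(base), blood_fluid)))
    before <- derive_pretests(base, 0.1)[["blood"]]
    after <- derive_pretests(augmented, 0.1)[["blood"]]
    expect_false(before == "positive" && after == "negative")
    expect_equal(after, "positive")
  }
})

test_that("cohort generation is seed-deterministic", {
  design <- list(
    list(spec = mixture_spec(c(saliva = 1)), n = 4),
    list(spec = mixture_spec(c(nasal_secretion = 0.5,
                               sperm_secretion = 0.5)), n = 3))
  a <- generate_cohort(design, seed = 123)
  b <- generate_cohort(design, seed = 123)
  expect_identical(a, b)
  c <- generate_cohort(design, seed = 124)
  expect_false(identical(a, c))
  expect_equal(nrow(a), 7)
})

test_that("duplicate noise respects the deviation bound", {
  sheet <- generate_cohort(single_source_design(50), seed = 7)
  for (mk in c("NB21", "B7", "MB4", "SA4", "V2", "N27SE")) {
    dev <- abs(sheet[[paste0(mk, "_rep1")]] - sheet[[paste0(mk, "_rep2")]])
    expect_true(all(dev <= 5))
    vals <- c(sheet[[paste0(mk, "_rep1")]], sheet[[paste0(mk, "_rep2")]])
    expect_true(all(vals >= 0 & vals <= 100))
  }
  expect_true(all(sheet$concentration_ng_ul >= 2.5))
})

test_that("zero noise gives identical replicates; QC injection works", {
  sheet <- generate_cohort(single_source_design(20), seed = 3, dup_noise = 0)
  expect_equal(sheet$SA4_rep1, sheet$SA4_rep2)
  bad <- generate_cohort(list(list(spec = mixture_spec(c(saliva = 1)),
                                   n = 400)),
                         seed = 8, deviation_exceed_rate = 0.3,
                         conversion_fail_rate = 0.2)
  dev <- abs(bad$SA4_rep1 - bad$SA4_rep2)
  expect_gt(mean(dev > 5), 0.15)
  expect_gt(mean(bad$conversion_control == "fail"), 0.1)
})

test_that("sample sheets round-trip through delimited text", {
  sheet <- generate_cohort(single_source_design(2), seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_sheet(sheet, path)
  back <- read_sample_sheet(path)
  expect_equal(back$sample_id, sheet$sample_id)
  expect_equal(back$NB21_rep1, sheet$NB21_rep1, tolerance = 1e-10)
  expect_equal(back$pretest_blood, sheet$pretest_blood)
})

test_that("the post-menopausal vaginal subpopulation is available on demand", {
  d <- marker_distributions(include_postmenopausal = TRUE)
  row <- d[d$group == "vaginal_postmenopausal" & d$marker == "V2", ]
  expect_equal(row$mean, 22)
  expect_equal(row$sd, 7)
  expect_equal(nrow(marker_distributions()), 36)
  set.seed(1)
  x <- draw_single_source("vaginal_postmenopausal", "V2", 5000, d)
  expect_lt(abs(mean(x) - 22), 3 * 7 / sqrt(5000))
})
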