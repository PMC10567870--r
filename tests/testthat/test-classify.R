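test_that("negative pre-tests exclude the corresponding fluids", {
  expect_setequal(names(exclude_by_pretests(all_negative)),
                  c("peripheral_blood", "menstrual_blood", "nasal_blood",
                    "saliva", "sperm_secretion"))
  expect_equal(names(exclude_by_pretests(
    pretest_panel(blood = "positive", sperm = "positive",
                  saliva = "negative"))), "saliva")
  expect_length(exclude_by_pretests(pretest_panel()), 0)
})

test_that("marker selection follows the decision workflow", {
  expect_equal(select_markers(all_negative), c("V2", "N27SE"))
  expect_equal(select_markers(pretest_panel(blood = "positive",
                                            saliva = "negative",
                                            sperm = "positive")),
               c("NB21", "B7", "MB4", "N27SE"))
  expect_equal(select_markers(pretest_panel(blood = "negative",
                                            saliva = "positive",
                                            sperm = "negative")),
               c("SA4", "V2", "N27SE"))
  # nothing tested yet: every marker is still informative
  expect_equal(select_markers(pretest_panel()),
               c("NB21", "B7", "MB4", "SA4", "V2", "N27SE"))
})

test_that("a profile with only non-target values comes back undetermined", {
  res <- classify(c(V2 = 8, N27SE = 5), all_negative)
  expect_true(res$undetermined)
  expect_length(res$called, 0)
})

test_that("sperm is called above its cutoff and kept under perturbation", {
  pt <- pretest_panel(sperm = "positive")
  res <- classify(c(N27SE = 95), pt)
  expect_true("sperm_secretion" %in% res$full)
  for (eps in c(0.001, 0.5, 10, 24.9)) {
    r <- classify(c(N27SE = 75 + eps), pt)
    expect_true("sperm_secretion" %in% r$called, label = paste("eps", eps))
  }
  # strict comparison: exactly 75 does not fire
  r <- classify(c(N27SE = 75), pretest_panel())
  expect_false("sperm_secretion" %in% r$called)
})

test_that("NB21 at or above 67 never creates a nasal call", {
  for (v in c(67, 67.001, 71, 80, 95, 100)) {
    r <- classify(c(NB21 = v), pretest_panel(blood = "positive"))
    expect_false(any(grepl("nasal", r$called)), label = paste("NB21", v))
  }
  r <- classify(c(NB21 = 50), pretest_panel(blood = "positive"))
  expect_equal(r$full, "nasal_blood")
  r <- classify(c(NB21 = 50), pretest_panel(blood = "negative"))
  expect_equal(r$full, "nasal_secretion")
  r <- classify(c(NB21 = 50), pretest_panel())
  expect_equal(r$full, "nasal_secretion_or_nasal_blood")
})

test_that("nasal mixtures in the 71-95 NB21 range stay invisible", {
  # the documented blind spot: nasal + vaginal / nasal + sperm mixtures
  pt <- pretest_panel(blood = "negative", saliva = "negative",
                      sperm = "positive")
  for (v in c(71, 80, 95)) {
    r <- classify(c(NB21 = v, N27SE = 60), pt)
    expect_false(any(grepl("nasal", r$called)))
  }
})

test_that("the MB4 mixture band needs a positive sperm pre-test", {
  pos <- pretest_panel(blood = "positive", sperm = "positive",
                       saliva = "negative")
  r <- classify(c(MB4 = 19.5), pos)
  expect_setequal(r$full, c("menstrual_blood", "sperm_secretion"))
  expect_true(r$mixture)
  # same value, sperm negative: plain menstrual blood via the relaxed tier
  neg <- pretest_panel(blood = "positive", sperm = "negative")
  r <- classify(c(MB4 = 19.5), neg)
  expect_equal(r$full, "menstrual_blood")
  # sperm not done: between the unconditional cutoff nothing fires
  r <- classify(c(MB4 = 19.5), pretest_panel(blood = "positive"))
  expect_false("menstrual_blood" %in% r$called)
})

test_that("saliva partial component between 18 and 35", {
  pt <- pretest_panel(saliva = "positive")
  r <- classify(c(SA4 = 28), pt)
  expect_true("saliva" %in% r$partial)
  r <- classify(c(SA4 = 40), pt)
  expect_equal(r$full, "saliva")
  expect_false("saliva" %in% r$partial)
})

test_that("V2 tiers disambiguate vaginal tract by pre-tests", {
  # > 50: vaginal secretion regardless of pre-tests
  r <- classify(c(V2 = 55), pretest_panel(saliva = "positive"))
  expect_true("vaginal_secretion" %in% r$full)
  # 40 < v <= 50 needs the negative saliva test
  r <- classify(c(V2 = 43), pretest_panel(saliva = "negative",
                                          blood = "negative"))
  expect_true("vaginal_secretion" %in% r$full)
  r <- classify(c(V2 = 43), pretest_panel(saliva = "positive",
                                          blood = "negative"))
  expect_true("vaginal_secretion" %in% r$partial)
  # > 25 with blood untested: could be vaginal secretion or menstrual blood
  r <- classify(c(V2 = 30), pretest_panel())
  expect_true("vaginal_tract_secretion" %in% r$partial)
})

test_that("pre-test-supported components obey the evidence", {
  # sperm positive, N27SE mid-range: sperm reported as sub-component
  r <- classify(c(N27SE = 51), pretest_panel(sperm = "positive",
                                             blood = "negative"))
  expect_true("sperm_secretion" %in% r$partial)
  # sperm positive but N27SE far below any sperm-containing mixture
  r <- classify(c(N27SE = 10), pretest_panel(sperm = "positive"))
  expect_false("sperm_secretion" %in% r$called)
  expect_true(any(grepl("not supported", r$flags)))
  # blood positive without resolving methylation evidence
  r <- classify(c(B7 = 40), pretest_panel(blood = "positive"))
  expect_true("blood_unspecified" %in% r$partial)
})

test_that("pre-test-excluded fluids never surface in calls", {
  set.seed(31)
  states <- c("positive", "negative", "not_done")
  for (i in 1:60) {
    pt <- pretest_panel(sample(states, 1), sample(states, 1),
                        sample(states, 1))
    prof <- stats::setNames(stats::runif(6, 0, 100),
                            c("NB21", "B7", "MB4", "SA4", "V2", "N27SE"))
    r <- classify(prof, pt)
    expect_length(intersect(r$called, names(r$excluded)), 0)
    expect_length(intersect(r$partial, names(r$excluded)), 0)
    expect_equal(r$undetermined, length(r$called) == 0)
  }
})

test_that("classification is deterministic and validates its inputs", {
  pt <- pretest_panel(blood = "positive", sperm = "positive",
                      saliva = "negative")
  prof <- c(NB21 = 90, B7 = 38, MB4 = 20, N27SE = 51)
  expect_identical(classify(prof, pt)[c("called", "full", "partial")],
                   classify(prof, pt)[c("called", "full", "partial")])
  expect_error(classify(c(NB21 = 101), pt), "\\[0, 100\\]")
  expect_error(classify(c(XX9 = 10), pt), "absent from threshold rules")
})

test_that("idealized single-source cohorts are called correctly", {
  # every fluid at its reference mean, pre-tests derived from composition
  expected <- list(
    nasal_secretion = "nasal_secretion",      # via the N27SE band at 31.40
    peripheral_blood = "peripheral_blood",    # B7 87.43 > 80
    menstrual_blood = "menstrual_blood",      # MB4 20.39 > 18, sperm negative
    saliva = "saliva",                        # SA4 38.98 > 35
    vaginal_secretion = "vaginal_secretion",  # V2 53.55 > 50
    sperm_secretion = "sperm_secretion")      # N27SE 90.39 > 75
  for (fluid in names(expected)) {
    pt <- derive_pretests(mixture_spec(stats::setNames(1, fluid)))
    r <- classify(mean_profile(fluid), pt)
    expect_true(expected[[fluid]] %in% r$full, label = fluid)
    # and no foreign full call beyond the blood-support composites
    expect_length(setdiff(r$full, c(expected[[fluid]])), 0)
  }
})

test_that("missing markers degrade gracefully with a coverage flag", {
  r <- classify(c(V2 = 55), all_negative)
  expect_true("vaginal_secretion" %in% r$full)
  expect_true(any(grepl("not analyzed", r$flags)))
})

test_that("classify_sheet runs the full pipeline on a generated cohort", {
  sheet <- generate_cohort(list(
    list(spec = mixture_spec(c(sperm_secretion = 1)), n = 10),
    list(spec = mixture_spec(c(saliva = 1)), n = 10)), seed = 41)
  out <- classify_sheet(sheet)
  expect_equal(nrow(out), 20)
  sperm_rows <- grepl("sperm_secretion:1", sheet$true_composition)
  expect_true(all(grepl("sperm_secretion", out$called_fluids[sperm_rows])))
  expect_true(all(grepl("saliva", out$called_fluids[!sperm_rows])))
  # narrative report mirrors the per-sample write-ups
  path <- withr::local_tempfile(fileext = ".txt")
  classify_sheet(sheet[1:2, ], narratives_path = path)
  expect_true(any(grepl("Verdict", readLines(path))))
})
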