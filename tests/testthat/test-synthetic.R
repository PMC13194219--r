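test_that("generation is byte-identical under a fixed seed", {
  a <- generate_study(default_study_config(13))
  b <- generate_study(default_study_config(13))
  expect_identical(a, b)
  c <- generate_study(default_study_config(14))
  expect_false(identical(a$peaks, c$peaks))
})

test_that("the generator leaves the global RNG stream untouched", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_study(default_study_config(13)))
  expect_identical(runif(3), before)
})

test_that("the design emulates the three-tree, three-phase study layout", {
  study <- generate_study(default_study_config(2))
  d <- study$design
  trunk <- d[!d$is_background, ]
  expect_setequal(unique(trunk$tree_id), c("ApC", "ApI", "ApN"))
  # duplicate samples per tree and day
  expect_true(all(table(trunk$tree_id, trunk$day) %in% c(0, 2)))
  # 42 sampling days over the 188-day window, control truncated
  expect_equal(length(unique(trunk$day[trunk$tree_id == "ApI"])), 42L)
  expect_lte(max(trunk$day[trunk$tree_id == "ApC"]), 138)
  expect_lte(max(trunk$day), 188)
  # backgrounds exist at both locations
  bg <- d[d$is_background, ]
  expect_setequal(unique(bg$location), c("outside", "inside_quarantine"))
  expect_true(all(is.na(bg$bark_area_dm2)))
})

test_that("censoring drops rows instead of writing zeros", {
  study <- generate_study(default_study_config(4))
  expect_true(all(study$peaks$area > 0))
  # planted trunk rates survive the area round trip above the threshold
  cfg <- default_study_config(4)
  res <- run_pipeline(study)
  expect_true(all(res$emissions$rate >= cfg$detection_threshold - 1e-9))
})

test_that("detection threshold at the q-th rate quantile yields ~100(1-q)%
           DF", {
  cfg <- default_study_config(21)
  cfg$ambient <- list()
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  for (q in c(0.2, 0.5, 0.8)) {
    # above the median the noiseless mean itself is censored, so the
    # planted compound is no longer continuously detectable
    cfg$compounds <- list(trunkvoc:::planted_compound(
      "probe", "aldehyde",
      if (q < 0.5 || qlnorm(q, -sigma^2 / 2, sigma) <= 1) "constitutive"
      else "unclassified", 800,
      base = c(ApI = 1, ApN = 1, ApC = 1)))
    cfg$detection_threshold <- qlnorm(q, meanlog = -sigma^2 / 2,
                                      sdlog = sigma)
    study <- generate_study(cfg)
    res <- run_pipeline(study)
    df <- detection_frequency(res$emissions, study$design, "probe")
    expect_lt(abs(df - 100 * (1 - q)), 5)
  }
})

test_that("generated retention times increase with the planted index", {
  study <- generate_study(default_study_config(6))
  rt <- tapply(study$peaks$rt_min, study$peaks$feature_id, median)
  lib_all <- study$library
  ann <- annotate_features(study$peaks,
                           alkane_ladder(study$alkanes$carbon_number,
                                         study$alkanes$rt_min),
                           lib_all, extrapolate = TRUE)
  ord <- order(ann$lri_exp)
  expect_true(all(diff(ann$rt_min[ord]) > 0))
})

test_that("the truth table lists planted labels and stays out of pipeline
           inputs", {
  cfg <- default_study_config(1)
  tr <- truth_table(cfg)
  expect_equal(nrow(tr), length(cfg$compounds))
  expect_equal(as.integer(table(tr$true_label)[c(
    "constitutive", "hipv", "neighbor_induced", "stress_induced")]),
    c(30L, 15L, 6L, 4L))
  # five planted de novo herbivore-induced compounds (no baseline anywhere)
  n_denovo <- sum(vapply(cfg$compounds, function(cp)
    cp$true_label == "hipv" && all(cp$base == 0), logical(1)))
  expect_equal(n_denovo, 5L)
  # the pipeline never reads the truth table
  study <- generate_study(cfg)
  expect_identical(run_pipeline(study[setdiff(names(study), "truth")]),
                   run_pipeline(study))
})

test_that("label-inconsistent configurations fail validation", {
  cfg <- default_study_config(1)
  bad <- cfg
  # a "constitutive" compound below the detection threshold everywhere
  bad$compounds <- list(trunkvoc:::planted_compound(
    "ghost", "ketone", "constitutive", 900,
    base = c(ApI = 1e-4, ApN = 1e-4, ApC = 1e-4)))
  expect_error(validate_study_config(bad), "inconsistent")
  # a "hipv" compound without any induction at the infested tree
  bad$compounds <- list(trunkvoc:::planted_compound(
    "inert", "NCV", "hipv", 900, base = c(ApI = 1, ApN = 1, ApC = 1)))
  expect_error(validate_study_config(bad), "inconsistent")
  expect_error(generate_study(bad), "inconsistent")
})
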