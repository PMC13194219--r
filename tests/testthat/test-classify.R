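test_that("detection frequency counts duplicates as separate samples", {
  # 61 biotic-stress samples at the infested tree, 30 detections
  d <- mini_design(trees = "ApI", pre_days = 0, post_days = 20:50, reps = 2)
  d <- d[-nrow(d), ]  # 2 pre + 61 post samples
  post_ids <- d$sample_id[assign_phase(d$day) == 3]
  em <- data.frame(compound = "X", compound_class = "NCV", tree_id = "ApI",
                   day = 0, replicate = 1, phase = 3,
                   sample_id = post_ids[1:30], rate = 1,
                   unit = "ng_per_dm2_h", tentative = FALSE,
                   below_calibration = FALSE)
  expect_equal(detection_frequency(em, d, "X", phases_sel = 3),
               100 * 30 / 61, tolerance = 1e-12)
  expect_equal(detection_frequency(em, d, "X", phases_sel = 3,
                                   trees = "ApI"), 49.18, tolerance = 1e-3)
  expect_equal(detection_frequency(em[0, ], d, "X"), 0)
  expect_error(detection_frequency(em, d, "X", trees = "ApZ"), "empty")
})

test_that("retention filter applies an inclusive 10% pooled threshold", {
  d <- mini_design(pre_days = c(0, 2), post_days = c(30, 60, 90))  # 30 maple samples
  em <- rbind(mini_emissions(d, "at10", "ApI", "post", 1, detect = 3),
              mini_emissions(d, "below10", "ApI", "post", 1, detect = 2),
              mini_emissions(d, "everywhere", "ApC", "pre", 1))
  expect_setequal(retention_filter(em, d, threshold = 10),
                  c("at10", "everywhere"))
  expect_equal(retention_filter(em[0, ], d), character(0))
})

test_that("constitutive rule is per-tree and inclusive at the threshold", {
  d <- mini_design()  # 12 pre samples per tree
  pre_all <- function(cp, detects) do.call(rbind, Map(function(tr, k)
    mini_emissions(d, cp, tr, "pre", 1, detect = k),
    c("ApC", "ApI", "ApN"), detects))
  em <- rbind(pre_all("core", c(8, 7, 7)),       # 67/58/58 %
              pre_all("edge", c(6, 6, 6)),       # exactly 50% everywhere
              pre_all("onefail", c(11, 11, 5)))  # 92/92/42 %
  expect_setequal(constitutive_set(em, d), c("core", "edge"))
  # pooled reading admits the compound that fails one tree
  expect_true("onefail" %in% constitutive_set(em, d, pooled = TRUE))
  # monotone non-increasing in the threshold
  expect_true(all(constitutive_set(em, d, threshold = 60) %in%
                    constitutive_set(em, d, threshold = 50)))
})

test_that("period means require 20% detection and average detected rates", {
  d <- mini_design(pre_days = c(0, 2, 4, 6, 10), post_days = c(30, 60))
  # 10 pre samples per tree
  em2 <- mini_emissions(d, "X", "ApI", "pre", c(2, 4), detect = 2)
  got <- phase_mean_rate(em2, d, "X", "ApI", phases_sel = 1:2)
  expect_equal(got$df, 20)           # exactly at threshold: defined
  expect_equal(got$mean, 3)
  em1 <- mini_emissions(d, "X", "ApI", "pre", 5, detect = 1)
  got1 <- phase_mean_rate(em1, d, "X", "ApI", phases_sel = 1:2)
  expect_equal(got1$df, 10)
  expect_true(is.na(got1$mean))      # sub-threshold: undefined
})

test_that("ratio marks follow the footnote rules", {
  expect_equal(ratio_with_marks(8, 2), list(value = 4, mark = "numeric"))
  r <- ratio_with_marks(8, NA, den_detected = TRUE)
  expect_equal(r$mark, "sparse")     # detected but < 20% of measurements
  r <- ratio_with_marks(8, NA, den_detected = FALSE)
  expect_equal(r$mark, "exclusive")  # never detected at comparison tree
  r <- ratio_with_marks(8, NA, den_detected = TRUE, intra = TRUE)
  expect_equal(r$mark, "de_novo")    # absent before exposure
  expect_error(ratio_with_marks(NA, NA), "both means undefined")
})

test_that("classification fires the twofold rules inclusively and in
           priority order", {
  d <- mini_design()
  em <- rbind(
    # exactly twofold at the boundary, exclusive to ApI after exposure
    mini_emissions(d, "boundary", "ApI", "pre", 1),
    mini_emissions(d, "boundary", "ApI", "post", 2),
    # just below twofold
    mini_emissions(d, "under", "ApI", "pre", 1),
    mini_emissions(d, "under", "ApI", "post", 1.99),
    # de novo at the infested tree only
    mini_emissions(d, "denovo", "ApI", "post", 3),
    # comparable increases at both quarantine trees (band 3.0 vs 3.1)
    mini_emissions(d, "both", "ApI", "pre", 1),
    mini_emissions(d, "both", "ApI", "post", 3),
    mini_emissions(d, "both", "ApN", "pre", 1),
    mini_emissions(d, "both", "ApN", "post", 3.1),
    # neighbor increase far beyond the infested tree's (outside the band)
    mini_emissions(d, "nb", "ApI", "pre", 1),
    mini_emissions(d, "nb", "ApI", "post", 3),
    mini_emissions(d, "nb", "ApN", "pre", 1),
    mini_emissions(d, "nb", "ApN", "post", 6.5),
    # constitutive core with an additional herbivory response
    do.call(rbind, lapply(c("ApC", "ApI", "ApN"), function(tr) rbind(
      mini_emissions(d, "core", tr, "pre", 1),
      mini_emissions(d, "core", tr, "post", if (tr == "ApI") 2.5 else 1)))))
  cl <- classify_volatiles(em, d)
  lab <- setNames(cl$label, cl$compound)
  expect_equal(unname(lab["boundary"]), "hipv")
  expect_equal(unname(lab["under"]), "unclassified")
  expect_equal(unname(lab["denovo"]), "hipv")
  expect_equal(cl$rule[cl$compound == "denovo"], "hipv_de_novo")
  expect_equal(cl$ratio_I_pre_post[cl$compound == "denovo"], "ALB")
  expect_equal(unname(lab["both"]), "stress_induced")
  expect_equal(unname(lab["nb"]), "neighbor_induced")
  expect_equal(unname(lab["core"]), "constitutive")
  expect_equal(cl$secondary[cl$compound == "core"], "hipv")
  # symbolic inter-tree marks render as the tree name for exclusives
  expect_equal(cl$ratio_I_vs_N[cl$compound == "boundary"], "ApI")
})

test_that("primary labels partition the retained compound set", {
  study <- generate_study(default_study_config(9))
  res <- run_pipeline(study)
  cl <- res$classification
  expect_true(all(cl$label %in% c("constitutive", "hipv",
                                  "neighbor_induced", "stress_induced",
                                  "unclassified")))
  expect_false(any(is.na(cl$label)))
  expect_equal(anyDuplicated(cl$compound), 0L)
  # DF columns agree with a direct recount from the emission table
  for (i in c(1L, 5L, 10L, 20L, nrow(cl))) {
    cp <- cl$compound[i]
    expect_equal(cl$df_pre_I[i],
                 detection_frequency(res$emissions, study$design, cp,
                                     trees = "ApI", phases_sel = 1:2))
    expect_equal(cl$df_post_N[i],
                 detection_frequency(res$emissions, study$design, cp,
                                     trees = "ApN", phases_sel = 3))
  }
})
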