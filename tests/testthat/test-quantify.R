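test_that("calibration fits exact and noisy level sets", {
  cv <- fit_calibration(data.frame(mass_ng = c(1, 2), area = c(1000, 2000)))
  expect_equal(cv$slope, 1000)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r_squared, 1)
  # collinear levels stay a perfect line
  cv4 <- fit_calibration(data.frame(mass_ng = c(0.5, 1, 2, 5),
                                    area = 200 + 300 * c(0.5, 1, 2, 5)))
  expect_equal(cv4$r_squared, 1)
  expect_equal(cv4$slope, 300)
  # noisy levels agree with the closed-form least-squares oracle
  set.seed(4)
  m <- c(0.5, 1, 2, 5, 10)
  a <- 500 + 2.1e5 * m + rnorm(5, 0, 3e4)
  cvn <- fit_calibration(data.frame(mass_ng = m, area = a))
  or <- ols_oracle(m, a)
  expect_equal(cvn$slope, unname(or["slope"]), tolerance = 1e-9)
  expect_equal(cvn$intercept, unname(or["intercept"]), tolerance = 1e-9)
  expect_error(fit_calibration(data.frame(mass_ng = c(2, 2),
                                          area = c(1, 2))), "distinct")
})

test_that("area-to-mass inverts the line, floors at zero and flags", {
  cv <- fit_calibration(data.frame(mass_ng = c(1, 5), area = c(1500, 5500)))
  expect_equal(cv$slope, 1000); expect_equal(cv$intercept, 500)
  expect_equal(as.numeric(area_to_mass(cv$intercept, cv)), 0)
  expect_equal(as.numeric(area_to_mass(5500, cv)), 5)
  m <- area_to_mass(200, cv)  # below the intercept
  expect_equal(as.numeric(m), 0)
  expect_true(attr(m, "below_calibration"))
  # round trip: mass -> area -> mass
  mass <- c(0.2, 1, 7, 19)
  expect_equal(as.numeric(area_to_mass(cv$slope * mass + cv$intercept, cv)),
               mass, tolerance = 1e-9)
})

test_that("emission-rate normalization scales as amount / (area * time)", {
  smp <- list(bark_area_dm2 = 2, duration_h = 1.5, is_background = FALSE)
  expect_equal(to_emission_rate(30, smp), 10)
  expect_equal(to_emission_rate(0, smp), 0)
  expect_equal(to_emission_rate(3.0e6, smp) / 1e6, 1.0)
  # homogeneity: degree 1 in amount, degree -1 in area and duration
  expect_equal(to_emission_rate(60, smp), 2 * to_emission_rate(30, smp))
  smp2 <- smp; smp2$bark_area_dm2 <- 4
  expect_equal(to_emission_rate(30, smp2), to_emission_rate(30, smp) / 2)
  smp3 <- smp; smp3$duration_h <- 3
  expect_equal(to_emission_rate(30, smp3), to_emission_rate(30, smp) / 2)
  expect_error(to_emission_rate(1, list(is_background = TRUE)),
               "background")
})

test_that("surrogate mapping tags tentative curves and passes through", {
  curves <- list(`alpha-Pinene` = fit_calibration(
    data.frame(mass_ng = c(1, 5), area = c(1000, 5000)), "alpha-Pinene"))
  map <- data.frame(compound = "Tricyclene", surrogate = "alpha-Pinene")
  cv <- surrogate_quantify("Tricyclene", curves, map)
  expect_true(cv$tentative)
  expect_equal(cv$surrogate, "alpha-Pinene")
  expect_equal(cv$slope, curves[["alpha-Pinene"]]$slope)
  own <- surrogate_quantify("alpha-Pinene", curves, map)
  expect_false(own$tentative)
  expect_null(surrogate_quantify("unknown NCV", curves, map))
  map2 <- data.frame(compound = "x", surrogate = "missing")
  expect_error(surrogate_quantify("x", curves, map2), "missing")
})

test_that("background filter keeps trunk-enriched and background-absent
           features", {
  design <- mini_design(trees = "ApI", pre_days = c(0, 2),
                        post_days = c(30, 60), reps = 1)
  bg <- design[1:2, ]
  bg$sample_id <- c("BG1", "BG2"); bg$tree_id <- "BG_in"
  bg$is_background <- TRUE; bg$bark_area_dm2 <- NA
  design <- rbind(design, bg)
  pk <- function(f, ids, area) data.frame(sample_id = ids, feature_id = f,
                                          rt_min = 5, area = area)
  peaks <- rbind(
    pk("absent_bg", design$sample_id[1:4], 100),        # not in background
    pk("enriched", design$sample_id[1:4], 1000),        # trunk 10x ambient
    pk("enriched", c("BG1", "BG2"), 100),
    pk("ambient", design$sample_id[1:4], 100),          # trunk == ambient
    pk("ambient", c("BG1", "BG2"), 100))
  kept <- background_filter(peaks, design, factor = 2)
  expect_true("absent_bg" %in% kept)
  expect_true("enriched" %in% kept)
  expect_false("ambient" %in% kept)
  # a very large factor keeps only background-absent features
  expect_equal(background_filter(peaks, design, factor = 1e9), "absent_bg")
  # no background samples: everything is retained
  kept_all <- background_filter(peaks[peaks$sample_id %in%
                                        design$sample_id[1:4], ],
                                design[!design$is_background, ])
  expect_setequal(kept_all, c("absent_bg", "enriched", "ambient"))
})

test_that("quantification recovers planted rates through the full chain", {
  cfg <- default_study_config(5, noise_cv = 0)
  study <- generate_study(cfg)
  res <- run_pipeline(study)
  em <- res$emissions
  # noiseless: every Hexanal observation equals its planted baseline
  hex <- em[em$compound == "Hexanal" & em$tree_id == "ApC", ]
  expect_true(nrow(hex) > 0)
  expect_equal(hex$rate, rep(14, nrow(hex)), tolerance = 1e-9)
  # surrogate-quantified compounds are flagged tentative
  expect_true(all(em$tentative[em$compound == "Cyclosativene"]))
  expect_false(any(em$tentative[em$compound == "alpha-Copaene"]))
})
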