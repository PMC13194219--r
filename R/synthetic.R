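# Synthetic study generator: emulates a three-tree, three-phase trunk
# volatile monitoring experiment with planted compound classes, so every
# pipeline stage can be exercised and verified without instrument data.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# one planted compound; baselines are per-tree mean rates (ng dm^-2 h^-1),
# kernels are lists of c(A, xc, w) peak pulses per tree
planted_compound <- function(name, compound_class, true_label, lri,
                             base = c(ApI = 0, ApN = 0, ApC = 0),
                             stress_multiplier = 1, kernels = list(),
                             quantified_by = NA_character_, id_tier = "MRS") {
  list(name = name, compound_class = compound_class, true_label = true_label,
       lri = lri, base = base, stress_multiplier = stress_multiplier,
       kernels = kernels, quantified_by = quantified_by, id_tier = id_tier)
}

#' Default synthetic study configuration
#'
#' Emulates the study conditions: three Norway maples (an outside control
#' ApC, an infested tree ApI and its non-infested neighbor ApN, both inside
#' a quarantine room), sampled in duplicate on 42 days over a 188-day
#' window (ApC truncated at day 138), with three phases (acclimation days
#' 0-8, abiotic stress 9-19, biotic stress 20-188), ~2 dm^2 enclosed bark
#' and 90-min sampling. Planted are 30 constitutive compounds (some with a
#' relocation-stress response), 15 herbivore-induced compounds (5 of them
#' de novo, with early-, double- and late-peak emission kernels), 6
#' neighbor-induced and 4 stress-induced compounds, plus ubiquitous ambient
#' features present in background air. Observations carry multiplicative
#' lognormal noise (CV 0.2) and are censored below a detection threshold of
#' 0.05 ng dm^-2 h^-1, which produces realistic detection frequencies.
#'
#' @param seed integer seed; fixes sampling days and all noise.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (default 0.2).
#' @param detection_threshold rate below which an observation is censored
#'   (dropped), in ng dm^-2 h^-1 (default 0.05).
#' @return a study configuration list for [generate_study()].
#' @export
default_study_config <- function(seed = 1L, noise_cv = 0.2,
                                 detection_threshold = 0.05) {
  pc <- planted_compound
  b3 <- function(v) c(ApI = v, ApN = v, ApC = v)             # equal baselines
  # emissions below the detection limit are modelled as absent (zero), so
  # tree-specific compounds stay identifiable when censoring is disabled
  bI <- function(i) c(ApI = i, ApN = 0, ApC = 0)
  bN <- function(n) c(ApI = 0, ApN = n, ApC = 0)
  bQ <- function(q) c(ApI = q, ApN = q, ApC = 0)
  K <- function(A, xc, w) c(A = A, xc = xc, w = w)

  constitutive <- list(
    pc("2-Methylpropanal", "aldehyde", "constitutive", 552, b3(0.45)),
    pc("Pentanal", "aldehyde", "constitutive", 692, b3(1.8)),
    pc("Hexanal", "aldehyde", "constitutive", 808, b3(14)),
    pc("Heptanal", "aldehyde", "constitutive", 909, b3(2.7)),
    pc("Benzaldehyde", "aldehyde", "constitutive", 962, b3(4.4)),
    pc("Nonanal", "aldehyde", "constitutive", 1108, b3(19)),
    pc("Decanal", "aldehyde", "constitutive", 1210, b3(4.7)),
    pc("2-Methylbutanal", "aldehyde", "constitutive", 668, b3(0.9)),
    pc("Pentane", "aliphatic_HC", "constitutive", 500, b3(0.76)),
    pc("Hexane", "aliphatic_HC", "constitutive", 600, b3(1.1)),
    pc("Heptane", "aliphatic_HC", "constitutive", 700, b3(1.3)),
    pc("Methylcyclohexane", "aliphatic_HC", "constitutive", 727, b3(0.3)),
    pc("1-Octene", "aliphatic_HC", "constitutive", 789, b3(0.74)),
    pc("Octane", "aliphatic_HC", "constitutive", 800, b3(3.5)),
    pc("Nonane", "aliphatic_HC", "constitutive", 901, b3(1.5)),
    pc("Undecane", "aliphatic_HC", "constitutive", 1100, b3(1.05)),
    pc("Dodecane", "aliphatic_HC", "constitutive", 1200, b3(0.86)),
    pc("Tetradecane", "aliphatic_HC", "constitutive", 1400, b3(0.74)),
    pc("Benzene", "aromatic_HC", "constitutive", 657, b3(1.2)),
    pc("Toluene", "aromatic_HC", "constitutive", 763, b3(4.8)),
    pc("p-Xylene", "aromatic_HC", "constitutive", 866, b3(2.0)),
    pc("o-Xylene", "aromatic_HC", "constitutive", 875, b3(1.05)),
    pc("1,2,4-Trimethylbenzene", "aromatic_HC", "constitutive", 996,
       b3(0.76), stress_multiplier = 2.5),
    pc("Isopropyl alcohol", "alcohol", "constitutive", 489, b3(7.6)),
    pc("2-Ethyl-1-hexanol", "alcohol", "constitutive", 1030, b3(1.7)),
    pc("Acetone", "ketone", "constitutive", 509, b3(5.4)),
    # 2-butanone: constitutive core compound with an additional
    # herbivory-associated pulse at the infested tree (secondary induction)
    pc("2-Butanone", "ketone", "constitutive", 590, b3(0.5),
       kernels = list(ApI = list(K(4, 45, 15)))),
    pc("alpha-Pinene", "monoterpenoid", "constitutive", 937, b3(2.4),
       stress_multiplier = 7),
    pc("beta-Pinene", "monoterpenoid", "constitutive", 980, b3(0.6),
       stress_multiplier = 5),
    pc("3-Carene", "monoterpenoid", "constitutive", 1011, b3(1.7),
       stress_multiplier = 7))

  hipv <- list(
    # present before infestation, strongly upregulated afterwards
    pc("Camphene", "monoterpenoid", "hipv", 946, bI(0.4),
       kernels = list(ApI = list(K(5, 34, 8), K(4, 55, 9)))),
    pc("Sabinene", "monoterpenoid", "hipv", 972, bI(0.3),
       kernels = list(ApI = list(K(4, 34, 8), K(3, 62, 9)))),
    pc("beta-Myrcene", "monoterpenoid", "hipv", 988, bI(0.25),
       kernels = list(ApI = list(K(3, 34, 8), K(2.5, 60, 9)))),
    pc("p-Cymene", "monoterpenoid", "hipv", 1022, bI(0.5),
       kernels = list(ApI = list(K(9, 34, 8), K(7, 60, 9)))),
    pc("gamma-Terpinene", "monoterpenoid", "hipv", 1057, bI(0.35),
       kernels = list(ApI = list(K(5, 35, 8), K(4, 61, 9)))),
    # earliest post-exposure response: sharp pulse well inside phase 3 so
    # that no induced emission precedes the exposure day
    pc("beta-Ocimene", "monoterpenoid", "hipv", 1046, bI(0.3),
       kernels = list(ApI = list(K(6, 31, 5)))),
    pc("(E)-4,8-Dimethylnona-1,3,7-triene", "monoterpenoid", "hipv", 1116,
       bI(0.4), kernels = list(ApI = list(K(8, 32, 10))),
       quantified_by = "beta-Ocimene", id_tier = "MR"),
    pc("Thymol methyl ether", "monoterpenoid", "hipv", 1235, bI(0.2),
       kernels = list(ApI = list(K(2, 38, 9), K(1.6, 63, 10))),
       quantified_by = "p-Cymene", id_tier = "MR"),
    pc("alpha-Longipinene", "sesquiterpenoid", "hipv", 1353, bI(0.3),
       kernels = list(ApI = list(K(4, 40, 9), K(6, 90, 12), K(4, 120, 10)))),
    pc("alpha-Curcumene", "sesquiterpenoid", "hipv", 1483, bI(0.35),
       kernels = list(ApI = list(K(7, 92, 20)))),
    # de novo after infestation
    pc("Cyclosativene", "sesquiterpenoid", "hipv", 1368,
       kernels = list(ApI = list(K(6, 90, 22))),
       quantified_by = "alpha-Copaene", id_tier = "MR"),
    pc("alpha-Copaene", "sesquiterpenoid", "hipv", 1376,
       kernels = list(ApI = list(K(4, 92, 20)))),
    pc("Zingiberene", "sesquiterpenoid", "hipv", 1495,
       kernels = list(ApI = list(K(3, 76, 9), K(4, 97, 10)))),
    pc("Isobutyronitrile", "NCV", "hipv", 626,
       kernels = list(ApI = list(K(2, 45, 15)))),
    pc("Butanal O-methyloxime", "NCV", "hipv", 680,
       kernels = list(ApI = list(K(4, 40, 18))),
       quantified_by = "Isobutyronitrile", id_tier = "MR"))

  neighbor <- list(
    pc("(Z)-alpha-Bergamotene", "sesquiterpenoid", "neighbor_induced", 1413,
       kernels = list(ApN = list(K(3, 76, 14)))),
    pc("alpha-Santalene", "sesquiterpenoid", "neighbor_induced", 1420,
       kernels = list(ApN = list(K(2, 40, 12), K(2, 90, 15)))),
    pc("Cuparene", "sesquiterpenoid", "neighbor_induced", 1504,
       kernels = list(ApN = list(K(1.5, 45, 12), K(2, 95, 14)))),
    pc("2-Heptanone", "ketone", "neighbor_induced", 884,
       kernels = list(ApN = list(K(1.2, 120, 40)))),
    pc("(E)-beta-Farnesene", "sesquiterpenoid", "neighbor_induced", 1455,
       base = bN(0.3), kernels = list(ApN = list(K(3, 80, 18)))),
    pc("beta-Sesquiphellandrene", "sesquiterpenoid", "neighbor_induced",
       1521, base = bN(0.35), kernels = list(ApN = list(K(2.5, 85, 16))),
       quantified_by = "Zingiberene", id_tier = "MR"))

  stress <- list(
    pc("Benzyl alcohol", "alcohol", "stress_induced", 1038, bQ(0.4),
       kernels = list(ApI = list(K(3, 50, 20)), ApN = list(K(3, 65, 20)))),
    pc("3-Methylbutanal", "aldehyde", "stress_induced", 645, bQ(0.35),
       kernels = list(ApI = list(K(2.5, 45, 18)), ApN = list(K(2.5, 60, 18)))),
    pc("Styrene", "aromatic_HC", "stress_induced", 893, bQ(0.3),
       kernels = list(ApI = list(K(2, 48, 20)), ApN = list(K(2, 62, 20)))),
    pc("Propylbenzene", "aromatic_HC", "stress_induced", 955, bQ(0.25),
       kernels = list(ApI = list(K(1.8, 52, 20)), ApN = list(K(1.8, 66, 20)))))

  ambient <- list(
    list(name = "Isoprene (ambient)", compound_class = "OCV_other",
         lri = 535, level = 4e5, id_tier = "MR"),
    list(name = "Butyl acetate (ambient)", compound_class = "ester",
         lri = 818, level = 6e5, id_tier = "MR"),
    list(name = "Decamethylcyclopentasiloxane", compound_class = "OCV_other",
         lri = 1345, level = 9e5, id_tier = "M"))

  compounds <- c(constitutive, hipv, neighbor, stress)
  cfg <- list(
    seed = as.integer(seed),
    phase_boundaries = list(c(0L, 8L), c(9L, 19L), c(20L, 188L)),
    window = 188L, apc_last_day = 138L,
    trees = data.frame(
      tree_id = c("ApC", "ApI", "ApN"),
      role = c("control", "infested", "neighbor"),
      location = c("outside", "inside_quarantine", "inside_quarantine"),
      stringsAsFactors = FALSE),
    n_days = c(phase1 = 7L, phase2 = 4L, phase3_early = 20L,
               phase3_late = 11L),
    bark_area_dm2 = 2, duration_h = 1.5, flow_ml_min = 30,
    noise_cv = noise_cv, detection_threshold = detection_threshold,
    rt_jitter_sd = 0.002,
    ladder = alkane_ladder(5:17, c(1.6, 2.4, 3.6, 5.1, 6.9, 8.8, 10.8,
                                   12.8, 14.7, 16.6, 18.4, 20.1, 21.7)),
    calibration_masses = c(0.5, 1, 2, 5, 10, 20),
    calibration_intercept = 500,
    compounds = compounds,
    ambient = ambient)
  validate_study_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' Checks that each planted compound's label holds by construction: the
#' noiseless mean emission curves, censored at the detection threshold and
#' evaluated on a uniform day grid, must reproduce the planted label under
#' the classification rule cascade (detection frequencies, fold-change
#' ratios and precedence as in [classify_volatiles()]). An early induction
#' kernel bleeding into the pre-exposure phases, an induced amplitude too
#' small for a twofold increase, or a "constitutive" baseline below the
#' detection threshold all error here rather than silently corrupting the
#' truth table.
#'
#' @param config study configuration list.
#' @param fold,mean_df,constitutive_df,band rule thresholds the planted
#'   labels must satisfy by construction (defaults as in the pipeline).
#' @return the config, invisibly; errors on inconsistency.
#' @export
validate_study_config <- function(config, fold = 2, mean_df = 20,
                                  constitutive_df = 50, band = 2) {
  lris <- vapply(config$compounds, `[[`, numeric(1), "lri")
  if (anyDuplicated(lris)) stop("planted retention indices must be unique")
  for (cp in config$compounds) {
    lab <- noiseless_label(cp, config, fold, mean_df, constitutive_df, band)
    if (lab != cp$true_label)
      stop("planted compound \"", cp$name, "\": label \"", cp$true_label,
           "\" is inconsistent with its baselines/kernels (noiseless rules",
           " give \"", lab, "\")")
  }
  invisible(config)
}

# apply the classification rule cascade to a compound's noiseless mean
# curves on a uniform day grid (the by-construction label)
noiseless_label <- function(cp, config, fold = 2, mean_df = 20,
                            constitutive_df = 50, band = 2) {
  phases <- default_phases(config$phase_boundaries)
  thr <- config$detection_threshold
  post <- nrow(phases)
  grid <- function(ids) unlist(lapply(ids, function(i)
    phases$day_min[i]:phases$day_max[i]))
  stat <- function(tree, phase_ids) {
    d <- grid(phase_ids)
    if (tree == "ApC") d <- d[d <= config$apc_last_day]
    m <- mean_rate_curve(cp, tree, d, config, phases)
    det <- m >= thr & m > 0
    list(df = 100 * mean(det),
         mean = if (mean(det) * 100 >= mean_df && any(det))
           mean(m[det]) else NA_real_,
         any = any(det))
  }
  pre <- lapply(c(I = "ApI", N = "ApN", C = "ApC"), stat,
                phase_ids = seq_len(post - 1L))
  pst <- lapply(c(I = "ApI", N = "ApN", C = "ApC"), stat, phase_ids = post)
  if (all(vapply(c("ApI", "ApN", "ApC"), function(tr)
    stat(tr, seq_len(post - 1L))$df >= constitutive_df, logical(1))))
    return("constitutive")
  rat <- function(num, den, intra = FALSE)
    if (is.na(num$mean)) list(value = NA_real_, mark = "undefined") else
      ratio_with_marks(num$mean, den$mean, den$any, intra)
  rII <- rat(pst$I, pre$I, TRUE); rNN <- rat(pst$N, pre$N, TRUE)
  if (rII$mark == "numeric" && rNN$mark == "numeric" &&
      rII$value >= fold && rNN$value >= fold &&
      rII$value / rNN$value <= band && rNN$value / rII$value <= band)
    return("stress_induced")
  de_novo_I <- pre$I$df < mean_df && pst$I$df >= mean_df
  de_novo_N <- pre$N$df < mean_df && pst$N$df >= mean_df
  if (de_novo_I ||
      (ratio_satisfied(rII, fold) &&
         ratio_satisfied(rat(pst$I, pst$N), fold) &&
         ratio_satisfied(rat(pst$I, pst$C), fold)))
    return("hipv")
  if (de_novo_N ||
      (ratio_satisfied(rNN, fold) &&
         ratio_satisfied(rat(pst$N, pst$I), fold) &&
         ratio_satisfied(rat(pst$N, pst$C), fold)))
    return("neighbor_induced")
  "unclassified"
}

mean_rate_curve <- function(cp, tree_id, day, config, phases) {
  inside <- config$trees$location[config$trees$tree_id == tree_id] ==
    "inside_quarantine"
  base <- unname(cp$base[tree_id])
  if (is.na(base)) base <- 0
  ph <- assign_phase(day, phases)
  m <- ifelse(inside & ph >= 2L, base * cp$stress_multiplier, base)
  for (k in cp$kernels[[tree_id]])
    m <- m + eval_extreme(day, 0, k[["A"]], k[["xc"]], k[["w"]])
  m
}

#' Generate a synthetic trunk volatile study
#'
#' Produces the full table bundle the pipeline reads: design and peak
#' tables, the alkane ladder, the compound library, calibration levels, the
#' surrogate mapping, and a truth table of planted labels (for tests only,
#' never a pipeline input). The mean emission of a compound at a tree and
#' day is its (possibly stress-multiplied) baseline plus the sum of its
#' induction kernels; observations are mean times mean-one lognormal noise,
#' censored (row dropped, never zero) below the detection threshold, two
#' replicates per sampled day. Retention times are back-computed from the
#' planted retention indices through the alkane ladder and component areas
#' through the calibration curve and sample geometry, so the pipeline's
#' annotation and quantification can recover the planted rates. A fixed
#' seed makes the output reproducible.
#'
#' @param config configuration from [default_study_config()].
#' @param dir optional directory; when given, all tables are written as CSV
#'   (design.csv, peaks.csv, alkanes.csv, library.csv, calibration.csv,
#'   surrogates.csv, truth.csv).
#' @return named list of data.frames: design, peaks, alkanes, library,
#'   calibration, surrogates, truth.
#' @export
generate_study <- function(config = default_study_config(), dir = NULL) {
  validate_study_config(config)
  phases <- default_phases(config$phase_boundaries)
  with_local_seed(config$seed, {
    nd <- config$n_days
    p3 <- config$phase_boundaries[[3L]]
    days <- sort(c(sample(config$phase_boundaries[[1L]][1L]:config$phase_boundaries[[1L]][2L], nd[["phase1"]]),
                   sample(config$phase_boundaries[[2L]][1L]:config$phase_boundaries[[2L]][2L], nd[["phase2"]]),
                   sample(p3[1L]:100L, nd[["phase3_early"]]),
                   sample(101L:p3[2L], nd[["phase3_late"]])))

    design <- do.call(rbind, lapply(config$trees$tree_id, function(tr) {
      d <- days
      if (tr == "ApC") d <- d[d <= config$apc_last_day]
      expand.grid(tree_id = tr, day = d, replicate = 1:2,
                  stringsAsFactors = FALSE)
    }))
    design$location <- config$trees$location[match(design$tree_id,
                                                   config$trees$tree_id)]
    design$is_background <- FALSE

    bg_out_days <- days[seq(1L, length(days), by = 3L)]
    bg_in_days <- days[days >= config$phase_boundaries[[2L]][1L]]
    bg_in_days <- bg_in_days[seq(1L, length(bg_in_days), by = 2L)]
    bg <- rbind(
      data.frame(tree_id = "BG_out", day = bg_out_days, replicate = 1L,
                 location = "outside", is_background = TRUE),
      data.frame(tree_id = "BG_in", day = bg_in_days, replicate = 1L,
                 location = "inside_quarantine", is_background = TRUE))
    design <- rbind(design, bg)
    design$sample_id <- sprintf("%s_d%03d_r%d", design$tree_id, design$day,
                                design$replicate)
    design$bark_area_dm2 <- ifelse(design$is_background, NA_real_,
                                   config$bark_area_dm2)
    design$duration_h <- config$duration_h
    design$flow_ml_min <- config$flow_ml_min
    design <- design[order(design$tree_id, design$day, design$replicate),
                     c("sample_id", "tree_id", "day", "replicate",
                       "bark_area_dm2", "duration_h", "flow_ml_min",
                       "is_background", "location")]
    rownames(design) <- NULL

    # calibration curve per compound: own slope, or the surrogate's curve
    nms <- vapply(config$compounds, `[[`, character(1), "name")
    slopes <- stats::setNames(2e5 + seq_along(nms) * 1e4, nms)
    surrogates <- do.call(rbind, lapply(config$compounds, function(cp)
      if (!is.na(cp$quantified_by))
        data.frame(compound = cp$name, surrogate = cp$quantified_by)))
    if (is.null(surrogates))
      surrogates <- data.frame(compound = character(0),
                               surrogate = character(0))
    own <- setdiff(nms, surrogates$compound)
    calibration <- do.call(rbind, lapply(own, function(nm)
      data.frame(compound = nm, mass_ng = config$calibration_masses,
                 area = slopes[[nm]] * config$calibration_masses +
                   config$calibration_intercept)))
    curve_of <- function(nm) {
      s <- surrogates$surrogate[surrogates$compound == nm]
      if (length(s)) s else nm
    }

    sigma <- if (config$noise_cv > 0)
      sqrt(log(1 + config$noise_cv^2)) else 0
    noise <- function(n) if (sigma == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)

    trunk <- design[!design$is_background, ]
    feature_ids <- stats::setNames(
      sprintf("F%03d", seq_len(length(config$compounds) + length(config$ambient))),
      c(nms, vapply(config$ambient, `[[`, character(1), "name")))

    peak_rows <- list()
    for (cp in config$compounds) {
      rt0 <- invert_lri(cp$lri, config$ladder, extrapolate = TRUE)
      slope <- slopes[[curve_of(cp$name)]]
      for (tr in config$trees$tree_id) {
        sub <- trunk[trunk$tree_id == tr, ]
        if (!nrow(sub)) next
        m <- mean_rate_curve(cp, tr, sub$day, config, phases)
        obs <- m * noise(nrow(sub))
        keep <- obs >= config$detection_threshold & obs > 0
        if (!any(keep)) next
        mass <- obs[keep] * config$bark_area_dm2 * config$duration_h
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          sample_id = sub$sample_id[keep],
          feature_id = feature_ids[[cp$name]],
          rt_min = rt0 + stats::rnorm(sum(keep), 0, config$rt_jitter_sd),
          area = slope * mass + config$calibration_intercept)
      }
    }
    for (am in config$ambient) {
      rt0 <- invert_lri(am$lri, config$ladder, extrapolate = TRUE)
      # ambient features pervade trunk and background air at similar levels
      lvl <- ifelse(design$is_background, am$level, 0.9 * am$level)
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        sample_id = design$sample_id,
        feature_id = feature_ids[[am$name]],
        rt_min = rt0 + stats::rnorm(nrow(design), 0, config$rt_jitter_sd),
        area = lvl * noise(nrow(design)))
    }
    peaks <- do.call(rbind, peak_rows)
    peaks <- peaks[order(peaks$sample_id, peaks$rt_min), ]
    rownames(peaks) <- NULL

    alkanes <- data.frame(carbon_number = config$ladder$carbon,
                          rt_min = config$ladder$rt_min)
    library <- rbind(
      do.call(rbind, lapply(config$compounds, function(cp)
        data.frame(name = cp$name, cas = "", formula = "",
                   lri_lit = cp$lri, compound_class = cp$compound_class,
                   id_tier = cp$id_tier))),
      do.call(rbind, lapply(config$ambient, function(am)
        data.frame(name = am$name, cas = "", formula = "",
                   lri_lit = am$lri, compound_class = am$compound_class,
                   id_tier = am$id_tier))))

    study <- list(design = design, peaks = peaks, alkanes = alkanes,
                  library = library, calibration = calibration,
                  surrogates = surrogates, truth = truth_table(config))
    if (!is.null(dir)) write_study(study, dir)
    study
  })
}

#' Truth table of planted compound labels
#'
#' One row per planted maple compound with its true classification label;
#' consumed only by tests and validation, never by the pipeline. Ambient
#' background features carry no classification label and are not listed.
#'
#' @param config study configuration.
#' @return data.frame: compound, compound_class, true_label, lri_true.
#' @export
truth_table <- function(config = default_study_config()) {
  do.call(rbind, lapply(config$compounds, function(cp)
    data.frame(compound = cp$name, compound_class = cp$compound_class,
               true_label = cp$true_label, lri_true = cp$lri,
               stringsAsFactors = FALSE)))
}
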