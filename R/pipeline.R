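# End-to-end orchestration: annotation -> background separation ->
# quantification -> classification -> dynamics -> reports, with an
# auditable manifest of the filter cascade.

#' Run the full trunk volatile pipeline
#'
#' Executes every stage on a study bundle and (optionally) writes all
#' outputs as CSV plus a YAML run manifest. The pipeline itself is fully
#' deterministic: identical inputs and settings produce byte-identical
#' outputs.
#'
#' @param study either a named list of data.frames (design, peaks, alkanes,
#'   library, calibration, surrogates) as from [generate_study()], or a
#'   directory containing the corresponding CSV files.
#' @param out_dir optional output directory for annotations.csv,
#'   emissions.csv, classification.csv, fits.csv, tau_matrix.csv,
#'   groups.csv, tests.csv, report tables and manifest.yaml.
#' @param roles named character vector mapping control / infested /
#'   neighbor roles to tree ids.
#' @param lri_tolerance library matching tolerance in index units.
#' @param lri_extrapolate index features eluting outside the alkane ladder
#'   span by extrapolating the terminal ladder segment (TRUE by default:
#'   very volatile compounds commonly elute before the first alkane).
#' @param background_factor trunk-over-background median excess required to
#'   keep a feature.
#' @param retention_df,constitutive_df,mean_df,fold,band classification
#'   thresholds, see [classify_volatiles()].
#' @param tau_min,alpha dynamics grouping thresholds, see [tau_group()].
#' @param dunn_adjust p-adjustment for Dunn comparisons ("none" or any
#'   [stats::p.adjust()] method).
#' @param min_fit_days minimum number of detected days for a peak fit.
#' @param phases phase table.
#' @return list with elements annotations, emissions, classification,
#'   fits, tau (per-class tau/p matrices), groups, tests,
#'   constitutive_table, induced_table, manifest.
#' @export
run_pipeline <- function(study, out_dir = NULL,
                         roles = c(control = "ApC", infested = "ApI",
                                   neighbor = "ApN"),
                         lri_tolerance = 15, lri_extrapolate = TRUE,
                         background_factor = 2,
                         retention_df = 10, constitutive_df = 50,
                         mean_df = 20, fold = 2, band = 2,
                         tau_min = 0.5, alpha = 0.05, dunn_adjust = "none",
                         min_fit_days = 8L, phases = default_phases()) {
  if (is.character(study)) study <- read_study(study)
  need <- c("design", "peaks", "alkanes", "library")
  miss <- setdiff(need, names(study))
  if (length(miss)) stop("study bundle is missing: ", paste(miss, collapse = ", "))
  design <- study$design
  peaks <- study$peaks
  ladder <- alkane_ladder(study$alkanes$carbon_number, study$alkanes$rt_min)

  annotations <- annotate_features(peaks, ladder, study$library,
                                   tolerance = lri_tolerance,
                                   extrapolate = lri_extrapolate)
  kept_features <- background_filter(peaks, design, phases,
                                     factor = background_factor)
  peaks_f <- peaks[peaks$feature_id %in% kept_features, , drop = FALSE]

  curves <- if (!is.null(study$calibration) && nrow(study$calibration))
    lapply(split(study$calibration, study$calibration$compound), function(g)
      fit_calibration(g[, c("mass_ng", "area")], g$compound[1L]))
  else list()
  surrogates <- if (!is.null(study$surrogates)) study$surrogates else
    data.frame(compound = character(0), surrogate = character(0))
  emissions <- quantify_emissions(peaks_f, design, annotations, curves,
                                  surrogates, phases)

  classification <- classify_volatiles(
    emissions, design, roles, phases, retention_df, constitutive_df,
    mean_df, fold, band)

  # temporal dynamics for induced (primary or secondary) compounds
  induced <- classification[classification$label != "unclassified" &
                              (classification$label != "constitutive" |
                                 !is.na(classification$secondary)), ]
  home_tree <- function(row) {
    lab <- if (row$label == "constitutive") row$secondary else row$label
    switch(lab, neighbor_induced = roles[["neighbor"]], roles[["infested"]])
  }
  fits <- list(); series_by_class <- list()
  for (i in seq_len(nrow(induced))) {
    row <- induced[i, ]
    tr <- home_tree(row)
    obs <- emissions[emissions$compound == row$compound &
                       emissions$tree_id == tr, ]
    if (length(unique(obs$day)) < min_fit_days) next
    agg <- daily_aggregate(obs$day, obs$rate)
    series_by_class[[row$compound_class]][[row$compound]] <- agg
    ft <- tryCatch(fit_extreme(agg$day, agg$mean), error = function(e) NULL)
    fits[[length(fits) + 1L]] <- data.frame(
      compound = row$compound, tree_id = tr,
      y0 = if (!is.null(ft) && ft$converged) ft$params$y0 else NA_real_,
      A = if (!is.null(ft) && ft$converged) ft$params$A else NA_real_,
      xc = if (!is.null(ft) && ft$converged) ft$params$xc else NA_real_,
      w = if (!is.null(ft) && ft$converged) ft$params$w else NA_real_,
      adj_r2 = if (!is.null(ft)) ft$adj_r2 else NA_real_,
      converged = !is.null(ft) && ft$converged,
      n_days = nrow(agg), stringsAsFactors = FALSE)
  }
  fits <- if (length(fits)) do.call(rbind, fits) else
    data.frame(compound = character(0), tree_id = character(0),
               y0 = numeric(0), A = numeric(0), xc = numeric(0),
               w = numeric(0), adj_r2 = numeric(0), converged = logical(0),
               n_days = integer(0))

  tau <- list(); groups <- list()
  for (cls in names(series_by_class)) {
    ser <- series_by_class[[cls]]
    if (length(ser) < 2L) next
    tg <- tau_group(ser, tau_min = tau_min, alpha = alpha)
    tau[[cls]] <- tg[c("tau", "p")]
    g <- tg$groups
    g$compound_class <- cls
    groups[[cls]] <- g
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(compound = character(0), group = integer(0),
               compound_class = character(0))
  rownames(groups) <- NULL

  tests <- run_group_tests(emissions, design, classification, phases,
                           alpha, dunn_adjust)

  constitutive_table <- make_report(classification, emissions, annotations,
                                    design, roles, phases,
                                    which = "constitutive")
  induced_table <- make_report(classification, emissions, annotations,
                               design, roles, phases, which = "induced")

  manifest <- build_manifest(design, peaks, kept_features, annotations,
                             emissions, classification, phases,
                             list(lri_tolerance = lri_tolerance,
                                  background_factor = background_factor,
                                  retention_df = retention_df,
                                  constitutive_df = constitutive_df,
                                  mean_df = mean_df, fold = fold,
                                  band = band, tau_min = tau_min,
                                  alpha = alpha))

  res <- list(annotations = annotations, emissions = emissions,
              classification = classification, fits = fits, tau = tau,
              groups = groups, tests = tests,
              constitutive_table = constitutive_table,
              induced_table = induced_table, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Kruskal-Wallis + Dunn for constitutive compounds: inter-tree within each
# phase, and intra-tree across phases (Dunn gatekept by the KW p-value)
run_group_tests <- function(emissions, design, classification, phases,
                            alpha = 0.05, dunn_adjust = "none") {
  core <- classification$compound[classification$label == "constitutive"]
  trees <- sort(unique(design$tree_id[!design$is_background]))
  rows <- list()
  add <- function(compound, comparison, grp) {
    grp <- grp[lengths(grp) > 0L]
    if (length(grp) < 2L || sum(lengths(grp)) < 3L) return()
    kw <- kw_test(grp)
    rows[[length(rows) + 1L]] <<- data.frame(
      compound = compound, comparison = comparison, test = "kruskal_wallis",
      group1 = NA_character_, group2 = NA_character_,
      statistic = kw$H, p = kw$p, p_adj = NA_real_, stringsAsFactors = FALSE)
    if (is.finite(kw$p) && kw$p < alpha) {
      dn <- dunn_posthoc(grp, adjust = dunn_adjust)
      rows[[length(rows) + 1L]] <<- data.frame(
        compound = compound, comparison = comparison, test = "dunn",
        group1 = dn$group1, group2 = dn$group2, statistic = dn$z,
        p = dn$p, p_adj = dn$p_adj, stringsAsFactors = FALSE)
    }
  }
  for (cp in core) {
    em <- emissions[emissions$compound == cp, ]
    for (ph in phases$phase_id)
      add(cp, paste0("inter_tree_phase", ph),
          lapply(stats::setNames(trees, trees), function(tr)
            em$rate[em$tree_id == tr & em$phase == ph]))
    for (tr in trees)
      add(cp, paste0("intra_tree_", tr),
          lapply(stats::setNames(phases$phase_id,
                                 paste0("phase", phases$phase_id)),
                 function(ph) em$rate[em$tree_id == tr & em$phase == ph]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound = character(0), comparison = character(0),
               test = character(0), group1 = character(0),
               group2 = character(0), statistic = numeric(0),
               p = numeric(0), p_adj = numeric(0))
  rownames(out) <- NULL
  out
}

#' Build a report table of constitutive or induced volatiles
#'
#' Per-compound summary in the style of a publication table: retention
#' index, detection frequency in the relevant scope, symbolic emission-rate
#' ratios (induced table), and the compound's percentage contribution to
#' the summed emission of all compounds listed, as mean and SEM of the
#' per-sample shares (undetected compounds contribute zero to a sample, so
#' contributions sum to 100 within the table). All listed compounds must
#' share one unit; mixing mass- and area-based rates is an error.
#'
#' @param classification output of [classify_volatiles()].
#' @param emissions emission table.
#' @param annotations annotation table.
#' @param design design table.
#' @param roles role-to-tree map.
#' @param phases phase table.
#' @param which "constitutive" (pre-stress scope, all trees) or "induced"
#'   (biotic-stress scope, quarantine trees).
#' @return data.frame report table.
#' @export
make_report <- function(classification, emissions, annotations, design,
                        roles = c(control = "ApC", infested = "ApI",
                                  neighbor = "ApN"),
                        phases = default_phases(),
                        which = c("constitutive", "induced")) {
  which <- match.arg(which)
  post_phase <- phases$phase_id[nrow(phases)]
  pre_phases <- setdiff(phases$phase_id, post_phase)
  if (which == "constitutive") {
    sel <- classification[classification$label == "constitutive", ]
    scope <- trunk_scope(design, phases_sel = NULL, phases = phases)
  } else {
    sel <- classification[!classification$label %in%
                            c("constitutive", "unclassified"), ]
    scope <- trunk_scope(design,
                         trees = c(roles[["infested"]], roles[["neighbor"]]),
                         phases_sel = post_phase, phases = phases)
  }
  if (!nrow(sel))
    return(data.frame(compound = character(0)))
  em <- emissions[emissions$compound %in% sel$compound &
                    emissions$sample_id %in% scope$sample_id, ]
  units <- unique(em$unit)
  if (length(units) > 1L)
    stop("report table would mix units: ", paste(units, collapse = ", "))
  # per-sample share of each compound in the summed rate of listed compounds
  rate_mat <- matrix(0, nrow(scope), nrow(sel),
                     dimnames = list(scope$sample_id, sel$compound))
  if (nrow(em))
    rate_mat[cbind(match(em$sample_id, scope$sample_id),
                   match(em$compound, sel$compound))] <- em$rate
  tot <- rowSums(rate_mat)
  share <- 100 * rate_mat[tot > 0, , drop = FALSE] / tot[tot > 0]
  contr_m <- colMeans(share)
  contr_se <- apply(share, 2L, stats::sd) / sqrt(nrow(share))
  ann <- annotations[match(sel$compound, annotations$best_match), ]
  df_scope <- if (which == "constitutive") {
    vapply(sel$compound, function(cp)
      detection_frequency(emissions, design, cp, phases_sel = pre_phases,
                          phases = phases), numeric(1))
  } else {
    home <- ifelse(sel$label == "neighbor_induced", roles[["neighbor"]],
                   roles[["infested"]])
    mapply(function(cp, tr)
      detection_frequency(emissions, design, cp, trees = tr,
                          phases_sel = post_phase, phases = phases),
      sel$compound, home)
  }
  out <- data.frame(
    compound = sel$compound, compound_class = sel$compound_class,
    label = sel$label, lri_exp = round(ann$lri_exp),
    id_tier = ann$id_tier, df_pct = round(df_scope),
    contribution_pct = round(contr_m, 2),
    contribution_sem = round(contr_se, 2),
    unit = if (length(units)) units else NA_character_,
    stringsAsFactors = FALSE)
  if (which == "induced") {
    m <- match(sel$compound, classification$compound)
    out$ratio_I_vs_N <- classification$ratio_I_vs_N[m]
    out$ratio_I_vs_C <- classification$ratio_I_vs_C[m]
    out$ratio_N_vs_C <- classification$ratio_N_vs_C[m]
    out$ratio_pre_post <- ifelse(sel$label == "neighbor_induced",
                                 classification$ratio_N_pre_post[m],
                                 classification$ratio_I_pre_post[m])
  }
  out <- out[order(out$compound_class, -out$contribution_pct), ]
  rownames(out) <- NULL
  out
}

build_manifest <- function(design, peaks, kept_features, annotations,
                           emissions, classification, phases, thresholds) {
  trunk <- design[!design$is_background, ]
  trunk$phase <- assign_phase(trunk$day, phases)
  counts_tp <- as.list(stats::setNames(
    as.integer(t(table(trunk$tree_id, trunk$phase))),
    as.vector(t(outer(sort(unique(trunk$tree_id)),
                      sort(unique(trunk$phase)),
                      function(a, b) paste0(a, "_phase", b))))))
  lab_tab <- table(classification$label)
  manifest <- list(
    thresholds = thresholds,
    counts = c(
      counts_tp,
      list(
        n_maple_samples = nrow(trunk),
        n_background_samples = sum(design$is_background),
        n_features = length(unique(peaks$feature_id)),
        n_features_after_background = length(kept_features),
        n_features_annotated = sum(!is.na(annotations$best_match)),
        n_compounds_quantified = length(unique(emissions$compound)),
        n_retained_df10 = nrow(classification),
        n_constitutive_df50 =
          sum(classification$label == "constitutive"),
        n_means_defined_df20 = sum(!is.na(c(
          classification$value_I_pre_post,
          classification$value_N_pre_post))))),
    labels = as.list(stats::setNames(as.integer(lab_tab), names(lab_tab))),
    rows = list(emissions = nrow(emissions),
                classification = nrow(classification)))
  manifest
}

#' Read a study bundle from a directory of CSV files
#' @param dir directory holding design.csv, peaks.csv, alkanes.csv,
#'   library.csv and optionally calibration.csv, surrogates.csv.
#' @return named list of data.frames.
#' @export
read_study <- function(dir) {
  tabs <- load_tables(file.path(dir, "design.csv"),
                      file.path(dir, "peaks.csv"))
  study <- list(design = tabs$design, peaks = tabs$peaks,
                alkanes = utils::read.csv(file.path(dir, "alkanes.csv")),
                library = read_library(file.path(dir, "library.csv")))
  for (nm in c("calibration", "surrogates")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) study[[nm]] <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  study
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm)
    utils::write.csv(df, file.path(out_dir, nm), row.names = FALSE)
  wr(res$annotations, "annotations.csv")
  wr(res$emissions, "emissions.csv")
  wr(res$classification, "classification.csv")
  wr(res$fits, "fits.csv")
  wr(res$groups, "groups.csv")
  wr(res$tests, "tests.csv")
  wr(res$constitutive_table, "constitutive_table.csv")
  wr(res$induced_table, "induced_table.csv")
  for (cls in names(res$tau)) {
    tm <- res$tau[[cls]]$tau
    utils::write.csv(data.frame(compound = rownames(tm), tm,
                                check.names = FALSE),
                     file.path(out_dir, paste0("tau_matrix_",
                                               gsub("[^A-Za-z0-9]", "_", cls),
                                               ".csv")),
                     row.names = FALSE)
  }
  manifest_txt <- yaml::as.yaml(res$manifest)
  # simple order-sensitive checksum makes manifest drift detectable
  bytes <- utf8ToInt(manifest_txt)
  checksum <- sum(bytes * (seq_along(bytes) %% 997)) %% 2147483647
  writeLines(c(manifest_txt, paste0("checksum: ", checksum)),
             file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
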