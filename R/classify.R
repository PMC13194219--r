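# Detection-frequency filters and fold-change classification of volatiles
# into constitutive / herbivore-induced / neighbor-induced / stress-induced.

trunk_scope <- function(design, trees = NULL, phases_sel = NULL,
                        phases = default_phases()) {
  d <- design[!design$is_background, , drop = FALSE]
  d$phase <- assign_phase(d$day, phases)
  if (!is.null(trees)) d <- d[d$tree_id %in% trees, , drop = FALSE]
  if (!is.null(phases_sel)) d <- d[d$phase %in% phases_sel, , drop = FALSE]
  d
}

#' Detection frequency of a compound
#'
#' DF = 100 * (samples with a detected observation) / (samples in scope).
#' Duplicate samples taken on the same day count as separate samples; the
#' denominator comes from the design table so censored (undetected) samples
#' are counted.
#'
#' @param emissions emission table ([quantify_emissions()]).
#' @param design design table.
#' @param compound compound name.
#' @param trees optional tree subset (NULL = all maples).
#' @param phases_sel optional phase-id subset (NULL = all phases).
#' @param phases phase table.
#' @return percentage in \[0, 100\].
#' @export
detection_frequency <- function(emissions, design, compound, trees = NULL,
                                phases_sel = NULL, phases = default_phases()) {
  scope <- trunk_scope(design, trees, phases_sel, phases)
  if (!nrow(scope)) stop("empty detection-frequency scope")
  det <- unique(emissions$sample_id[emissions$compound == compound])
  100 * sum(scope$sample_id %in% det) / nrow(scope)
}

#' Retain compounds with sufficient overall detection frequency
#'
#' With a single tree per treatment, reliability comes from consistency of
#' detection: only compounds seen in at least `threshold` percent of all
#' maple samples (pooled over trees and phases, background excluded) are
#' processed further. The comparison is inclusive.
#'
#' @inheritParams detection_frequency
#' @param threshold minimum pooled DF in percent (default 10).
#' @return character vector of retained compound names (sorted).
#' @export
retention_filter <- function(emissions, design, threshold = 10,
                             phases = default_phases()) {
  compounds <- sort(unique(emissions$compound))
  df <- vapply(compounds, detection_frequency, numeric(1),
               emissions = emissions, design = design, phases = phases)
  compounds[df >= threshold]
}

#' Identify the constitutive core volatiles
#'
#' Constitutive emissions are continuously emitted rather than transiently
#' expressed: a compound qualifies when its detection frequency reaches
#' `threshold` percent in the pre-biotic-stress phases at every tree
#' (per-tree reading; `pooled = TRUE` instead applies the threshold to all
#' trees' pre-stress samples pooled).
#'
#' @inheritParams retention_filter
#' @param compounds candidate compounds (default: all in the table).
#' @param threshold per-tree DF threshold in percent (default 50, inclusive).
#' @param phases_sel pre-stress phase ids (default 1:2).
#' @param pooled pool trees before applying the threshold?
#' @return character vector of constitutive compound names.
#' @export
constitutive_set <- function(emissions, design, compounds = NULL,
                             threshold = 50, phases_sel = c(1L, 2L),
                             pooled = FALSE, phases = default_phases()) {
  if (is.null(compounds)) compounds <- sort(unique(emissions$compound))
  trees <- sort(unique(design$tree_id[!design$is_background]))
  ok <- vapply(compounds, function(cp) {
    if (pooled)
      return(detection_frequency(emissions, design, cp,
                                 phases_sel = phases_sel,
                                 phases = phases) >= threshold)
    all(vapply(trees, function(tr)
      detection_frequency(emissions, design, cp, trees = tr,
                          phases_sel = phases_sel,
                          phases = phases) >= threshold, logical(1)))
  }, logical(1))
  compounds[ok]
}

#' Mean emission rate of a compound within a (tree, period) scope
#'
#' Arithmetic mean over the detected observations, reported only when the
#' compound was detected in at least `min_df` percent of the scope's
#' samples (inclusive); below that the mean is undefined (NA) and triggers
#' symbolic ratio marks downstream.
#'
#' @inheritParams detection_frequency
#' @param tree single tree id.
#' @param min_df minimum DF in percent for a defined mean (default 20).
#' @return list with `mean` (NA when undefined), `df`, `n` (samples in
#'   scope), `n_detected`.
#' @export
phase_mean_rate <- function(emissions, design, compound, tree,
                            phases_sel = NULL, min_df = 20,
                            phases = default_phases()) {
  scope <- trunk_scope(design, tree, phases_sel, phases)
  if (!nrow(scope)) stop("empty (tree, period) scope")
  obs <- emissions[emissions$compound == compound &
                     emissions$sample_id %in% scope$sample_id, , drop = FALSE]
  df <- 100 * nrow(obs) / nrow(scope)
  list(mean = if (df >= min_df && nrow(obs)) mean(obs$rate) else NA_real_,
       df = df, n = nrow(scope), n_detected = nrow(obs))
}

#' Form an emission-rate ratio with symbolic marks
#'
#' Numeric when both means are defined. When the denominator mean is
#' undefined (sub-threshold detection), the ratio degenerates to a symbolic
#' mark: `"exclusive"` if the compound was never detected in the comparison
#' scope, `"sparse"` (rendered ">") if detected but below the DF threshold,
#' or `"de_novo"` (rendered "ALB") for intra-tree pre/post comparisons
#' where the compound was (virtually) absent before exposure.
#'
#' @param num_mean numerator mean (must be defined).
#' @param den_mean denominator mean or NA.
#' @param den_detected was the compound detected at all in the denominator
#'   scope?
#' @param intra is this an intra-tree post-vs-pre comparison?
#' @return list with `value` (numeric or NA) and `mark` (one of "numeric",
#'   "exclusive", "sparse", "de_novo").
#' @export
ratio_with_marks <- function(num_mean, den_mean, den_detected = TRUE,
                             intra = FALSE) {
  if (is.na(num_mean)) {
    if (is.na(den_mean)) stop("ratio with both means undefined")
    return(list(value = NA_real_, mark = "undefined"))
  }
  if (!is.na(den_mean))
    return(list(value = num_mean / den_mean, mark = "numeric"))
  if (intra) return(list(value = NA_real_, mark = "de_novo"))
  if (!den_detected) return(list(value = NA_real_, mark = "exclusive"))
  list(value = NA_real_, mark = "sparse")
}

render_mark <- function(ratio, exclusive_label) {
  switch(ratio$mark,
         numeric = formatC(ratio$value, format = "fg", digits = 4),
         exclusive = exclusive_label,
         sparse = ">",
         de_novo = "ALB",
         undefined = "")
}

# a fold-change requirement is satisfied by a numeric ratio >= fold or by
# any symbolic mark (exclusive / sparse / de novo all imply "at least")
ratio_satisfied <- function(ratio, fold) {
  if (ratio$mark == "numeric") return(ratio$value >= fold)
  ratio$mark %in% c("exclusive", "sparse", "de_novo")
}

#' Classify retained volatiles
#'
#' Implements the rule cascade on the emission table. Compounds detected at
#' every tree in at least `constitutive_df` percent of pre-stress samples
#' form the constitutive core. The remaining compounds are tested, in
#' order: stress-induced (post/pre increase of at least `fold` at both
#' quarantine trees, to a comparable extent), herbivore-induced (de novo at
#' the infested tree, or post/pre and both inter-tree ratios at least
#' `fold`), neighbor-induced (same with the neighbor tree as numerator),
#' otherwise unclassified. A constitutive compound that additionally
#' satisfies an induced rule keeps `constitutive` as its primary label and
#' carries the induced rule as a secondary flag, so primary labels
#' partition the retained set.
#'
#' @param emissions emission table.
#' @param design design table.
#' @param roles named character vector mapping roles to tree ids, e.g.
#'   `c(control = "ApC", infested = "ApI", neighbor = "ApN")`.
#' @param phases phase table; the last phase is the biotic-stress period,
#'   all earlier phases are "pre".
#' @param retention_df pooled DF retention threshold in percent (default 10).
#' @param constitutive_df per-tree pre-stress DF threshold (default 50).
#' @param mean_df minimum DF for a defined period mean (default 20).
#' @param fold fold-change threshold (default 2, inclusive).
#' @param band comparability band for the stress rule: the two trees'
#'   post/pre increases must be within this factor of each other
#'   (default 2).
#' @param pooled_constitutive pass-through to [constitutive_set()].
#' @return data.frame, one row per retained compound: `compound`,
#'   `compound_class`, `label`, `secondary`, `rule`, per-tree pre/post DF
#'   columns, rendered ratio columns, and numeric ratio columns.
#' @export
classify_volatiles <- function(emissions, design,
                               roles = c(control = "ApC", infested = "ApI",
                                         neighbor = "ApN"),
                               phases = default_phases(),
                               retention_df = 10, constitutive_df = 50,
                               mean_df = 20, fold = 2, band = 2,
                               pooled_constitutive = FALSE) {
  stopifnot(all(c("control", "infested", "neighbor") %in% names(roles)))
  post_phase <- phases$phase_id[nrow(phases)]
  pre_phases <- setdiff(phases$phase_id, post_phase)
  retained <- retention_filter(emissions, design, retention_df, phases)
  core <- constitutive_set(emissions, design, retained, constitutive_df,
                           pre_phases, pooled_constitutive, phases)
  cls <- emissions$compound_class[match(retained, emissions$compound)]

  ev_one <- function(cp, tree, phs) {
    phase_mean_rate(emissions, design, cp, tree, phs, mean_df, phases)
  }
  rows <- lapply(seq_along(retained), function(i) {
    cp <- retained[i]
    I <- roles[["infested"]]; N <- roles[["neighbor"]]; C <- roles[["control"]]
    pre <- lapply(c(I = I, N = N, C = C), ev_one, cp = cp, phs = pre_phases)
    post <- lapply(c(I = I, N = N, C = C), ev_one, cp = cp, phs = post_phase)
    rat <- function(num, den, intra = FALSE) {
      if (is.na(num$mean)) return(list(value = NA_real_, mark = "undefined"))
      ratio_with_marks(num$mean, den$mean, den$n_detected > 0, intra)
    }
    r_intra_I <- rat(post$I, pre$I, intra = TRUE)
    r_intra_N <- rat(post$N, pre$N, intra = TRUE)
    r_IN <- rat(post$I, post$N)
    r_IC <- rat(post$I, post$C)
    r_NI <- rat(post$N, post$I)
    r_NC <- rat(post$N, post$C)
    de_novo_I <- pre$I$df < mean_df && post$I$df >= mean_df
    de_novo_N <- pre$N$df < mean_df && post$N$df >= mean_df

    stress <- r_intra_I$mark == "numeric" && r_intra_N$mark == "numeric" &&
      r_intra_I$value >= fold && r_intra_N$value >= fold &&
      r_intra_I$value / r_intra_N$value <= band &&
      r_intra_N$value / r_intra_I$value <= band
    hipv <- de_novo_I ||
      (ratio_satisfied(r_intra_I, fold) && ratio_satisfied(r_IN, fold) &&
         ratio_satisfied(r_IC, fold))
    neighbor <- de_novo_N ||
      (ratio_satisfied(r_intra_N, fold) && ratio_satisfied(r_NI, fold) &&
         ratio_satisfied(r_NC, fold))

    induced_rule <- if (stress) "stress_induced" else if (hipv) "hipv" else
      if (neighbor) "neighbor_induced" else NA_character_
    if (cp %in% core) {
      label <- "constitutive"
      rule <- "constitutive_df"
      secondary <- induced_rule
    } else {
      label <- if (is.na(induced_rule)) "unclassified" else induced_rule
      rule <- if (is.na(induced_rule)) "none" else {
        if (induced_rule == "hipv" && de_novo_I) "hipv_de_novo"
        else if (induced_rule == "neighbor_induced" && de_novo_N)
          "neighbor_de_novo"
        else paste0(induced_rule, "_fold")
      }
      secondary <- NA_character_
    }
    data.frame(
      compound = cp, compound_class = cls[i], label = label,
      secondary = secondary, rule = rule,
      df_pre_I = pre$I$df, df_pre_N = pre$N$df, df_pre_C = pre$C$df,
      df_post_I = post$I$df, df_post_N = post$N$df, df_post_C = post$C$df,
      ratio_I_pre_post = render_mark(r_intra_I, "ALB"),
      ratio_N_pre_post = render_mark(r_intra_N, "ALB"),
      ratio_I_vs_N = render_mark(r_IN, I),
      ratio_I_vs_C = render_mark(r_IC, I),
      ratio_N_vs_I = render_mark(r_NI, N),
      ratio_N_vs_C = render_mark(r_NC, N),
      value_I_pre_post = r_intra_I$value, value_N_pre_post = r_intra_N$value,
      value_I_vs_N = r_IN$value, value_I_vs_C = r_IC$value,
      value_N_vs_I = r_NI$value, value_N_vs_C = r_NC$value,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
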