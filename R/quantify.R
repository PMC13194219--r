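# Calibration, emission-rate normalization and background separation.

#' Fit a calibration curve
#'
#' Ordinary least-squares line area = slope * mass + intercept over the
#' spiked calibration levels of one compound. The intercept is kept free
#' (not forced through the origin) so that any constant adsorbent blank is
#' absorbed rather than biasing the slope.
#'
#' @param levels data.frame with columns `mass_ng` and `area` (2-8 rows
#'   typical; at least 2 distinct masses required).
#' @param compound compound name carried on the curve.
#' @return object of class `calibration_curve`: list with `compound`,
#'   `slope` (counts/ng), `intercept` (counts), `r_squared`, `levels`,
#'   `tentative` (FALSE for a compound's own curve).
#' @export
#' @examples
#' fit_calibration(data.frame(mass_ng = 1:4, area = c(1000, 2000, 3000, 4000)))
fit_calibration <- function(levels, compound = NA_character_) {
  stopifnot(is.data.frame(levels), all(c("mass_ng", "area") %in% names(levels)))
  if (nrow(levels) < 2L || length(unique(levels$mass_ng)) < 2L)
    stop("calibration needs >= 2 distinct mass levels")
  fit <- stats::lm(area ~ mass_ng, data = levels)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((levels$area - mean(levels$area))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(compound = compound,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 levels = levels,
                 tentative = FALSE,
                 surrogate = NA_character_),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve%s: area = %.4g * mass_ng + %.4g (R^2 = %.5f, %d levels)%s\n",
              if (is.na(x$compound)) "" else paste0(" for ", x$compound),
              x$slope, x$intercept, x$r_squared, nrow(x$levels),
              if (isTRUE(x$tentative))
                paste0(" [tentative, via ", x$surrogate, "]") else ""))
  invisible(x)
}

#' Convert component area to mass
#'
#' mass = (area - intercept) / slope, floored at zero. Detections whose
#' back-calculated mass is negative (area below the fitted intercept) are
#' expected for trace-level peaks below the lowest calibration level; they
#' are floored and flagged rather than treated as errors.
#'
#' @param area numeric vector of component areas.
#' @param curve a `calibration_curve`.
#' @return numeric vector of masses (ng) with a logical attribute
#'   `below_calibration` marking floored values.
#' @export
area_to_mass <- function(area, curve) {
  stopifnot(inherits(curve, "calibration_curve"), curve$slope > 0)
  raw <- (area - curve$intercept) / curve$slope
  out <- pmax(raw, 0)
  attr(out, "below_calibration") <- raw < 0
  out
}

#' Normalize an amount to an emission rate
#'
#' rate = amount / (bark_area * duration). With mass input the unit is
#' ng dm^-2 h^-1; with component-area input, area counts dm^-2 h^-1 (the
#' conventional reporting scale is x 10^6 dm^-2 h^-1, handled at report
#' time). Background samples are ambient air and have no enclosed bark
#' surface, so they are never area-normalized.
#'
#' @param amount ng (or counts) collected during the sampling interval.
#' @param sample one design-table row (list or 1-row data.frame) with
#'   `bark_area_dm2`, `duration_h`, `is_background`.
#' @return numeric emission rate(s).
#' @export
to_emission_rate <- function(amount, sample) {
  if (isTRUE(as.logical(sample$is_background)))
    stop("background samples are not area-normalized")
  a <- as.numeric(sample$bark_area_dm2)
  h <- as.numeric(sample$duration_h)
  if (!is.finite(a) || a <= 0) stop("bark_area_dm2 must be > 0")
  if (!is.finite(h) || h <= 0) stop("duration_h must be > 0")
  amount / (a * h)
}

#' Resolve the calibration curve for a compound
#'
#' Compounds without an authentic standard are tentatively quantified via a
#' structurally related compound with similar retention behaviour (surrogate
#' standard). A compound with its own curve uses it untouched; a mapped
#' compound gets the surrogate's curve tagged `tentative`; an unmapped
#' compound without a curve stays in area units (NULL return).
#'
#' @param compound compound name.
#' @param curves named list of `calibration_curve`s (names = compounds).
#' @param mapping data.frame with columns `compound`, `surrogate` (may be
#'   empty).
#' @return a `calibration_curve` or NULL when the compound cannot be
#'   quantified in mass units.
#' @export
surrogate_quantify <- function(compound, curves,
                               mapping = data.frame(compound = character(0),
                                                    surrogate = character(0))) {
  if (compound %in% names(curves)) return(curves[[compound]])
  hit <- mapping$surrogate[mapping$compound == compound]
  if (length(hit) == 1L) {
    if (!hit %in% names(curves))
      stop("surrogate \"", hit, "\" for \"", compound,
           "\" has no calibration curve")
    cv <- curves[[hit]]
    cv$tentative <- TRUE
    cv$surrogate <- hit
    cv$compound <- compound
    return(cv)
  }
  NULL
}

#' Separate trunk volatiles from ubiquitous ambient features
#'
#' Ambient-air background samples taken alongside the enclosure samples
#' define what is "in the air anyway". A feature is retained when, in at
#' least one (location, phase) stratum with background coverage, its median
#' trunk area exceeds `factor` times the stratum's median background area
#' (undetected background samples enter the median as zero). Features never
#' seen in any background sample are always retained.
#'
#' @param peaks feature observation table.
#' @param design design table; rows with `is_background = TRUE` are the
#'   background samples, matched to trunk samples by `location` and phase.
#' @param phases phase table ([default_phases()]).
#' @param factor required trunk/background median excess, >= 1 (default 2).
#' @return character vector of retained feature_ids.
#' @export
background_filter <- function(peaks, design, phases = default_phases(),
                              factor = 2) {
  stopifnot(factor >= 1)
  if (!nrow(peaks)) return(character(0))
  design$phase <- assign_phase(design$day, phases)
  bg <- design[design$is_background, ]
  trunk <- design[!design$is_background, ]
  feats <- sort(unique(peaks$feature_id))
  if (!nrow(bg)) return(feats)
  key <- function(d) paste(d$location, d$phase, sep = "/")
  strata <- intersect(unique(key(bg)), unique(key(trunk)))
  med_area <- function(ids, feat) {
    # median over ALL samples in scope; absent observation counts as 0
    a <- peaks$area[peaks$feature_id == feat & peaks$sample_id %in% ids]
    stats::median(c(a, rep(0, length(ids) - length(a))))
  }
  keep <- vapply(feats, function(f) {
    seen_bg <- any(peaks$feature_id == f & peaks$sample_id %in% bg$sample_id)
    if (!seen_bg) return(TRUE)
    any(vapply(strata, function(s) {
      tr_ids <- trunk$sample_id[key(trunk) == s]
      bg_ids <- bg$sample_id[key(bg) == s]
      if (!length(tr_ids) || !length(bg_ids)) return(FALSE)
      med_area(tr_ids, f) > factor * med_area(bg_ids, f)
    }, logical(1)))
  }, logical(1))
  feats[keep]
}

#' Build the per-compound emission table
#'
#' Joins annotated features to samples, applies calibration (own or
#' surrogate curve) and normalizes to bark area and sampling time. Features
#' without any library match are dropped; compounds without a usable curve
#' are reported in area units. Absence stays encoded as a missing row.
#'
#' @param peaks feature observation table (trunk samples only are used).
#' @param design design table.
#' @param annotations output of [annotate_features()].
#' @param curves named list of `calibration_curve`s.
#' @param surrogates surrogate mapping data.frame (`compound`, `surrogate`).
#' @param phases phase table.
#' @return data.frame: compound, compound_class, tree_id, day, replicate,
#'   phase, sample_id, rate, unit ("ng_per_dm2_h" or "area_per_dm2_h"),
#'   tentative, below_calibration.
#' @export
quantify_emissions <- function(peaks, design, annotations, curves = list(),
                               surrogates = data.frame(compound = character(0),
                                                       surrogate = character(0)),
                               phases = default_phases()) {
  ann <- annotations[!is.na(annotations$best_match), , drop = FALSE]
  trunk <- design[!design$is_background, , drop = FALSE]
  obs <- merge(peaks, ann[, c("feature_id", "best_match", "compound_class")],
               by = "feature_id")
  obs <- merge(obs, trunk[, c("sample_id", "tree_id", "day", "replicate",
                              "bark_area_dm2", "duration_h")],
               by = "sample_id")
  if (!nrow(obs))
    return(data.frame(compound = character(0), compound_class = character(0),
                      tree_id = character(0), day = integer(0),
                      replicate = integer(0), phase = integer(0),
                      sample_id = character(0), rate = numeric(0),
                      unit = character(0), tentative = logical(0),
                      below_calibration = logical(0)))
  out <- lapply(split(obs, obs$best_match), function(g) {
    compound <- g$best_match[1L]
    curve <- surrogate_quantify(compound, curves, surrogates)
    if (is.null(curve)) {
      amount <- g$area
      unit <- "area_per_dm2_h"
      tentative <- FALSE
      below <- rep(FALSE, nrow(g))
    } else {
      amount <- area_to_mass(g$area, curve)
      below <- attr(amount, "below_calibration")
      unit <- "ng_per_dm2_h"
      tentative <- isTRUE(curve$tentative)
    }
    data.frame(compound = compound,
               compound_class = g$compound_class,
               tree_id = g$tree_id, day = g$day, replicate = g$replicate,
               sample_id = g$sample_id,
               rate = as.numeric(amount) / (g$bark_area_dm2 * g$duration_h),
               unit = unit, tentative = tentative,
               below_calibration = below,
               stringsAsFactors = FALSE)
  })
  em <- do.call(rbind, out)
  em$phase <- assign_phase(em$day, phases)
  em <- em[order(em$compound, em$tree_id, em$day, em$replicate),
           c("compound", "compound_class", "tree_id", "day", "replicate",
             "phase", "sample_id", "rate", "unit", "tentative",
             "below_calibration")]
  rownames(em) <- NULL
  em
}

#' Read calibration level tables
#'
#' @param path CSV with columns compound, mass_ng, area.
#' @return named list of `calibration_curve`s.
#' @export
read_calibration <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound", "mass_ng", "area") %in% names(cl)))
    stop("calibration table needs columns compound, mass_ng, area")
  lapply(split(cl, cl$compound), function(g)
    fit_calibration(g[, c("mass_ng", "area")], compound = g$compound[1L]))
}
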