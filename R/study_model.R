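#' trunkvoc: trunk volatile emission analysis
#'
#' Tools for longitudinal TD-GC-MS trunk volatile studies: retention-index
#' annotation, calibrated emission-rate quantification, background
#' separation, detection-frequency / fold-change classification of
#' constitutive and induced volatiles, peak-shaped emission-dynamics
#' modelling, and a synthetic study generator.
#'
#' @keywords internal
"_PACKAGE"

# ---- study phases ----------------------------------------------------------

#' Default experimental phases
#'
#' The study timeline is split into three disjoint periods: acclimation after
#' tree arrival (days 0-8), abiotic stress from pruning and relocation into
#' the quarantine room (days 9-19), and biotic stress after beetles are
#' released onto the infested tree (days 20-188).
#'
#' @param boundaries optional list of length-2 integer vectors, one closed
#'   day interval per phase, ordered and disjoint.
#' @return data.frame with columns `phase_id`, `label`, `day_min`, `day_max`.
#' @export
#' @examples
#' default_phases()
default_phases <- function(boundaries = list(c(0L, 8L), c(9L, 19L), c(20L, 188L))) {
  labels <- c("acclimation", "abiotic_stress", "biotic_stress")
  stopifnot(length(boundaries) >= 1L)
  ph <- data.frame(
    phase_id = seq_along(boundaries),
    label = labels[seq_along(boundaries)],
    day_min = vapply(boundaries, function(b) as.integer(b[1L]), integer(1)),
    day_max = vapply(boundaries, function(b) as.integer(b[2L]), integer(1)),
    stringsAsFactors = FALSE
  )
  validate_phases(ph)
  ph
}

validate_phases <- function(phases) {
  stopifnot(is.data.frame(phases),
            all(c("phase_id", "day_min", "day_max") %in% names(phases)))
  if (any(phases$day_min > phases$day_max))
    stop("phase with day_min > day_max")
  o <- order(phases$day_min)
  if (!identical(o, seq_len(nrow(phases))))
    stop("phases must be sorted by day")
  if (nrow(phases) > 1L &&
      any(phases$day_min[-1L] <= phases$day_max[-nrow(phases)]))
    stop("phases must be disjoint")
  invisible(phases)
}

#' Assign study days to experimental phases
#'
#' @param day integer vector of days since tree arrival (day 0 = arrival).
#' @param phases phase table as returned by [default_phases()].
#' @return integer vector of phase ids.
#' @export
#' @examples
#' assign_phase(c(5, 19, 20))
assign_phase <- function(day, phases = default_phases()) {
  validate_phases(phases)
  day <- as.integer(day)
  idx <- vapply(day, function(d) {
    hit <- which(d >= phases$day_min & d <= phases$day_max)
    if (length(hit) != 1L)
      stop("day ", d, " is outside the study window (",
           min(phases$day_min), "-", max(phases$day_max), ")")
    hit
  }, integer(1))
  phases$phase_id[idx]
}

# ---- table I/O -------------------------------------------------------------

.design_cols <- c("sample_id", "tree_id", "day", "replicate", "bark_area_dm2",
                  "duration_h", "flow_ml_min", "is_background", "location")
.peaks_cols <- c("sample_id", "feature_id", "rt_min", "area")

#' Read the study design table
#'
#' One row per enclosure sampling event. `is_background` marks ambient-air
#' samples; `location` is `outside` or `inside_quarantine`. Absent compounds
#' are encoded as missing rows in the peak table, never as zero areas.
#'
#' @param path CSV file with columns sample_id, tree_id, day, replicate,
#'   bark_area_dm2, duration_h, flow_ml_min, is_background, location.
#' @return data.frame of sample records.
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.design_cols, names(d))
  if (length(miss))
    stop("design table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  d$day <- as.integer(d$day)
  d$replicate <- as.integer(d$replicate)
  d$is_background <- as.logical(d$is_background)
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id in design table")
  if (any(d$day < 0L)) stop("negative day in design table")
  trunk <- !d$is_background
  if (any(trunk & (!is.finite(d$bark_area_dm2) | d$bark_area_dm2 <= 0)))
    stop("trunk samples require bark_area_dm2 > 0")
  if (any(!is.finite(d$duration_h) | d$duration_h <= 0))
    stop("duration_h must be > 0")
  d
}

#' Read the component (peak) table
#'
#' @param path CSV file with columns sample_id, feature_id, rt_min, area and
#'   optionally match_score.
#' @return data.frame of feature observations.
#' @export
read_peaks <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.peaks_cols, names(p))
  if (length(miss))
    stop("peak table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!"match_score" %in% names(p)) p$match_score <- rep(NA_real_, nrow(p))
  if (nrow(p)) {
    if (any(!is.finite(p$rt_min) | p$rt_min <= 0))
      stop("rt_min must be > 0")
    if (any(!is.finite(p$area) | p$area <= 0))
      stop("area must be > 0 (absence is a missing row, not zero)")
  }
  p
}

#' Load and cross-check design and peak tables
#'
#' @param design_path,peaks_path CSV paths (see [read_design()],
#'   [read_peaks()]).
#' @return list with elements `design` and `peaks`; every peak row's
#'   sample_id is guaranteed to resolve to a design row.
#' @export
load_tables <- function(design_path, peaks_path) {
  design <- read_design(design_path)
  peaks <- read_peaks(peaks_path)
  if (nrow(peaks)) {
    bad <- !(peaks$sample_id %in% design$sample_id)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("peak row ", i, " references unknown sample \"",
           peaks$sample_id[i], "\"")
    }
  }
  list(design = design, peaks = peaks)
}

#' Write a study bundle to CSV files
#'
#' @param study named list of data.frames (as from [generate_study()]).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written (named by table).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(study), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(study[[nm]], path, row.names = FALSE, quote = TRUE)
    path
  }, character(1))
  invisible(paths)
}
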