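# Linear retention index (LRI) computation and library matching.

#' Construct an n-alkane ladder
#'
#' Retention times of co-analysed n-alkanes anchor the linear retention
#' index scale: the index of alkane CnH2n+2 is 100*n by definition, and
#' analytes between two alkanes are indexed by linear interpolation of
#' retention time (van Den Dool & Kratz).
#'
#' @param carbon integer carbon numbers, strictly increasing.
#' @param rt_min retention times in minutes, strictly increasing.
#' @return data.frame with columns `carbon`, `rt_min`.
#' @export
alkane_ladder <- function(carbon, rt_min) {
  carbon <- as.integer(carbon)
  if (length(carbon) < 2L || length(carbon) != length(rt_min))
    stop("ladder needs >= 2 (carbon, rt) pairs of equal length")
  if (any(diff(carbon) <= 0L)) stop("carbon numbers must be strictly increasing")
  if (any(diff(rt_min) <= 0)) stop("retention times must be strictly increasing")
  data.frame(carbon = carbon, rt_min = as.numeric(rt_min))
}

#' Read an alkane ladder table
#' @param path CSV with columns carbon_number, rt_min.
#' @return data.frame as from [alkane_ladder()].
#' @export
read_alkanes <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("carbon_number", "rt_min") %in% names(a)))
    stop("alkane table needs columns carbon_number, rt_min")
  a <- a[order(a$carbon_number), ]
  alkane_ladder(a$carbon_number, a$rt_min)
}

#' Compute linear retention indices
#'
#' LRI = 100*n + 100*(t - t_n)/(t_{n+1} - t_n) for the alkanes n, n+1
#' bracketing the analyte's retention time t (generalised to ladders with
#' missing carbon numbers by scaling with the carbon gap). Indices of ladder
#' alkanes are exact multiples of 100 and the index is strictly increasing
#' in retention time.
#'
#' @param rt retention time(s) in minutes.
#' @param ladder data.frame from [alkane_ladder()].
#' @param extrapolate if TRUE, retention times outside the ladder span are
#'   extrapolated linearly from the terminal segment (indices below the first
#'   alkane are then possible); by default they are an error.
#' @return numeric vector of retention indices.
#' @export
#' @examples
#' lad <- alkane_ladder(9:10, c(9.0, 11.4))
#' compute_lri(9.6, lad)  # 925
compute_lri <- function(rt, ladder, extrapolate = FALSE) {
  stopifnot(is.data.frame(ladder), nrow(ladder) >= 2L)
  tl <- ladder$rt_min
  cn <- ladder$carbon
  vapply(as.numeric(rt), function(t) {
    if (!is.finite(t)) stop("non-finite retention time")
    i <- if (t < tl[1L]) {
      if (!extrapolate)
        stop("retention time ", t, " min below the ladder span; ",
             "set extrapolate = TRUE to index it")
      1L
    } else if (t > tl[length(tl)]) {
      if (!extrapolate)
        stop("retention time ", t, " min above the ladder span; ",
             "set extrapolate = TRUE to index it")
      length(tl) - 1L
    } else {
      max(1L, findInterval(t, tl, rightmost.closed = TRUE))
    }
    100 * cn[i] + 100 * (cn[i + 1L] - cn[i]) * (t - tl[i]) / (tl[i + 1L] - tl[i])
  }, numeric(1))
}

#' Invert the retention-index mapping
#'
#' Back-computes the retention time at which an analyte of a given index
#' elutes, by piecewise-linear inversion of the ladder. Used by the
#' synthetic study generator; inverse of [compute_lri()] on the ladder span.
#'
#' @param lri retention index (or vector).
#' @inheritParams compute_lri
#' @return retention times in minutes.
#' @export
invert_lri <- function(lri, ladder, extrapolate = FALSE) {
  idx <- 100 * ladder$carbon
  lo <- idx[1L]; hi <- idx[length(idx)]
  vapply(as.numeric(lri), function(v) {
    if ((v < lo || v > hi) && !extrapolate)
      stop("index ", v, " outside ladder span")
    i <- min(max(findInterval(v, idx, rightmost.closed = TRUE), 1L),
             length(idx) - 1L)
    ladder$rt_min[i] + (v - idx[i]) / (idx[i + 1L] - idx[i]) *
      (ladder$rt_min[i + 1L] - ladder$rt_min[i])
  }, numeric(1))
}

#' Read a reference compound library
#'
#' Columns: name, cas, formula, lri_lit, compound_class, id_tier. The
#' identification tier encodes how a compound was identified: M = mass
#' spectrum, R = retention index, S = authentic standard (e.g. "MRS", "MR").
#'
#' @param path CSV path.
#' @return data.frame of compound records.
#' @export
read_library <- function(path) {
  l <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "lri_lit", "compound_class", "id_tier")
  miss <- setdiff(need, names(l))
  if (length(miss))
    stop("compound library missing column(s): ", paste(miss, collapse = ", "))
  if (!"cas" %in% names(l)) l$cas <- ""
  if (!"formula" %in% names(l)) l$formula <- ""
  if (any(!is.na(l$lri_lit) & l$lri_lit <= 0)) stop("lri_lit must be > 0")
  if (any(!nzchar(l$id_tier))) stop("id_tier must be non-empty")
  l
}

#' Match an experimental retention index against a compound library
#'
#' Candidates within `tolerance` index units are returned sorted by
#' ascending absolute index difference; ties are broken lexicographically by
#' compound name so output order is deterministic. Spectral match scores,
#' where present upstream, never override the index filter.
#'
#' @param lri_exp experimental retention index (scalar).
#' @param library data.frame from [read_library()].
#' @param tolerance maximum |LRI_exp - LRI_lit| in index units. The default
#'   of 15 units comfortably covers typical library-vs-column offsets of
#'   nonpolar phases (differences up to ~12 units occur for sesquiterpenes).
#' @return data.frame of candidate rows with an extra `delta_lri` column;
#'   zero rows when nothing matches.
#' @export
match_library <- function(lri_exp, library, tolerance = 15) {
  stopifnot(length(lri_exp) == 1L, tolerance > 0)
  if (!nrow(library)) return(cbind(library, delta_lri = numeric(0)))
  delta <- lri_exp - library$lri_lit
  keep <- !is.na(delta) & abs(delta) <= tolerance
  out <- library[keep, , drop = FALSE]
  out$delta_lri <- delta[keep]
  out[order(abs(out$delta_lri), out$name), , drop = FALSE]
}

#' Annotate features with retention indices and library matches
#'
#' Each feature's retention time is summarised as the median over its
#' observations, indexed against the alkane ladder, and matched against the
#' library; the top-ranked candidate (if any) becomes the annotation.
#'
#' @param peaks feature observation table (see [read_peaks()]).
#' @param ladder alkane ladder.
#' @param library compound library.
#' @param tolerance index tolerance passed to [match_library()].
#' @param extrapolate passed to [compute_lri()].
#' @return data.frame: feature_id, rt_min (median), lri_exp, best_match,
#'   delta_lri, compound_class, id_tier (NA where unmatched).
#' @export
annotate_features <- function(peaks, ladder, library, tolerance = 15,
                              extrapolate = FALSE) {
  if (!nrow(peaks))
    return(data.frame(feature_id = character(0), rt_min = numeric(0),
                      lri_exp = numeric(0), best_match = character(0),
                      delta_lri = numeric(0), compound_class = character(0),
                      id_tier = character(0)))
  rt <- tapply(peaks$rt_min, peaks$feature_id, stats::median)
  ann <- data.frame(feature_id = names(rt), rt_min = as.numeric(rt),
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$rt_min, ann$feature_id), ]
  ann$lri_exp <- compute_lri(ann$rt_min, ladder, extrapolate = extrapolate)
  hit <- lapply(ann$lri_exp, match_library, library = library,
                tolerance = tolerance)
  ann$best_match <- vapply(hit, function(h)
    if (nrow(h)) h$name[1L] else NA_character_, character(1))
  ann$delta_lri <- vapply(hit, function(h)
    if (nrow(h)) h$delta_lri[1L] else NA_real_, numeric(1))
  ann$compound_class <- vapply(hit, function(h)
    if (nrow(h)) h$compound_class[1L] else NA_character_, character(1))
  ann$id_tier <- vapply(hit, function(h)
    if (nrow(h)) h$id_tier[1L] else NA_character_, character(1))
  rownames(ann) <- NULL
  ann
}
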