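# Temporal emission dynamics: daily aggregation, asymmetric peak-function
# fitting, Kendall rank-correlation grouping, Kruskal-Wallis and Dunn tests.

#' Aggregate replicate measurements per day
#'
#' Double determinations taken on the same day are averaged; variability is
#' reported as the standard error of the mean (sample SD / sqrt(k)), which
#' for duplicate samples equals |a - b| / 2. SEM is undefined (NA) for
#' single determinations.
#'
#' @param day numeric vector of sampling days.
#' @param rate emission rates, same length as `day`.
#' @return data.frame with columns `day`, `mean`, `sem`, `n`, sorted by day.
#' @export
#' @examples
#' daily_aggregate(c(1, 1, 2), c(4, 6, 7))
daily_aggregate <- function(day, rate) {
  stopifnot(length(day) == length(rate), length(day) >= 1L)
  sp <- split(rate, day)
  out <- data.frame(
    day = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1)),
    n = lengths(sp))
  out <- out[order(out$day), ]
  rownames(out) <- NULL
  out
}

#' Evaluate the 'Extreme' peak function
#'
#' The four-parameter asymmetric peak model
#' \deqn{y = y_0 + A e^{-e^{-z} - z + 1}, \quad z = (x - x_c)/w}
#' describes a rise-and-decay emission pulse: `xc` is the peak day, `y0`
#' the emission offset, `A` the peak amplitude and `w` the peak width
#' (days). At x = xc the model attains its maximum y0 + A; for large x it
#' decays back to the offset y0.
#'
#' @param x day(s) at which to evaluate.
#' @param y0,A,xc,w model parameters (w > 0).
#' @return numeric vector of rates.
#' @export
#' @examples
#' eval_extreme(34, y0 = 1, A = 10, xc = 34, w = 8)  # 11
eval_extreme <- function(x, y0, A, xc, w) {
  stopifnot(w > 0)
  z <- (x - xc) / w
  y0 + A * exp(-exp(-z) - z + 1)
}

extreme_start <- function(day, y) {
  y0 <- min(y)
  A <- max(y) - y0
  xc <- day[which.max(y)]
  w <- max(sum(y > y0 + A / 2) / 2, 1)
  list(y0 = y0, A = A, xc = xc, w = w)
}

#' Fit the 'Extreme' peak function to an emission series
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [eval_extreme()]
#' against daily mean emissions. Starting values default to a robust
#' single-peak heuristic (peak day = day of the series maximum, offset =
#' series minimum, amplitude = range, width = half the number of days above
#' half height, floored at one day); on non-convergence a small set of
#' deterministically perturbed starts is tried.
#'
#' @param day sampling days (>= 5 points).
#' @param y daily mean rates.
#' @param init optional named list/vector with starting values y0, A, xc, w.
#' @return object of class `extreme_fit`: list with `params` (y0, A, xc,
#'   w), `adj_r2` (adjusted for the 4 model parameters), `r2`, `converged`,
#'   `n_points`, `fitted`, `data`.
#' @export
fit_extreme <- function(day, y, init = NULL) {
  stopifnot(length(day) == length(y))
  keep <- is.finite(day) & is.finite(y)
  day <- day[keep]; y <- y[keep]
  if (length(day) < 5L) stop("need >= 5 points to fit a 4-parameter peak")
  if (stats::sd(y) == 0) stop("flat series: no variance to fit")
  s0 <- if (is.null(init)) extreme_start(day, y) else as.list(init)[c("y0", "A", "xc", "w")]
  # deterministic multi-start: perturb width / position on failure
  starts <- list(
    s0,
    within(s0, {w <- w * 2.5}),
    within(s0, {w <- w * 0.5; xc <- xc - w}),
    within(s0, {w <- max(diff(range(day)) / 6, 1); xc <- mean(range(day))}))
  dat <- data.frame(x = day, y = y)
  fit <- NULL
  for (st in starts) {
    st$w <- max(st$w, 1)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ y0 + A * exp(-exp(-(x - xc) / w) - (x - xc) / w + 1),
        data = dat, start = st,
        lower = c(y0 = -Inf, A = -Inf, xc = -Inf, w = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  n <- length(y)
  if (is.null(fit)) {
    out <- list(params = s0, r2 = NA_real_, adj_r2 = NA_real_,
                converged = FALSE, n_points = n,
                fitted = rep(NA_real_, n), data = dat)
    class(out) <- "extreme_fit"
    return(out)
  }
  p <- as.list(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - 4 - 1)
  out <- list(params = p, r2 = r2, adj_r2 = adj, converged = TRUE,
              n_points = n, fitted = stats::fitted(fit), data = dat)
  class(out) <- "extreme_fit"
  out
}

#' @export
print.extreme_fit <- function(x, ...) {
  cat("'Extreme' peak fit", if (!x$converged) "(did not converge)", "\n")
  if (x$converged) {
    with(x$params, cat(sprintf(
      "  y0 = %.4g, A = %.4g, xc = %.4g days, w = %.4g days\n", y0, A, xc, w)))
    cat(sprintf("  n = %d, adj. R^2 = %.5f\n", x$n_points, x$adj_r2))
  }
  invisible(x)
}

#' @export
coef.extreme_fit <- function(object, ...) {
  unlist(object$params)[c("y0", "A", "xc", "w")]
}

#' @export
predict.extreme_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  do.call(eval_extreme, c(list(x = x), object$params))
}

#' @export
residuals.extreme_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
summary.extreme_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Kendall rank correlation between two emission series
#'
#' Tie-corrected tau-b with a two-sided p-value (normal approximation, as
#' ties from censored days make the exact distribution unavailable).
#'
#' @param x,y paired series values (same days), length >= 3.
#' @return list with `tau` and `p`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need >= 3 paired observations")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Group emission series by Kendall correlation
#'
#' Pairwise tau-b is computed on the days shared by each pair of series
#' (undetected days are dropped, not zero-filled). Compound pairs with
#' tau >= `tau_min` and p < `alpha` are linked; single-linkage connected
#' components form the temporal-pattern groups, and unlinked compounds stay
#' singletons.
#'
#' @param series named list of data.frames with columns `day`, `mean` (one
#'   per compound).
#' @param tau_min minimum tau to link two compounds (default 0.5).
#' @param alpha significance level for the link (default 0.05).
#' @param min_shared minimum number of shared days for a computable pair.
#' @return list with `tau` (matrix), `p` (matrix), `groups` (data.frame
#'   compound/group).
#' @export
tau_group <- function(series, tau_min = 0.5, alpha = 0.05, min_shared = 3L) {
  nm <- names(series)
  k <- length(series)
  tau <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(tau) <- 1; diag(p) <- 0
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    shared <- intersect(series[[i]]$day, series[[j]]$day)
    if (length(shared) < min_shared) next
    xi <- series[[i]]$mean[match(shared, series[[i]]$day)]
    yj <- series[[j]]$mean[match(shared, series[[j]]$day)]
    if (stats::sd(xi) == 0 || stats::sd(yj) == 0) next
    kt <- kendall_tau(xi, yj)
    tau[i, j] <- tau[j, i] <- kt$tau
    p[i, j] <- p[j, i] <- kt$p
    if (is.finite(kt$tau) && kt$tau >= tau_min && kt$p < alpha) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  groups <- data.frame(compound = nm,
                       group = as.integer(factor(comp, levels = unique(comp))),
                       stringsAsFactors = FALSE)
  list(tau = tau, p = p, groups = groups)
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with a chi-square p-value (k - 1 degrees of
#' freedom). Completely tied data (every value identical) are a degenerate
#' no-signal case and return H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return list with `H`, `p`, `df`.
#' @export
kw_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 1L)) stop("every group needs >= 1 observation")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post hoc test
#'
#' Pairwise comparisons of mean ranks after a Kruskal-Wallis test:
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)) with tie
#' correction T = sum(t^3 - t) / (12 (N - 1)), two-sided normal p-values,
#' optionally multiplicity-adjusted.
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @param adjust p-value adjustment method (default "none"; any
#'   [stats::p.adjust()] method, e.g. "holm").
#' @return data.frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = "none") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 1L)) stop("every group needs >= 1 observation")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  Tcorr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  pairs <- utils::combn(length(groups), 2L)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    if (se > 0) (rbar[[as.character(i)]] - rbar[[as.character(j)]]) / se else 0
  }, numeric(1))
  out <- data.frame(group1 = nm[pairs[1L, ]], group2 = nm[pairs[2L, ]],
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}
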