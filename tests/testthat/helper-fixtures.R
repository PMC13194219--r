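# In-code fixtures: a hand-sized study design and emission rows for rule
# tests, and independent oracles used across test files.

# design with three maples, duplicate samples on pre-stress and
# biotic-stress days (default phases: pre = phases 1-2, post = phase 3)
mini_design <- function(trees = c("ApC", "ApI", "ApN"),
                        pre_days = c(0, 2, 4, 6, 10, 12),
                        post_days = c(30, 60, 90, 120, 150),
                        reps = 2) {
  g <- expand.grid(tree_id = trees, day = c(pre_days, post_days),
                   replicate = seq_len(reps), stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_d%03d_r%d", g$tree_id, g$day, g$replicate)
  g$bark_area_dm2 <- 2
  g$duration_h <- 1.5
  g$flow_ml_min <- 30
  g$is_background <- FALSE
  g$location <- ifelse(g$tree_id == "ApC", "outside", "inside_quarantine")
  g[order(g$tree_id, g$day, g$replicate), ]
}

# emission rows for one compound: `detect` rows of the (tree, scope) design
# subset get rate `rate` (vector recycled); scope = "pre" or "post"
mini_emissions <- function(design, compound, tree, scope, rate,
                           detect = NULL, compound_class = "monoterpenoid") {
  sub <- design[design$tree_id == tree, ]
  ph <- assign_phase(sub$day)
  sub <- sub[if (scope == "pre") ph <= 2 else ph == 3, ]
  if (is.null(detect)) detect <- nrow(sub)
  sub <- sub[seq_len(detect), , drop = FALSE]
  data.frame(compound = compound, compound_class = compound_class,
             tree_id = tree, day = sub$day, replicate = sub$replicate,
             phase = assign_phase(sub$day), sample_id = sub$sample_id,
             rate = rep_len(rate, nrow(sub)), unit = "ng_per_dm2_h",
             tentative = FALSE, below_calibration = FALSE,
             stringsAsFactors = FALSE)
}

# O(n^2) Kendall pair-counting oracle; tau-b closed form with ties
tau_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# tie-corrected Kruskal-Wallis H by the rank formula (independent of
# stats::kruskal.test)
kw_oracle_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) -
    3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# closed-form simple linear regression (normal equations)
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - b * mean(x), slope = b)
}
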