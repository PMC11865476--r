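# Common-PC-space projection of embeddings and distribution-shift
# quantification: a single PCA basis is fit on a declared reference set and
# every condition group is projected with that same basis, so PC coordinates
# are comparable across groups. Shifts are quantified by threshold-proportion
# rules on (PC1, PC2) with two-proportion Z-tests, kernel-density maps, and
# axis-outlier accounting for display limits.

#' Fit a 2-D PCA projection basis on a reference embedding set
#'
#' Centers the reference embeddings and takes the two leading principal
#' components. Loading signs are fixed by the convention that each loading's
#' largest-magnitude coefficient is positive, so projections (and any PC
#' thresholds defined on them) are reproducible across runs.
#'
#' @param embeddings numeric matrix, rows = items, columns = features.
#' @return a `projection_basis`: list with `center`, `loadings` (features x
#'   2, orthonormal), `var_explained` (fractions for PC1, PC2), `sdev`.
#' @export
fit_pca <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 3) stopf("PCA needs at least 3 rows")
  if (all(apply(embeddings, 2, function(c) var(c) == 0)))
    stopf("degenerate input: all rows identical (zero variance)")
  pc <- prcomp(embeddings, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12)
    stopf("embeddings are rank-deficient; cannot extract two components")
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(load2[, j]))
    if (load2[k, j] < 0) load2[, j] <- -load2[, j]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(center = pc$center, loadings = load2,
                 var_explained = ve[1:2], sdev = pc$sdev[1:2]),
            class = "projection_basis")
}

#' @export
print.projection_basis <- function(x, ...) {
  cat(sprintf("<projection_basis: %d features; PC1 %.1f%%, PC2 %.1f%% of variance>\n",
              nrow(x$loadings), 100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' Project embeddings onto a common PC basis
#'
#' Centered dot products with the basis loadings. All groups to be compared
#' must be projected with the same basis.
#'
#' @param embeddings matrix rows = items, columns = features.
#' @param basis a [fit_pca()] basis.
#' @return data.frame with columns `PC1`, `PC2`.
#' @export
project_embeddings <- function(embeddings, basis) {
  stopifnot(inherits(basis, "projection_basis"))
  embeddings <- as.matrix(embeddings)
  if (ncol(embeddings) != nrow(basis$loadings))
    stopf("embedding dimensionality (%d) does not match the basis (%d)",
          ncol(embeddings), nrow(basis$loadings))
  sc <- sweep(embeddings, 2, basis$center) %*% basis$loadings
  data.frame(PC1 = sc[, 1], PC2 = sc[, 2])
}

#' 2-D kernel density map of PC coordinates
#'
#' Gaussian-kernel density on a regular grid spanning the data range plus
#' three bandwidths, with the normal-reference rule-of-thumb bandwidth scaled
#' by `bandwidth_adjust` (default 2, a deliberately smooth display setting).
#' Contour levels start at `density_threshold` of the maximum density
#' (default 0.1), i.e. the lowest 10% of the density is not contoured.
#'
#' @param pc data.frame with `PC1`, `PC2` (at least 10 points).
#' @param bandwidth_adjust scale factor on the rule-of-thumb bandwidth.
#' @param density_threshold lowest contoured density as a fraction of the max.
#' @param grid_n grid resolution per axis.
#' @param n_levels number of contour levels.
#' @return list with `x`, `y`, `z` (density grid, integrates to 1), `levels`
#'   (contour levels above the threshold), `bandwidth`.
#' @export
kde_map <- function(pc, bandwidth_adjust = 2, density_threshold = 0.1,
                    grid_n = 200L, n_levels = 10L) {
  if (nrow(pc) < 10) stopf("kde_map needs at least 10 points")
  h <- c(MASS::bandwidth.nrd(pc$PC1), MASS::bandwidth.nrd(pc$PC2)) * bandwidth_adjust
  if (any(h <= 0)) stopf("degenerate bandwidth (constant coordinate)")
  lims <- c(min(pc$PC1) - 3 * h[1], max(pc$PC1) + 3 * h[1],
            min(pc$PC2) - 3 * h[2], max(pc$PC2) + 3 * h[2])
  k <- MASS::kde2d(pc$PC1, pc$PC2, h = h, n = grid_n, lims = lims)
  zmax <- max(k$z)
  levels <- seq(density_threshold * zmax, zmax, length.out = n_levels + 1)[-(n_levels + 1)]
  list(x = k$x, y = k$y, z = k$z, levels = levels, bandwidth = h)
}

#' Threshold rule over PC coordinates
#'
#' A named conjunction of inequalities on PC1/PC2, e.g. "PC1 > 50",
#' "PC2 > 15", or the joint "PC1 > 100 and PC2 > 0".
#'
#' @param pc1_gt,pc1_lt,pc2_gt,pc2_lt finite bounds; `NULL` to omit.
#' @param name optional rule label.
#' @return object of class `threshold_rule`, callable on a PC data.frame.
#' @export
threshold_rule <- function(pc1_gt = NULL, pc1_lt = NULL, pc2_gt = NULL,
                           pc2_lt = NULL, name = NULL) {
  parts <- list(pc1_gt = pc1_gt, pc1_lt = pc1_lt, pc2_gt = pc2_gt, pc2_lt = pc2_lt)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stopf("threshold_rule needs at least one bound")
  stopifnot(all(vapply(parts, is.finite, logical(1))))
  if (is.null(name)) {
    lab <- c(pc1_gt = "PC1 > %g", pc1_lt = "PC1 < %g",
             pc2_gt = "PC2 > %g", pc2_lt = "PC2 < %g")
    name <- paste(sprintf(lab[names(parts)], unlist(parts)), collapse = " & ")
  }
  structure(list(parts = parts, name = name), class = "threshold_rule")
}

rule_satisfied <- function(rule, pc) {
  ok <- rep(TRUE, nrow(pc))
  p <- rule$parts
  if (!is.null(p$pc1_gt)) ok <- ok & pc$PC1 > p$pc1_gt
  if (!is.null(p$pc1_lt)) ok <- ok & pc$PC1 < p$pc1_lt
  if (!is.null(p$pc2_gt)) ok <- ok & pc$PC2 > p$pc2_gt
  if (!is.null(p$pc2_lt)) ok <- ok & pc$PC2 < p$pc2_lt
  ok
}

#' Per-group threshold proportions with CIs and pairwise Z-tests
#'
#' For each group, the proportion of points satisfying the rule with its
#' normal-approximation 95% CI; for each requested group pair, a
#' two-proportion Z-test on the difference.
#'
#' @param pc data.frame with `PC1`, `PC2`.
#' @param groups group label per row.
#' @param rule a [threshold_rule()].
#' @param pairs list of length-2 character vectors of group names to test;
#'   default: every group against the first (reference) group.
#' @return list with `proportions` (data.frame: group, n, k, proportion,
#'   ci_lower, ci_upper) and `tests` (data.frame: group1, group2, z, p_value).
#' @export
threshold_proportions <- function(pc, groups, rule, pairs = NULL) {
  stopifnot(inherits(rule, "threshold_rule"), nrow(pc) == length(groups))
  groups <- as.character(groups)
  glev <- unique(groups)
  sat <- rule_satisfied(rule, pc)
  props <- do.call(rbind, lapply(glev, function(g) {
    idx <- groups == g
    n <- sum(idx)
    if (n == 0) stopf("empty group '%s'", g)
    k <- sum(sat[idx])
    ci <- proportion_ci(k / n, n)
    data.frame(group = g, n = n, k = k, proportion = k / n,
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) && length(glev) > 1)
    pairs <- lapply(glev[-1], function(g) c(glev[1], g))
  tests <- NULL
  if (length(pairs)) {
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      a <- props[props$group == pr[1], ]; b <- props[props$group == pr[2], ]
      if (!nrow(a) || !nrow(b)) stopf("unknown group in pair: %s/%s", pr[1], pr[2])
      pooled <- (a$k + b$k) / (a$n + b$n)
      if (pooled == 0 || pooled == 1) {
        # both groups at the same boundary: no evidence of a difference
        zt <- list(statistic = NA_real_, p_value = 1)
      } else {
        zt <- two_proportion_ztest(a$k, a$n, b$k, b$n)
      }
      data.frame(group1 = pr[1], group2 = pr[2], z = zt$statistic,
                 p_value = zt$p_value, stringsAsFactors = FALSE)
    }))
  }
  list(rule = rule$name, proportions = props, tests = tests)
}

#' Count points excluded by display axis limits
#'
#' Display-only accounting of outliers beyond axis limits; statistics are
#' always computed on the full data. Rules are applied in declaration order
#' and each point is charged to the first rule it violates, so the per-rule
#' counts are disjoint and sum to the total.
#'
#' @param pc data.frame with `PC1`, `PC2`.
#' @param limits named list in declaration order; names among `pc1_max`,
#'   `pc1_min`, `pc2_max`, `pc2_min`.
#' @return list with `per_rule` (named counts), `total`, and `keep` (logical
#'   vector of points inside all limits).
#' @export
axis_outlier_counts <- function(pc, limits) {
  stopifnot(all(names(limits) %in% c("pc1_max", "pc1_min", "pc2_max", "pc2_min")),
            all(vapply(limits, is.finite, logical(1))))
  assigned <- rep(FALSE, nrow(pc))
  per_rule <- stats::setNames(integer(length(limits)), names(limits))
  for (nm in names(limits)) {
    viol <- switch(nm,
                   pc1_max = pc$PC1 > limits[[nm]],
                   pc1_min = pc$PC1 < limits[[nm]],
                   pc2_max = pc$PC2 > limits[[nm]],
                   pc2_min = pc$PC2 < limits[[nm]])
    hit <- viol & !assigned
    per_rule[nm] <- sum(hit)
    assigned <- assigned | viol
  }
  list(per_rule = per_rule, total = sum(assigned), keep = !assigned)
}

#' Quantile-based threshold helper (extension)
#'
#' Convenience for choosing a PC threshold as an upper quantile of a held-out
#' reference group, so that shift tests on other groups are not chosen on the
#' data they test. This is a pragmatic extension, not a published convention.
#'
#' @param pc_reference PC data.frame of the held-out reference set.
#' @param axis `"PC1"` or `"PC2"`.
#' @param q upper quantile (default 0.95).
#' @return a [threshold_rule()].
#' @export
quantile_threshold_rule <- function(pc_reference, axis = c("PC1", "PC2"), q = 0.95) {
  axis <- match.arg(axis)
  cut <- quantile(pc_reference[[axis]], q, names = FALSE)
  if (axis == "PC1") threshold_rule(pc1_gt = cut) else threshold_rule(pc2_gt = cut)
}
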