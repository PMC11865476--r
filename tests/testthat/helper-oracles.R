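# Independent brute-force oracles used across test files. Each one is a
# straight-from-definition reimplementation, deliberately naive and sharing
# no code with the package internals.

# Otsu: exhaustive search over all candidate thresholds, maximizing the
# between-class variance w0*w1*(mu0-mu1)^2 directly.
oracle_otsu <- function(x) {
  v <- as.vector(x)
  lev <- sort(unique(v))
  best <- -Inf; best_t <- lev[1]
  for (t in lev[-length(lev)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  best_t
}

# Perceptual blur, re-derived from its definition: per axis, uniformly
# re-blur; compare absolute Sobel-smoothed directional gradients; sum the
# positive gradient loss over the interior; return the worse axis.
oracle_blur <- function(x, h_size = 11L) {
  pad_reflect <- function(m, before, after) {
    rbind(m[rev(seq_len(before)), , drop = FALSE], m,
          m[nrow(m) + 1 - seq_len(after), , drop = FALSE])
  }
  conv_rows <- function(m, k) {
    half <- (length(k) - 1) %/% 2
    mp <- pad_reflect(m, half, length(k) - 1 - half)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + nrow(m) - 1), , drop = FALSE]
    out
  }
  conv_cols <- function(m, k) t(conv_rows(t(m), k))
  sobel <- function(m, axis) {
    if (axis == 1) conv_cols(conv_rows(m, c(1, 0, -1)), c(1, 2, 1))
    else conv_rows(conv_cols(m, c(1, 0, -1)), c(1, 2, 1))
  }
  vals <- numeric(2)
  ri <- 3:(nrow(x) - 1); ci <- 3:(ncol(x) - 1)
  for (axis in 1:2) {
    filt <- if (axis == 1) conv_rows(x, rep(1 / h_size, h_size))
            else conv_cols(x, rep(1 / h_size, h_size))
    gs <- abs(sobel(x, axis)); gb <- abs(sobel(filt, axis))
    tt <- gs - gb; tt[tt < 0] <- 0
    m1 <- sum(gs[ri, ci])
    vals[axis] <- if (m1 == 0) 1 else abs(m1 - sum(tt[ri, ci])) / m1
  }
  max(vals)
}

# Naive per-criterion re-check of a filter profile on one record.
oracle_filter_pass <- function(record, profile) {
  qc <- record$qc; pr <- record$props
  ok <- TRUE
  chk <- function(cond) ok <<- ok && isTRUE(cond)
  if (!is.null(profile$area_min)) chk(pr$area >= profile$area_min)
  if (!is.null(profile$area_max)) chk(pr$area <= profile$area_max)
  if (!is.null(profile$minor_axis_min)) chk(pr$minor_axis_length >= profile$minor_axis_min)
  if (!is.null(profile$major_axis_max)) chk(pr$major_axis_length <= profile$major_axis_max)
  if (!is.null(profile$eccentricity_max)) chk(pr$eccentricity <= profile$eccentricity_max)
  for (ch in names(profile$intensity_min)) chk(qc$mean[[ch]] >= profile$intensity_min[[ch]])
  for (ch in names(profile$center_intensity_min))
    chk(qc$center_mean[[ch]] >= profile$center_intensity_min[[ch]])
  for (ch in names(profile$blur_max)) chk(qc$blur[[ch]] <= profile$blur_max[[ch]])
  for (ch in names(profile$sharpness_min)) chk(qc$sharpness[[ch]] >= profile$sharpness_min[[ch]])
  for (ch in profile$low_contrast_channels) chk(!qc$low_contrast[[ch]])
  ok
}

# Build a synthetic nucleus_record-like list with chosen props and qc values
# (no rendering), for filter-engine randomized testing.
make_fake_record <- function(props, qc, channels = c("DAPI", "EdU", "PCNA")) {
  crop <- array(1000, c(16, 16, length(channels)),
                dimnames = list(NULL, NULL, channels))
  rec <- list(crop = crop, mask = matrix(TRUE, 16, 16), props = props,
              source = list(field_id = "fake", label = 1L),
              touches_border = FALSE, qc = structure(qc, class = "qc_metrics"),
              labels = list())
  class(rec) <- "nucleus_record"
  rec
}

# Permutation p-value for the chi-squared homogeneity statistic: shuffle
# item-level group assignments, recompute the statistic, two-sided-by-design
# upper tail.
oracle_perm_chi2 <- function(counts, n_perm = 2000L, seed = 1L) {
  groups <- rep(rownames(counts), rowSums(counts))
  classes <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(colnames(counts), counts[i, ])))
  stat <- function(g, cl) {
    tab <- table(g, cl)
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - exp)^2 / exp)
  }
  obs <- stat(groups, classes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  perm <- replicate(n_perm, stat(sample(groups), classes))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  mean(perm >= obs - 1e-12)
}

# small helper: balanced 5-class mixture used across tests
five_class_mix <- c(early = 0.2, early_mid = 0.2, mid = 0.2,
                    mid_late = 0.2, late = 0.2)

make_qc <- function(mean_v, center_v, blur_v, sharp_v, lc) {
  list(mean = mean_v, center_mean = center_v, blur = blur_v,
       sharpness = sharp_v, low_contrast = lc)
}

# a randomized nucleus record spanning both sides of every filter threshold
random_record <- function(i) {
  with_seed(child_seed(555L, i), {
    chans <- c("DAPI", "EdU", "PCNA")
    qc <- make_qc(
      setNames(runif(3, 0, 4000), chans),
      setNames(runif(3, 0, 4000), chans),
      setNames(runif(3, 0, 1), chans),
      setNames(runif(3, 0, 300), chans),
      setNames(runif(3) < 0.2, chans))
    props <- list(area = runif(1, 500, 30000),
                  minor_axis_length = runif(1, 10, 120),
                  major_axis_length = runif(1, 120, 300),
                  eccentricity = runif(1),
                  centroid = c(row = 8, col = 8))
    make_fake_record(props, qc, chans)
  })
}
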