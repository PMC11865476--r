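# Per-nucleus quality-control metrics and the inclusion-criterion filter
# engine. Thresholds come in two dialects, matching the cell systems they
# were derived for: chromocenter-rich mESC nuclei and larger, flatter U2OS
# nuclei. Every criterion is evaluated and reported individually; the overall
# verdict is the logical AND.

# reflect-padded 1-D filtering along rows of a matrix (axis = 1 rows, 2 cols)
filter1d <- function(x, kernel, axis) {
  if (axis == 2) return(t(filter1d(t(x), kernel, 1)))
  k <- length(kernel); half <- (k - 1) %/% 2
  n <- nrow(x)
  # 'reflect' boundary: (c b a | a b c ... | z y x)
  idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - seq_len(k - 1 - half))
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (j in seq_len(k)) out <- out + kernel[j] * xp[(j):(j + n - 1), , drop = FALSE]
  out
}

# separable Sobel derivative along one axis: derivative [1,0,-1] on `axis`,
# smoothing [1,2,1] on the other
sobel_axis <- function(x, axis) {
  d <- filter1d(x, c(1, 0, -1), axis)
  filter1d(d, c(1, 2, 1), if (axis == 1) 2 else 1)
}

#' Perceptual blur metric
#'
#' Estimates blur by comparing directional gradient magnitudes of the image
#' against those of a strongly re-blurred copy (uniform filter of width
#' `h_size` along each axis): in a sharp image re-blurring destroys most of
#' the gradient, in an already-blurred image it changes little. Returns the
#' worse (larger) of the two axis values. 0 means sharp, 1 maximally blurred;
#' a constant image (no gradient anywhere) is defined as 1.
#'
#' @param x numeric matrix.
#' @param h_size re-blur width in pixels (default 11).
#' @return value in \[0,1\].
#' @export
blur_metric <- function(x, h_size = 11L) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (nrow(x) < 4 || ncol(x) < 4) stopf("image too small for the blur metric")
  kern <- rep(1 / h_size, h_size)
  b <- numeric(2)
  ri <- 3:(nrow(x) - 1); ci <- 3:(ncol(x) - 1)   # interior, excluding filter edges
  for (axis in 1:2) {
    filt <- filter1d(x, kern, axis)
    im_sharp <- abs(sobel_axis(x, axis))
    im_blur <- abs(sobel_axis(filt, axis))
    tt <- pmax(im_sharp - im_blur, 0)
    m1 <- sum(im_sharp[ri, ci])
    b[axis] <- if (m1 == 0) 1 else abs(m1 - sum(tt[ri, ci])) / m1
  }
  max(b)
}

#' Mean gradient-norm sharpness
#'
#' Mean over pixels of `sqrt(gx^2 + gy^2)` where the gradients use central
#' differences in the interior and one-sided differences at the borders.
#'
#' @param x numeric matrix.
#' @return nonnegative scalar.
#' @export
gradient_sharpness <- function(x) {
  stopifnot(is.matrix(x))
  n <- nrow(x); m <- ncol(x)
  gr <- x; gc <- x
  if (n >= 3) gr[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / 2
  if (n >= 2) { gr[1, ] <- x[2, ] - x[1, ]; gr[n, ] <- x[n, ] - x[n - 1, ] } else gr[] <- 0
  if (m >= 3) gc[, 2:(m - 1)] <- (x[, 3:m] - x[, 1:(m - 2)]) / 2
  if (m >= 2) { gc[, 1] <- x[, 2] - x[, 1]; gc[, m] <- x[, m] - x[, m - 1] } else gc[] <- 0
  mean(sqrt(gr^2 + gc^2))
}

#' Low-contrast flag
#'
#' Flags an image whose intensity spread (span between the lower and upper
#' percentiles) is a small fraction of the data-type range — the signature of
#' uniformly high background with no real signal.
#'
#' @param x numeric matrix.
#' @param fraction_threshold flag when span/range falls below this (default 0.05).
#' @param percentiles lower/upper percentiles of the span (default 1 and 99).
#' @param dtype_range full data-type range (default 65535, 16-bit).
#' @return logical flag.
#' @export
low_contrast_flag <- function(x, fraction_threshold = 0.05,
                              percentiles = c(1, 99), dtype_range = 65535) {
  stopifnot(all(is.finite(x)))
  lim <- quantile(x, percentiles / 100, names = FALSE)
  (lim[2] - lim[1]) / dtype_range < fraction_threshold
}

#' Compute QC metrics for a nucleus record
#'
#' Per channel: whole-crop mean intensity, mean intensity of the 10 x 10 px
#' square centered on the crop center (crops are centroid-centered, so this
#' is the image centroid; for odd sizes the square rounds toward the top
#' left), perceptual blur, mean gradient-norm sharpness, and the low-contrast
#' flag. Metrics use raw 16-bit values, computed on the full crop.
#'
#' @param record a `nucleus_record` from [extract_records()], or any list
#'   with a `crop` array carrying channel dimnames.
#' @return the record with its `qc` slot filled (a `qc_metrics` list of
#'   per-channel named vectors: `mean`, `center_mean`, `blur`, `sharpness`,
#'   `low_contrast`).
#' @export
compute_qc <- function(record) {
  crop <- record$crop
  chn <- dimnames(crop)[[3]]
  if (is.null(chn)) stopf("crop channels must be named")
  s <- dim(crop)[1:2]
  r0 <- (s[1] - 10) %/% 2; c0 <- (s[2] - 10) %/% 2
  rows <- (r0 + 1):(r0 + 10); cols <- (c0 + 1):(c0 + 10)
  qc <- list(mean = numeric(0), center_mean = numeric(0), blur = numeric(0),
             sharpness = numeric(0), low_contrast = logical(0))
  for (ch in chn) {
    p <- crop[, , ch]
    qc$mean[ch] <- mean(p)
    qc$center_mean[ch] <- mean(p[rows, cols])
    qc$blur[ch] <- blur_metric(p)
    qc$sharpness[ch] <- gradient_sharpness(p)
    qc$low_contrast[ch] <- low_contrast_flag(p)
  }
  record$qc <- structure(qc, class = "qc_metrics")
  record
}

#' Inclusion-criterion profiles
#'
#' Named threshold sets for the per-nucleus filter. The `"mESC"` profile:
#' area 2000–10000 px^2, minor axis >= 40 px, major axis <= 120 px,
#' eccentricity <= 0.7, mean and center-square EdU intensity >= 1000, blur
#' <= 0.75 (DAPI) and 0.7 (EdU). The `"U2OS"` profile: area 2000–25000,
#' minor >= 40, major <= 250, eccentricity <= 0.8, EdU >= 2000 and PCNA
#' >= 500 (whole crop and center square), blur <= 0.75/0.7/0.7
#' (DAPI/EdU/PCNA), gradient sharpness >= 100 (EdU) and >= 50 (PCNA), and
#' exclusion of low-contrast EdU images. Pixel units; intensities on the raw
#' 16-bit scale.
#'
#' @param name `"mESC"`, `"U2OS"`, or `"custom"` (supply every field).
#' @param area_min,area_max area bounds in px^2.
#' @param minor_axis_min,major_axis_max axis-length bounds in px.
#' @param eccentricity_max maximum eccentricity.
#' @param intensity_min named per-channel whole-crop mean intensity minima.
#' @param center_intensity_min named per-channel center-square minima.
#' @param blur_max named per-channel blur maxima.
#' @param sharpness_min named per-channel gradient-sharpness minima (or NULL).
#' @param low_contrast_channels channels excluded when low-contrast (or NULL).
#' @return an object of class `filter_profile`.
#' @export
filter_profile <- function(name = c("mESC", "U2OS", "custom"),
                           area_min = NULL, area_max = NULL,
                           minor_axis_min = NULL, major_axis_max = NULL,
                           eccentricity_max = NULL,
                           intensity_min = NULL, center_intensity_min = NULL,
                           blur_max = NULL, sharpness_min = NULL,
                           low_contrast_channels = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    mESC = list(area_min = 2000, area_max = 10000, minor_axis_min = 40,
                major_axis_max = 120, eccentricity_max = 0.7,
                intensity_min = c(EdU = 1000),
                center_intensity_min = c(EdU = 1000),
                blur_max = c(DAPI = 0.75, EdU = 0.7),
                sharpness_min = NULL, low_contrast_channels = NULL),
    U2OS = list(area_min = 2000, area_max = 25000, minor_axis_min = 40,
                major_axis_max = 250, eccentricity_max = 0.8,
                intensity_min = c(EdU = 2000, PCNA = 500),
                center_intensity_min = c(EdU = 2000, PCNA = 500),
                blur_max = c(DAPI = 0.75, EdU = 0.7, PCNA = 0.7),
                sharpness_min = c(EdU = 100, PCNA = 50),
                low_contrast_channels = "EdU"),
    custom = list(area_min = area_min, area_max = area_max,
                  minor_axis_min = minor_axis_min,
                  major_axis_max = major_axis_max,
                  eccentricity_max = eccentricity_max,
                  intensity_min = intensity_min,
                  center_intensity_min = center_intensity_min,
                  blur_max = blur_max, sharpness_min = sharpness_min,
                  low_contrast_channels = low_contrast_channels))
  if (name == "custom") {
    args <- list(area_min = area_min, area_max = area_max,
                 minor_axis_min = minor_axis_min,
                 major_axis_max = major_axis_max,
                 eccentricity_max = eccentricity_max,
                 intensity_min = intensity_min,
                 center_intensity_min = center_intensity_min,
                 blur_max = blur_max, sharpness_min = sharpness_min,
                 low_contrast_channels = low_contrast_channels)
    def[names(args)] <- args
  } else {
    # allow selective overrides of a named dialect
    ov <- list(area_min = area_min, area_max = area_max,
               minor_axis_min = minor_axis_min,
               major_axis_max = major_axis_max,
               eccentricity_max = eccentricity_max,
               intensity_min = intensity_min,
               center_intensity_min = center_intensity_min,
               blur_max = blur_max, sharpness_min = sharpness_min,
               low_contrast_channels = low_contrast_channels)
    ov <- ov[!vapply(ov, is.null, logical(1))]
    def[names(ov)] <- ov
  }
  if (!is.null(def$area_min) && !is.null(def$area_max) &&
      def$area_min > def$area_max)
    stopf("area_min exceeds area_max")
  structure(c(list(name = name), def), class = "filter_profile")
}

#' @export
print.filter_profile <- function(x, ...) {
  cat(sprintf("<filter_profile %s: area [%s, %s], minor >= %s, major <= %s, ecc <= %s>\n",
              x$name, x$area_min, x$area_max, x$minor_axis_min,
              x$major_axis_max, x$eccentricity_max))
  invisible(x)
}

#' Apply inclusion criteria to a nucleus record
#'
#' Evaluates every criterion of the profile against the record's region
#' properties and QC metrics and reports each one (measured value, threshold,
#' verdict). The overall decision is the logical AND of all applicable
#' criteria.
#'
#' @param record a `nucleus_record` with `qc` computed (see [compute_qc()]);
#'   QC is computed on the fly if absent.
#' @param profile a [filter_profile()].
#' @return a `filter_report`: list with `criteria` (data.frame: criterion,
#'   value, threshold, pass), `pass` (overall), `reasons` (failed criteria).
#' @export
apply_filters <- function(record, profile) {
  stopifnot(inherits(profile, "filter_profile"))
  if (is.null(record$qc)) record <- compute_qc(record)
  qc <- record$qc; pr <- record$props
  chn <- dimnames(record$crop)[[3]]
  need <- unique(c(names(profile$intensity_min), names(profile$center_intensity_min),
                   names(profile$blur_max), names(profile$sharpness_min),
                   profile$low_contrast_channels))
  missing_ch <- setdiff(need, chn)
  if (length(missing_ch))
    stopf("profile '%s' requires channel(s) absent from the record: %s",
          profile$name, paste(missing_ch, collapse = ", "))

  crit <- list()
  add <- function(name, value, threshold, pass)
    crit[[length(crit) + 1]] <<- data.frame(criterion = name, value = value,
                                            threshold = threshold, pass = pass,
                                            stringsAsFactors = FALSE)
  if (!is.null(profile$area_min))
    add("area_min", pr$area, profile$area_min, pr$area >= profile$area_min)
  if (!is.null(profile$area_max))
    add("area_max", pr$area, profile$area_max, pr$area <= profile$area_max)
  if (!is.null(profile$minor_axis_min))
    add("minor_axis_min", pr$minor_axis_length, profile$minor_axis_min,
        pr$minor_axis_length >= profile$minor_axis_min)
  if (!is.null(profile$major_axis_max))
    add("major_axis_max", pr$major_axis_length, profile$major_axis_max,
        pr$major_axis_length <= profile$major_axis_max)
  if (!is.null(profile$eccentricity_max))
    add("eccentricity_max", pr$eccentricity, profile$eccentricity_max,
        pr$eccentricity <= profile$eccentricity_max)
  for (ch in names(profile$intensity_min))
    add(paste0("mean_intensity_min_", ch), qc$mean[[ch]],
        profile$intensity_min[[ch]], qc$mean[[ch]] >= profile$intensity_min[[ch]])
  for (ch in names(profile$center_intensity_min))
    add(paste0("center_intensity_min_", ch), qc$center_mean[[ch]],
        profile$center_intensity_min[[ch]],
        qc$center_mean[[ch]] >= profile$center_intensity_min[[ch]])
  for (ch in names(profile$blur_max))
    add(paste0("blur_max_", ch), qc$blur[[ch]], profile$blur_max[[ch]],
        qc$blur[[ch]] <= profile$blur_max[[ch]])
  for (ch in names(profile$sharpness_min))
    add(paste0("sharpness_min_", ch), qc$sharpness[[ch]],
        profile$sharpness_min[[ch]],
        qc$sharpness[[ch]] >= profile$sharpness_min[[ch]])
  for (ch in profile$low_contrast_channels)
    add(paste0("low_contrast_", ch), as.numeric(qc$low_contrast[[ch]]), 0,
        !qc$low_contrast[[ch]])
  criteria <- do.call(rbind, crit)
  structure(list(criteria = criteria, pass = all(criteria$pass),
                 reasons = criteria$criterion[!criteria$pass]),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %s%s>\n", if (x$pass) "PASS" else "FAIL",
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]") else ""))
  print(x$criteria, row.names = FALSE)
  invisible(x)
}

#' Filter a batch of nucleus records
#'
#' @param records list of `nucleus_record`s.
#' @param profile a [filter_profile()].
#' @return data.frame with one row per record: id columns, overall pass, and
#'   failure reasons (semicolon-separated).
#' @export
filter_records <- function(records, profile) {
  rows <- lapply(seq_along(records), function(i) {
    rep <- apply_filters(records[[i]], profile)
    src <- records[[i]]$source
    data.frame(field_id = if (is.null(src$field_id)) NA_character_ else src$field_id,
               label = if (is.null(src$label)) i else src$label,
               pass = rep$pass,
               reasons = paste(rep$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
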