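# Nucleus segmentation from the DAPI channel: Otsu threshold -> hole filling
# -> distance transform -> seed detection (local maxima with a minimum
# separation) -> seeded watershed. Crops are extracted centered on each
# nucleus centroid with zero padding at field borders.

#' Otsu intensity threshold
#'
#' Computes the threshold maximizing between-class variance over the image
#' histogram of raw intensity values (no rescaling; suited to 16-bit counts).
#'
#' @param x numeric matrix (one channel).
#' @return scalar threshold; pixels with value > threshold are foreground.
#' @export
otsu_threshold <- function(x) {
  v <- as.vector(x)
  stopifnot(all(is.finite(v)))
  lev <- sort(unique(v))
  if (length(lev) < 2) stopf("Otsu threshold undefined for a constant image")
  # histogram over observed levels; candidate thresholds between levels
  cnt <- as.numeric(tabulate(match(v, lev)))
  n <- length(v)
  w <- cumsum(cnt)
  mu <- cumsum(cnt * lev)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(lev) - 1)          # split after level k
  between <- (mu_t * w[k] / n - mu[k])^2 / (w[k] * (n - w[k]))
  i <- which.max(between)
  lev[i]
}

# local maxima of a distance map with a minimum separation, via grayscale
# dilation over a (2r+1) square window
detect_seeds <- function(dist, min_sep) {
  r <- max(1L, floor(min_sep / 2))
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "box")
  dil <- EBImage::dilate(EBImage::Image(dist), kern)
  mx <- (dist == as.matrix(dil)) & (dist > 0)
  seeds <- EBImage::bwlabel(EBImage::Image(mx))
  as.matrix(EBImage::imageData(seeds))
}

#' Segment nuclei in a field image
#'
#' Otsu threshold on the DAPI channel, hole filling, Euclidean distance
#' transform, seed detection as distance-map local maxima with a minimum
#' separation, then watershed growth of the seeds over the foreground mask
#' (splitting touching nuclei). Background is 0 and labels are contiguous
#' from 1.
#'
#' @param field array `rows x cols x channels` with channel dimnames
#'   including `"DAPI"`, or a list with element `field`.
#' @param min_seed_separation minimum seed separation in pixels; default 24
#'   (about half the expected nucleus minor axis).
#' @param min_area objects smaller than this many pixels are dropped as
#'   debris before labelling (default 200).
#' @return integer label matrix. If no foreground survives, an all-zero map
#'   is returned with a warning.
#' @export
segment_field <- function(field, min_seed_separation = 24, min_area = 200) {
  if (is.list(field) && !is.null(field$field)) field <- field$field
  chn <- dimnames(field)[[3]]
  if (is.null(chn) || !"DAPI" %in% chn) stopf("field must carry a DAPI channel")
  dapi <- field[, , "DAPI"]
  thr <- tryCatch(otsu_threshold(dapi), error = function(e) NA_real_)
  if (is.na(thr)) {
    warning("constant DAPI channel; returning empty label map")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  mask <- dapi > thr
  if (!any(mask)) {
    warning("no foreground after Otsu thresholding; returning empty label map")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  mask <- EBImage::fillHull(EBImage::Image(mask))
  # drop sub-nuclear debris
  lab0 <- EBImage::bwlabel(mask)
  areas <- table(as.vector(EBImage::imageData(lab0)))
  areas <- areas[names(areas) != "0"]
  small <- as.integer(names(areas)[areas < min_area])
  m <- as.matrix(EBImage::imageData(lab0))
  m[m %in% small] <- 0L
  mask <- m > 0
  if (!any(mask)) {
    warning("no foreground after debris removal; returning empty label map")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  dist <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask))))
  # smooth the ridge of the distance map so one nucleus yields one seed
  dist_s <- as.matrix(EBImage::gblur(EBImage::Image(dist), sigma = 4))
  dist_s[!mask] <- 0
  seeds <- detect_seeds(dist_s, min_seed_separation)
  labels <- EBImage::propagate(EBImage::Image(dist), EBImage::Image(seeds),
                               mask = EBImage::Image(mask))
  lab <- as.matrix(EBImage::imageData(labels))
  # relabel contiguously from 1
  u <- sort(unique(as.vector(lab))); u <- u[u != 0]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

#' Region properties of a binary mask
#'
#' Moments-based area, axis lengths (fitted-ellipse convention: axis =
#' 4 * sqrt(eigenvalue of the second central moments)), eccentricity, and
#' centroid, matching standard image-analysis toolkits.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return list with `area`, `major_axis_length`, `minor_axis_length`,
#'   `eccentricity`, `centroid` (row, col).
#' @export
mask_regionprops <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  stopifnot(area > 0)
  cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
  mrr <- mean((idx[, 1] - cr)^2); mcc <- mean((idx[, 2] - cc)^2)
  mrc <- mean((idx[, 1] - cr) * (idx[, 2] - cc))
  tr <- mrr + mcc
  det <- sqrt(pmax((mrr - mcc)^2 + 4 * mrc^2, 0))
  l1 <- (tr + det) / 2; l2 <- pmax((tr - det) / 2, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  list(area = area, major_axis_length = major, minor_axis_length = minor,
       eccentricity = ecc, centroid = c(row = cr, col = cc))
}

#' Extract per-nucleus records from a labelled field
#'
#' For each label, crops a fixed-size window centered on the mask centroid
#' (zero-padded at field borders), carries the aligned binary mask, and
#' computes region properties (area, axis lengths, eccentricity, centroid).
#' Objects touching the field border are kept and flagged.
#'
#' @param field array `rows x cols x channels`.
#' @param labels integer label matrix aligned with `field`.
#' @param crop_size_px crop side length (default 224).
#' @param field_id identifier recorded in each record's `source`.
#' @return list of `nucleus_record` objects: `crop` (array side x side x C),
#'   `mask`, `props`, `source` (field id + label), `touches_border`, and a
#'   `qc` slot filled later by [compute_qc()].
#' @export
extract_records <- function(field, labels, crop_size_px = 224L,
                            field_id = "field_1") {
  stopifnot(all(dim(labels) == dim(field)[1:2]))
  chn <- dimnames(field)[[3]]
  nlab <- max(labels)
  half <- crop_size_px %/% 2
  out <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    m <- labels == l
    props <- mask_regionprops(m)
    cr <- round(props$centroid["row"]); cc <- round(props$centroid["col"])
    rr <- (cr - half + 1):(cr - half + crop_size_px)
    cc2 <- (cc - half + 1):(cc - half + crop_size_px)
    crop <- array(0, c(crop_size_px, crop_size_px, dim(field)[3]),
                  dimnames = list(NULL, NULL, chn))
    mask <- matrix(FALSE, crop_size_px, crop_size_px)
    okr <- rr >= 1 & rr <= nrow(labels); okc <- cc2 >= 1 & cc2 <= ncol(labels)
    crop[which(okr), which(okc), ] <- field[rr[okr], cc2[okc], , drop = FALSE]
    mask[which(okr), which(okc)] <- m[rr[okr], cc2[okc]]
    bbox <- range(which(m, arr.ind = TRUE)[, 1])
    touches <- any(which(m, arr.ind = TRUE)[, 1] %in% c(1L, nrow(m))) ||
      any(which(m, arr.ind = TRUE)[, 2] %in% c(1L, ncol(m)))
    out[[l]] <- structure(list(
      crop = crop, mask = mask, props = props,
      source = list(field_id = field_id, label = l),
      touches_border = touches, qc = NULL, labels = list()),
      class = "nucleus_record")
  }
  out
}

#' @export
print.nucleus_record <- function(x, ...) {
  cat(sprintf("<nucleus_record %s/%d: area %d px^2, ecc %.2f%s>\n",
              x$source$field_id, x$source$label, x$props$area,
              x$props$eccentricity,
              if (x$touches_border) ", touches border" else ""))
  invisible(x)
}
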