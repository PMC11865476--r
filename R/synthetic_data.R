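# Synthetic fluorescence-microscopy generator.
#
# Renders seeded multi-channel nucleus crops and field images with ground
# truth: an elliptical DAPI nucleus with bright heterochromatic chromocenters
# (mESC-style) or smooth DAPI (U2OS-style), an EdU channel realising one of
# five S-phase replication-foci pattern classes (diffuse early, transition
# classes, chromocenter-coincident mid, large non-chromocenter late) or an
# EdU-negative G1/G2 nucleus, and an optional PCNA channel sharing the EdU
# focus geometry. Intensity model: Gaussian-profile foci plus constant
# background, with Poisson shot noise, on a 16-bit scale.

S_CLASSES <- c("early", "early_mid", "mid", "mid_late", "late", "g1g2")
ARTIFACT_CLASSES <- c("none", "abnormal_morphology", "blurry", "missegmented")
PLACEMENTS <- c("diffuse", "chromocenter", "periphery", "non_chromocenter", "mixed")
KNOWN_CHANNELS <- c("DAPI", "EdU", "PCNA")

# Per-class rendering defaults, at the native 80 px crop scale. Focus counts
# and sizes are free design knobs (the stage phenomenology fixes only their
# ordering: many small diffuse foci early, few large foci late).
class_defaults <- function(s_class) {
  switch(s_class,
    early     = list(n_foci = 120L, focus_radius_px = 1.2, focus_placement = "diffuse"),
    early_mid = list(n_foci = 80L,  focus_radius_px = 1.5, focus_placement = "mixed"),
    mid       = list(n_foci = 45L,  focus_radius_px = 1.8, focus_placement = "mixed"),
    mid_late  = list(n_foci = 20L,  focus_radius_px = 2.2, focus_placement = "mixed"),
    late      = list(n_foci = 8L,   focus_radius_px = 3.0, focus_placement = "non_chromocenter"),
    g1g2      = list(n_foci = 0L,   focus_radius_px = 1.2, focus_placement = "diffuse"),
    stopf("unknown s_class '%s'", s_class)
  )
}

# Placement composition per class: which placement modes are used and with
# what probability. "mixed" classes blend modes, mirroring the transition
# patterns seen between stages.
class_placement_mix <- function(s_class, focus_placement) {
  if (focus_placement != "mixed") {
    return(stats::setNames(1, focus_placement))
  }
  switch(s_class,
    early_mid = c(diffuse = 0.6, chromocenter = 0.4),
    mid       = c(chromocenter = 0.65, periphery = 0.35),
    mid_late  = c(chromocenter = 0.5, non_chromocenter = 0.5),
    c(diffuse = 1)
  )
}

#' Describe one synthetic nucleus pattern
#'
#' A `PatternSpec` captures everything needed to render one nucleus: its
#' S-phase class, number/size/placement of EdU replication foci, the EdU
#' whole-crop mean intensity target, and whether DAPI chromocenters are
#' rendered. Defaults per class encode the stage phenomenology: diffuse EdU
#' early, chromocenter-coincident foci mid, large non-chromocenter foci late,
#' and EdU-negative G1/G2.
#'
#' @param s_class one of `"early"`, `"early_mid"`, `"mid"`, `"mid_late"`,
#'   `"late"`, `"g1g2"`.
#' @param n_foci number of EdU foci; class default if `NULL`.
#' @param focus_radius_px focus Gaussian sigma in pixels; class default if `NULL`.
#' @param focus_placement one of `"diffuse"`, `"chromocenter"`, `"periphery"`,
#'   `"non_chromocenter"`, `"mixed"`; class default if `NULL`.
#' @param edu_mean_target target whole-crop mean EdU intensity (16-bit scale).
#'   Defaults to 3200 for S-phase classes and 300 for G1/G2 (below the mESC
#'   inclusion threshold of 1000, as the class semantics require).
#' @param chromocenters_visible render DAPI chromocenter blobs (mESC dialect)?
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(s_class, n_foci = NULL, focus_radius_px = NULL,
                         focus_placement = NULL, edu_mean_target = NULL,
                         chromocenters_visible = TRUE) {
  s_class <- match.arg(s_class, S_CLASSES)
  d <- class_defaults(s_class)
  if (is.null(n_foci)) n_foci <- d$n_foci
  if (is.null(focus_radius_px)) focus_radius_px <- d$focus_radius_px
  if (is.null(focus_placement)) focus_placement <- d$focus_placement
  focus_placement <- match.arg(focus_placement, PLACEMENTS)
  if (is.null(edu_mean_target)) edu_mean_target <- if (s_class == "g1g2") 300 else 3200
  if (!is_count(n_foci)) stopf("n_foci must be a nonnegative count")
  if (s_class == "g1g2" && edu_mean_target >= 1000)
    stopf("g1g2 nuclei must have edu_mean_target below the EdU inclusion threshold (1000)")
  if (s_class == "early" && focus_placement != "diffuse")
    stopf("early S-phase implies diffuse focus placement")
  if (s_class == "late" && !focus_placement %in% c("non_chromocenter", "diffuse"))
    stopf("late S-phase foci do not coincide with chromocenters")
  structure(list(
    s_class = s_class, n_foci = as.integer(n_foci),
    focus_radius_px = focus_radius_px, focus_placement = focus_placement,
    edu_mean_target = edu_mean_target,
    chromocenters_visible = isTRUE(chromocenters_visible)
  ), class = "pattern_spec")
}

#' Describe a condition (perturbation) effect on a nucleus population
#'
#' Emulates phenotypes such as loss of the replication-timing regulator RIF1:
#' a fraction of non-early S-phase nuclei re-rendered with an early-like
#' diffuse EdU pattern, a multiplicative change in replication-focus counts,
#' and a rate of imaging artifacts.
#'
#' @param early_like_shift fraction in \[0,1\] of non-early S-phase nuclei
#'   re-rendered with diffuse early-like EdU.
#' @param focus_count_multiplier positive scale factor on per-nucleus focus
#'   counts (rounded, floored at 1).
#' @param artifact_rate fraction in \[0,1\] of nuclei rendered as an artifact
#'   class (abnormal morphology, blur, mis-segmentation).
#' @return an object of class `condition_effect`.
#' @export
condition_effect <- function(early_like_shift = 0, focus_count_multiplier = 1,
                             artifact_rate = 0) {
  stopifnot(is.finite(early_like_shift), is.finite(focus_count_multiplier),
            is.finite(artifact_rate))
  if (early_like_shift < 0 || early_like_shift > 1) stopf("early_like_shift must be in [0,1]")
  if (artifact_rate < 0 || artifact_rate > 1) stopf("artifact_rate must be in [0,1]")
  if (focus_count_multiplier <= 0) stopf("focus_count_multiplier must be > 0")
  structure(list(early_like_shift = early_like_shift,
                 focus_count_multiplier = focus_count_multiplier,
                 artifact_rate = artifact_rate),
            class = "condition_effect")
}

#' Apply a condition effect to a population of pattern specs
#'
#' Each non-early, non-G1/G2 nucleus is re-rendered with an early-like
#' diffuse pattern with probability `effect$early_like_shift`; all focus
#' counts are scaled by `effect$focus_count_multiplier` (rounded to the
#' nearest integer, floored at 1 for nuclei that had any foci).
#'
#' @param patterns list of [pattern_spec()] objects.
#' @param effect a [condition_effect()].
#' @param rng_seed integer seed.
#' @return list of modified `pattern_spec` objects; each carries an
#'   `early_like` attribute marking re-rendered nuclei.
#' @export
apply_condition_effect <- function(patterns, effect, rng_seed = 1L) {
  if (!length(patterns)) stopf("pattern population is empty")
  stopifnot(inherits(effect, "condition_effect"))
  with_seed(rng_seed, {
    lapply(patterns, function(p) {
      stopifnot(inherits(p, "pattern_spec"))
      early_like <- FALSE
      if (!p$s_class %in% c("early", "g1g2") &&
          runif(1) < effect$early_like_shift) {
        early_like <- TRUE
        d <- class_defaults("early")
        p$focus_placement <- "diffuse"
        p$n_foci <- d$n_foci
        p$focus_radius_px <- d$focus_radius_px
      }
      if (p$n_foci > 0L)
        p$n_foci <- max(1L, as.integer(round(p$n_foci * effect$focus_count_multiplier)))
      attr(p, "early_like") <- early_like
      p
    })
  })
}

# --- geometry helpers -------------------------------------------------------

# Squared elliptical metric of grid points (row, col) around center (cr, cc),
# semi-axes (a, b) along an orientation theta; value 1 on the boundary.
ellipse_metric <- function(nr, nc, cr, cc, a, b, theta) {
  r <- matrix(seq_len(nr), nr, nc) - cr
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  u <- r * cos(theta) + cl * sin(theta)
  v <- -r * sin(theta) + cl * cos(theta)
  (u / a)^2 + (v / b)^2
}

# Sample n points uniformly inside the ellipse (rejection-free, via radius sqrt).
sample_in_ellipse <- function(n, cr, cc, a, b, theta, shrink = 1) {
  if (n == 0) return(cbind(row = numeric(0), col = numeric(0)))
  ang <- runif(n, 0, 2 * pi)
  rad <- sqrt(runif(n))
  u <- rad * a * shrink * cos(ang)
  v <- rad * b * shrink * sin(ang)
  cbind(row = cr + u * cos(theta) - v * sin(theta),
        col = cc + u * sin(theta) + v * cos(theta))
}

# Add Gaussian stamps of weight w and sd sigma at the given centers.
render_foci <- function(img, centers, sigma, w = 1) {
  nr <- nrow(img); nc <- ncol(img)
  half <- max(2L, ceiling(3 * sigma))
  win <- (-half):half
  g1 <- exp(-(win^2) / (2 * sigma^2))
  for (i in seq_len(nrow(centers))) {
    r0 <- round(centers[i, 1]); c0 <- round(centers[i, 2])
    rr <- r0 + win; cc <- c0 + win
    okr <- rr >= 1 & rr <= nr; okc <- cc >= 1 & cc <= nc
    if (!any(okr) || !any(okc)) next
    stamp <- outer(g1[okr], g1[okc]) * w
    img[rr[okr], cc[okc]] <- img[rr[okr], cc[okc]] + stamp
  }
  img
}

# --- nucleus rendering ------------------------------------------------------

# Render the clean (noise-free, background-free) intensity planes plus masks
# for one nucleus. Shared by generate_nucleus() and generate_field().
render_nucleus_clean <- function(pattern, channels, size_px,
                                 shape = NULL, dialect = "mESC") {
  nr <- nc <- size_px
  if (is.null(shape)) {
    a <- runif(1, 29, 33)
    b <- a * runif(1, 0.84, 0.95)
    shape <- list(cr = nr / 2 + runif(1, -2, 2), cc = nc / 2 + runif(1, -2, 2),
                  a = a, b = b, theta = runif(1, 0, pi))
  }
  if (shape$a * 2 + 6 > size_px || shape$b * 2 + 6 > size_px)
    stopf("size_px = %d is too small to host the nucleus and its foci", size_px)

  em <- ellipse_metric(nr, nc, shape$cr, shape$cc, shape$a, shape$b, shape$theta)
  soft <- 1 / (1 + exp((em - 1) * 12))      # soft-edged nucleus profile
  nucleus_mask <- em <= 1

  # chromocenters: 3-8 bright DAPI blobs (always positioned, rendered only in
  # the mESC dialect when visible; U2OS DAPI is smooth)
  k <- sample(5:8, 1)
  cm_r <- runif(k, 3.8, 4.8)
  cm_pos <- sample_in_ellipse(k, shape$cr, shape$cc, shape$a, shape$b, shape$theta,
                              shrink = 0.65)
  chromo_mask <- matrix(FALSE, nr, nc)
  rowg <- matrix(seq_len(nr), nr, nc); colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(k)) {
    chromo_mask <- chromo_mask |
      ((rowg - cm_pos[i, 1])^2 + (colg - cm_pos[i, 2])^2 <= cm_r[i]^2)
  }
  chromo_mask <- chromo_mask & nucleus_mask

  show_cc <- pattern$chromocenters_visible && dialect == "mESC"
  dapi <- 3000 * soft
  if (show_cc) {
    for (i in seq_len(k))
      dapi <- render_foci(dapi, cm_pos[i, , drop = FALSE], sigma = cm_r[i] / 1.6,
                          w = 6000)
  }

  # EdU focus placement
  mix <- class_placement_mix(pattern$s_class, pattern$focus_placement)
  n_foci <- pattern$n_foci
  foci <- NULL
  if (n_foci > 0) {
    modes <- sample(names(mix), n_foci, replace = TRUE, prob = mix)
    pts <- matrix(NA_real_, n_foci, 2)
    for (i in seq_len(n_foci)) {
      pts[i, ] <- switch(modes[i],
        diffuse = sample_in_ellipse(1, shape$cr, shape$cc, shape$a, shape$b,
                                    shape$theta, shrink = 0.95),
        chromocenter = {
          j <- sample.int(k, 1)
          ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * cm_r[j] * 0.7
          c(cm_pos[j, 1] + rad * cos(ang), cm_pos[j, 2] + rad * sin(ang))
        },
        periphery = {
          ang <- runif(1, 0, 2 * pi); f <- runif(1, 0.82, 0.95)
          u <- f * shape$a * cos(ang); v <- f * shape$b * sin(ang)
          c(shape$cr + u * cos(shape$theta) - v * sin(shape$theta),
            shape$cc + u * sin(shape$theta) + v * cos(shape$theta))
        },
        non_chromocenter = {
          # keep a 2.5-sigma margin from every chromocenter so focus tails do
          # not spill into the chromocenter mask
          min_d <- cm_r + 2.5 * pattern$focus_radius_px
          p <- sample_in_ellipse(1, shape$cr, shape$cc, shape$a, shape$b,
                                 shape$theta, shrink = 0.9)
          tries <- 0
          too_close <- function(p) any(sqrt((cm_pos[, 1] - p[1])^2 +
                                            (cm_pos[, 2] - p[2])^2) < min_d)
          while (too_close(p) && tries < 100) {
            p <- sample_in_ellipse(1, shape$cr, shape$cc, shape$a, shape$b,
                                   shape$theta, shrink = 0.9)
            tries <- tries + 1
          }
          p
        })
    }
    foci <- data.frame(row = pts[, 1], col = pts[, 2], placement = modes,
                       stringsAsFactors = FALSE)
  }

  # EdU plane: Gaussian foci plus a diffuse nucleoplasmic component carrying
  # 15% of the signal mass (keeps the centroid square EdU-positive for every
  # S-phase class), scaled to hit the whole-crop mean target.
  edu <- matrix(0, nr, nc)
  if (n_foci > 0)
    edu <- render_foci(edu, as.matrix(foci[, c("row", "col")]),
                       sigma = pattern$focus_radius_px, w = 1)
  focal_mass <- sum(edu)
  diffuse_frac <- 0.15
  nuc_area <- sum(soft)
  if (focal_mass > 0) {
    diffuse_level <- diffuse_frac / (1 - diffuse_frac) * focal_mass / nuc_area
    edu <- edu + soft * diffuse_level
  } else {
    edu <- soft  # G1/G2: weak uniform nucleoplasmic signal only
  }
  # U2OS acquisitions run brighter EdU/PCNA (their inclusion thresholds are
  # higher); scale the mean target accordingly
  dial_scale <- if (dialect == "U2OS") 2.2 else 1
  target_mass <- pattern$edu_mean_target * dial_scale * nr * nc
  edu <- edu * (target_mass / sum(edu))

  planes <- list(DAPI = dapi)
  if ("EdU" %in% channels) planes$EdU <- edu
  if ("PCNA" %in% channels) {
    # PCNA mirrors the EdU focus geometry; its own mean target keeps it above
    # the U2OS inclusion threshold (500) for S-phase nuclei.
    pcna_target <- if (pattern$s_class == "g1g2") 200 else 1800
    planes$PCNA <- edu * (pcna_target / (pattern$edu_mean_target * dial_scale))
  }
  list(planes = planes, nucleus_mask = nucleus_mask, chromo_mask = chromo_mask,
       foci = foci, shape = shape)
}

# Background levels per channel (16-bit counts) and Poisson shot noise.
CHANNEL_BG <- c(DAPI = 150, EdU = 100, PCNA = 100)

add_noise <- function(plane, channel) {
  lam <- pmax(plane + CHANNEL_BG[[channel]], 0)
  x <- rpois(length(lam), lam)
  matrix(pmin(x, 65535), nrow(plane), ncol(plane))
}

#' Generate one synthetic nucleus crop
#'
#' Renders a multi-channel crop realising a [pattern_spec()]: an elliptical
#' soft-edged DAPI nucleus (with bright chromocenter blobs in the mESC
#' dialect), an EdU channel with class-specific replication-foci placement,
#' and optionally a PCNA channel sharing the EdU focus geometry with
#' independent shot noise. Identical `(pattern, seed)` inputs reproduce the
#' crop bit for bit.
#'
#' @param pattern a [pattern_spec()].
#' @param channels character vector of channel names; must include `"DAPI"`.
#' @param size_px crop side length in pixels (minimum 64; the default 80
#'   hosts nuclei whose dimensions satisfy the mESC morphology thresholds).
#' @param rng_seed integer seed.
#' @param dialect `"mESC"` (chromocenter-rich DAPI) or `"U2OS"` (smooth DAPI).
#' @return a list with `img` (array `size_px x size_px x n_channels`, 16-bit
#'   range, dimnames carry channel names), `truth` (one-row data.frame),
#'   `nucleus_mask`, `chromo_mask`, and `foci` (placement log with focus
#'   centers, used to audit placement fidelity).
#' @export
generate_nucleus <- function(pattern, channels = c("DAPI", "EdU"), size_px = 80L,
                             rng_seed = 1L, dialect = c("mESC", "U2OS")) {
  stopifnot(inherits(pattern, "pattern_spec"))
  dialect <- match.arg(dialect)
  if (!length(channels)) stopf("at least one channel is required")
  bad <- setdiff(channels, KNOWN_CHANNELS)
  if (length(bad)) stopf("unknown channel(s): %s", paste(bad, collapse = ", "))
  if (!"DAPI" %in% channels) stopf("channels must include DAPI")
  if (size_px < 64) stopf("size_px must be at least 64")

  with_seed(rng_seed, {
    cl <- render_nucleus_clean(pattern, channels, size_px, dialect = dialect)
    img <- array(0, c(size_px, size_px, length(channels)),
                 dimnames = list(NULL, NULL, channels))
    for (ch in channels) img[, , ch] <- add_noise(cl$planes[[ch]], ch)
    truth <- data.frame(s_class = pattern$s_class,
                        n_foci = pattern$n_foci,
                        focus_placement = pattern$focus_placement,
                        edu_mean_target = pattern$edu_mean_target,
                        seed = as.integer(rng_seed),
                        stringsAsFactors = FALSE)
    list(img = img, truth = truth, nucleus_mask = cl$nucleus_mask,
         chromo_mask = cl$chromo_mask, foci = cl$foci)
  })
}

# --- field rendering --------------------------------------------------------

sample_classes <- function(n, class_mixture) {
  if (is.null(names(class_mixture)) || !all(names(class_mixture) %in% S_CLASSES))
    stopf("class_mixture must be named with S-phase classes")
  if (abs(sum(class_mixture) - 1) > 1e-9) stopf("class_mixture must sum to 1")
  sample(names(class_mixture), n, replace = TRUE, prob = class_mixture)
}

#' Generate a synthetic multi-nucleus field image
#'
#' Places `n_nuclei` nuclei (classes drawn from `class_mixture`, modified by a
#' [condition_effect()]) at rejection-sampled positions with a minimum
#' separation, renders all channels with a single field-level Poisson noise
#' pass, and returns the field, the ground-truth instance label map and the
#' manifest rows.
#'
#' @param n_nuclei number of nuclei to place.
#' @param class_mixture named probability vector over S-phase classes.
#' @param effect a [condition_effect()]; identity by default.
#' @param field_size_px `c(rows, cols)` of the field.
#' @param rng_seed integer seed.
#' @param channels channel names (must include DAPI).
#' @param separation_px minimum boundary separation between nuclei.
#' @param condition condition label recorded in the manifest.
#' @param field_id field identifier recorded in the manifest.
#' @param dialect `"mESC"` or `"U2OS"`.
#' @return list with `field` (array rows x cols x channels), `labels`
#'   (integer instance label map, background 0), `manifest` (data.frame:
#'   id, field_id, s_class, artifact_class, condition, centroid_row,
#'   centroid_col, seed).
#' @export
generate_field <- function(n_nuclei, class_mixture = c(early = 1),
                           effect = condition_effect(),
                           field_size_px = c(512L, 512L), rng_seed = 1L,
                           channels = c("DAPI", "EdU"), separation_px = 10,
                           condition = "control", field_id = "field_1",
                           dialect = "mESC") {
  stopifnot(is_count(n_nuclei), n_nuclei >= 1)
  if (!length(channels)) stopf("at least one channel is required")
  bad <- setdiff(channels, KNOWN_CHANNELS)
  if (length(bad)) stopf("unknown channel(s): %s", paste(bad, collapse = ", "))
  if (!"DAPI" %in% channels) stopf("channels must include DAPI")
  nr <- field_size_px[1]; nc <- field_size_px[2]
  crop <- 80L; rmax <- 33
  with_seed(rng_seed, {
    classes <- sample_classes(n_nuclei, class_mixture)
    patterns <- lapply(classes, pattern_spec)
    patterns <- apply_condition_effect(patterns, effect,
                                       rng_seed = child_seed(rng_seed, 1L))
    artifacts <- rep("none", n_nuclei)
    if (effect$artifact_rate > 0) {
      hit <- runif(n_nuclei) < effect$artifact_rate
      artifacts[hit] <- sample(ARTIFACT_CLASSES[-1], sum(hit), replace = TRUE)
    }

    # rejection-sample nucleus centers with a minimum center distance
    min_d <- 2 * rmax + separation_px
    margin <- crop / 2 + 2
    centers <- matrix(NA_real_, n_nuclei, 2)
    placed <- 0L; attempts <- 0L; max_attempts <- 2000L * n_nuclei
    while (placed < n_nuclei && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      ok <- placed == 0L ||
        min(sqrt((centers[seq_len(placed), 1] - p[1])^2 +
                 (centers[seq_len(placed), 2] - p[2])^2)) >= min_d
      if (ok) { placed <- placed + 1L; centers[placed, ] <- p }
    }
    if (placed < n_nuclei)
      stopf("could not place %d nuclei in a %dx%d field at separation %g",
            n_nuclei, nr, nc, separation_px)

    field_clean <- array(0, c(nr, nc, length(channels)),
                         dimnames = list(NULL, NULL, channels))
    labels <- matrix(0L, nr, nc)
    man <- vector("list", n_nuclei)
    blur_targets <- integer(0)
    for (i in seq_len(n_nuclei)) {
      seed_i <- child_seed(rng_seed, i + 10L)
      pat <- patterns[[i]]
      shape_override <- NULL
      cl <- with_seed(seed_i, {
        if (artifacts[i] == "abnormal_morphology") {
          # violate the morphology criteria: hyper-elongated or undersized
          if (runif(1) < 0.5) {
            a <- runif(1, 30, 33); b <- a * runif(1, 0.4, 0.48)
          } else {
            a <- runif(1, 13, 15); b <- a * runif(1, 0.85, 0.95)
          }
          shape_override <- list(cr = crop / 2, cc = crop / 2, a = a, b = b,
                                 theta = runif(1, 0, pi))
        }
        out <- render_nucleus_clean(pat, channels, crop, shape = shape_override,
                                    dialect = dialect)
        if (artifacts[i] == "missegmented") {
          # fuse a second overlapping nucleus into the same crop/label
          sh <- out$shape
          off <- sh$b * 1.4
          sh2 <- list(cr = sh$cr + off * runif(1, -0.4, 0.4),
                      cc = sh$cc + off * sample(c(-1, 1), 1) * 0.8,
                      a = sh$a * 0.9, b = sh$b * 0.9, theta = runif(1, 0, pi))
          sh2$cr <- max(sh2$b + 3, min(crop - sh2$b - 3, sh2$cr))
          sh2$cc <- max(sh2$b + 3, min(crop - sh2$b - 3, sh2$cc))
          out2 <- render_nucleus_clean(pat, channels, crop, shape = sh2,
                                       dialect = dialect)
          for (ch in names(out$planes))
            out$planes[[ch]] <- pmax(out$planes[[ch]], out2$planes[[ch]])
          out$nucleus_mask <- out$nucleus_mask | out2$nucleus_mask
        }
        out
      })
      r0 <- round(centers[i, 1]) - crop / 2; c0 <- round(centers[i, 2]) - crop / 2
      rr <- (r0 + 1):(r0 + crop); cc <- (c0 + 1):(c0 + crop)
      for (ch in channels)
        field_clean[rr, cc, ch] <- pmax(field_clean[rr, cc, ch], cl$planes[[ch]])
      lab_patch <- labels[rr, cc]
      lab_patch[cl$nucleus_mask] <- i
      labels[rr, cc] <- lab_patch
      if (artifacts[i] == "blurry") blur_targets <- c(blur_targets, i)
      man[[i]] <- data.frame(
        id = sprintf("%s_n%03d", field_id, i), field_id = field_id,
        s_class = pat$s_class, artifact_class = artifacts[i],
        condition = condition,
        centroid_row = mean(which(cl$nucleus_mask, arr.ind = TRUE)[, 1]) + r0 - 1,
        centroid_col = mean(which(cl$nucleus_mask, arr.ind = TRUE)[, 2]) + c0 - 1,
        seed = seed_i, stringsAsFactors = FALSE)
    }

    field <- field_clean
    for (ch in channels) field[, , ch] <- add_noise(field_clean[, , ch], ch)
    # blur artifacts: defocus the nucleus crop region after noise
    for (i in blur_targets) {
      r0 <- round(centers[i, 1]) - crop / 2; c0 <- round(centers[i, 2]) - crop / 2
      rr <- (r0 + 1):(r0 + crop); cc <- (c0 + 1):(c0 + crop)
      for (ch in channels)
        field[rr, cc, ch] <- as.matrix(EBImage::gblur(
          EBImage::Image(field[rr, cc, ch]), sigma = 5))
    }
    manifest <- do.call(rbind, man)
    list(field = field, labels = labels, manifest = manifest)
  })
}

#' Generate pre-cropped nucleus images for model training
#'
#' Convenience generator used by the learning modules: renders `n` single
#' nucleus crops directly (no field placement/segmentation), with classes
#' drawn from `class_mixture` and an optional [condition_effect()].
#'
#' @inheritParams generate_field
#' @param n number of nuclei.
#' @param size_px crop side (minimum 64).
#' @return list with `images` (array size x size x channels x n) and
#'   `manifest` (data.frame with id, s_class, artifact_class, condition,
#'   early_like flag, seed).
#' @export
generate_nuclei <- function(n, class_mixture = c(early = 1),
                            effect = condition_effect(), rng_seed = 1L,
                            channels = c("DAPI", "EdU"), size_px = 80L,
                            condition = "control", dialect = "mESC") {
  stopifnot(is_count(n), n >= 1)
  with_seed(rng_seed, {
    classes <- sample_classes(n, class_mixture)
    patterns <- lapply(classes, pattern_spec)
    patterns <- apply_condition_effect(patterns, effect,
                                       rng_seed = child_seed(rng_seed, 1L))
    artifacts <- rep("none", n)
    if (effect$artifact_rate > 0) {
      hit <- runif(n) < effect$artifact_rate
      artifacts[hit] <- sample(ARTIFACT_CLASSES[-1], sum(hit), replace = TRUE)
    }
    imgs <- array(0, c(size_px, size_px, length(channels), n),
                  dimnames = list(NULL, NULL, channels, NULL))
    man <- vector("list", n)
    for (i in seq_len(n)) {
      seed_i <- child_seed(rng_seed, i + 10L)
      g <- generate_nucleus(patterns[[i]], channels, size_px, seed_i,
                            dialect = dialect)
      img <- g$img
      if (artifacts[i] == "blurry") {
        for (ch in channels)
          img[, , ch] <- as.matrix(EBImage::gblur(EBImage::Image(img[, , ch]),
                                                  sigma = 5))
      }
      imgs[, , , i] <- img
      man[[i]] <- data.frame(
        id = sprintf("nuc_%05d", i), s_class = patterns[[i]]$s_class,
        artifact_class = artifacts[i], condition = condition,
        early_like = isTRUE(attr(patterns[[i]], "early_like")),
        seed = seed_i, stringsAsFactors = FALSE)
    }
    list(images = imgs, manifest = do.call(rbind, man))
  })
}

#' EdU chromocenter-mass statistic (pixel oracle)
#'
#' Fraction of total EdU signal mass falling inside the chromocenter mask.
#' A brute-force statistic used to certify that synthetic classes carry
#' learnable signal: diffuse early nuclei spread EdU uniformly (fraction near
#' the chromocenter area fraction), late nuclei avoid chromocenters.
#'
#' @param edu EdU channel matrix.
#' @param chromo_mask logical chromocenter mask.
#' @return fraction in \[0,1\].
#' @export
edu_chromocenter_fraction <- function(edu, chromo_mask) {
  s <- sum(edu)
  if (s <= 0) return(0)
  sum(edu[chromo_mask]) / s
}

#' Write a synthetic dataset to disk
#'
#' Renders `n_fields` fields per condition and writes a self-describing
#' dataset directory: one 16-bit TIFF per field and channel, one 16-bit TIFF
#' ground-truth label map per field, a `manifest.csv` with one row per
#' nucleus, and a `dataset.yaml` recording every generation parameter and the
#' seed. Generation is fully determined by `rng_seed` (field i of condition j
#' uses a derived child seed), so re-running with the same arguments
#' reproduces the files bit for bit. While writing, `dataset.yaml` carries
#' `status: incomplete`; it is rewritten with `status: complete` only after
#' the last file lands, so interrupted runs are detectable.
#'
#' @param out_dir output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param n_fields number of fields per condition.
#' @param nuclei_per_field nuclei per field.
#' @param conditions named list: condition label -> [condition_effect()].
#' @param class_mixture named probability vector over S-phase classes.
#' @param rng_seed integer master seed.
#' @param channels channel names (must include DAPI).
#' @param field_size_px `c(rows, cols)`.
#' @param dialect `"mESC"` or `"U2OS"`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) the dataset description list, as written to
#'   `dataset.yaml`.
#' @export
generate_dataset <- function(out_dir, n_fields = 4L, nuclei_per_field = 12L,
                             conditions = list(control = condition_effect()),
                             class_mixture = c(early = 0.2, early_mid = 0.2,
                                               mid = 0.2, mid_late = 0.2,
                                               late = 0.2),
                             rng_seed = 1L, channels = c("DAPI", "EdU"),
                             field_size_px = c(512L, 512L), dialect = "mESC",
                             overwrite = FALSE) {
  stopifnot(is_count(n_fields), n_fields >= 1,
            is_count(nuclei_per_field), nuclei_per_field >= 1)
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stopf("conditions must be a named list of condition_effect objects")
  for (e in conditions)
    if (!inherits(e, "condition_effect"))
      stopf("every element of conditions must be a condition_effect")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stopf("output directory '%s' is not empty (use overwrite = TRUE)", out_dir)
  dir.create(file.path(out_dir, "fields"), recursive = TRUE, showWarnings = FALSE)

  desc <- list(
    status = "incomplete", seed = as.integer(rng_seed),
    n_fields = as.integer(n_fields),
    nuclei_per_field = as.integer(nuclei_per_field),
    conditions = lapply(conditions, unclass),
    class_mixture = as.list(class_mixture), channels = as.list(channels),
    field_size_px = as.integer(field_size_px), dialect = dialect)
  yaml_path <- file.path(out_dir, "dataset.yaml")
  yaml::write_yaml(desc, yaml_path)

  man <- list()
  fidx <- 0L
  for (j in seq_along(conditions)) {
    cond <- names(conditions)[j]
    for (i in seq_len(n_fields)) {
      fidx <- fidx + 1L
      field_id <- sprintf("%s_f%03d", cond, i)
      fs <- child_seed(rng_seed, fidx)
      g <- generate_field(nuclei_per_field, class_mixture,
                          effect = conditions[[j]],
                          field_size_px = field_size_px, rng_seed = fs,
                          channels = channels, condition = cond,
                          field_id = field_id, dialect = dialect)
      for (ch in channels)
        tiff::writeTIFF(g$field[, , ch] / 65535,
                        file.path(out_dir, "fields",
                                  sprintf("%s_%s.tif", field_id, ch)),
                        bits.per.sample = 16L, compression = "none")
      tiff::writeTIFF(g$labels / 65535,
                      file.path(out_dir, "fields",
                                sprintf("%s_labels.tif", field_id)),
                      bits.per.sample = 16L, compression = "none")
      man[[fidx]] <- g$manifest
    }
  }
  manifest <- do.call(rbind, man)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  desc$status <- "complete"
  yaml::write_yaml(desc, yaml_path)
  invisible(desc)
}

#' Read a dataset directory written by [generate_dataset()]
#'
#' Errors if `dataset.yaml` is missing or still marked `status: incomplete`.
#'
#' @param dir dataset directory.
#' @return list with `description`, `manifest`, and `fields` (named list per
#'   field id: `field` array rows x cols x channels on the 16-bit scale and
#'   integer `labels` map).
#' @export
read_dataset <- function(dir) {
  yaml_path <- file.path(dir, "dataset.yaml")
  if (!file.exists(yaml_path)) stopf("'%s' is not a dataset directory", dir)
  desc <- yaml::read_yaml(yaml_path)
  if (!identical(desc$status, "complete"))
    stopf("dataset at '%s' is marked '%s' (generation did not finish)",
          dir, desc$status)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  channels <- unlist(desc$channels)
  ids <- unique(manifest$field_id)
  fields <- lapply(ids, function(fid) {
    planes <- lapply(channels, function(ch) {
      round(tiff::readTIFF(file.path(dir, "fields",
                                     sprintf("%s_%s.tif", fid, ch))) * 65535)
    })
    field <- array(0, c(dim(planes[[1]]), length(channels)),
                   dimnames = list(NULL, NULL, channels))
    for (k in seq_along(channels)) field[, , k] <- planes[[k]]
    labels <- round(tiff::readTIFF(file.path(
      dir, "fields", sprintf("%s_labels.tif", fid))) * 65535)
    storage.mode(labels) <- "integer"
    list(field = field, labels = labels)
  })
  names(fields) <- ids
  list(description = desc, manifest = manifest, fields = fields)
}
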