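test_that("pattern_spec enforces class invariants and defaults", {
  p <- pattern_spec("early")
  expect_s3_class(p, "pattern_spec")
  expect_identical(p$focus_placement, "diffuse")
  g <- pattern_spec("g1g2")
  expect_lt(g$edu_mean_target, 1000)
  expect_error(pattern_spec("g1g2", edu_mean_target = 1500), "below the EdU")
  expect_error(pattern_spec("early", focus_placement = "chromocenter"), "diffuse")
  expect_error(pattern_spec("late", focus_placement = "chromocenter"))
  expect_error(pattern_spec("weird"), "one of")
})

test_that("generate_nucleus: g1g2 EdU mean below 1000; seeded determinism", {
  g <- generate_nucleus(pattern_spec("g1g2"), c("DAPI", "EdU"), rng_seed = 3L)
  expect_lt(mean(g$img[, , "EdU"]), 1000)
  a <- generate_nucleus(pattern_spec("early"), c("DAPI", "EdU"), rng_seed = 7L)
  b <- generate_nucleus(pattern_spec("early"), c("DAPI", "EdU"), rng_seed = 7L)
  expect_identical(a$img, b$img)
  expect_true(all(a$img >= 0 & a$img <= 65535))
})

test_that("generate_nucleus error cases", {
  expect_error(generate_nucleus(pattern_spec("early"), c("DAPI", "GFP")), "GFP")
  expect_error(generate_nucleus(pattern_spec("early"), c("EdU")), "DAPI")
  expect_error(generate_nucleus(pattern_spec("early"), c("DAPI", "EdU"),
                                size_px = 32L))
})

test_that("mid-class chromocenter placement: >= 80% of foci inside chromocenter mask", {
  g <- generate_nucleus(pattern_spec("mid", focus_placement = "chromocenter"),
                        c("DAPI", "EdU"), rng_seed = 11L)
  centers <- g$foci
  inside <- mapply(function(r, c) g$chromo_mask[round(r), round(c)],
                   centers$row, centers$col)
  expect_gte(mean(inside), 0.8)
})

test_that("generate_field produces the requested label structure", {
  g <- generate_field(12L, five_class_mix, rng_seed = 2L)
  u <- setdiff(unique(as.vector(g$labels)), 0L)
  expect_length(u, 12L)
  expect_identical(nrow(g$manifest), 12L)
  # delta mixture: all early
  g2 <- generate_field(5L, c(early = 1), rng_seed = 4L)
  expect_true(all(g2$manifest$s_class == "early"))
  # infeasible density errors
  expect_error(generate_field(50L, c(early = 1), field_size_px = c(256L, 256L),
                              rng_seed = 1L), "could not place")
})

test_that("field class counts fall within exact binomial 99% bounds", {
  # mixture at the reference composition 384:210:110:100:54
  mix <- c(early = 384, early_mid = 210, mid = 110, mid_late = 100, late = 54)
  mix <- mix / sum(mix)
  g <- generate_nuclei(200L, mix, rng_seed = 1L)
  counts <- table(factor(g$manifest$s_class, names(mix)))
  for (cl in names(mix)) {
    bounds <- qbinom(c(0.005, 0.995), 200, mix[[cl]])
    expect_gte(counts[[cl]], bounds[1])
    expect_lte(counts[[cl]], bounds[2])
  }
})

test_that("apply_condition_effect: identity, multiplier, shift bounds", {
  pats <- replicate(40, pattern_spec("mid"), simplify = FALSE)
  same <- apply_condition_effect(pats, condition_effect(), rng_seed = 1L)
  # compare field values; the effect pass may annotate bookkeeping attributes
  strip <- function(p) p[names(p)]
  expect_identical(lapply(same, strip), lapply(pats, strip))
  expect_false(any(vapply(same, function(p) isTRUE(attr(p, "early_like")),
                          logical(1))))
  p10 <- list(pattern_spec("mid", n_foci = 10L))
  doubled <- apply_condition_effect(p10, condition_effect(focus_count_multiplier = 2),
                                    rng_seed = 1L)
  expect_identical(doubled[[1]]$n_foci, 20L)
  # shift 0.5 on 1000 mid nuclei: diffuse-rendered count within 99% bounds
  pats <- replicate(1000, pattern_spec("mid"), simplify = FALSE)
  shifted <- apply_condition_effect(pats, condition_effect(early_like_shift = 0.5),
                                    rng_seed = 5L)
  n_diffuse <- sum(vapply(shifted, function(p) isTRUE(attr(p, "early_like")),
                          logical(1)))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_diffuse, bounds[1])
  expect_lte(n_diffuse, bounds[2])
})

test_that("condition_effect validates its fields", {
  expect_error(condition_effect(early_like_shift = 1.5))
  expect_error(condition_effect(focus_count_multiplier = 0))
  expect_error(condition_effect(artifact_rate = -0.1))
})

test_that("filter-pass property: clean S-phase nuclei pass the mESC profile >= 95%", {
  n <- 120L
  classes <- sample(names(five_class_mix), n, replace = TRUE)
  prof <- filter_profile("mESC")
  pass <- logical(n)
  for (i in seq_len(n)) {
    g <- generate_nucleus(pattern_spec(classes[i]), c("DAPI", "EdU"),
                          rng_seed = child_seed(31L, i))
    rec <- list(crop = g$img, props = mask_regionprops(g$nucleus_mask))
    rec <- compute_qc(rec)
    pass[i] <- apply_filters(rec, prof)$pass
  }
  expect_gte(mean(pass), 0.95)
})

test_that("class separability: EdU chromocenter fraction separates early vs late", {
  n <- 50L
  fr <- function(cl, seed0) vapply(seq_len(n), function(i) {
    g <- generate_nucleus(pattern_spec(cl), c("DAPI", "EdU"),
                          rng_seed = child_seed(seed0, i))
    edu_chromocenter_fraction(g$img[, , "EdU"], g$chromo_mask)
  }, numeric(1))
  early <- fr("early", 100L)
  late <- fr("late", 200L)
  expect_gt(min(early), max(late))  # perfect separation
})

test_that("generate_dataset writes bit-identical re-runs and marks partial state", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- list(n_fields = 1L, nuclei_per_field = 4L,
               conditions = list(control = condition_effect(),
                                 aberrant = condition_effect(early_like_shift = 0.5)),
               rng_seed = 9L, overwrite = TRUE)
  do.call(generate_dataset, c(list(d1), args))
  do.call(generate_dataset, c(list(d2), args))
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 6e6),
                     readBin(file.path(d2, f), "raw", 6e6))
  ds <- read_dataset(d1)
  expect_setequal(unique(ds$manifest$condition), c("control", "aberrant"))
  expect_identical(nrow(ds$manifest), 8L)
  # manifest CSV round-trips losslessly
  man2 <- utils::read.csv(file.path(d1, "manifest.csv"), stringsAsFactors = FALSE)
  expect_identical(man2, ds$manifest)
  # incomplete marker blocks reads
  y <- yaml::read_yaml(file.path(d1, "dataset.yaml"))
  y$status <- "incomplete"
  yaml::write_yaml(y, file.path(d1, "dataset.yaml"))
  expect_error(read_dataset(d1), "incomplete")
})

test_that("generate_dataset artifact rate within 99% binomial bounds", {
  d <- withr::local_tempdir()
  generate_dataset(d, n_fields = 2L, nuclei_per_field = 10L,
                   conditions = list(a = condition_effect(artifact_rate = 0.2)),
                   rng_seed = 3L, overwrite = TRUE)
  man <- read_dataset(d)$manifest
  k <- sum(man$artifact_class != "none")
  bounds <- qbinom(c(0.005, 0.995), nrow(man), 0.2)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("generate_dataset error cases write nothing harmful", {
  d <- withr::local_tempdir()
  expect_error(
    generate_dataset(d, n_fields = 1L, nuclei_per_field = 2L,
                     conditions = list(a = condition_effect()),
                     channels = character(0), overwrite = TRUE))
  expect_error(
    generate_dataset(d, conditions = list(condition_effect())), "named")
})
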