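test_that("blur_metric: monotone under blur, constant -> 1, matches oracle to 1e-9", {
  chk <- with_seed(21L, matrix(runif(64 * 64, 0, 60000), 64, 64))
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(chk / 65535), sigma = 4)) * 65535
  expect_gt(blur_metric(blurred), blur_metric(chk))
  expect_identical(blur_metric(matrix(7, 32, 32)), 1)
  # independent from-definition oracle on seeded noise
  x <- with_seed(11L, matrix(runif(48 * 48, 0, 65535), 48, 48))
  expect_equal(blur_metric(x), oracle_blur(x), tolerance = 1e-9)
  for (s in 1:5) {
    y <- with_seed(s, matrix(rnorm(40 * 44, 500, 200), 40, 44))
    expect_equal(blur_metric(y), oracle_blur(y), tolerance = 1e-9)
  }
  expect_true(blur_metric(x) >= 0 && blur_metric(x) <= 1)
})

test_that("gradient_sharpness: constant, ramp, and hand-computed 5x5 case", {
  expect_identical(gradient_sharpness(matrix(3, 10, 10)), 0)
  ramp <- matrix(rep(1:50, each = 50), 50, 50)  # column-index ramp, slope 1
  expect_equal(gradient_sharpness(ramp), 1, tolerance = 1e-12)
  # hand-computed toy raster
  x <- matrix(c(0, 0, 0, 0, 0,
                0, 0, 0, 0, 0,
                0, 0, 10, 0, 0,
                0, 0, 0, 0, 0,
                0, 0, 0, 0, 0), 5, 5, byrow = TRUE)
  # central differences: gr nonzero at (2,3)=5,(4,3)=-5; gc at (3,2)=5,(3,4)=-5
  # norms: 4 cells of 5, center 0 => mean = 20/25
  expect_equal(gradient_sharpness(x), 20 / 25, tolerance = 1e-12)
})

test_that("low_contrast_flag: constant, full ramp, 4%-span raster", {
  expect_true(low_contrast_flag(matrix(1000, 8, 8)))
  expect_false(low_contrast_flag(matrix(seq(0, 65535, length.out = 400), 20, 20)))
  narrow <- matrix(seq(0, 0.04 * 65535, length.out = 400), 20, 20)
  expect_true(low_contrast_flag(narrow))
})

test_that("compute_qc populates all metrics; constant channel gives mean == center", {
  crop <- array(0, c(40, 40, 2), dimnames = list(NULL, NULL, c("DAPI", "EdU")))
  crop[, , "DAPI"] <- with_seed(2L, matrix(runif(1600, 0, 4000), 40, 40))
  crop[, , "EdU"] <- 1234
  rec <- compute_qc(list(crop = crop))
  qc <- rec$qc
  expect_s3_class(qc, "qc_metrics")
  expect_equal(qc$mean[["EdU"]], 1234)
  expect_equal(qc$center_mean[["EdU"]], 1234)
  expect_true(all(is.finite(c(qc$mean, qc$center_mean, qc$blur, qc$sharpness))))
  expect_error(compute_qc(list(crop = array(1, c(20, 20, 1)))), "named")
})

test_that("generator tuning: early nucleus EdU >= 1000; blurred artifact exceeds blur cap", {
  g <- generate_nucleus(pattern_spec("early"), c("DAPI", "EdU"), rng_seed = 6L)
  rec <- compute_qc(list(crop = g$img))
  expect_gte(rec$qc$mean[["EdU"]], 1000)
  blurred <- g$img
  for (ch in c("DAPI", "EdU"))
    blurred[, , ch] <- as.matrix(EBImage::gblur(EBImage::Image(g$img[, , ch]),
                                                sigma = 5))
  rb <- compute_qc(list(crop = blurred))
  expect_gt(rb$qc$blur[["DAPI"]], 0.75)
})

test_that("filter profiles reproduce every dialect threshold field-by-field", {
  m <- filter_profile("mESC")
  expect_equal(m$area_min, 2000)
  expect_equal(m$area_max, 10000)
  expect_equal(m$minor_axis_min, 40)
  expect_equal(m$major_axis_max, 120)
  expect_equal(m$eccentricity_max, 0.7)
  expect_equal(m$intensity_min, c(EdU = 1000))
  expect_equal(m$center_intensity_min, c(EdU = 1000))
  expect_equal(m$blur_max, c(DAPI = 0.75, EdU = 0.7))
  u <- filter_profile("U2OS")
  expect_equal(u$area_min, 2000)
  expect_equal(u$area_max, 25000)
  expect_equal(u$minor_axis_min, 40)
  expect_equal(u$major_axis_max, 250)
  expect_equal(u$eccentricity_max, 0.8)
  expect_equal(u$intensity_min, c(EdU = 2000, PCNA = 500))
  expect_equal(u$center_intensity_min, c(EdU = 2000, PCNA = 500))
  expect_equal(u$blur_max, c(DAPI = 0.75, EdU = 0.7, PCNA = 0.7))
  expect_equal(u$sharpness_min, c(EdU = 100, PCNA = 50))
  expect_identical(u$low_contrast_channels, "EdU")
  expect_error(filter_profile("mESC", area_min = 50000), "area_min")
})

test_that("apply_filters: eccentricity failure named; passing record clean", {
  chans <- c("DAPI", "EdU")
  qc <- make_qc(c(DAPI = 3000, EdU = 2000), c(DAPI = 3000, EdU = 2000),
                c(DAPI = 0.3, EdU = 0.3), c(DAPI = 200, EdU = 200),
                c(DAPI = FALSE, EdU = FALSE))
  props <- list(area = 5000, minor_axis_length = 60, major_axis_length = 90,
                eccentricity = 0.75, centroid = c(row = 40, col = 40))
  rec <- make_fake_record(props, qc, chans)
  rep <- apply_filters(rec, filter_profile("mESC"))
  expect_false(rep$pass)
  expect_identical(rep$reasons, "eccentricity_max")
  props$eccentricity <- 0.5
  rep2 <- apply_filters(make_fake_record(props, qc, chans), filter_profile("mESC"))
  expect_true(rep2$pass)
  expect_length(rep2$reasons, 0L)
  expect_identical(rep2$pass, all(rep2$criteria$pass))
})

test_that("apply_filters errors when the profile needs an absent channel", {
  qc <- make_qc(c(DAPI = 3000, EdU = 2500), c(DAPI = 3000, EdU = 2500),
                c(DAPI = 0.3, EdU = 0.3), c(DAPI = 200, EdU = 200),
                c(DAPI = FALSE, EdU = FALSE))
  props <- list(area = 5000, minor_axis_length = 60, major_axis_length = 90,
                eccentricity = 0.5, centroid = c(row = 40, col = 40))
  rec <- make_fake_record(props, qc, c("DAPI", "EdU"))
  expect_error(apply_filters(rec, filter_profile("U2OS")), "PCNA")
})

test_that("engine/oracle equivalence on 1000 randomized records (both dialects)", {
  profs <- list(filter_profile("mESC"), filter_profile("U2OS"))
  for (i in seq_len(1000)) {
    rec <- random_record(i)
    p <- profs[[(i %% 2) + 1]]
    expect_identical(apply_filters(rec, p)$pass, oracle_filter_pass(rec, p))
  }
})

test_that("monotonicity: relaxing a threshold never decreases survivors", {
  recs <- lapply(1:100, random_record)
  count_pass <- function(p) sum(vapply(recs, function(r) apply_filters(r, p)$pass,
                                       logical(1)))
  base <- filter_profile("U2OS")
  n0 <- count_pass(base)
  expect_gte(count_pass(filter_profile("U2OS", eccentricity_max = 0.95)), n0)
  expect_gte(count_pass(filter_profile("U2OS", area_max = 1e6)), n0)
  expect_gte(count_pass(filter_profile("U2OS", intensity_min = c(EdU = 0, PCNA = 0))), n0)
  expect_gte(count_pass(filter_profile("U2OS", blur_max = c(DAPI = 1, EdU = 1, PCNA = 1))), n0)
  expect_gte(count_pass(filter_profile("U2OS", sharpness_min = c(EdU = 0, PCNA = 0))), n0)
})

test_that("filter_records summarizes a batch", {
  recs <- lapply(1:20, random_record)
  tab <- filter_records(recs, filter_profile("mESC"))
  expect_identical(nrow(tab), 20L)
  expect_true(all(c("pass", "reasons") %in% names(tab)))
  expect_identical(sum(tab$pass),
                   sum(vapply(recs, function(r)
                     oracle_filter_pass(r, filter_profile("mESC")), logical(1))))
})
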