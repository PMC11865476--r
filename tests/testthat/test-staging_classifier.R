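test_that("stratified_split: sizes, disjointness, stratification bounds, determinism", {
  lab <- rep("a", 100)
  sp <- stratified_split(lab, seed = 1L)
  expect_identical(lengths(sp), c(train = 60L, val = 20L, test = 20L))
  expect_identical(sort(unname(unlist(sp))), 1:100)

  # reference composition: per-class test counts within +/-1 of 20%
  counts <- c(a = 384L, b = 210L, c = 110L, d = 100L, e = 54L)
  lab <- rep(names(counts), counts)
  sp <- stratified_split(lab, seed = 2L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  expect_identical(sort(unname(unlist(sp))), seq_along(lab))
  for (cl in names(counts)) {
    k <- sum(lab[sp$test] == cl)
    expect_lte(abs(k - 0.2 * counts[[cl]]), 1)
    k <- sum(lab[sp$train] == cl)
    expect_lte(abs(k - 0.6 * counts[[cl]]), 1)
  }
  expect_true(length(sp$test) %in% c(171L, 172L))
  expect_identical(stratified_split(lab, seed = 7L), stratified_split(lab, seed = 7L))
  expect_error(stratified_split(c("a", "a", "b"), seed = 1L), "at least 3")
  expect_error(stratified_split(lab, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("channel_standardize: fit vs apply contract; hand-computed toy case", {
  x <- with_seed(1L, array(rnorm(8 * 8 * 2 * 10, 100, 20), c(8, 8, 2, 10)))
  fit <- channel_standardize(x)
  for (ch in 1:2) {
    expect_equal(mean(fit$images[, , ch, ]), 0, tolerance = 1e-6)
    expect_equal(sd(as.vector(fit$images[, , ch, ])), 1, tolerance = 1e-6)
  }
  # applying train-fit stats to other data does not refit
  y <- x + 50
  applied <- channel_standardize(y, fit$stats)
  expect_gt(abs(mean(applied$images)), 0.5)
  # 4-image toy set, hand-computed
  z <- array(0, c(1, 1, 1, 4)); z[1, 1, 1, ] <- c(1, 2, 3, 4)
  fz <- channel_standardize(z)
  expect_equal(fz$stats$mean, 2.5)
  expect_equal(fz$stats$sd, sd(1:4))
  expect_equal(as.vector(fz$images), (c(1, 2, 3, 4) - 2.5) / sd(1:4))
  expect_error(channel_standardize(array(5, c(2, 2, 1, 3))), "zero-variance")
})

test_that("sampler_weights balance expected class draws", {
  lab <- c(rep("a", 90), rep("b", 10))
  w <- sampler_weights(lab)
  expect_equal(sum(w[lab == "a"]), sum(w[lab == "b"]))
  expect_equal(sum(w), 1)
  expect_equal(unique(sampler_weights(rep("x", 5))), 0.2)
  # reference composition: Monte-Carlo draw frequencies within 1% of uniform
  counts <- c(a = 384L, b = 210L, c = 110L, d = 100L, e = 54L)
  lab <- rep(names(counts), counts)
  w <- sampler_weights(lab)
  draws <- with_seed(2L, sample(lab, 1e6, replace = TRUE, prob = w))
  expect_true(all(abs(table(draws) / 1e6 - 0.2) < 0.01))
  expect_error(sampler_weights(character(0)), "nonempty")
})

test_that("lr_at implements cosine annealing with warm restarts", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 1e-2)
  expect_equal(lr_at(20, cfg), 1e-2)   # restart
  expect_equal(lr_at(10, cfg), 5e-3)   # midpoint
  expect_equal(lr_at(40.5, cfg), lr_at(0.5, cfg))
  tol <- 1e-12
  expect_lt(lr_at(19.999, cfg), 1e-6)
})

test_that("train_config validates the recipe", {
  cfg <- train_config()
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$lr_init, 1e-2)
  expect_equal(cfg$lr_min, 0)
  expect_identical(cfg$restart_period, 20L)
  expect_identical(cfg$batch_size, 32L)
  expect_error(train_config("resnet50"), "not implemented")
  expect_error(train_config(pretrained = TRUE), "pretrained")
  expect_error(train_config(lr_init = 0, lr_min = 1))
})

# a quick separable 2-class set: g1g2 (EdU-negative) vs early (EdU-bright)
separable_set <- function(n_per, seed) {
  mix <- c(early = 0.5, g1g2 = 0.5)
  g <- generate_nuclei(2L * n_per, mix, rng_seed = seed)
  g
}

test_that("train_classifier: separable 2-class set reaches held-out accuracy 1.0", {
  g <- separable_set(32L, 17L)
  lab <- g$manifest$s_class
  sp <- stratified_split(lab, seed = 1L)
  cfg <- train_config(max_epochs = 8L, patience = 8L, seed = 1L)
  m <- train_classifier(g$images[, , , sp$train, drop = FALSE], lab[sp$train],
                        g$images[, , , sp$val, drop = FALSE], lab[sp$val], cfg)
  ev <- evaluate_classifier(m, g$images[, , , sp$test, drop = FALSE], lab[sp$test])
  expect_equal(ev$accuracy, 1.0)
  # seeded reproducibility of the training history
  m2 <- train_classifier(g$images[, , , sp$train, drop = FALSE], lab[sp$train],
                         g$images[, , , sp$val, drop = FALSE], lab[sp$val], cfg)
  expect_identical(m$history, m2$history)
  # embeddings: penultimate width; duplicates identical; linear probe separates
  emb <- extract_embeddings(m, g$images[, , , sp$test, drop = FALSE])
  expect_identical(ncol(emb), tail(cfg$widths, 1L))
  dup <- extract_embeddings(m, g$images[, , , c(sp$test[1], sp$test[1]), drop = FALSE])
  expect_identical(dup[1, ], dup[2, ])
  probe <- suppressWarnings(
    glm(I(lab[sp$test] == "early") ~ ., data = as.data.frame(emb), family = binomial))
  pred <- predict(probe, type = "response") > 0.5
  expect_equal(mean(pred == (lab[sp$test] == "early")), 1.0)
})

test_that("train_classifier honors a 1-epoch budget with patience 0", {
  g <- separable_set(8L, 23L)
  lab <- g$manifest$s_class
  sp <- stratified_split(lab, seed = 1L)
  cfg <- train_config(max_epochs = 1L, patience = 0L, seed = 1L)
  m <- train_classifier(g$images[, , , sp$train, drop = FALSE], lab[sp$train],
                        g$images[, , , sp$val, drop = FALSE], lab[sp$val], cfg)
  expect_identical(nrow(m$history), 1L)
  expect_identical(m$best_epoch, 1L)
})

test_that("augmentation closure: flips preserve the pixel-oracle class signal", {
  g <- generate_nucleus(pattern_spec("early"), c("DAPI", "EdU"), rng_seed = 3L)
  f0 <- edu_chromocenter_fraction(g$img[, , "EdU"], g$chromo_mask)
  fh <- edu_chromocenter_fraction(g$img[80:1, , "EdU"], g$chromo_mask[80:1, ])
  fv <- edu_chromocenter_fraction(g$img[, 80:1, "EdU"], g$chromo_mask[, 80:1])
  expect_equal(fh, f0)
  expect_equal(fv, f0)
})

test_that("evaluate_classifier: confusion equals brute-force tally; errors", {
  g <- separable_set(10L, 29L)
  lab <- g$manifest$s_class
  sp <- stratified_split(lab, seed = 1L)
  cfg <- train_config(max_epochs = 3L, patience = 3L, seed = 1L)
  m <- train_classifier(g$images[, , , sp$train, drop = FALSE], lab[sp$train],
                        g$images[, , , sp$val, drop = FALSE], lab[sp$val], cfg)
  ev <- evaluate_classifier(m, g$images[, , , sp$test, drop = FALSE], lab[sp$test])
  pred <- predict(m, g$images[, , , sp$test, drop = FALSE])
  for (tr in m$classes) for (pc in m$classes)
    expect_identical(as.integer(ev$confusion[tr, pc]),
                     sum(lab[sp$test] == tr & pred == pc))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / length(sp$test))
  expect_identical(as.integer(rowSums(ev$confusion)),
                   as.integer(table(factor(lab[sp$test], m$classes))[m$classes]))
  expect_error(evaluate_classifier(m, g$images[, , , integer(0), drop = FALSE],
                                   character(0)), "empty")
})

test_that("train_overall_classifier separates S from G1/G2 and validates input", {
  mix <- c(early = 0.25, mid = 0.25, g1g2 = 0.5)
  g <- generate_nuclei(160L, mix, rng_seed = 41L)
  cfg <- train_config(max_epochs = 10L, patience = 10L, seed = 1L)
  m <- train_overall_classifier(g$images, g$manifest, cfg, split_seed = 1L)
  expect_identical(m$task, "overall")
  target <- ifelse(g$manifest$s_class == "g1g2", "g1g2", "s_phase")
  pred <- predict(m, g$images[, , , m$split$test, drop = FALSE])
  s_idx <- target[m$split$test] == "s_phase"
  expect_gte(mean(pred[s_idx] == "s_phase"), 0.95)
  expect_error(train_overall_classifier(g$images, data.frame(s_class = target),
                                        cfg), "artifact_class")
  one <- data.frame(s_class = rep("early", 10), artifact_class = "none")
  expect_error(train_overall_classifier(g$images[, , , 1:10, drop = FALSE],
                                        one, cfg), "at least 2")
})
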