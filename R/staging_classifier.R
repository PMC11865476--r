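# Supervised S-phase stage classifier: stratified 60:20:20 split, per-channel
# standardization fit on the training set, inverse-class-frequency resampling,
# flip-only augmentation, SGD with momentum under cosine annealing with warm
# restarts, early stopping on validation accuracy with best-weights return,
# and penultimate-layer (global-average-pool) embeddings.

#' Stratified train/validation/test split
#'
#' Splits indices into disjoint train/validation/test sets with per-stratum
#' sizes allocated by the largest-remainder rule, so every stratum's split
#' sizes are within one item of the exact ratios.
#'
#' @param labels vector of stratum labels (one per item).
#' @param ratios numeric triple summing to 1 (default `c(0.6, 0.2, 0.2)`).
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-9) stopf("split ratios must sum to 1")
  labels <- as.character(labels)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      m <- length(idx)
      if (m < 3) stopf("stratum '%s' has %d item(s); need at least 3", cl, m)
      target <- m * ratios
      sizes <- floor(target)
      rem <- target - sizes
      short <- m - sum(sizes)
      if (short > 0) {
        give <- order(rem, decreasing = TRUE)[seq_len(short)]
        sizes[give] <- sizes[give] + 1
      }
      idx <- sample(idx)
      out$train <- c(out$train, idx[seq_len(sizes[1])])
      out$val <- c(out$val, idx[sizes[1] + seq_len(sizes[2])])
      out$test <- c(out$test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
  })
  lapply(out, sort)
}

#' Per-channel standardization
#'
#' Standardizes an image stack channel-wise. When `stats` is `NULL` the
#' per-channel mean and standard deviation are fit on `images` (the split the
#' stats should come from); otherwise the supplied stats are applied without
#' refitting — the contract used when projecting validation/test or external
#' data through training-set statistics.
#'
#' @param images array `H x W x C x N`.
#' @param stats optional list with `mean` and `sd` per-channel vectors.
#' @return list with `images` (standardized) and `stats`.
#' @export
channel_standardize <- function(images, stats = NULL) {
  d <- dim(images)
  m <- images; dim(m) <- c(d[1] * d[2], d[3], d[4])
  if (is.null(stats)) {
    mu <- apply(m, 2, mean)
    sg <- apply(m, 2, sd)
    if (any(!is.finite(sg)) || any(sg <= 0))
      stopf("zero-variance channel; cannot standardize")
    stats <- list(mean = mu, sd = sg)
  }
  for (ch in seq_len(d[3]))
    m[, ch, ] <- (m[, ch, ] - stats$mean[ch]) / stats$sd[ch]
  dim(m) <- d
  dimnames(m) <- dimnames(images)
  list(images = m, stats = stats)
}

#' Inverse-class-frequency sampling weights
#'
#' Weight of an item is proportional to one over its class count, so that
#' weighted resampling draws each class with equal expected probability.
#'
#' @param labels vector of class labels.
#' @return numeric weights, one per item, normalized to sum to 1.
#' @export
sampler_weights <- function(labels) {
  if (!length(labels)) stopf("labels must be nonempty")
  cnt <- table(labels)
  w <- 1 / as.numeric(cnt[as.character(labels)])
  w / sum(w)
}

#' Training configuration
#'
#' The optimization recipe: SGD with momentum 0.9, cosine annealing with warm
#' restarts every 20 epochs from an initial rate of 1e-2 down to 0, batch
#' size 32, flip-only augmentation, inverse-class-frequency resampling, and
#' early stopping on validation accuracy.
#'
#' @param architecture `"small_cnn"` (implemented) or `"resnet50"` (declared
#'   for configuration compatibility; not available in this engine).
#' @param input_side square input side in pixels images are resized to.
#' @param widths channel widths of the four convolution blocks.
#' @param batch_size minibatch size.
#' @param momentum SGD momentum.
#' @param lr_init,lr_min cosine schedule endpoints.
#' @param restart_period warm-restart period in epochs.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience in epochs (0 disables waiting).
#' @param augment apply random horizontal/vertical flips.
#' @param resample use inverse-class-frequency weighted resampling.
#' @param pretrained declared flag (no pretrained weights ship with this
#'   engine; must be FALSE).
#' @param seed integer seed covering initialization, sampling, augmentation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(architecture = c("small_cnn", "resnet50"),
                         input_side = 32L, widths = c(8L, 16L, 32L, 32L),
                         batch_size = 32L, momentum = 0.9,
                         lr_init = 1e-2, lr_min = 0, restart_period = 20L,
                         max_epochs = 60L, patience = 10L,
                         augment = TRUE, resample = TRUE,
                         pretrained = FALSE, seed = 1L) {
  architecture <- match.arg(architecture)
  if (architecture == "resnet50")
    stopf("the resnet50 architecture is declared for configuration parity but not implemented; use small_cnn")
  if (isTRUE(pretrained)) stopf("no pretrained weights are available")
  stopifnot(lr_min <= lr_init, restart_period >= 1, batch_size >= 1,
            input_side %% 16 == 0)
  structure(list(architecture = architecture, input_side = as.integer(input_side),
                 widths = as.integer(widths), batch_size = as.integer(batch_size),
                 momentum = momentum, lr_init = lr_init, lr_min = lr_min,
                 restart_period = as.integer(restart_period),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 augment = isTRUE(augment), resample = isTRUE(resample),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealing learning rate with warm restarts
#'
#' `lr(t) = lr_min + (lr_init - lr_min)/2 * (1 + cos(pi * (t mod T) / T))`
#' where `T` is the restart period: the rate restarts at `lr_init` every `T`
#' epochs and reaches `lr_min` just before each restart.
#'
#' @param t epoch position (fractional values allowed), `t >= 0`.
#' @param config a [train_config()] (or any list with `lr_init`, `lr_min`,
#'   `restart_period`).
#' @return learning rate at `t`.
#' @export
lr_at <- function(t, config) {
  stopifnot(all(t >= 0))
  T <- config$restart_period
  config$lr_min + 0.5 * (config$lr_init - config$lr_min) *
    (1 + cos(pi * (t %% T) / T))
}

# images: raw 16-bit (H,W,C,N) -> model-ready standardized stack
prepare_images <- function(images, side, stats = NULL) {
  x <- resize_images(images, side) / 65535
  channel_standardize(x, stats)
}

model_accuracy <- function(params, widths, x, y_idx, batch = 256L) {
  n <- dim(x)[4]
  pred <- integer(n)
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    f <- cnn_forward(params, x[, , , s:e, drop = FALSE], widths)
    pred[s:e] <- max.col(t(f$logits))
  }
  mean(pred == y_idx)
}

#' Train the S-phase stage classifier
#'
#' Trains a small four-block CNN with the full recipe: per-channel
#' standardization fit on the training images, inverse-class-frequency
#' resampling each epoch, random horizontal/vertical flips, SGD with momentum
#' 0.9 under cosine annealing with warm restarts, early stopping on
#' validation accuracy, returning the best-validation weights. Fully seeded:
#' identical data, config and seed reproduce the training history.
#'
#' @param train_images,train_labels training stack (`H x W x C x N`, raw
#'   16-bit) and class labels.
#' @param val_images,val_labels validation stack and labels.
#' @param config a [train_config()].
#' @return an object of class `stage_classifier`: trained parameters, class
#'   levels, channel statistics, the training `history` (epoch, loss,
#'   validation accuracy, learning rate) and `best_epoch`.
#' @export
train_classifier <- function(train_images, train_labels, val_images, val_labels,
                             config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  classes <- sort(unique(as.character(train_labels)))
  if (length(classes) < 2) stopf("training requires at least 2 classes")
  y <- match(as.character(train_labels), classes)
  yv <- match(as.character(val_labels), classes)
  if (anyNA(yv)) stopf("validation labels outside the training label space")

  prep <- prepare_images(train_images, config$input_side)
  xtr <- prep$images; stats <- prep$stats
  xval <- prepare_images(val_images, config$input_side, stats)$images
  n <- dim(xtr)[4]; c_in <- dim(xtr)[3]
  w <- if (config$resample) sampler_weights(y) else rep(1 / n, n)

  with_seed(config$seed, {
    params <- cnn_init(c_in, config$widths, n_out = length(classes))
    opt_state <- NULL
    best <- list(acc = -Inf, params = params, epoch = 0L)
    hist <- list(); wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      lr <- lr_at(epoch - 1, config)
      ord <- sample.int(n, n, replace = TRUE, prob = w)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1, n, by = config$batch_size)) {
        ids <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- xtr[, , , ids, drop = FALSE]
        if (config$augment)
          xb <- flip_batch(xb, runif(length(ids)) < 0.5, runif(length(ids)) < 0.5)
        f <- cnn_forward(params, xb, config$widths)
        sx <- softmax_xent(f$logits, y[ids])
        if (!is.finite(sx$loss)) stopf("training diverged (non-finite loss) at epoch %d", epoch)
        g <- cnn_backward(params, f, config$widths, dlogits = sx$dlogits)
        st <- sgd_momentum_step(params, g, opt_state, lr, config$momentum)
        params <- st$params; opt_state <- st$state
        ep_loss <- ep_loss + sx$loss; nb <- nb + 1L
      }
      vacc <- model_accuracy(params, config$widths, xval, yv)
      hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss / nb,
                                  val_accuracy = vacc, lr = lr)
      if (vacc > best$acc) {
        best <- list(acc = vacc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > config$patience) break
      }
    }
    structure(list(params = best$params, classes = classes, config = config,
                   channel_stats = stats, history = do.call(rbind, hist),
                   best_epoch = best$epoch, task = "stage"),
              class = "stage_classifier")
  })
}

#' @export
print.stage_classifier <- function(x, ...) {
  cat(sprintf("<stage_classifier (%s, side %d): %d classes [%s]\n",
              x$config$architecture, x$config$input_side, length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epochs, best validation accuracy %.3f at epoch %d>\n",
              nrow(x$history), max(x$history$val_accuracy), x$best_epoch))
  invisible(x)
}

#' Predict S-phase stages (or embeddings) for new images
#'
#' @param object a trained [train_classifier()] model.
#' @param images raw image stack `H x W x C x N`.
#' @param type `"class"`, `"prob"`, or `"embedding"` (penultimate pooled layer).
#' @param ... unused.
#' @return class labels, a probability matrix (N x K), or an embedding matrix
#'   (N x penultimate width).
#' @export
predict.stage_classifier <- function(object, images,
                                     type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  x <- prepare_images(images, object$config$input_side, object$channel_stats)$images
  n <- dim(x)[4]
  f <- cnn_forward(object$params, x, object$config$widths)
  if (type == "embedding") {
    e <- t(f$emb)
    colnames(e) <- paste0("f", seq_len(ncol(e)))
    return(e)
  }
  sm <- exp(sweep(f$logits, 2, apply(f$logits, 2, max)))
  pr <- t(sweep(sm, 2, colSums(sm), "/"))
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  object$classes[max.col(pr)]
}

#' Extract penultimate-layer embeddings
#'
#' One fixed-length vector per image: the activations of the global-average-
#' pooled layer immediately before the classification layer.
#'
#' @param model a `stage_classifier`.
#' @param images raw image stack.
#' @return matrix N x D.
#' @export
extract_embeddings <- function(model, images) {
  predict(model, images, type = "embedding")
}

#' Evaluate a classifier on a test set
#'
#' Predictions count as correct only when the exact target class is
#' predicted. Reports the confusion matrix (true x predicted), overall
#' accuracy with its normal-approximation 95% CI, and per-class accuracies.
#'
#' @param model a `stage_classifier`.
#' @param images test stack.
#' @param labels true labels.
#' @return an `eval_result`: list with `confusion`, `accuracy`, `ci`
#'   (from [proportion_ci()]), `per_class`, `n`.
#' @export
evaluate_classifier <- function(model, images, labels) {
  n <- length(labels)
  if (n == 0) stopf("empty test set")
  stopifnot(dim(images)[4] == n)
  pred <- predict(model, images, type = "class")
  labels <- as.character(labels)
  if (!all(labels %in% model$classes))
    stopf("test labels outside the model's label space")
  lev <- model$classes
  confusion <- table(factor(labels, lev), factor(pred, lev), dnn = c("true", "predicted"))
  acc <- sum(diag(confusion)) / n
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, accuracy = acc,
                 ci = proportion_ci(acc, n), per_class = per_class, n = n),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("accuracy %.3f (95%% CI %.3f-%.3f, n = %d)\n",
              x$accuracy, x$ci[1], x$ci[2], x$n))
  print(x$confusion)
  invisible(x)
}

#' Train the overall classifier (S-phase vs G1/G2 vs artifact classes)
#'
#' Same training recipe as the stage classifier, but over the five screening
#' target classes used to select S-phase nuclei at scale: `s_phase`, `g1g2`,
#' `abnormal_morphology`, `blurry`, `missegmented`. Targets are derived from
#' the manifest: the artifact class when present, otherwise G1/G2 versus
#' S-phase by stage class.
#'
#' @param images raw stack `H x W x C x N`.
#' @param manifest data.frame with columns `s_class` and `artifact_class`.
#' @param config a [train_config()].
#' @param split_seed seed for the internal stratified 60:20:20 split.
#' @return a `stage_classifier` whose `task` is `"overall"`, with the split
#'   indices attached as `split`.
#' @export
train_overall_classifier <- function(images, manifest, config = train_config(),
                                     split_seed = 1L) {
  for (col in c("s_class", "artifact_class"))
    if (is.null(manifest[[col]]))
      stopf("manifest lacks required column '%s'", col)
  target <- ifelse(manifest$artifact_class != "none",
                   as.character(manifest$artifact_class),
                   ifelse(manifest$s_class == "g1g2", "g1g2", "s_phase"))
  if (length(unique(target)) < 2)
    stopf("overall classifier needs at least 2 target classes; got only '%s'",
          unique(target))
  sp <- stratified_split(target, seed = split_seed)
  model <- train_classifier(images[, , , sp$train, drop = FALSE], target[sp$train],
                            images[, , , sp$val, drop = FALSE], target[sp$val],
                            config)
  model$task <- "overall"
  model$split <- sp
  model
}
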