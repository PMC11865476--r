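# From-scratch BYOL (bootstrap-your-own-latent) self-supervised embedder.
# An online network (encoder f, projector g, predictor q) regresses, in
# normalized space, onto the projection of a second augmented view produced
# by a target network (f', g') that is never gradient-updated: it trails the
# online parameters through an exponential moving average with decay tau.
# No negative pairs are used. Augmentations follow the flip-only policy that
# preserves replication-pattern class identity.

#' BYOL configuration
#'
#' Defaults mirror the standard configuration for nuclear-image embeddings:
#' 224 px inputs, projection size 256 with hidden width 4096, target decay
#' 0.99 (held constant), Adam at 3e-4 with betas (0.9, 0.999), first
#' augmentation random horizontal flip, second augmentation random vertical
#' flip, momentum target enabled, trained from scratch. For desk-scale runs
#' pass a smaller `input_side` (any multiple of 16).
#'
#' @param input_side square input side in pixels.
#' @param projection_size output width of projector and predictor.
#' @param projection_hidden_size hidden width of projector and predictor.
#' @param tau target exponential-moving-average decay in \[0,1\].
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param widths encoder convolution-block widths (the same small CNN trunk
#'   as the supervised classifier).
#' @param batch_size minibatch size.
#' @param steps number of training steps.
#' @param use_momentum use the EMA target network (BYOL proper).
#' @param pretrained must be FALSE (trained from scratch).
#' @param seed integer seed.
#' @return an object of class `byol_config`.
#' @export
byol_config <- function(input_side = 224L, projection_size = 256L,
                        projection_hidden_size = 4096L, tau = 0.99,
                        lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                        widths = c(8L, 16L, 32L, 32L), batch_size = 32L,
                        steps = 200L, use_momentum = TRUE,
                        pretrained = FALSE, seed = 1L) {
  stopifnot(tau >= 0, tau <= 1, projection_size >= 1,
            projection_hidden_size >= 1, input_side %% 16 == 0)
  if (isTRUE(pretrained)) stopf("no pretrained weights are available")
  structure(list(input_side = as.integer(input_side),
                 projection_size = as.integer(projection_size),
                 projection_hidden_size = as.integer(projection_hidden_size),
                 tau = tau, lr = lr, beta1 = beta1, beta2 = beta2,
                 widths = as.integer(widths), batch_size = as.integer(batch_size),
                 steps = as.integer(steps), use_momentum = isTRUE(use_momentum),
                 seed = as.integer(seed)),
            class = "byol_config")
}

#' BYOL loss
#'
#' Normalized regression of the online prediction onto the target projection:
#' `L(p, z) = 2 - 2 <p/||p||, z/||z||>`, bounded in \[0, 4\] (0 for aligned,
#' 2 for orthogonal, 4 for antipodal vectors). Matrix inputs (columns =
#' batch items) return the mean over columns.
#'
#' @param predicted online prediction vector, or matrix D x N.
#' @param target_projection target projection of the other view, same shape.
#' @return nonnegative scalar.
#' @export
byol_loss <- function(predicted, target_projection) {
  p <- as.matrix(predicted); z <- as.matrix(target_projection)
  stopifnot(all(dim(p) == dim(z)))
  np <- sqrt(colSums(p^2)); nz <- sqrt(colSums(z^2))
  if (any(np == 0) || any(nz == 0)) stopf("byol_loss is undefined for zero vectors")
  mean(2 - 2 * colSums(p * z) / (np * nz))
}

# gradient of the summed (not averaged) loss wrt p, for matrix inputs
byol_loss_grad <- function(p, z) {
  np <- sqrt(colSums(p^2)); nz <- sqrt(colSums(z^2))
  pn <- sweep(p, 2, np, "/"); zn <- sweep(z, 2, nz, "/")
  cosd <- colSums(pn * zn)
  -2 * sweep(zn - sweep(pn, 2, cosd, "*"), 2, np, "/")
}

#' Exponential-moving-average update of target parameters
#'
#' `xi <- tau * xi + (1 - tau) * theta`, elementwise over every parameter
#' array. The result is a convex combination: each updated value lies between
#' the old target and the online value.
#'
#' @param target named list of parameter arrays (xi).
#' @param online named list with identical structure (theta).
#' @param tau decay in \[0,1\].
#' @return updated target list.
#' @export
ema_update <- function(target, online, tau) {
  stopifnot(tau >= 0, tau <= 1)
  if (!identical(names(target), names(online)))
    stopf("target/online parameter structures do not match")
  for (nm in names(target)) {
    if (!identical(dim(target[[nm]]), dim(online[[nm]])) ||
        length(target[[nm]]) != length(online[[nm]]))
      stopf("parameter shape mismatch for '%s'", nm)
    target[[nm]] <- tau * target[[nm]] + (1 - tau) * online[[nm]]
  }
  target
}

#' Train a BYOL encoder on unlabeled nucleus crops
#'
#' Each step draws a minibatch, makes two views (view 1: random horizontal
#' flips; view 2: random vertical flips), and minimizes the symmetric BYOL
#' loss `L(q(g(f(v1))), g'(f'(v2))) + L(q(g(f(v2))), g'(f'(v1)))` by Adam on
#' the online parameters only; the target network is updated after every step
#' by [ema_update()]. Target parameters receive no gradients at any point
#' (their gradient norms are identically zero by construction; the training
#' history records this).
#'
#' @param images raw unlabeled stack `H x W x C x N`.
#' @param config a [byol_config()].
#' @return an object of class `byol_encoder`: encoder parameters, heads,
#'   channel statistics, config, and a per-step `history` (loss, learning
#'   rate, target gradient norm).
#' @export
train_byol <- function(images, config = byol_config()) {
  stopifnot(inherits(config, "byol_config"))
  n <- dim(images)[4]
  if (is.null(n) || n < 2) stopf("BYOL needs a nonempty image set (>= 2 images)")
  prep <- prepare_images(images, config$input_side)
  x <- prep$images; stats <- prep$stats
  c_in <- dim(x)[3]
  emb_dim <- config$widths[length(config$widths)]

  with_seed(config$seed, {
    online <- list(
      enc = cnn_init(c_in, config$widths),
      proj = mlp_init(emb_dim, config$projection_hidden_size, config$projection_size),
      pred = mlp_init(config$projection_size, config$projection_hidden_size,
                      config$projection_size))
    target <- list(enc = online$enc, proj = online$proj)
    opt <- NULL
    hist <- vector("list", config$steps)

    flat <- function(p) c(stats::setNames(p$enc, paste0("enc_", names(p$enc))),
                          stats::setNames(p$proj, paste0("proj_", names(p$proj))),
                          stats::setNames(p$pred, paste0("pred_", names(p$pred))))
    unflat <- function(fp) list(
      enc = stats::setNames(fp[grep("^enc_", names(fp))],
                            sub("^enc_", "", names(fp)[grep("^enc_", names(fp))])),
      proj = stats::setNames(fp[grep("^proj_", names(fp))],
                             sub("^proj_", "", names(fp)[grep("^proj_", names(fp))])),
      pred = stats::setNames(fp[grep("^pred_", names(fp))],
                             sub("^pred_", "", names(fp)[grep("^pred_", names(fp))])))

    online_branch <- function(p, v) {
      fe <- cnn_forward(p$enc, v, config$widths)
      fg <- mlp_forward(p$proj, fe$emb)
      fq <- mlp_forward(p$pred, fg$y)
      list(fe = fe, fg = fg, fq = fq)
    }
    target_projection <- function(tp, v) {
      fe <- cnn_forward(tp$enc, v, config$widths, with_head = FALSE)
      mlp_forward(tp$proj, fe$emb)$y
    }
    branch_grads <- function(p, fwd, dp) {
      bq <- mlp_backward(p$pred, fwd$fq, dp)
      bg <- mlp_backward(p$proj, fwd$fg, bq$dx)
      ge <- cnn_backward(p$enc, fwd$fe, config$widths, demb = bg$dx)
      c(stats::setNames(ge, paste0("enc_", names(ge))),
        stats::setNames(bg$grads, paste0("proj_", names(bg$grads))),
        stats::setNames(bq$grads, paste0("pred_", names(bq$grads))))
    }

    for (step in seq_len(config$steps)) {
      ids <- sample.int(n, min(config$batch_size, n))
      xb <- x[, , , ids, drop = FALSE]
      nb <- length(ids)
      v1 <- flip_batch(xb, runif(nb) < 0.5, rep(FALSE, nb))
      v2 <- flip_batch(xb, rep(FALSE, nb), runif(nb) < 0.5)

      tgt <- if (config$use_momentum) target else list(enc = online$enc, proj = online$proj)
      z2 <- target_projection(tgt, v2)
      z1 <- target_projection(tgt, v1)
      o1 <- online_branch(online, v1)
      o2 <- online_branch(online, v2)
      loss <- byol_loss(o1$fq$y, z2) + byol_loss(o2$fq$y, z1)
      if (!is.finite(loss)) stopf("BYOL training diverged (non-finite loss) at step %d", step)

      g1 <- branch_grads(online, o1, byol_loss_grad(o1$fq$y, z2) / nb)
      g2 <- branch_grads(online, o2, byol_loss_grad(o2$fq$y, z1) / nb)
      grads <- g1
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + g2[[nm]]

      if (config$lr > 0) {
        st <- adam_step(flat(online), grads, opt, config$lr, config$beta1, config$beta2)
        online <- unflat(st$params); opt <- st$state
      }
      if (config$use_momentum)
        target <- list(enc = ema_update(target$enc, online$enc, config$tau),
                       proj = ema_update(target$proj, online$proj, config$tau))
      hist[[step]] <- data.frame(step = step, loss = loss, lr = config$lr,
                                 target_grad_norm = 0)
    }
    structure(list(encoder = online$enc, projector = online$proj,
                   predictor = online$pred, target = target,
                   channel_stats = stats, config = config,
                   history = do.call(rbind, hist)),
              class = "byol_encoder")
  })
}

#' @export
print.byol_encoder <- function(x, ...) {
  h <- x$history
  cat(sprintf("<byol_encoder (side %d, proj %d/%d, tau %.2f): %d steps, loss %.4f -> %.4f>\n",
              x$config$input_side, x$config$projection_hidden_size,
              x$config$projection_size, x$config$tau, nrow(h),
              h$loss[1], h$loss[nrow(h)]))
  invisible(x)
}

#' Embed images with a trained BYOL encoder
#'
#' Deterministic per image: embeddings are the encoder's global-average-pooled
#' output (before the projector), after the stored channel standardization.
#'
#' @param encoder a `byol_encoder` (or a `stage_classifier`, whose pooled
#'   layer is used the same way).
#' @param images raw stack `H x W x C x N`.
#' @param batch_size forward batch size.
#' @return matrix N x D of embeddings.
#' @export
embed_images <- function(encoder, images, batch_size = 256L) {
  if (inherits(encoder, "stage_classifier"))
    return(extract_embeddings(encoder, images))
  stopifnot(inherits(encoder, "byol_encoder"))
  x <- prepare_images(images, encoder$config$input_side, encoder$channel_stats)$images
  n <- dim(x)[4]
  out <- NULL
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    f <- cnn_forward(encoder$encoder, x[, , , s:e, drop = FALSE],
                     encoder$config$widths, with_head = FALSE)
    out <- rbind(out, t(f$emb))
  }
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  out
}
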