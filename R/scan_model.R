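#' Scan encoder
#'
#' The shared encoder F maps a 2-channel scan volume X (2 x H x W x l) to a
#' 3D encoding A of shape d x ceil(H/sr) x ceil(W/sr) x ceil(l/tr), whose
#' voxels are d-dimensional feature vectors a_{i,j,k}. The reduction factors
#' are a declared contract: the full-size configuration
#' ([full_scan_encoder()]) reduces 224 x 224 in-plane by 32x to 7 x 7 and
#' slices by 6x with ceiling, emitting d = 1024 channels; the default tiny
#' configuration (8x spatial, 2x temporal, d = 32) trains on a CPU in
#' seconds and honors the same interface.
#'
#' Internals (this package's design; any encoder with the same contract can
#' replace it): block-average pooling down to the declared grid, three
#' appended normalized-coordinate channels so downstream attention heads can
#' condition on anatomical position, then a pointwise 2-layer ReLU network
#' to d channels. All rectifier units honor the guided-backpropagation
#' contract used by [compute_saliency()].
#'
#' @param d output channels (default 32).
#' @param hidden pointwise hidden width (default 32).
#' @param spatial_reduction,temporal_reduction declared reduction factors.
#' @param seed integer seed for weight initialization.
#' @return object of class `scan_encoder`.
#' @export
scan_encoder <- function(d = 32L, hidden = 32L, spatial_reduction = 8L,
                         temporal_reduction = 2L, seed = 1L) {
  set.seed(seed)
  cin <- 2L + 3L  # PET, CT + 3 coordinate channels
  params <- list(
    W1 = matrix(stats::rnorm(cin * hidden, sd = sqrt(2 / cin)), cin, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * d, sd = sqrt(2 / hidden)), hidden, d),
    b2 = numeric(d))
  structure(list(params = params, d = d, hidden = hidden,
                 spatial_reduction = as.integer(spatial_reduction),
                 temporal_reduction = as.integer(temporal_reduction)),
            class = "scan_encoder")
}

#' Full-size encoder configuration
#'
#' Honors the published contract: d = 1024 channels of shape
#' 7 x 7 x ceil(l/6) for a 2 x 224 x 224 x l input (e.g. 33 temporal
#' positions at l = 198).
#' @param seed integer seed.
#' @return a `scan_encoder`.
#' @export
full_scan_encoder <- function(seed = 1L) {
  scan_encoder(d = 1024L, hidden = 64L, spatial_reduction = 32L,
               temporal_reduction = 6L, seed = seed)
}

#' Output shape of an encoder for a given input shape
#' @param encoder a `scan_encoder`.
#' @param h,w,l input in-plane sizes and slice count.
#' @return integer vector `c(d, gh, gw, gl)` (ceiling division per axis).
#' @export
encoding_shape <- function(encoder, h, w, l) {
  c(encoder$d,
    as.integer(ceiling(h / encoder$spatial_reduction)),
    as.integer(ceiling(w / encoder$spatial_reduction)),
    as.integer(ceiling(l / encoder$temporal_reduction)))
}

#' @export
print.scan_encoder <- function(x, ...) {
  cat(sprintf(
    "<scan_encoder> d = %d, reductions %dx spatial / %dx temporal\n",
    x$d, x$spatial_reduction, x$temporal_reduction))
  invisible(x)
}

# Block-average pooling of a scan to the encoder grid, plus coordinate
# channels. Returns voxel matrix V (n x 5), grid dims, and the per-voxel
# group/count bookkeeping needed to push gradients back to the input grid.
.pool_volume <- function(scan, encoder) {
  d <- dim(scan$data)
  H <- d[2L]; W <- d[3L]; l <- d[4L]
  sr <- encoder$spatial_reduction; tr <- encoder$temporal_reduction
  g1 <- as.integer(ceiling(H / sr))
  g2 <- as.integer(ceiling(W / sr))
  g3 <- as.integer(ceiling(l / tr))
  gh <- ceiling(seq_len(H) / sr)
  gw <- ceiling(seq_len(W) / sr)
  gl <- ceiling(seq_len(l) / tr)
  group <- rep(gh, times = W * l) +
    (rep(rep(gw, each = H), times = l) - 1L) * g1 +
    (rep(gl, each = H * W) - 1L) * g1 * g2
  counts <- tabulate(group, nbins = g1 * g2 * g3)
  pet <- rowsum(as.vector(scan$data[1L, , , ]), group) / counts
  ct  <- rowsum(as.vector(scan$data[2L, , , ]), group) / counts
  # normalized block-center coordinates in [0, 1]
  cx <- (rep(seq_len(g1), times = g2 * g3) - 0.5) / g1
  cy <- (rep(rep(seq_len(g2), each = g1), times = g3) - 0.5) / g2
  cz <- (rep(seq_len(g3), each = g1 * g2) - 0.5) / g3
  V <- cbind(pet = as.numeric(pet), ct = as.numeric(ct),
             x = cx, y = cy, z = cz)
  list(V = V, grid = c(g1, g2, g3), group = group, counts = counts,
       in_dim = d)
}

# pointwise MLP forward; cache intermediates for backprop when asked
.scan_forward <- function(params, V, cache = FALSE) {
  H1 <- pmax(sweep(V %*% params$W1, 2L, params$b1, `+`), 0)
  A <- pmax(sweep(H1 %*% params$W2, 2L, params$b2, `+`), 0)
  if (cache) list(A = A, H1 = H1, V = V) else list(A = A)
}

#' Encode a scan volume
#'
#' Deterministic forward pass through the encoder; output shape follows
#' [encoding_shape()] exactly.
#'
#' @param encoder a `scan_encoder` (or a `multitask_model`, whose encoder is
#'   used).
#' @param scan a `scan_volume`.
#' @return object of class `scan_encoding`: list with `data` (array
#'   d x gh x gw x gl), `grid`, and the voxel matrix `voxels` (n x d, voxels
#'   in grid column-major order).
#' @export
encode_scan <- function(encoder, scan) {
  if (inherits(encoder, "multitask_model")) encoder <- encoder$encoder
  stopifnot(inherits(encoder, "scan_encoder"), inherits(scan, "scan_volume"))
  if (dim(scan$data)[4L] < encoder$temporal_reduction) {
    stop("slice count below the encoder minimum (one temporal block)")
  }
  pooled <- .pool_volume(scan, encoder)
  A <- .scan_forward(encoder$params, pooled$V)$A
  structure(list(data = array(t(A), dim = c(encoder$d, pooled$grid)),
                 grid = pooled$grid, voxels = A),
            class = "scan_encoding")
}

#' Per-region task head
#'
#' A task head carries an attention vector w (scores each encoding voxel by
#' dot product), and a linear sigmoid classifier (u, b) applied to the
#' attention-pooled vector.
#' @param d encoder channel count.
#' @param region_id region the head is charged with.
#' @param seed integer seed.
#' @return list of class `task_head` with `w`, `u`, `b`, `region_id`.
#' @export
task_head <- function(d, region_id = NA_character_, seed = 1L) {
  set.seed(seed)
  structure(list(w = stats::rnorm(d, sd = 0.1),
                 u = stats::rnorm(d, sd = 0.1),
                 b = 0, region_id = region_id),
            class = "task_head")
}

#' Soft attention pooling
#'
#' Scores every voxel of the encoding by its dot product with the head's
#' attention vector, `s_{i,j,k} = w' a_{i,j,k}`, applies a softmax jointly
#' over all voxels to obtain non-negative weights alpha summing to 1, and
#' returns the attention-weighted sum of voxel vectors
#' `a = sum alpha_{i,j,k} a_{i,j,k}` together with alpha for interpretation.
#'
#' @param head a `task_head`.
#' @param encoding a `scan_encoding` (or a plain n x d voxel matrix).
#' @return list with `pooled` (length-d vector) and `alpha` (array over the
#'   encoding grid, or vector for a plain matrix input).
#' @export
attend <- function(head, encoding) {
  A <- if (inherits(encoding, "scan_encoding")) encoding$voxels else encoding
  if (ncol(A) != length(head$w)) {
    stop(sprintf("head dimension %d does not match encoding channels %d",
                 length(head$w), ncol(A)))
  }
  s <- as.numeric(A %*% head$w)
  alpha <- .softmax(s)
  pooled <- as.numeric(crossprod(A, alpha))
  if (inherits(encoding, "scan_encoding")) {
    alpha <- array(alpha, dim = encoding$grid)
  }
  list(pooled = pooled, alpha = alpha)
}

.softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

#' Head probability from a pooled vector
#' @param head a `task_head`.
#' @param pooled attention-pooled feature vector.
#' @return probability in (0, 1): `sigmoid(u' a + b)`.
#' @export
predict_region <- function(head, pooled) {
  as.numeric(.sigmoid(sum(head$u * pooled) + head$b))
}

#' Multi-task soft-target cross-entropy loss
#'
#' Mean over the T task heads of the binary cross-entropy between the
#' (possibly probabilistic) weak target and the model prediction,
#' `-[ybar log yhat + (1 - ybar) log(1 - yhat)]`; for a batch (matrix input,
#' exams in rows) the per-exam means are averaged. Predictions are clamped
#' to `[eps, 1 - eps]` before the logarithm.
#'
#' @param targets,preds numeric vectors over regions (one exam) or matrices
#'   (exams x regions), all values in \[0, 1\].
#' @param eps clamping constant (1e-7).
#' @return scalar loss.
#' @export
multitask_loss <- function(targets, preds, eps = 1e-7) {
  stopifnot(length(targets) == length(preds),
            all(targets >= 0 & targets <= 1), all(preds >= 0 & preds <= 1))
  p <- .clamp01(preds, eps)
  ce <- -(targets * log(p) + (1 - targets) * log(1 - p))
  if (is.matrix(targets)) mean(rowMeans(ce)) else mean(ce)
}

#' Assemble a multi-task scan model
#'
#' @param encoder a `scan_encoder`.
#' @param regions character vector of region ids, one task head each.
#' @param seed integer seed for head initialization.
#' @return object of class `multitask_model`: `encoder`, `heads` (named
#'   list of `task_head`s), `regions`.
#' @export
multitask_model <- function(encoder, regions, seed = 1L) {
  stopifnot(inherits(encoder, "scan_encoder"), length(regions) >= 1L)
  heads <- lapply(seq_along(regions), function(i)
    task_head(encoder$d, regions[i], seed = seed + i))
  names(heads) <- regions
  structure(list(encoder = encoder, heads = heads, regions = regions),
            class = "multitask_model")
}

#' @export
print.multitask_model <- function(x, ...) {
  cat(sprintf("<multitask_model> %d task heads over a d = %d encoder\n",
              length(x$heads), x$encoder$d))
  invisible(x)
}

#' Predict region probabilities for scan volumes
#' @param model a `multitask_model`.
#' @param volumes a `scan_volume` or list of them.
#' @return numeric matrix exams x regions.
#' @export
predict_scan <- function(model, volumes) {
  if (inherits(volumes, "scan_volume")) volumes <- list(volumes)
  out <- matrix(NA_real_, length(volumes), length(model$regions),
                dimnames = list(NULL, model$regions))
  for (i in seq_along(volumes)) {
    enc <- encode_scan(model$encoder, volumes[[i]])
    for (r in model$regions) {
      att <- attend(model$heads[[r]], enc)
      out[i, r] <- predict_region(model$heads[[r]], att$pooled)
    }
  }
  out
}

#' Scan-model training configuration
#'
#' `profile = "published"` reproduces the published training schedule: Adam at 1e-4
#' annealed by half every 16 epochs, batch size 2, 2000 exams sampled with
#' replacement per epoch, 15 multi-task epochs, 5 fine-tuning epochs,
#' crop/brightness augmentation. `profile = "desk"` shrinks the samples per
#' epoch and raises the learning rate so the tiny encoder trains on a CPU in
#' seconds; augmentation is off by default at desk scale.
#'
#' @param profile `"desk"` or `"published"`.
#' @param ... field overrides.
#' @return list of training hyperparameters.
#' @export
scan_train_config <- function(profile = c("desk", "published"), ...) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    desk  = list(epochs = 15L, samples_per_epoch = 500L, batch_size = 8L,
                 lr = 0.02, anneal_every = 16L, anneal_factor = 0.5,
                 finetune_epochs = 5L, augment = FALSE),
    published = list(epochs = 15L, samples_per_epoch = 2000L, batch_size = 2L,
                 lr = 1e-4, anneal_every = 16L, anneal_factor = 0.5,
                 finetune_epochs = 5L, augment = TRUE))
  utils::modifyList(cfg, list(...))
}

# flatten model parameters into one named list for the optimizer
.flatten_model <- function(model) {
  p <- model$encoder$params
  for (r in model$regions) {
    h <- model$heads[[r]]
    p[[paste0("w.", r)]] <- h$w
    p[[paste0("u.", r)]] <- h$u
    p[[paste0("b.", r)]] <- h$b
  }
  p
}

.unflatten_model <- function(model, params) {
  model$encoder$params <- params[c("W1", "b1", "W2", "b2")]
  for (r in model$regions) {
    model$heads[[r]]$w <- params[[paste0("w.", r)]]
    model$heads[[r]]$u <- params[[paste0("u.", r)]]
    model$heads[[r]]$b <- params[[paste0("b.", r)]]
  }
  model
}

# loss + gradients for one exam given its pooled voxel matrix V and target
# vector ybar (named by region). Gradients on every parameter of every head
# plus the encoder; with `encoder_grad = FALSE` the encoder is frozen.
.scan_grad <- function(params, regions, V, ybar, encoder_grad = TRUE) {
  fwd <- .scan_forward(params[c("W1", "b1", "W2", "b2")], V, cache = TRUE)
  A <- fwd$A
  Tn <- length(regions)
  grads <- list()
  dA <- matrix(0, nrow(A), ncol(A))
  loss <- 0
  preds <- numeric(Tn)
  for (ti in seq_along(regions)) {
    r <- regions[ti]
    w <- params[[paste0("w.", r)]]
    u <- params[[paste0("u.", r)]]
    b <- params[[paste0("b.", r)]]
    s <- as.numeric(A %*% w)
    alpha <- .softmax(s)
    a <- as.numeric(crossprod(A, alpha))
    yhat <- .clamp01(.sigmoid(sum(u * a) + b))
    y <- ybar[[r]]
    loss <- loss + (-(y * log(yhat) + (1 - y) * log(1 - yhat))) / Tn
    preds[ti] <- yhat

    dlogit <- (yhat - y) / Tn
    grads[[paste0("u.", r)]] <- dlogit * a
    grads[[paste0("b.", r)]] <- dlogit
    da <- dlogit * u
    dalpha <- as.numeric(A %*% da)
    ds <- alpha * (dalpha - sum(alpha * dalpha))
    grads[[paste0("w.", r)]] <- as.numeric(crossprod(A, ds))
    dA <- dA + outer(alpha, da) + outer(ds, w)
  }
  if (encoder_grad) {
    dZ2 <- dA * (A > 0)
    grads$W2 <- crossprod(fwd$H1, dZ2)
    grads$b2 <- colSums(dZ2)
    dH1 <- dZ2 %*% t(params$W2)
    dZ1 <- dH1 * (fwd$H1 > 0)
    grads$W1 <- crossprod(V, dZ1)
    grads$b1 <- colSums(dZ1)
  }
  list(loss = loss, grads = grads, preds = preds)
}

#' Train the multi-task scan model
#'
#' Optimizes the soft-target multi-task loss with Adam under the step-
#' annealing schedule of the config, sampling exams with replacement each
#' epoch. Weak labels enter the loss as-is (probabilistic soft targets, not
#' binarized). Per-epoch mean training loss, learning rate and (when a
#' validation split is given) mean validation AUROC across regions are
#' logged in `history`.
#'
#' @param model a `multitask_model`.
#' @param volumes list of `scan_volume`s.
#' @param labels numeric matrix exams x regions of weak labels in \[0, 1\];
#'   columns must cover the model's regions.
#' @param config a [scan_train_config()].
#' @param val_volumes,val_labels optional validation split.
#' @param seed integer seed for sampling (and augmentation draws, if on).
#' @return the trained `multitask_model`, with `history` (data.frame) and
#'   `config` attached.
#' @export
train_multitask <- function(model, volumes, labels,
                            config = scan_train_config(),
                            val_volumes = NULL, val_labels = NULL,
                            seed = 1L) {
  stopifnot(inherits(model, "multitask_model"))
  if (!length(volumes)) stop("empty dataset")
  if (!all(model$regions %in% colnames(labels))) {
    stop("labels are missing model region(s): ",
         paste(setdiff(model$regions, colnames(labels)), collapse = ", "))
  }
  set.seed(seed)
  pooled <- lapply(volumes, function(v) .pool_volume(v, model$encoder)$V)
  params <- .flatten_model(model)
  state <- adam_init(params)
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     val_auroc = numeric())
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    idx <- sample.int(length(volumes), config$samples_per_epoch,
                      replace = TRUE)
    losses <- numeric()
    for (bstart in seq(1L, length(idx), by = config$batch_size)) {
      batch <- idx[bstart:min(bstart + config$batch_size - 1L, length(idx))]
      acc <- list()
      bl <- 0
      for (ei in batch) {
        V <- if (isTRUE(config$augment)) {
          .pool_volume(augment(volumes[[ei]]), model$encoder)$V
        } else pooled[[ei]]
        gs <- .scan_grad(params, model$regions, V, labels[ei, ])
        bl <- bl + gs$loss
        for (nm in names(gs$grads)) acc <- .acc(acc, nm, gs$grads[[nm]])
      }
      acc <- lapply(acc, `/`, length(batch))
      upd <- adam_step(params, acc, state, lr)
      params <- upd$params; state <- upd$state
      losses <- c(losses, bl / length(batch))
    }
    va <- NA_real_
    if (!is.null(val_volumes)) {
      m <- .unflatten_model(model, params)
      preds <- predict_scan(m, val_volumes)
      va <- .mean_region_auroc(preds, val_labels[, model$regions, drop = FALSE])
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   lr = lr, val_auroc = va))
  }
  model <- .unflatten_model(model, params)
  model$history <- hist
  model$config <- config
  model
}

.mean_region_auroc <- function(preds, labels) {
  aurocs <- vapply(colnames(preds), function(r) {
    y <- as.integer(labels[, r] >= 0.5)
    if (length(unique(y)) < 2L) return(NA_real_)
    binary_metrics(preds[, r], y)$auroc
  }, 0)
  mean(aurocs, na.rm = TRUE)
}

#' Fine-tune a single task from a pre-trained model
#'
#' Attaches one freshly initialized task head for `region` to the (deep copy
#' of the) given model's encoder, then optimizes all parameters on the
#' single task for `config$finetune_epochs` epochs, returning the parameters
#' from the epoch with the highest validation AUROC — not necessarily the
#' last epoch. With an untrained encoder this doubles as the from-scratch
#' single-task baseline. Any binary or probabilistic label vector works, so
#' external tasks (e.g. the mortality labels of
#' [derive_mortality_label()]) plug in with no architecture change.
#'
#' @param model a `multitask_model` (pre-trained, or fresh for the baseline).
#' @param region id for the fine-tuned task (need not be one of the model's
#'   multi-task regions).
#' @param volumes,labels training volumes and a numeric label vector.
#' @param config a [scan_train_config()]; `finetune_epochs` is used.
#' @param val_volumes,val_labels validation split used for model selection.
#' @param seed integer seed.
#' @return a single-task `multitask_model` (one head) with `history` and
#'   `best_epoch` attached.
#' @export
finetune_single_task <- function(model, region, volumes, labels,
                                 config = scan_train_config(),
                                 val_volumes = NULL, val_labels = NULL,
                                 seed = 1L) {
  stopifnot(inherits(model, "multitask_model"))
  set.seed(seed)
  st <- structure(list(encoder = model$encoder,
                       heads = stats::setNames(
                         list(task_head(model$encoder$d, region,
                                        seed = seed + 101L)), region),
                       regions = region),
                  class = "multitask_model")
  pooled <- lapply(volumes, function(v) .pool_volume(v, st$encoder)$V)
  params <- .flatten_model(st)
  state <- adam_init(params)
  lab <- matrix(as.numeric(labels), ncol = 1L,
                dimnames = list(NULL, region))
  best <- list(auroc = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_auroc = numeric())
  for (epoch in seq_len(config$finetune_epochs)) {
    lr <- lr_at_epoch(config, epoch)
    idx <- sample.int(length(volumes), config$samples_per_epoch,
                      replace = TRUE)
    losses <- numeric()
    for (bstart in seq(1L, length(idx), by = config$batch_size)) {
      batch <- idx[bstart:min(bstart + config$batch_size - 1L, length(idx))]
      acc <- list()
      bl <- 0
      for (ei in batch) {
        gs <- .scan_grad(params, region, pooled[[ei]],
                         stats::setNames(lab[ei, 1L], region))
        bl <- bl + gs$loss
        for (nm in names(gs$grads)) acc <- .acc(acc, nm, gs$grads[[nm]])
      }
      acc <- lapply(acc, `/`, length(batch))
      upd <- adam_step(params, acc, state, lr)
      params <- upd$params; state <- upd$state
      losses <- c(losses, bl / length(batch))
    }
    va <- NA_real_
    if (!is.null(val_volumes)) {
      m <- .unflatten_model(st, params)
      preds <- predict_scan(m, val_volumes)
      y <- as.integer(as.numeric(val_labels) >= 0.5)
      va <- if (length(unique(y)) < 2L) NA_real_ else
        binary_metrics(preds[, 1L], y)$auroc
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   val_auroc = va))
    if (!is.na(va) && va > best$auroc) {
      best <- list(auroc = va, params = params, epoch = epoch)
    }
  }
  if (is.finite(best$auroc)) params <- best$params
  st <- .unflatten_model(st, params)
  st$history <- hist
  st$best_epoch <- if (is.finite(best$auroc)) best$epoch else
    config$finetune_epochs
  st
}
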