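#' Hybrid loss configuration
#'
#' The training objective is `alpha * Dice + beta * RMSE`: the Dice term
#' rewards overlap between predicted and target spot regions, the RMSE term
#' enforces pixel-wise accuracy of the regressed heatmap.
#'
#' @param alpha Dice weight (default 0.6).
#' @param beta RMSE weight (default 0.4).
#' @param epsilon smoothing constant preventing division by zero in the
#'   Dice term (default 1e-5).
#' @return a `LossConfig` object.
#' @export
loss_config <- function(alpha = 0.6, beta = 0.4, epsilon = 1e-5) {
  if (alpha < 0 || beta < 0 || alpha + beta <= 0) {
    stop("need alpha, beta >= 0 and alpha + beta > 0", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "LossConfig")
}

as_map <- function(p) if (inherits(p, "ImageND")) p$data else p

check_same_shape <- function(p, t) {
  if (!identical(dim(p), dim(t))) {
    stop("predicted and target maps have different shapes", call. = FALSE)
  }
}

#' Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p^2) + sum(t^2) + eps)`; equals 0 when
#' the maps are identical (including both all-zero) and approaches 1 for
#' disjoint maps.
#'
#' @param p,t numeric arrays of the same shape with values in `[0, 1]`.
#' @param epsilon smoothing constant.
#' @return a scalar in `[0, 1]`.
#' @export
dice_loss <- function(p, t, epsilon = 1e-5) {
  p <- as_map(p); t <- as_map(t)
  check_same_shape(p, t)
  1 - (2 * sum(p * t) + epsilon) / (sum(p^2) + sum(t^2) + epsilon)
}

#' Root-mean-square-error loss
#' @inheritParams dice_loss
#' @return `sqrt(mean((p - t)^2))`.
#' @export
rmse_loss <- function(p, t) {
  p <- as_map(p); t <- as_map(t)
  check_same_shape(p, t)
  sqrt(mean((p - t)^2))
}

#' Weighted hybrid loss
#'
#' `alpha * dice_loss + beta * rmse_loss` with the weights of
#' [loss_config()].
#'
#' @inheritParams dice_loss
#' @param config a [loss_config()].
#' @return a non-negative scalar; 0 iff `p == t` elementwise.
#' @export
total_loss <- function(p, t, config = loss_config()) {
  config$alpha * dice_loss(p, t, config$epsilon) +
    config$beta * rmse_loss(p, t)
}

#' Training configuration
#'
#' @param learning_rate optimizer step size (default 1e-4).
#' @param batch_size mini-batch size (default 16).
#' @param epochs training epochs (default 200).
#' @param snapshot_every persist a periodic snapshot every this many epochs
#'   (default 5).
#' @param optimizer one of `"adam"`, `"adamw"`, `"sgd"`, `"rmsprop"`.
#' @param seed integer seed controlling shuffling, augmentation and weight
#'   initialization reproducibility.
#' @param patch_size random crop size when images are larger (default 512).
#' @param augment apply random 90-degree rotations and flips (default TRUE).
#' @param weight_decay decoupled weight decay for `"adamw"` (default 1e-4,
#'   ignored by plain `"adam"` unless positive).
#' @return a `TrainConfig` object.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         epochs = 200L, snapshot_every = 5L,
                         optimizer = c("adam", "adamw", "sgd", "rmsprop"),
                         seed = NULL, patch_size = 512L, augment = TRUE,
                         weight_decay = 0) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 snapshot_every = as.integer(snapshot_every),
                 optimizer = optimizer, seed = seed,
                 patch_size = as.integer(patch_size), augment = augment,
                 weight_decay = weight_decay),
            class = "TrainConfig")
}

rot90m <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

augment_pair <- function(x, t) {
  k <- sample(0:3, 1)
  for (i in seq_len(k)) { x <- rot90m(x); t <- rot90m(t) }
  if (sample(c(TRUE, FALSE), 1)) {
    x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    t <- t[rev(seq_len(nrow(t))), , drop = FALSE]
  }
  list(x = x, t = t)
}

#' Train the enhancement network
#'
#' Each training pair is a raw image plus its spot annotations; targets are
#' rendered once with [make_target()] and inputs normalized once with
#' [normalize_image()]. Per epoch the pairs are shuffled into mini-batches
#' and optimized on the hybrid loss; after every epoch the mean validation
#' loss (evaluation mode) is computed, the running best checkpoint is
#' refreshed whenever it strictly improves, and periodic snapshots are
#' written every `snapshot_every` epochs.
#'
#' @param model an `enhancer_net` from [build_enhancement_net()].
#' @param train_pairs,val_pairs lists of `list(image =, spots =)` pairs
#'   (as produced by [simulate_field()]).
#' @param target_cfg a [target_config()].
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param norm_spec a [normalization_spec()].
#' @param checkpoint_dir directory for `best.ckpt`, `epoch_{k}.ckpt` and
#'   `history.json`; `NULL` disables checkpointing.
#' @param verbose print per-epoch losses.
#' @return the trained model (weights of the lowest-validation-loss epoch),
#'   with attribute `"history"`: a data frame of per-epoch train/val losses.
#' @export
train_model <- function(model, train_pairs, val_pairs,
                        target_cfg = target_config(),
                        cfg = train_config(), loss_cfg = loss_config(),
                        norm_spec = normalization_spec(),
                        checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "enhancer_net"))
  if (!length(train_pairs) || !length(val_pairs)) {
    stop("training and validation sets must both be non-empty", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  prep <- function(pair) {
    img <- normalize_image(pair$image, norm_spec)
    shp <- dim(img$data)
    tgt <- make_target(pair$spots, shp, target_cfg)
    list(x = img$data, t = tgt$data)
  }
  tr <- lapply(train_pairs, prep)
  va <- lapply(val_pairs, prep)
  ptr <- net_ptr(model)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_params <- NULL
  best_bn <- NULL
  best_epoch <- NA_integer_
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(length(tr))
    batch_losses <- numeric(0)
    for (b in seq(1, length(ord), by = cfg$batch_size)) {
      sel <- ord[b:min(b + cfg$batch_size - 1, length(ord))]
      xs <- vector("list", length(sel)); ts <- xs
      for (i in seq_along(sel)) {
        p <- tr[[sel[i]]]
        x <- p$x; t <- p$t
        crop <- maybe_crop(x, t, cfg$patch_size)
        x <- crop$x; t <- crop$t
        if (cfg$augment) {
          a <- augment_pair(x, t)
          x <- a$x; t <- a$t
        }
        # strided encoder needs extents divisible by 2^n_levels
        mult <- 2^model$config$n_levels
        xs[[i]] <- pad_to_multiple(x, mult)$m
        ts[[i]] <- pad_to_multiple(t, mult)$m
      }
      l <- net_train_batch(ptr, xs, ts, cfg$learning_rate, loss_cfg$alpha,
                           loss_cfg$beta, loss_cfg$epsilon, cfg$optimizer,
                           cfg$weight_decay)
      batch_losses <- c(batch_losses, l)
    }
      val_loss <- validation_loss(ptr, va, loss_cfg,
                                2^model$config$n_levels)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      mean(batch_losses), val_loss))
    }
    if (!is.finite(val_loss)) stop("non-finite validation loss", call. = FALSE)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_epoch <- epoch
      best_params <- net_get_params(ptr)
      best_bn <- net_get_bn_state(ptr)
      if (!is.null(checkpoint_dir)) {
        net_sync_from_ptr(model)
        save_checkpoint(model, file.path(checkpoint_dir, "best.ckpt"),
                        extra = list(epoch = epoch, val_loss = val_loss))
      }
    }
    if (!is.null(checkpoint_dir) && epoch %% cfg$snapshot_every == 0) {
      net_sync_from_ptr(model)
      save_checkpoint(model,
                      file.path(checkpoint_dir, sprintf("epoch_%d.ckpt", epoch)),
                      extra = list(epoch = epoch, val_loss = val_loss))
    }
  }
  # restore the best-validation weights
  model$params <- best_params
  model$bn_state <- best_bn
  net_set_params(ptr, best_params)
  net_set_bn_state(ptr, best_bn)
  if (!is.null(checkpoint_dir)) {
    hist_out <- list(best_epoch = best_epoch, best_val_loss = best_val,
                     epochs = history)
    jsonlite::write_json(hist_out, file.path(checkpoint_dir, "history.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  attr(model, "history") <- history
  attr(model, "best_epoch") <- best_epoch
  model
}

maybe_crop <- function(x, t, patch) {
  H <- nrow(x); W <- ncol(x)
  if (H <= patch && W <= patch) return(list(x = x, t = t))
  r0 <- sample.int(max(H - patch + 1, 1), 1)
  c0 <- sample.int(max(W - patch + 1, 1), 1)
  rows <- r0:min(r0 + patch - 1, H)
  cols <- c0:min(c0 + patch - 1, W)
  list(x = x[rows, cols, drop = FALSE], t = t[rows, cols, drop = FALSE])
}

validation_loss <- function(ptr, va, loss_cfg, mult) {
  losses <- vapply(va, function(p) {
    pred <- net_forward(ptr, list(pad_to_multiple(p$x, mult)$m), FALSE)[[1]]
    pred <- pred[seq_len(nrow(p$t)), seq_len(ncol(p$t)), drop = FALSE]
    loss_cfg$alpha * dice_loss(pred, p$t, loss_cfg$epsilon) +
      loss_cfg$beta * rmse_loss(pred, p$t)
  }, 0)
  mean(losses)
}
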