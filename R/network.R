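#' Enhancement network configuration
#'
#' A compact constant-width encoder-decoder for heatmap regression: a
#' two-convolution stem, strided-convolution downsamplings each followed by
#' a residual block, a bottleneck of residual blocks around a channel+spatial
#' attention block, nearest-neighbour upsampling decoders with skip
#' concatenation, and an attention-gated two-convolution head ending in a
#' 1x1 convolution and sigmoid. With the defaults the model has 162,761
#' trainable parameters (~163k).
#'
#' @param base_channels constant channel width (default 32).
#' @param n_levels number of 2x downsamplings (default 2).
#' @param bottleneck_res_blocks residual blocks in the bottleneck (default 2,
#'   placed around the attention block).
#' @param attention_reduction channel-gate bottleneck reduction ratio
#'   (default 16; the hidden width is `max(base_channels / reduction, 1)`).
#' @param spatial_attention_kernel spatial-gate convolution size (default 7).
#' @return a `NetworkConfig` object.
#' @export
network_config <- function(base_channels = 32L, n_levels = 2L,
                           bottleneck_res_blocks = 2L,
                           attention_reduction = 16L,
                           spatial_attention_kernel = 7L) {
  if (base_channels < 8) stop("base_channels must be >= 8", call. = FALSE)
  if (n_levels < 1) stop("n_levels must be >= 1", call. = FALSE)
  if (bottleneck_res_blocks < 1) {
    stop("bottleneck_res_blocks must be >= 1", call. = FALSE)
  }
  structure(list(base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels),
                 bottleneck_res_blocks = as.integer(bottleneck_res_blocks),
                 attention_reduction = as.integer(attention_reduction),
                 spatial_attention_kernel = as.integer(spatial_attention_kernel)),
            class = "NetworkConfig")
}

#' Analytic receptive-field radius of the convolutional pathway
#'
#' Half-width of the input window that can influence one output pixel
#' through the convolutional path (stem, strided encoders, residual blocks,
#' spatial attention convolutions, decoders, head). The channel attention
#' gates additionally pool globally; block-wise inference reconstructs those
#' pooled statistics exactly (see [enhance_chunked()]), so this radius is
#' the halo needed for tiled inference to match whole-image inference.
#'
#' @param config a [network_config()].
#' @return integer radius in pixels (45 for the default configuration).
#' @export
receptive_field_radius <- function(config = network_config()) {
  L <- config$n_levels
  B <- config$bottleneck_res_blocks
  sk <- (config$spatial_attention_kernel - 1L) %/% 2L
  r <- 2L  # stem: two 3x3 convolutions
  j <- 1L
  for (l in seq_len(L)) {
    r <- r + j       # strided 3x3 downsampling conv
    j <- j * 2L
    r <- r + j       # residual block 3x3 conv
  }
  r <- r + B * j + sk * j  # bottleneck residual 3x3s + spatial gate conv
  for (l in seq_len(L)) {
    j <- j %/% 2L
    r <- r + j       # post-upsample 3x3 conv
    r <- r + 2L * j  # two fusion 3x3 convs
  }
  r + sk + 2L        # head spatial gate + two 3x3 convs
}

#' Build the enhancement network
#'
#' Instantiates the architecture of [network_config()] with He-initialized
#' convolution weights, unit batch-norm gains and zero biases. The returned
#' model maps a normalized 2D image to a same-shape map in `[0, 1]`.
#'
#' @param config a [network_config()].
#' @param seed optional integer seed for weight initialization.
#' @return an `enhancer_net` object (also of class `enhancement_model`).
#' @examples
#' model <- build_enhancement_net(seed = 1)
#' count_parameters(model)
#' @export
build_enhancement_net <- function(config = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ptr <- net_create(config$base_channels, config$n_levels,
                    config$bottleneck_res_blocks, config$attention_reduction,
                    config$spatial_attention_kernel)
  shapes <- net_param_shapes(ptr)
  params <- lapply(names(shapes), function(nm) {
    d <- shapes[[nm]]
    if (grepl("\\.gamma$", nm)) return(matrix(1, d[1], d[2]))
    if (grepl("\\.(b|beta|b1|b2)$", nm)) return(matrix(0, d[1], d[2]))
    matrix(rnorm(prod(d), 0, sqrt(2 / d[1])), d[1], d[2])  # He, fan_in = rows
  })
  names(params) <- names(shapes)
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- params
  model$bn_state <- NULL
  model$ptr <- NULL
  class(model) <- c("enhancer_net", "enhancement_model")
  model
}

# materialize (or reuse) the C++ network for a model environment
net_ptr <- function(model) {
  if (is.null(model$ptr)) {
    model$ptr <- net_create(model$config$base_channels, model$config$n_levels,
                            model$config$bottleneck_res_blocks,
                            model$config$attention_reduction,
                            model$config$spatial_attention_kernel)
    net_set_params(model$ptr, model$params)
    if (!is.null(model$bn_state)) net_set_bn_state(model$ptr, model$bn_state)
  }
  model$ptr
}

# pull trained weights back from C++ into the R-side model
net_sync_from_ptr <- function(model) {
  if (!is.null(model$ptr)) {
    model$params <- net_get_params(model$ptr)
    model$bn_state <- net_get_bn_state(model$ptr)
  }
  invisible(model)
}

#' Count trainable parameters
#'
#' Sum of all trainable scalars: convolution weights and biases, batch-norm
#' affine pairs, and attention weights. Batch-norm running statistics are
#' not trainable and are excluded.
#'
#' @param model an `enhancer_net`.
#' @return integer parameter count (162,761 for the default configuration).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "enhancer_net"))
  sum(vapply(model$params, length, 0L))
}

#' @export
print.enhancer_net <- function(x, ...) {
  cat(sprintf("<enhancer_net> C=%d, levels=%d, %s parameters, rf radius %d\n",
              x$config$base_channels, x$config$n_levels,
              format(count_parameters(x), big.mark = ","),
              receptive_field_radius(x$config)))
  invisible(x)
}

#' Wrap a plain function as an enhancement model
#'
#' Useful for stub enhancers in tests and for rule-based baselines: any
#' function mapping a 2D matrix to a same-shape matrix in `[0, 1]` can stand
#' in for the network.
#'
#' @param fn function of one 2D matrix argument.
#' @param receptive_field radius (px) outside which the stub's output does
#'   not depend on the input; 0 for pointwise stubs.
#' @param name display name.
#' @return an `enhancer_stub` object (also of class `enhancement_model`).
#' @export
enhancer_stub <- function(fn, receptive_field = 0L, name = "stub") {
  structure(list(fn = fn, receptive_field = as.integer(receptive_field),
                 name = name),
            class = c("enhancer_stub", "enhancement_model"))
}

#' Identity stub enhancer
#' @return an [enhancer_stub()] that returns its (already normalized) input.
#' @export
enhancer_identity <- function() {
  enhancer_stub(function(m) m, 0L, "identity")
}

#' Gaussian matched-filter stub enhancer
#'
#' Smooths with a Gaussian kernel matched to the PSF and rescales the result
#' to peak 1; a crude but training-free stand-in for the learned enhancer.
#'
#' @param sigma kernel sigma in pixels.
#' @return an [enhancer_stub()].
#' @export
enhancer_matched_filter <- function(sigma = 1.3) {
  r <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  enhancer_stub(function(m) {
    sm <- conv_separable_2d(m, k)
    mx <- max(sm)
    if (mx > 0) sm / mx else sm
  }, receptive_field = r, name = sprintf("matched_filter(sigma=%g)", sigma))
}

# separable 2D convolution with zero padding (kernel k applied along rows
# then columns)
conv_separable_2d <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n1 <- nrow(m); n2 <- ncol(m)
  pad1 <- rbind(matrix(0, r, n2), m, matrix(0, r, n2))
  sm <- matrix(0, n1, n2)
  for (i in seq_along(k)) sm <- sm + k[i] * pad1[i:(i + n1 - 1L), , drop = FALSE]
  pad2 <- cbind(matrix(0, n1, r), sm, matrix(0, n1, r))
  out <- matrix(0, n1, n2)
  for (i in seq_along(k)) out <- out + k[i] * pad2[, i:(i + n2 - 1L), drop = FALSE]
  out
}

#' Apply an enhancement model to a single 2D image
#'
#' For the network model the input is padded at the bottom/right edges with
#' a mirror reflection to a multiple of `2^n_levels` (so the strided encoder
#' divides evenly), run through the network in evaluation mode, and cropped
#' back to the original shape. The origin is never shifted, which keeps
#' tiled inference consistent with whole-image inference.
#'
#' @param model an `enhancement_model`.
#' @param img a 2D [image_nd()] or matrix with values in `[0, 1]`.
#' @param ... further arguments for methods (internal gate overrides).
#' @return an object of the same kind as `img` (matrix in, matrix out) with
#'   values in `[0, 1]`.
#' @export
apply_model <- function(model, img, ...) UseMethod("apply_model")

#' @export
apply_model.enhancer_net <- function(model, img, gates = NULL, ...) {
  m <- as_matrix_2d(img)
  pad <- pad_to_multiple(m, 2^model$config$n_levels)
  g1 <- if (!is.null(gates)) gates[[1]] else NULL
  g2 <- if (!is.null(gates) && length(gates) > 1) gates[[2]] else NULL
  out <- net_forward(net_ptr(model), list(pad$m), FALSE, g1, g2)[[1]]
  out <- out[seq_len(nrow(m)), seq_len(ncol(m)), drop = FALSE]
  rewrap_2d(img, out)
}

#' @export
apply_model.enhancer_stub <- function(model, img, ...) {
  m <- as_matrix_2d(img)
  out <- model$fn(m)
  if (!identical(dim(out), dim(m))) {
    stop("stub enhancer changed the image shape", call. = FALSE)
  }
  rewrap_2d(img, pmin(pmax(out, 0), 1))
}

as_matrix_2d <- function(img) {
  m <- if (inherits(img, "ImageND")) img$data else img
  if (length(dim(m)) != 2) {
    stop("apply_model expects a single 2D image", call. = FALSE)
  }
  m
}

rewrap_2d <- function(img, out) {
  if (inherits(img, "ImageND")) image_nd(out, img$axes, img$pixel_size) else out
}

# mirror-pad the bottom/right edges so both extents divide `mult`
pad_to_multiple <- function(m, mult) {
  H <- nrow(m); W <- ncol(m)
  ph <- (mult - H %% mult) %% mult
  pw <- (mult - W %% mult) %% mult
  if (ph > 0) m <- rbind(m, m[H - seq_len(ph), , drop = FALSE])
  if (pw > 0) m <- cbind(m, m[, W - seq_len(pw), drop = FALSE])
  list(m = m, ph = ph, pw = pw)
}

#' Save an enhancement model checkpoint
#'
#' Single-file checkpoint with a versioned header carrying the network
#' configuration, all trainable weights and the batch-norm running
#' statistics.
#'
#' @param model an `enhancer_net`.
#' @param path destination file.
#' @param extra optional named list stored alongside (epoch, losses, ...).
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "enhancer_net"))
  net_sync_from_ptr(model)
  obj <- list(format = "fishspotr-enhancer", version = 1L,
              config = model$config, params = model$params,
              bn_state = model$bn_state, extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load an enhancement model checkpoint
#' @param path checkpoint file written by [save_checkpoint()].
#' @return an `enhancer_net`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "fishspotr-enhancer")) {
    stop("not a fishspotr checkpoint: ", path, call. = FALSE)
  }
  model <- new.env(parent = emptyenv())
  model$config <- obj$config
  model$params <- obj$params
  model$bn_state <- obj$bn_state
  model$ptr <- NULL
  model$extra <- obj$extra
  class(model) <- c("enhancer_net", "enhancement_model")
  model
}

model_receptive_field <- function(model) {
  if (inherits(model, "enhancer_net")) receptive_field_radius(model$config)
  else model$receptive_field
}
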