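#' Enhance an image by 2D slice routing
#'
#' Every `(y, x)` slice across all leading `t/c/z` indices is independently
#' percentile-normalized and passed through the model; channels and planes
#' are never mixed.
#'
#' @param model an `enhancement_model`.
#' @param img an [image_nd()] with trailing `(y, x)` axes.
#' @param norm_spec a [normalization_spec()].
#' @return an [image_nd()] of the same shape and axes with values in
#'   `[0, 1]`.
#' @export
enhance_2d <- function(model, img, norm_spec = normalization_spec()) {
  stopifnot(inherits(img, "ImageND"))
  apply_yx_slices(img, function(m) {
    as_matrix_2d(apply_model(model, normalize_slice(m, norm_spec)))
  })
}

#' Enhance a volume by tri-axial blending
#'
#' A 2D model applied plane-by-plane along z alone tends to enhance
#' axially elongated spots in several consecutive planes, which downstream
#' peak detection then reports repeatedly. Tri-axial blending runs the 2D
#' model over slices perpendicular to each of the three axes (z, y, x)
#' separately — each pass normalizes its own slices — and multiplies the
#' three enhanced stacks elementwise. A true spot is bright in all three
#' views, so the product keeps it, while axial smears bright in only the
#' z view are suppressed.
#'
#' @param model an `enhancement_model`.
#' @param vol an [image_nd()] with trailing `(z, y, x)` axes (leading `t/c`
#'   allowed); every spatial extent must be at least 16.
#' @param norm_spec a [normalization_spec()].
#' @return an [image_nd()] of the same shape with values in `[0, 1]`.
#' @export
enhance_3d_blend <- function(model, vol, norm_spec = normalization_spec()) {
  stopifnot(inherits(vol, "ImageND"))
  ax <- vol$axes
  if (!all(c("z", "y", "x") %in% ax)) {
    stop("enhance_3d_blend needs z, y and x axes", call. = FALSE)
  }
  d <- dim(vol$data)
  sp <- match(c("z", "y", "x"), ax)
  if (any(d[sp] < 16)) {
    stop("every spatial extent must be >= 16 for enhancement", call. = FALSE)
  }
  apply_zyx_volumes(vol, function(a) blend_volume(model, a, norm_spec))
}

blend_volume <- function(model, a, norm_spec) {
  d <- dim(a)  # (z, y, x)
  enh_axis <- function(axis) {
    out <- array(0, d)
    if (axis == 1) {
      for (i in seq_len(d[1])) {
        out[i, , ] <- as_matrix_2d(apply_model(
          model, normalize_slice(array(a[i, , ], d[2:3]), norm_spec)))
      }
    } else if (axis == 2) {
      for (i in seq_len(d[2])) {
        out[, i, ] <- as_matrix_2d(apply_model(
          model, normalize_slice(array(a[, i, ], d[c(1, 3)]), norm_spec)))
      }
    } else {
      for (i in seq_len(d[3])) {
        out[, , i] <- as_matrix_2d(apply_model(
          model, normalize_slice(array(a[, , i], d[1:2]), norm_spec)))
      }
    }
    out
  }
  enh_axis(1) * enh_axis(2) * enh_axis(3)
}

# apply f to every (z, y, x) sub-volume across leading indices
apply_zyx_volumes <- function(vol, f) {
  ax <- vol$axes
  sp <- match(c("z", "y", "x"), ax)
  d <- dim(vol$data)
  lead <- setdiff(seq_along(d), sp)
  out <- vol$data
  if (!length(lead)) {
    out[] <- f(vol$data)
    return(image_nd(out, ax, vol$pixel_size))
  }
  grid <- expand.grid(lapply(d[lead], seq_len))
  for (r in seq_len(nrow(grid))) {
    idx <- rep(list(quote(expr = )), length(d))
    for (k in seq_along(lead)) idx[[lead[k]]] <- grid[[k]][r]
    sl <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
    res <- f(array(sl, d[sp]))
    out <- do.call(`[<-`, c(list(out), idx, list(value = array(res, dim(sl)))))
  }
  image_nd(out, ax, vol$pixel_size)
}

#' Block plan for chunked inference
#'
#' @param block_shape core block extents on the spatial axes, e.g.
#'   `c(y = 256, x = 256)`. Extents are rounded up internally to a multiple
#'   of the model's downsampling factor so the strided encoder stays aligned
#'   with the whole-image stride grid.
#' @param halo overlap margin read around each block, or `"auto"` for the
#'   model's receptive-field radius (rounded up to the downsampling
#'   multiple). With `halo >= receptive_field_radius(config)` the chunked
#'   result matches whole-image enhancement.
#' @return a `ChunkPlan` object.
#' @export
chunk_plan <- function(block_shape = c(y = 256L, x = 256L), halo = "auto") {
  block_shape <- as.integer(block_shape)
  if (any(block_shape < 1)) stop("block extents must be >= 1", call. = FALSE)
  if (!identical(halo, "auto")) {
    halo <- as.integer(halo)
    if (halo < 0) stop("halo must be >= 0", call. = FALSE)
  }
  structure(list(block_shape = block_shape, halo = halo),
            class = "ChunkPlan")
}

# ---------------------------------------------------------------------------
# array-store abstraction: zarr on disk or in-memory arrays

as_store <- function(x) {
  if (inherits(x, "zarr_store")) return(list(kind = "zarr", store = x))
  if (is.character(x)) return(list(kind = "zarr", store = zarr_open(x)))
  if (inherits(x, "ImageND")) {
    e <- new.env(parent = emptyenv())
    e$data <- x$data
    return(list(kind = "mem", env = e, axes = x$axes))
  }
  stop("expected a zarr store, a zarr path or an ImageND", call. = FALSE)
}

store_shape <- function(st) {
  if (st$kind == "zarr") st$store$shape else dim(st$env$data)
}

store_axes <- function(st) {
  if (st$kind == "zarr") {
    if (!is.null(st$store$attrs$axes)) {
      return(strsplit(st$store$attrs$axes, "")[[1]])
    }
    return(default_axes(length(st$store$shape)))
  }
  st$axes
}

store_read <- function(st, offset, size) {
  if (st$kind == "zarr") return(zarr_read_sub(st$store, offset, size))
  nd <- length(offset)
  idx <- lapply(seq_len(nd), function(i) (offset[i] + 1L):(offset[i] + size[i]))
  do.call(`[`, c(list(st$env$data), idx, list(drop = FALSE)))
}

store_write <- function(st, offset, arr) {
  if (st$kind == "zarr") return(zarr_write_sub(st$store, offset, arr))
  nd <- length(offset)
  d <- dim(arr)
  idx <- lapply(seq_len(nd), function(i) (offset[i] + 1L):(offset[i] + d[i]))
  st$env$data <- do.call(`[<-`, c(list(st$env$data), idx, list(value = arr)))
  invisible(st)
}

#' Chunked block-wise enhancement over array stores
#'
#' Processes an image store block by block: each spatial block is read with
#' an overlap margin (halo, clipped at image borders), enhanced, and only
#' the core region written back, so peak resident memory is bounded by one
#' haloed block plus one 2D slice of normalization/attention statistics.
#'
#' For the network model the channel-attention gates pool over the whole
#' slice, so a naive tiled pass would not reproduce whole-image inference.
#' The driver therefore makes one extra pass per attention block, collecting
#' each block's contribution to the pooled statistics over exactly its core
#' region, derives the whole-slice gate scalars, and re-runs the blocks with
#' the gates pinned. With `halo` at least the receptive-field radius the
#' result then equals monolithic [enhance_2d()] to within float rounding.
#'
#' @param model an `enhancement_model`.
#' @param src source: a zarr path/store or an [image_nd()].
#' @param dst destination: a zarr path (created with chunks equal to the
#'   block shape), an existing store of identical shape, or `NULL` when
#'   `src` is in-memory (the result is returned as an [image_nd()]).
#' @param plan a [chunk_plan()].
#' @param mode `"2d"` (slice routing) or `"3d_blend"` (tri-axial blending;
#'   chunked across planes, holding one slice at a time).
#' @param norm_spec a [normalization_spec()].
#' @return the destination store handle, or an [image_nd()] for in-memory
#'   output.
#' @export
enhance_chunked <- function(model, src, dst = NULL, plan = chunk_plan(),
                            mode = c("2d", "3d_blend"),
                            norm_spec = normalization_spec()) {
  mode <- match.arg(mode)
  sstore <- as_store(src)
  shape <- store_shape(sstore)
  axes <- store_axes(sstore)
  nd <- length(shape)
  # destination
  ret_mem <- FALSE
  if (is.null(dst)) {
    if (sstore$kind != "mem") {
      stop("dst may only be NULL for in-memory sources", call. = FALSE)
    }
    e <- new.env(parent = emptyenv())
    e$data <- array(0, shape)
    dstore <- list(kind = "mem", env = e, axes = axes)
    ret_mem <- TRUE
  } else if (is.character(dst) && !is_zarr_path(dst)) {
    chunks <- rep(1L, nd)
    sp_ax <- intersect(c("y", "x"), axes)
    ip <- match(sp_ax, axes)
    bs <- plan_block_for(plan, sp_ax)
    chunks[ip] <- pmin(bs, shape[ip])
    if ("z" %in% axes) chunks[match("z", axes)] <- min(16L, shape[match("z", axes)])
    dstore <- list(kind = "zarr",
                   store = zarr_create(dst, shape, chunks = chunks,
                                       dtype = "<f8",
                                       attrs = list(axes = paste(axes, collapse = ""))))
  } else {
    dstore <- as_store(dst)
    if (!identical(store_shape(dstore), shape)) {
      stop("src and dst shapes differ", call. = FALSE)
    }
  }
  if (mode == "2d") {
    chunked_2d(model, sstore, dstore, plan, norm_spec, shape, axes)
  } else {
    chunked_3d_blend(model, sstore, dstore, plan, norm_spec, shape, axes)
  }
  if (ret_mem) image_nd(dstore$env$data, axes) else
    (if (dstore$kind == "zarr") dstore$store else dstore)
}

plan_block_for <- function(plan, sp_ax) {
  bs <- plan$block_shape
  if (!is.null(names(bs)) && all(sp_ax %in% names(bs))) return(bs[sp_ax])
  if (length(bs) == length(sp_ax)) return(bs)
  rep(bs[1], length(sp_ax))
}

plan_halo <- function(plan, model, mult) {
  if (identical(plan$halo, "auto")) {
    rf <- model_receptive_field(model)
    as.integer(ceiling(rf / mult) * mult)
  } else {
    as.integer(ceiling(plan$halo / mult) * mult)
  }
}

chunked_2d <- function(model, sstore, dstore, plan, norm_spec, shape, axes) {
  iy <- match("y", axes); ix <- match("x", axes)
  if (is.na(iy) || is.na(ix)) stop("store lacks y or x axis", call. = FALSE)
  nd <- length(shape)
  lead <- setdiff(seq_len(nd), c(iy, ix))
  grid <- if (length(lead)) {
    expand.grid(lapply(shape[lead], function(n) 0:(n - 1L)))
  } else {
    data.frame(row.names = 1)
  }
  for (r in seq_len(nrow(grid))) {
    lead_off <- if (length(lead)) as.integer(grid[r, ]) else integer(0)
    read_slice_block <- function(y0, x0, ny, nx) {
      off <- integer(nd); size <- rep(1L, nd)
      off[lead] <- lead_off
      off[iy] <- y0; off[ix] <- x0
      size[iy] <- ny; size[ix] <- nx
      matrix(store_read(sstore, off, size), ny, nx)
    }
    write_slice_block <- function(y0, x0, m) {
      off <- integer(nd)
      off[lead] <- lead_off
      off[iy] <- y0; off[ix] <- x0
      d <- rep(1L, nd); d[iy] <- nrow(m); d[ix] <- ncol(m)
      store_write(dstore, off, array(m, d))
    }
    enhance_slice_chunked(model, read_slice_block, write_slice_block,
                          shape[iy], shape[ix], plan, norm_spec)
  }
  invisible(dstore)
}

enhance_slice_chunked <- function(model, read_block, write_block, H, W,
                                  plan, norm_spec) {
  is_net <- inherits(model, "enhancer_net")
  mult <- if (is_net) 2^model$config$n_levels else 1L
  bs <- plan_block_for(plan, c("y", "x"))
  by <- as.integer(ceiling(bs[1] / mult) * mult)
  bx <- as.integer(ceiling(bs[2] / mult) * mult)
  halo <- plan_halo(plan, model, mult)
  y0s <- seq(0L, H - 1L, by = by)
  x0s <- seq(0L, W - 1L, by = bx)
  blocks <- expand.grid(y0 = y0s, x0 = x0s)
  # pass A: slice-wide normalization percentiles (identical to enhance_2d)
  normalize_with <- identity
  if (!is.null(norm_spec)) {
    vals <- numeric(H * W)
    pos <- 1L
    for (b in seq_len(nrow(blocks))) {
      y0 <- blocks$y0[b]; x0 <- blocks$x0[b]
      ny <- min(by, H - y0); nx <- min(bx, W - x0)
      blk <- read_block(y0, x0, ny, nx)
      vals[pos:(pos + length(blk) - 1L)] <- blk
      pos <- pos + length(blk)
    }
    qs <- quantile(vals, c(norm_spec$low_percentile,
                           norm_spec$high_percentile) / 100,
                   names = FALSE, type = 1)
    normalize_with <- function(m) {
      if (qs[2] <= qs[1]) return(matrix(0, nrow(m), ncol(m)))
      pmin(pmax((m - qs[1]) / (qs[2] - qs[1]), 0), 1)
    }
  }
  block_geom <- function(b, h) {
    y0 <- blocks$y0[b]; x0 <- blocks$x0[b]
    y1 <- min(y0 + by, H); x1 <- min(x0 + bx, W)
    Y0 <- max(0L, y0 - h); Y1 <- min(H, y1 + h)
    X0 <- max(0L, x0 - h); X1 <- min(W, x1 + h)
    list(y0 = y0, y1 = y1, x0 = x0, x1 = x1,
         Y0 = Y0, Y1 = Y1, X0 = X0, X1 = X1,
         Hp = as.integer(ceiling((Y1 - Y0) / mult) * mult),
         Wp = as.integer(ceiling((X1 - X0) / mult) * mult))
  }
  gates <- NULL
  if (is_net) {
    ptr <- net_ptr(model)
    S <- mult
    # statistics passes always use a clean receptive-field halo so the
    # reconstructed gate scalars equal the whole-image ones regardless of
    # the inference halo
    halo_stats <- max(halo, plan_halo(chunk_plan(halo = "auto"), model, mult))
    gates <- list(NULL, NULL)
    for (att in 0:1) {
      s_at <- if (att == 0) S else 1L
      tot_sum <- NULL; tot_max <- NULL; tot_n <- 0
      for (b in seq_len(nrow(blocks))) {
        g <- block_geom(b, halo_stats)
        blk <- normalize_with(read_block(g$Y0, g$X0, g$Y1 - g$Y0, g$X1 - g$X0))
        blk <- pad_to_multiple(blk, mult)$m
        r0 <- (g$y0 - g$Y0) %/% s_at
        r1 <- if (g$y1 == H) g$Hp %/% s_at else (g$y1 - g$Y0) %/% s_at
        c0 <- (g$x0 - g$X0) %/% s_at
        c1 <- if (g$x1 == W) g$Wp %/% s_at else (g$x1 - g$X0) %/% s_at
        st <- net_collect_stats(ptr, blk, att, r0, r1, c0, c1, gates[[1]])
        if (is.null(tot_sum)) {
          tot_sum <- st$sum; tot_max <- st$max
        } else {
          tot_sum <- tot_sum + st$sum
          tot_max <- pmax(tot_max, st$max)
        }
        tot_n <- tot_n + st$n
      }
      gates[[att + 1]] <- net_gate_from_stats(ptr, att, tot_sum / tot_n,
                                              tot_max)
    }
  }
  # final pass: enhance and write cores
  for (b in seq_len(nrow(blocks))) {
    g <- block_geom(b, halo)
    blk <- normalize_with(read_block(g$Y0, g$X0, g$Y1 - g$Y0, g$X1 - g$X0))
    enh <- if (is_net) {
      as_matrix_2d(apply_model(model, blk, gates = gates))
    } else {
      as_matrix_2d(apply_model(model, blk))
    }
    core <- enh[(g$y0 - g$Y0 + 1L):(g$y1 - g$Y0),
                (g$x0 - g$X0 + 1L):(g$x1 - g$X0), drop = FALSE]
    write_block(g$y0, g$x0, core)
  }
  invisible(NULL)
}

chunked_3d_blend <- function(model, sstore, dstore, plan, norm_spec, shape,
                             axes) {
  sp <- match(c("z", "y", "x"), axes)
  if (anyNA(sp)) stop("3d_blend needs z, y and x axes", call. = FALSE)
  nd <- length(shape)
  lead <- setdiff(seq_len(nd), sp)
  grid <- if (length(lead)) {
    expand.grid(lapply(shape[lead], function(n) 0:(n - 1L)))
  } else {
    data.frame(row.names = 1)
  }
  d3 <- shape[sp]
  for (r in seq_len(nrow(grid))) {
    lead_off <- if (length(lead)) as.integer(grid[r, ]) else integer(0)
    read_plane <- function(axis, i) {
      off <- integer(nd); size <- rep(1L, nd)
      off[lead] <- lead_off
      off[sp] <- c(0L, 0L, 0L); off[sp[axis]] <- i
      size[sp] <- d3; size[sp[axis]] <- 1L
      array(store_read(sstore, off, size), d3[-axis])
    }
    # per-axis enhanced stacks held in temporary chunked stores
    tmp <- lapply(1:3, function(axis) {
      td <- tempfile(sprintf("blend_ax%d_", axis))
      st <- zarr_create(td, d3, chunks = c(min(16L, d3[1]), d3[2], d3[3]),
                        dtype = "<f8")
      for (i in seq_len(d3[axis])) {
        m <- normalize_slice(read_plane(axis, i - 1L), norm_spec)
        enh <- as_matrix_2d(apply_model(model, m))
        off <- c(0L, 0L, 0L); off[axis] <- i - 1L
        sz <- d3; sz[axis] <- 1L
        zarr_write_sub(st, off, array(enh, sz))
      }
      st
    })
    # multiply the three stacks block-wise along z
    zstep <- min(16L, d3[1])
    for (z0 in seq(0L, d3[1] - 1L, by = zstep)) {
      nz <- min(zstep, d3[1] - z0)
      prod_blk <- zarr_read_sub(tmp[[1]], c(z0, 0L, 0L), c(nz, d3[2], d3[3])) *
        zarr_read_sub(tmp[[2]], c(z0, 0L, 0L), c(nz, d3[2], d3[3])) *
        zarr_read_sub(tmp[[3]], c(z0, 0L, 0L), c(nz, d3[2], d3[3]))
      off <- integer(nd); size <- rep(1L, nd)
      off[lead] <- lead_off
      off[sp] <- c(z0, 0L, 0L)
      size[sp] <- c(nz, d3[2], d3[3])
      store_write(dstore, off, array(prod_blk, size))
    }
    for (st in tmp) unlink(st$path, recursive = TRUE)
  }
  invisible(dstore)
}
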