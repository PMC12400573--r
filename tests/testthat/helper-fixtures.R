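# shared fixtures: tiny simulated datasets and models built in code

sim_pairs <- function(n, seed0, shape = c(128L, 128L), n_spots = c(10L, 40L),
                      ...) {
  lapply(seq_len(n), function(i) {
    simulate_field(simulation_config(shape = shape, n_spots = n_spots,
                                     seed = seed0 + i, ...))
  })
}

# a small, fast network for tests that exercise training mechanics rather
# than the default architecture
tiny_net_config <- function() {
  network_config(base_channels = 8L, n_levels = 1L,
                 bottleneck_res_blocks = 1L, attention_reduction = 4L)
}

# brute-force plateau-aware local maxima oracle (2D), independent of the
# package implementation
brute_maxima_2d <- function(m, threshold) {
  d <- dim(m)
  lab <- array(0L, d)
  nextl <- 0L
  res <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (lab[i, j] > 0 || m[i, j] < threshold) next
    # flood fill equal-valued region
    nextl <- nextl + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nextl
    region <- NULL
    ismax <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      region <- rbind(region, p)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        q <- p + c(di, dj)
        if (q[1] < 1 || q[1] > d[1] || q[2] < 1 || q[2] > d[2]) next
        if (m[q[1], q[2]] == m[p[1], p[2]]) {
          if (lab[q[1], q[2]] == 0) {
            lab[q[1], q[2]] <- nextl
            stack[[length(stack) + 1L]] <- q
          }
        } else if (m[q[1], q[2]] > m[p[1], p[2]]) {
          ismax <- FALSE
        }
      }
    }
    if (ismax) res <- rbind(res, colMeans(region) - 1)
  }
  res
}

# brute-force greedy matcher: enumerate all pairs, sort, assign one-to-one
brute_match <- function(pred, gt, cutoff) {
  pm <- as.matrix(as.data.frame(pred))
  gm <- as.matrix(as.data.frame(gt))
  if (!nrow(pm) || !nrow(gm)) {
    return(list(tp = 0L, pairs = data.frame(gt = integer(0),
                                            pred = integer(0),
                                            distance = numeric(0))))
  }
  cand <- NULL
  for (g in seq_len(nrow(gm))) for (p in seq_len(nrow(pm))) {
    dd <- sqrt(sum((gm[g, ] - pm[p, ])^2))
    if (dd < cutoff) cand <- rbind(cand, data.frame(gt = g, pred = p,
                                                    distance = dd))
  }
  if (is.null(cand)) {
    return(list(tp = 0L, pairs = data.frame(gt = integer(0),
                                            pred = integer(0),
                                            distance = numeric(0))))
  }
  cand <- cand[order(cand$distance, cand$gt, cand$pred), ]
  ug <- logical(nrow(gm)); up <- logical(nrow(pm)); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!ug[cand$gt[i]] && !up[cand$pred[i]]) {
      ug[cand$gt[i]] <- TRUE; up[cand$pred[i]] <- TRUE; keep[i] <- TRUE
    }
  }
  list(tp = sum(keep), pairs = cand[keep, ])
}

place_well_separated <- function(n, d, min_sep) {
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    cand <- c(runif(1, 2, d[1] - 3), runif(1, 2, d[2] - 3))
    if (!nrow(pts) || min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}

conv_sep_test <- function(m) {
  k <- exp(-0.5 * ((-3):3 / 1.2)^2); k <- k / sum(k)
  n1 <- nrow(m); n2 <- ncol(m); r <- 3
  p <- rbind(matrix(0, r, n2), m, matrix(0, r, n2))
  s <- matrix(0, n1, n2)
  for (i in seq_along(k)) s <- s + k[i] * p[i:(i + n1 - 1), ]
  p <- cbind(matrix(0, n1, r), s, matrix(0, n1, r))
  out <- matrix(0, n1, n2)
  for (i in seq_along(k)) out <- out + k[i] * p[, i:(i + n2 - 1)]
  out / max(out)
}
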