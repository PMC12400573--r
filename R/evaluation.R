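#' Matching configuration
#'
#' @param cutoff maximum Euclidean distance (pixels) for a prediction to
#'   count as a true positive; matches require distance strictly below the
#'   cutoff (default 3).
#' @return a `MatchConfig` object.
#' @export
match_config <- function(cutoff = 3.0) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  structure(list(cutoff = cutoff), class = "MatchConfig")
}

#' Match predicted spots to ground truth
#'
#' Candidate pairs within the cutoff are found with a uniform spatial grid
#' (bucket width = cutoff, the same neighbour-pruning role a KD-tree plays)
#' and assigned greedily in ascending distance order, each point used at
#' most once; ties are broken by (ground-truth index, prediction index) for
#' determinism. One-to-one assignment guarantees `fp = n_pred - tp >= 0`
#' even when several ground-truth points share a nearest prediction.
#'
#' @param pred,gt [spot_table()]s of equal dimensionality.
#' @param config a [match_config()].
#' @return a `MatchResult`: list with `pairs` (data frame of `gt`, `pred`,
#'   `distance`), counts `tp`, `fp`, `fn`, `n_pred`, `n_gt`, and the cutoff.
#' @export
match_spots <- function(pred, gt, config = match_config()) {
  pm <- as.matrix(as.data.frame(pred))
  gm <- as.matrix(as.data.frame(gt))
  if (ncol(pm) != ncol(gm) && nrow(pm) && nrow(gm)) {
    stop("predicted and ground-truth tables have different dimensionality",
         call. = FALSE)
  }
  cand <- candidate_pairs(gm, pm, config$cutoff)
  pairs <- data.frame(gt = integer(0), pred = integer(0),
                      distance = numeric(0))
  if (nrow(cand)) {
    cand <- cand[order(cand$distance, cand$gt, cand$pred), , drop = FALSE]
    used_g <- logical(nrow(gm))
    used_p <- logical(nrow(pm))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      g <- cand$gt[i]; p <- cand$pred[i]
      if (!used_g[g] && !used_p[p]) {
        used_g[g] <- TRUE
        used_p[p] <- TRUE
        keep[i] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  tp <- nrow(pairs)
  structure(list(pairs = pairs, tp = tp, fp = nrow(pm) - tp,
                 fn = nrow(gm) - tp, n_pred = nrow(pm), n_gt = nrow(gm),
                 cutoff = config$cutoff),
            class = "MatchResult")
}

# all (gt, pred) pairs with distance < cutoff, via grid-bucket pruning
candidate_pairs <- function(gm, pm, cutoff) {
  empty <- data.frame(gt = integer(0), pred = integer(0),
                      distance = numeric(0))
  if (!nrow(gm) || !nrow(pm)) return(empty)
  nd <- ncol(gm)
  cell_key <- function(m) {
    cells <- floor(m / cutoff)
    apply(cells, 1, paste, collapse = ",")
  }
  pk <- split(seq_len(nrow(pm)), cell_key(pm))
  gcells <- floor(gm / cutoff)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  res_g <- integer(0); res_p <- integer(0); res_d <- numeric(0)
  for (g in seq_len(nrow(gm))) {
    neigh <- integer(0)
    for (o in seq_len(nrow(offs))) {
      key <- paste(gcells[g, ] + offs[o, ], collapse = ",")
      neigh <- c(neigh, pk[[key]])
    }
    if (!length(neigh)) next
    dd <- sqrt(colSums((t(pm[neigh, , drop = FALSE]) - gm[g, ])^2))
    ok <- dd < cutoff
    if (any(ok)) {
      res_g <- c(res_g, rep(g, sum(ok)))
      res_p <- c(res_p, neigh[ok])
      res_d <- c(res_d, dd[ok])
    }
  }
  data.frame(gt = res_g, pred = res_p, distance = res_d)
}

#' Detection metrics from a match result
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2 * precision * recall / (precision + recall)`, and the
#' localization (distance) error is the mean distance over matched pairs.
#' Conventions: with no predictions and no ground truth, `f1 = 1` and
#' `distance_error = 0` (an all-negative image is a perfect result); with
#' points present but no matches, `f1 = 0` and the distance error is the
#' undefined sentinel `NA`.
#'
#' @param match a `MatchResult` from [match_spots()].
#' @return a list with `f1`, `precision`, `recall`, `distance_error`.
#' @export
compute_metrics <- function(match) {
  stopifnot(inherits(match, "MatchResult"))
  if (match$n_pred == 0 && match$n_gt == 0) {
    return(list(f1 = 1, precision = 1, recall = 1, distance_error = 0))
  }
  if (match$tp == 0) {
    return(list(f1 = 0, precision = 0, recall = 0,
                distance_error = NA_real_))
  }
  precision <- match$tp / (match$tp + match$fp)
  recall <- match$tp / (match$tp + match$fn)
  list(f1 = 2 * precision * recall / (precision + recall),
       precision = precision, recall = recall,
       distance_error = mean(match$pairs$distance))
}

#' Evaluate a detector over a dataset
#'
#' Matches each predicted table against its aligned ground-truth table and
#' reports per-image metrics plus the dataset medians of F1 and of the
#' defined distance errors (images with no matches contribute no distance
#' error).
#'
#' @param pred_tables,gt_tables equal-length lists of [spot_table()]s.
#' @param config a [match_config()].
#' @return a list with `per_image` (data frame) and `median_f1`,
#'   `median_distance_error`.
#' @export
evaluate_dataset <- function(pred_tables, gt_tables,
                             config = match_config()) {
  if (length(pred_tables) != length(gt_tables)) {
    stop("prediction and ground-truth lists have different lengths",
         call. = FALSE)
  }
  rows <- lapply(seq_along(pred_tables), function(i) {
    m <- match_spots(pred_tables[[i]], gt_tables[[i]], config)
    met <- compute_metrics(m)
    data.frame(image = i, n_pred = m$n_pred, n_gt = m$n_gt, tp = m$tp,
               fp = m$fp, fn = m$fn, f1 = met$f1,
               precision = met$precision, recall = met$recall,
               distance_error = met$distance_error)
  })
  per_image <- do.call(rbind, rows)
  de <- per_image$distance_error
  list(per_image = per_image,
       median_f1 = median(per_image$f1),
       median_distance_error = if (any(!is.na(de))) {
         median(de[!is.na(de)])
       } else {
         NA_real_
       })
}
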