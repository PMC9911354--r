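# Detection and segmentation metrics: tolerance-radius particle matching
# with F1, voxel-F1 (Sorensen-Dice), AUPRC on randomly sampled voxels, and
# the cross-validation fold planner.

#' Match predicted against ground-truth particles within a tolerance radius
#'
#' A predicted particle is a true positive when its coordinates fall within
#' `tolerance_voxels` (default 10 voxels, 135 Angstrom at 13.48 Angstrom
#' spacing) of an unmatched ground-truth particle.  Matching is one-to-one
#' and greedy by ascending pairwise distance (ties broken by prediction
#' order); unmatched predictions are false positives, unmatched ground
#' truth false negatives.
#'
#' @param pred,gt [particle_set()] objects in the same volume geometry.
#' @param tolerance_voxels matching radius in voxels.
#' @param voxel_size_A optional spacing used to report the tolerance in
#'   Angstrom.
#' @return An object of class `"match_result"` with counts `TP`, `FP`,
#'   `FN` and the matched `pairs` (pred index, gt index, distance).
#' @export
match_particles <- function(pred, gt, tolerance_voxels = 10,
                            voxel_size_A = NULL) {
  stopifnot(tolerance_voxels > 0)
  np <- nrow(pred)
  ng <- nrow(gt)
  pairs <- data.frame(pred = integer(), gt = integer(),
                      distance = numeric())
  if (np > 0 && ng > 0) {
    dx <- outer(pred$x, gt$x, `-`)
    dy <- outer(pred$y, gt$y, `-`)
    dz <- outer(pred$z, gt$z, `-`)
    dd <- sqrt(dx^2 + dy^2 + dz^2)
    cand <- which(dd <= tolerance_voxels, arr.ind = TRUE)
    if (nrow(cand)) {
      dist <- dd[cand]
      ord <- order(dist, cand[, 1], cand[, 2])
      used_p <- logical(np)
      used_g <- logical(ng)
      for (i in ord) {
        p <- cand[i, 1]
        g <- cand[i, 2]
        if (used_p[p] || used_g[g]) next
        used_p[p] <- TRUE
        used_g[g] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = p, gt = g,
                                         distance = dist[i]))
      }
    }
  }
  tp <- nrow(pairs)
  res <- structure(list(TP = tp, FP = np - tp, FN = ng - tp, pairs = pairs,
                        tolerance_voxels = tolerance_voxels),
                   class = "match_result")
  if (!is.null(voxel_size_A))
    res$tolerance_A <- tolerance_voxels * mean(voxel_size_A)
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (tolerance %g voxels%s)\n",
              x$TP, x$FP, x$FN, x$tolerance_voxels,
              if (!is.null(x$tolerance_A))
                sprintf(" = %g A", x$tolerance_A) else ""))
  invisible(x)
}

#' Precision, recall and F1 from a particle match
#'
#' Recall is the proportion of ground-truth particles recovered, precision
#' the proportion of predictions that are true positives, and F1 their
#' harmonic mean (0 when undefined).
#'
#' @param match a [match_particles()] result (or list with `TP`, `FP`, `FN`).
#' @return A list with `precision`, `recall` and `f1`.
#' @export
detection_f1 <- function(match) {
  tp <- match$TP; fp <- match$FP; fn <- match$FN
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Voxel-wise F1 (Sorensen-Dice coefficient) of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; symmetric, 1 for identical masks.  When both
#' masks are empty the score is defined as 1 (nothing to segment, nothing
#' segmented).
#'
#' @param a,b binary [label_mask()] objects or arrays of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
voxel_f1 <- function(a, b) {
  ma <- if (inherits(a, "label_mask")) a$data else a
  mb <- if (inherits(b, "label_mask")) b$data else b
  if (!identical(dim(ma), dim(mb)))
    stopf("voxel_f1: mask shapes differ (%s vs %s)",
          paste(dim(ma), collapse = "x"), paste(dim(mb), collapse = "x"))
  na <- sum(ma > 0)
  nb <- sum(mb > 0)
  if (na + nb == 0) return(1)
  2 * sum(ma > 0 & mb > 0) / (na + nb)
}

#' Area under the precision-recall curve on sampled voxels
#'
#' Evaluates a probability map against a ground-truth mask on `n_sample`
#' randomly picked voxels (default 5,000): precision and recall are
#' computed at every threshold attained by the sampled scores and the area
#' is integrated by the trapezoidal rule over recall.
#'
#' @param probmap a `"prob_map"` or 3D array of scores.
#' @param gt_mask binary [label_mask()] or array of the same shape.
#' @param n_sample number of voxels to sample.
#' @param seed RNG seed for the voxel sample.
#' @return An object of class `"auprc"`: list with `auprc`, the PR `curve`
#'   (threshold, precision, recall) and the sampled prevalence.
#' @export
auprc <- function(probmap, gt_mask, n_sample = 5000, seed = 1) {
  p <- if (inherits(probmap, "prob_map")) probmap$data else probmap
  g <- if (inherits(gt_mask, "label_mask")) gt_mask$data else gt_mask
  if (!identical(dim(p), dim(g))) stopf("auprc: shape mismatch")
  N <- length(p)
  pick <- function() if (N <= n_sample) seq_len(N) else
    sample.int(N, n_sample)
  idx <- with_seed(seed, pick())
  if (!any(g[idx] > 0)) {
    warnf("no positive voxels in AUPRC sample; resampling once")
    idx <- with_seed(seed + 1, pick())
    if (!any(g[idx] > 0))
      stopf("undefined metric: no positive voxels among sampled voxels")
  }
  scores <- as.numeric(p[idx])
  labels <- as.integer(g[idx] > 0)
  ord <- order(-scores)
  scores <- scores[ord]
  labels <- labels[ord]
  P <- sum(labels)
  cum_tp <- cumsum(labels)
  npred <- seq_along(labels)
  # group tied scores: evaluate at the last index of each unique score
  last <- which(!duplicated(scores, fromLast = TRUE))
  precision <- cum_tp[last] / npred[last]
  recall <- cum_tp[last] / P
  curve <- data.frame(threshold = scores[last], precision = precision,
                      recall = recall)
  rec <- c(0, recall)
  prec <- c(precision[1], precision)
  area <- sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
  structure(list(auprc = area, curve = curve,
                 prevalence = P / length(labels), n_sample = length(idx)),
            class = "auprc")
}

#' @export
print.auprc <- function(x, ...) {
  cat(sprintf("<auprc> %.4f (prevalence %.3f on %d sampled voxels)\n",
              x$auprc, x$prevalence, x$n_sample))
  invisible(x)
}

#' Plan cross-validation folds with fixed-size test sets
#'
#' Shuffles the tomogram ids and assigns `n_folds` disjoint test sets of
#' `test_size` ids; each fold trains on all remaining ids.  With 10 ids,
#' 3 folds and test size 2 this reproduces a threefold scheme with 8
#' training and 2 test tomograms per fold.
#'
#' @param ids vector of tomogram identifiers.
#' @param n_folds number of folds.
#' @param test_size test tomograms per fold.
#' @param seed RNG seed for the shuffle.
#' @return An object of class `"fold_plan"`: list of folds, each with
#'   `train` and `test` id vectors.
#' @export
make_folds <- function(ids, n_folds = 3, test_size = 2, seed = 1) {
  if (n_folds < 1 || test_size < 1 || n_folds * test_size > length(ids))
    stopf(paste0("configuration error: cannot draw %d disjoint test sets ",
                 "of %d from %d ids"), n_folds, test_size, length(ids))
  shuffled <- with_seed(seed, sample(ids))
  folds <- lapply(seq_len(n_folds), function(k) {
    test <- shuffled[((k - 1) * test_size + 1):(k * test_size)]
    list(train = setdiff(ids, test), test = test)
  })
  structure(list(folds = folds, seed = seed), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d fold(s)\n", length(x$folds)))
  for (k in seq_along(x$folds))
    cat(sprintf("  fold %d: %d train / %d test\n", k,
                length(x$folds[[k]]$train), length(x$folds[[k]]$test)))
  invisible(x)
}
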