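#' Circular Euclidean distance between two catalog rotamers
#'
#' Distance between mean torsion vectors in the seven-dimensional suite
#' torsion space, each coordinate difference wrapped into (-180, 180].
#'
#' @param r1,r2 Rotamer ids.
#' @param catalog From [load_catalog()].
#' @return Distance in degrees.
#' @export
rotamer_distance <- function(r1, r2, catalog) {
  torsion_distance(rotamer_means(catalog, r1), rotamer_means(catalog, r2))
}

# all pairwise circular distances between catalog mean vectors
rotamer_distance_matrix <- function(catalog) {
  M <- as.matrix(catalog[, torsion_cols()])
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(catalog$rotamer_id,
                                       catalog$rotamer_id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sqrt(sum(wrap180(M[i, ] - M[j, ])^2))
  D
}

#' Build a rotamer substitution matrix (ROSUM)
#'
#' Weights a predicted-vs-true label pair by torsion-space proximity: the
#' matrix entry is a Gaussian kernel in the circular inter-rotamer
#' distance, W\[a,b\] = exp(-d(a,b)^2 / (2 * bandwidth^2)), so the diagonal
#' is exactly 1 and near-miss predictions retain credit.  For a family
#' scheme, the distance between two families is the frequency-weighted
#' mean pairwise distance between their member rotamers.  Rotamer
#' frequencies enter the evaluation through the random-baseline
#' calibration (see [random_baseline()]) rather than being folded into W.
#'
#' @param catalog From [load_catalog()].
#' @param scheme_id `"rotamer"` for the 46-label matrix, or a family
#'   scheme id.
#' @param bandwidth Kernel bandwidth in degrees, or `"auto"` for the
#'   median pairwise inter-rotamer distance.
#' @param family_map From [load_family_map()].
#' @return A `rosum` object: `labels`, `weights` (square matrix,
#'   diagonal 1), `scheme_id`, `bandwidth`.
#' @export
build_rosum <- function(catalog, scheme_id = "rotamer", bandwidth = "auto",
                        family_map = load_family_map()) {
  D <- rotamer_distance_matrix(catalog)
  if (identical(bandwidth, "auto"))
    bandwidth <- stats::median(D[upper.tri(D)])
  stopifnot(bandwidth > 0)
  if (identical(scheme_id, "rotamer")) {
    labels <- catalog$rotamer_id
    Df <- D
  } else {
    fam <- family_of(catalog$rotamer_id, scheme_id, family_map)
    labels <- sort(unique(fam))
    w <- catalog$frequency
    Df <- matrix(0, length(labels), length(labels),
                 dimnames = list(labels, labels))
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      if (i == j) next
      mi <- which(fam == labels[i]); mj <- which(fam == labels[j])
      ww <- outer(w[mi], w[mj])
      Df[i, j] <- sum(ww * D[mi, mj, drop = FALSE]) / sum(ww)
    }
  }
  W <- exp(-Df^2 / (2 * bandwidth^2))
  diag(W) <- 1
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, weights = W, scheme_id = scheme_id,
                 bandwidth = bandwidth),
            class = "rosum")
}

#' @export
print.rosum <- function(x, ...) {
  cat("ROSUM for scheme", x$scheme_id, "-", length(x$labels),
      "labels, bandwidth", round(x$bandwidth, 2), "deg\n")
  invisible(x)
}

#' ROSUM-weighted accuracy
#'
#' Mean over items of W\[true, predicted\]: 1 for exact matches, partial
#' credit for predictions close in torsion space, recalibrating the
#' contribution of the unevenly observed rotamers.
#'
#' @param truth,predicted Equal-length label vectors (labels must be in
#'   the matrix).
#' @param rosum From [build_rosum()].
#' @return Score in \[0, 1\].
#' @export
weighted_accuracy <- function(truth, predicted, rosum) {
  stopifnot(length(truth) == length(predicted))
  bad <- setdiff(c(truth, predicted), rosum$labels)
  if (length(bad))
    stop("label(s) not in ROSUM: ", paste(bad, collapse = ", "))
  mean(rosum$weights[cbind(truth, predicted)])
}

#' Support-weighted precision, recall and F1
#'
#' Per-label precision, recall and F1 (the harmonic mean of the two),
#' averaged with weights equal to each label's support in the truth.
#' Labels that are only ever predicted contribute zero precision and are
#' reported in the `predicted_only` attribute.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return Named numeric vector `precision`, `recall`, `f1`, with the
#'   per-label table in attribute `"per_label"`.
#' @export
standard_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  labs <- sort(unique(c(truth, predicted)))
  per <- t(vapply(labs, function(l) {
    tp <- sum(truth == l & predicted == l)
    fp <- sum(truth != l & predicted == l)
    fn <- sum(truth == l & predicted != l)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1, support = tp + fn)
  }, numeric(4)))
  w <- per[, "support"] / sum(per[, "support"])
  out <- c(precision = sum(w * per[, "precision"]),
           recall = sum(w * per[, "recall"]),
           f1 = sum(w * per[, "f1"]))
  attr(out, "per_label") <- per
  attr(out, "predicted_only") <- labs[!(labs %in% truth)]
  out
}

#' Expected scores of the random-choice baseline
#'
#' The random classifier predicts labels by sampling from a reference
#' label distribution (by default the catalog observation frequencies
#' mapped through the scheme).  Its expected weighted accuracy over a test
#' set is sum_t p(t) sum_p q(p) W[t, p]; this calibration is reported
#' alongside every score so uneven rotamer frequencies are explicit.
#'
#' @param truth Test label vector.
#' @param rosum From [build_rosum()].
#' @param prob Named prediction distribution over labels; defaults to
#'   uniform over the matrix labels.
#' @return Named vector: expected `weighted_accuracy` and expected plain
#'   `accuracy` of the random classifier.
#' @export
random_baseline <- function(truth, rosum, prob = NULL) {
  labs <- rosum$labels
  if (is.null(prob)) prob <- stats::setNames(rep(1 / length(labs),
                                                 length(labs)), labs)
  prob <- prob[labs] / sum(prob[labs], na.rm = TRUE)
  prob[is.na(prob)] <- 0
  pt <- table(factor(truth, levels = labs)) / length(truth)
  c(weighted_accuracy = as.numeric(t(as.numeric(pt)) %*% rosum$weights %*%
                                     as.numeric(prob)),
    accuracy = sum(as.numeric(pt) * as.numeric(prob)))
}
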