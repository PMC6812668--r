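#' Shannon entropy of an angle sample
#'
#' Entropy S = -sum(P_i log P_i) in nats of the normalised histogram of
#' the sample over fixed bins \[0,5), \[5,10), ..., \[355,360) degrees
#' (bin width configurable); empty bins contribute zero.
#'
#' @param values Numeric vector of angles in degrees (wrapped to \[0,360)).
#' @param bin_width Histogram bin width in degrees (default 5).
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon_entropy(rep(2, 50))                   # one bin: 0
#' shannon_entropy(c(2, 7, 12, 17))              # uniform over 4 bins: log(4)
shannon_entropy <- function(values, bin_width = 5) {
  if (!length(values)) stop("empty sample")
  b <- floor(wrap360(values) / bin_width)
  p <- tabulate(as.integer(b) + 1L)
  p <- p[p > 0] / length(values)
  -sum(p * log(p))
}

# total entropy of a torsion-vector matrix: sum of the 7 marginal entropies
total_suite_entropy <- function(tv, bin_width = 5) {
  sum(apply(tv, 2, shannon_entropy, bin_width = bin_width))
}

#' Entropy retention curve over subsample sizes
#'
#' For each sample size n, draws `replicates` subsets (without
#' replacement) of the conformer set's torsion vectors and computes the
#' subset's total entropy (the sum of the seven per-torsion histogram
#' entropies) as a percentage of the full set's total entropy.
#'
#' @param conformer_set From [sample_rotamer()], or a plain torsion matrix.
#' @param sample_sizes Integer vector of subset sizes (must not exceed the
#'   set size).
#' @param replicates Subsets drawn per size.
#' @param seed Integer seed.
#' @param bin_width Histogram bin width in degrees.
#' @return Data.frame with columns `n`, `mean_pct`, `min_pct`, `max_pct`.
#' @export
entropy_curve <- function(conformer_set, sample_sizes = seq(5, 100, by = 5),
                          replicates = 50, seed = 1, bin_width = 5) {
  tv <- if (is.matrix(conformer_set)) conformer_set else
    conformer_set$torsion_vectors
  if (any(sample_sizes > nrow(tv)))
    stop("sample size exceeds conformer set size (", nrow(tv), ")")
  full <- total_suite_entropy(tv, bin_width)
  set.seed(seed)
  out <- lapply(sample_sizes, function(n) {
    pct <- vapply(seq_len(replicates), function(r) {
      sub <- tv[sample.int(nrow(tv), n), , drop = FALSE]
      if (full == 0) 100 else 100 * total_suite_entropy(sub, bin_width) / full
    }, numeric(1))
    data.frame(n = n, mean_pct = mean(pct), min_pct = min(pct),
               max_pct = max(pct))
  })
  do.call(rbind, out)
}

#' Select a subsample size from an entropy curve
#'
#' Smallest n whose mean entropy percentage reaches the cutoff (default
#' 80% of the full-set entropy); if no size reaches it, the largest n is
#' returned with a warning.
#'
#' @param curve From [entropy_curve()].
#' @param cutoff_percent Retention threshold in percent.
#' @return Integer sample size.
#' @export
select_sample_size <- function(curve, cutoff_percent = 80) {
  stopifnot(nrow(curve) > 0)
  curve <- curve[order(curve$n), , drop = FALSE]
  hit <- which(curve$mean_pct >= cutoff_percent)
  if (!length(hit)) {
    warning("no sample size reaches ", cutoff_percent,
            "% entropy; returning the largest")
    return(curve$n[nrow(curve)])
  }
  curve$n[hit[1]]
}
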