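#' Default parameters of the synthetic shielding generator
#'
#' The generator emulates the empirical structure of ribose 13C'
#' shieldings: the dominant dependence is on the ribose pucker pair (the
#' dd family of the generating rotamer, i.e. the delta(i-1)/delta(i)
#' states), a weaker smooth dependence on the alpha and gamma torsions, a
#' sequence-dependent offset per base, and Gaussian theoretical noise.
#' A-form vs non-A-form rotamers get no effect beyond pucker, so that
#' distinction is unlearnable from shifts by construction.
#'
#' Units: ppm.  `base_shield` are per-nucleus shieldings whose simple
#' referencing (185 - sigma) lands in the observed ribose shift ranges
#' (C1' ~92, C2' ~75, C3' ~73, C4' ~83, C5' ~65 ppm).  `pucker_unit` is
#' the shielding change for a C2'-endo delta(i); delta(i-1) contributes
#' `prev_factor` of it.  `angle_amp` are cosine-series amplitudes for the
#' alpha and gamma dependence; `noise_sd` is the theoretical noise.
#'
#' @return A named list of generator parameters.
#' @export
default_shift_params <- function() {
  nuc <- nucleus_cols()
  base_shield <- c(C1p = 93.0, C2p = 110.0, C3p = 112.0, C4p = 102.0,
                   C5p = 120.0)
  # sequence offsets per base of residue i (rows = nuclei)
  seq_effect <- matrix(c(
    # A     C     G     U
    0.9, -0.4, 0.5, -0.8,   # C1p
    -0.3, 0.6, -0.6, 0.4,   # C2p
    0.4, -0.5, 0.7, -0.3,   # C3p
    -0.6, 0.3, -0.2, 0.5,   # C4p
    0.5, -0.7, 0.3, -0.2),  # C5p
    nrow = 5, byrow = TRUE,
    dimnames = list(nuc, c("A", "C", "G", "U")))
  pucker_unit <- c(C1p = -1.6, C2p = -1.2, C3p = 4.2, C4p = 2.4, C5p = -0.8)
  # dd families: a = (3',3'), b = (3',2'), c = (2',3'), d = (2',2')
  pucker_effect <- cbind(a = 0 * pucker_unit,
                         b = pucker_unit,
                         c = 0.5 * pucker_unit,
                         d = 1.5 * pucker_unit)
  angle_amp <- matrix(c(
    0.2, 0.2,    # C1p: alpha, gamma
    0.2, 0.2,    # C2p
    0.3, 0.2,    # C3p
    0.3, 0.5,    # C4p
    0.2, 1.0),   # C5p: gamma-sensitive
    nrow = 5, byrow = TRUE, dimnames = list(nuc, c("alpha", "gamma")))
  list(base_shield = base_shield, seq_effect = seq_effect,
       prev_factor = 0.3, pucker_effect = pucker_effect,
       angle_amp = angle_amp, angle_phase = c(alpha = 0.7, gamma = -0.4),
       noise_sd = 0.3)
}

#' Generate synthetic theoretical shielding records
#'
#' Stands in for quantum-chemical shielding computation: for each rotamer
#' x sequence x conformer, suite torsions are drawn from the catalog
#' wrapped normals (or taken from supplied conformer sets) and the five
#' shieldings are built as
#' sigma(nucleus) = base + sequence offsets + pucker term (keyed by the
#' generating rotamer's dd family) + cosine terms in alpha and gamma +
#' Gaussian noise.  Referenced shifts under the simple 185.00 ppm scheme
#' are included as the `C1p ... C5p` columns.
#'
#' @param catalog From [load_catalog()].
#' @param sequences Character vector of DN sequences to emulate.
#' @param n_per_rotamer Conformers per rotamer per sequence.
#' @param params From [default_shift_params()].
#' @param seed Integer seed (reproducible).
#' @param rotamers Subset of rotamer ids (default: all 46).
#' @param family_map From [load_family_map()].
#' @param torsion_sets Optional named list `rotamer_id -> sequence ->`
#'   torsion matrix from [sample_rotamer()]; when given, torsions come
#'   from these conformers instead of fresh draws.
#' @return Data.frame of records: `rotamer_id`, `sequence`, `conformer`,
#'   `origin = "theoretical"`, torsions `alpha`/`gamma`, `sigma_C1p` ...
#'   `sigma_C5p` and shifts `C1p` ... `C5p`.
#' @export
generate_theoretical <- function(catalog, sequences = c("AA", "GC"),
                                 n_per_rotamer = 40,
                                 params = default_shift_params(), seed = 1,
                                 rotamers = catalog$rotamer_id,
                                 family_map = load_family_map(),
                                 torsion_sets = NULL) {
  stopifnot(all(rotamers %in% catalog$rotamer_id))
  dd <- family_of(rotamers, "dd", family_map)
  if (!all(dd %in% colnames(params$pucker_effect)))
    stop("generation error: unknown dd family key")
  set.seed(seed)
  nuc <- nucleus_cols()
  out <- list()
  for (ri in seq_along(rotamers)) {
    id <- rotamers[ri]
    mu <- rotamer_means(catalog, id)
    sdv <- rotamer_spreads(catalog, id)
    for (sq in sequences) {
      bases <- strsplit(sq, "")[[1]]
      if (!is.null(torsion_sets)) {
        tv <- torsion_sets[[id]][[sq]]
        if (is.null(tv)) stop("no torsion set for ", id, "/", sq)
        n <- nrow(tv)
      } else {
        n <- n_per_rotamer
        tv <- matrix(wrap360(stats::rnorm(7L * n, mu, sdv)),
                     ncol = 7, byrow = TRUE,
                     dimnames = list(NULL, torsion_cols()))
      }
      mean_part <- params$base_shield +
        params$seq_effect[, bases[2]] +
        params$prev_factor * params$seq_effect[, bases[1]] +
        params$pucker_effect[, dd[ri]]
      arad <- tv[, "a"] * pi / 180
      grad <- tv[, "g"] * pi / 180
      ang_part <-
        outer(cos(arad + params$angle_phase[["alpha"]]),
              params$angle_amp[, "alpha"]) +
        0.5 * outer(cos(2 * arad), params$angle_amp[, "alpha"]) +
        outer(cos(grad + params$angle_phase[["gamma"]]),
              params$angle_amp[, "gamma"]) +
        0.5 * outer(cos(2 * grad), params$angle_amp[, "gamma"])
      sig <- sweep(ang_part, 2, mean_part, "+") +
        matrix(stats::rnorm(n * 5L, 0, params$noise_sd), n, 5L)
      colnames(sig) <- paste0("sigma_", nuc)
      rec <- data.frame(rotamer_id = id, sequence = sq,
                        conformer = seq_len(n), origin = "theoretical",
                        alpha = tv[, "a"], gamma = tv[, "g"], sig,
                        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- rec
    }
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  reference_records(rec, simple_reference(), family_map)
}

#' Derive experimental-like records from theoretical ones
#'
#' Adds i.i.d. Gaussian noise per nucleus at the expected
#' theory-vs-experiment discrepancy (1.47 ppm by default) to the
#' referenced shifts, optionally perturbs them by per-context offsets, and
#' subsamples records per rotamer according to a sparsity profile -
#' mimicking the sparse, noisy experimental dataset.
#'
#' @param records From [generate_theoretical()].
#' @param noise_sd Noise standard deviation in ppm.
#' @param sparsity Optional named vector `rotamer_id -> retention`:
#'   values in \[0, 1\] are retention probabilities, values > 1 are
#'   retained counts.  Rotamers absent from the profile keep everything.
#' @param seed Integer seed.
#' @param offsets Optional per-sequence offset table (named vector
#'   `sequence -> ppm`) added to all five shifts; used to emulate a
#'   systematic theory/experiment discrepancy that effective references
#'   should recover.
#' @return Records with `origin = "experimental_like"`, shift columns
#'   perturbed, sigma columns dropped.
#' @export
generate_experimental_like <- function(records, noise_sd = 1.47,
                                       sparsity = NULL, seed = 1,
                                       offsets = NULL) {
  stopifnot(noise_sd >= 0)
  if (!is.null(sparsity)) {
    bad <- setdiff(names(sparsity), unique(records$rotamer_id))
    if (length(bad))
      stop("sparsity profile names unknown rotamer(s): ",
           paste(bad, collapse = ", "))
  }
  set.seed(seed)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(sparsity)) {
    for (id in names(sparsity)) {
      rows <- which(records$rotamer_id == id)
      r <- sparsity[[id]]
      k <- if (r <= 1) stats::rbinom(1, length(rows), r)
      else min(length(rows), as.integer(r))
      drop <- if (k < length(rows))
        if (k == 0) rows else rows[-sample(seq_along(rows), k)]
      else integer()
      keep[drop] <- FALSE
    }
  }
  out <- records[keep, , drop = FALSE]
  nuc <- nucleus_cols()
  off <- if (is.null(offsets)) 0 else {
    o <- offsets[out$sequence]
    o[is.na(o)] <- 0
    o
  }
  for (c_ in nuc)
    out[[c_]] <- out[[c_]] + off +
      stats::rnorm(nrow(out), 0, noise_sd)
  out$origin <- "experimental_like"
  out[paste0("sigma_", nuc)] <- NULL
  rownames(out) <- NULL
  out
}
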