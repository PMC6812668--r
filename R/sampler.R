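#' Set a suite torsion on template coordinates
#'
#' Rotates the torsion's downstream atom set about the central bond so
#' that the measured dihedral equals `target`, leaving every bond length
#' and bond angle unchanged (rigid geometry approximation).
#'
#' @param coords Matrix (n x 3) of template coordinates.
#' @param torsion_def One element of a template's `torsions` list:
#'   `atoms` (4 indices) and `downstream` (indices rotated with the bond).
#' @param target Target dihedral in degrees.
#' @return The new coordinate matrix.
#' @export
set_torsion <- function(coords, torsion_def, target) {
  q <- torsion_def$atoms
  ds <- torsion_def$downstream
  if (!length(ds)) stop("template definition error: empty downstream set")
  cur <- dihedral(coords[q[1], ], coords[q[2], ], coords[q[3], ],
                  coords[q[4], ])
  delta <- wrap180(target - cur)
  if (abs(delta) < 1e-12) return(coords)
  coords[ds, ] <- rotate_about_axis(coords[ds, , drop = FALSE],
                                    coords[q[2], ],
                                    coords[q[3], ] - coords[q[2], ],
                                    delta)
  coords
}

#' Van der Waals radii used for clash detection (Angstrom)
#' @return Named numeric vector by element symbol.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80)
}

#' Detect steric clashes
#'
#' TRUE iff some pair of atoms separated by more than 3 bonds in the bond
#' graph lies closer than `overlap_factor` times the sum of the two van
#' der Waals radii.  Pairs 1-3 bonds apart are never counted.
#'
#' @param coords Matrix (n x 3).
#' @param bonds 2-column index matrix (the bond list).
#' @param elements Character vector of element symbols per atom.
#' @param overlap_factor Overlap tolerance (default 0.7).
#' @param bond_sep Precomputed bond-graph distance matrix (optional,
#'   avoids recomputing in sampling loops).
#' @return Logical scalar.
#' @export
detect_clash <- function(coords, bonds, elements, overlap_factor = 0.7,
                         bond_sep = NULL) {
  r <- vdw_radii()[elements]
  if (anyNA(r))
    stop("clash configuration error: unknown element(s) ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  if (is.null(bond_sep)) bond_sep <- bond_separation(bonds, nrow(coords))
  d2 <- as.matrix(stats::dist(coords))^2
  cut <- outer(r, r, "+") * overlap_factor
  check <- bond_sep > 3
  any(d2[check] < cut[check]^2)
}

#' @rdname detect_clash
#' @param n_atoms Number of atoms (vertices) in the graph.
#' @export
bond_separation <- function(bonds, n_atoms) {
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_atoms - igraph::vcount(g)))
  igraph::distances(g)
}

#' Sample conformers of one rotamer on a template
#'
#' Monte-Carlo rigid-geometry sampling: each of the seven suite torsions
#' is drawn independently from a wrapped normal with the catalog mean and
#' spread, all seven are applied with [set_torsion()], and conformers with
#' atom clashes are rejected, until `n_target` conformers are retained or
#' the attempt cap (`100 * n_target`) is reached.
#'
#' @param template From [dn_template()].
#' @param rotamer_def One catalog row (data.frame) or a list with
#'   `rotamer_id`, mean torsions and spreads in the catalog column layout.
#' @param n_target Number of retained conformers wanted.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param overlap_factor Clash threshold, see [detect_clash()].
#' @param keep_coords If TRUE, retain each conformer's coordinates.
#' @return A `conformer_set` list: `rotamer_id`, `sequence`,
#'   `torsion_vectors` (retained x 7 matrix of measured torsions),
#'   `coords` (list or NULL), `counts` (generated, clash_rejected,
#'   retained) and `warning_partial`.
#' @export
sample_rotamer <- function(template, rotamer_def, n_target, seed = 1,
                           overlap_factor = 0.7, keep_coords = FALSE) {
  stopifnot(n_target >= 1)
  mu <- unlist(rotamer_def[torsion_cols()])
  sd <- unlist(rotamer_def[paste0("sd_", torsion_cols())])
  coords0 <- as.matrix(template$atoms[, c("x", "y", "z")])
  sep <- bond_separation(template$bonds, nrow(coords0))
  set.seed(seed)
  kept <- list(); coords_kept <- list()
  generated <- 0L; rejected <- 0L
  cap <- 100L * n_target
  while (length(kept) < n_target && generated < cap) {
    generated <- generated + 1L
    tor <- wrap360(stats::rnorm(7, mu, sd))
    cc <- coords0
    for (k in seq_along(template$torsions))
      cc <- set_torsion(cc, template$torsions[[k]], tor[k])
    if (detect_clash(cc, template$bonds, template$atoms$element,
                     overlap_factor, bond_sep = sep)) {
      rejected <- rejected + 1L
      next
    }
    kept[[length(kept) + 1L]] <- tor
    if (keep_coords) coords_kept[[length(coords_kept) + 1L]] <- cc
  }
  tv <- if (length(kept)) do.call(rbind, kept) else
    matrix(numeric(), 0, 7)
  colnames(tv) <- torsion_cols()
  partial <- length(kept) < n_target
  if (partial)
    warning("attempt cap reached: ", length(kept), " of ", n_target,
            " conformers retained for ", rotamer_def$rotamer_id)
  structure(list(rotamer_id = rotamer_def$rotamer_id,
                 sequence = template$sequence,
                 torsion_vectors = tv,
                 coords = if (keep_coords) coords_kept else NULL,
                 counts = c(generated = generated, clash_rejected = rejected,
                            retained = nrow(tv)),
                 warning_partial = partial),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("conformer_set:", x$rotamer_id, "/", x$sequence, "-",
      x$counts[["retained"]], "retained of", x$counts[["generated"]],
      "generated (", x$counts[["clash_rejected"]], "clash-rejected )\n")
  invisible(x)
}
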