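#' Dinucleotide templates for rigid-geometry sampling
#'
#' One idealized dinucleotide (DN) template per 2-letter sequence over
#' {A, C, G, U}: heavy-atom coordinates built from standard internal
#' coordinates, a bond list, and the atom quadruple plus downstream atom
#' set for each of the seven suite torsions.  The sugar is represented as
#' an open (acyclic) branch hanging off C4' via O4', so that every torsion
#' rotation is an exact branch rotation preserving all bond lengths and
#' bond angles; the base is reduced to the glycosidic nitrogen plus two
#' (pyrimidine) or three (purine) ring atoms, enough to give clash
#' detection a realistic excluded volume.  Templates are constructed in
#' code, not taken from deposited structures.
#'
#' @param sequence 2-letter dinucleotide, e.g. "AA", "GC".
#' @param ref_torsions Suite torsions used for the build pose (defaults to
#'   the A-form rotamer 1a means); any pose works since all seven torsions
#'   are reset during sampling.
#' @return A `dn_template` list: `sequence`, `atoms` (data.frame with
#'   `name`, `residue`, `element`, `x`, `y`, `z`), `bonds` (2-column index
#'   matrix), `torsions` (named list with `atoms` = 4 indices and
#'   `downstream` = rotated atom indices for d1, e1, z1, a, b, g, d2).
#' @export
#' @examples
#' tpl <- dn_template("AA")
#' length(dn_templates())  # 16
dn_template <- function(sequence,
                        ref_torsions = c(81, 212, 289, 295, 174, 54, 81)) {
  stopifnot(nchar(sequence) == 2)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "U")))
    stop("sequence must be over A, C, G, U")
  g <- backbone_geom()
  atoms <- list(); bonds <- list()
  add <- function(residue, name, element, xyz, bond_to = NULL) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, residue = residue, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    i_new <- length(atoms)
    if (!is.null(bond_to))
      bonds[[length(bonds) + 1L]] <<- c(idx(bond_to), i_new)
    i_new
  }
  idx <- function(key) {
    nm <- vapply(atoms, function(a) paste0(a$residue, ":", a$name), "")
    i <- match(key, nm)
    if (is.na(i)) stop("template build: unknown atom ", key)
    i
  }
  xyz <- function(key) {
    a <- atoms[[idx(key)]]
    c(a$x, a$y, a$z)
  }
  put <- function(residue, name, element, aref, bref, cref,
                  len, ang, tor) {
    p <- place_atom(xyz(aref), xyz(bref), xyz(cref), len, ang, tor)
    add(residue, name, element, p, bond_to = cref)
  }
  # sugar + base branch, attached at C4' through O4' (open ribose: the
  # C2'-C3' ring closure is intentionally absent so the bond graph is a tree)
  add_sugar_base <- function(r, base) {
    purine <- base %in% c("A", "G")
    c5 <- paste0(r, ":C5'")
    c4 <- paste0(r, ":C4'")
    # O4' sits +121 deg from C3' about the C5'-C4' axis, whatever the pose
    put(r, "O4'", "O", paste0(r, ":C3'"), c5, c4, 1.450, 109.2, 121)
    put(r, "C1'", "C", c5, c4, paste0(r, ":O4'"), 1.414, 109.7, 100)
    put(r, "C2'", "C", c4, paste0(r, ":O4'"), paste0(r, ":C1'"),
        1.527, 106.5, 180)
    put(r, "O2'", "O", paste0(r, ":O4'"), paste0(r, ":C1'"),
        paste0(r, ":C2'"), 1.413, 110.0, 60)
    nglyc <- if (purine) "N9" else "N1"
    put(r, nglyc, "N", c4, paste0(r, ":O4'"), paste0(r, ":C1'"),
        1.475, 108.5, 0)
    cb1 <- if (purine) "C8" else "C6"
    put(r, cb1, "C", paste0(r, ":O4'"), paste0(r, ":C1'"),
        paste0(r, ":", nglyc), 1.372, 127.0, 200)
    cb2 <- if (purine) "N7" else "C5"
    put(r, cb2, if (purine) "N" else "C", paste0(r, ":C1'"),
        paste0(r, ":", nglyc), paste0(r, ":", cb1), 1.380, 113.0, 180)
    if (purine)
      put(r, "C5", "C", paste0(r, ":", nglyc), paste0(r, ":", cb1),
          paste0(r, ":", cb2), 1.390, 104.0, 0)
  }
  tr <- ref_torsions
  # residue 1 backbone seed (as in build_suite_chain); the suite is
  # sugar-to-sugar, so residue 1 carries no 5' phosphate or O5'
  c5a <- add(1L, "C5'", "C", c(0, 0, 0))
  c4a <- add(1L, "C4'", "C", c(g$len[["C5'-C4'"]], 0, 0), bond_to = "1:C5'")
  th <- (180 - g$ang[["C5'-C4'-C3'"]]) * pi / 180
  add(1L, "C3'", "C",
      c(g$len[["C5'-C4'"]] + g$len[["C4'-C3'"]] * cos(th),
        g$len[["C4'-C3'"]] * sin(th), 0), bond_to = "1:C4'")
  put(1L, "O3'", "O", "1:C5'", "1:C4'", "1:C3'",
      g$len[["C3'-O3'"]], g$ang[["C4'-C3'-O3'"]], tr[1])
  put(2L, "P", "P", "1:C4'", "1:C3'", "1:O3'",
      g$len[["O3'-P"]], g$ang[["C3'-O3'-P"]], tr[2])
  put(2L, "O5'", "O", "1:C3'", "1:O3'", "2:P",
      g$len[["P-O5'"]], g$ang[["O3'-P-O5'"]], tr[3])
  put(2L, "OP1", "O", "1:C3'", "1:O3'", "2:P", 1.485, 108.1, tr[3] + 119)
  put(2L, "OP2", "O", "1:C3'", "1:O3'", "2:P", 1.485, 108.1, tr[3] - 119)
  put(2L, "C5'", "C", "1:O3'", "2:P", "2:O5'",
      g$len[["O5'-C5'"]], g$ang[["P-O5'-C5'"]], tr[4])
  put(2L, "C4'", "C", "2:P", "2:O5'", "2:C5'",
      g$len[["C5'-C4'"]], g$ang[["O5'-C5'-C4'"]], tr[5])
  put(2L, "C3'", "C", "2:O5'", "2:C5'", "2:C4'",
      g$len[["C4'-C3'"]], g$ang[["C5'-C4'-C3'"]], tr[6])
  put(2L, "O3'", "O", "2:C5'", "2:C4'", "2:C3'",
      g$len[["C3'-O3'"]], g$ang[["C4'-C3'-O3'"]], tr[7])
  add_sugar_base(1L, bases[1])
  add_sugar_base(2L, bases[2])
  at <- do.call(rbind, atoms)
  rownames(at) <- NULL
  B <- do.call(rbind, bonds)
  key <- function(r, n) which(at$residue == r & at$name == n)
  quad <- function(a, b, c, d) c(key(a[1], a[2]), key(b[1], b[2]),
                                 key(c[1], c[2]), key(d[1], d[2]))
  tors <- list(
    d1 = quad(c(1, "C5'"), c(1, "C4'"), c(1, "C3'"), c(1, "O3'")),
    e1 = quad(c(1, "C4'"), c(1, "C3'"), c(1, "O3'"), c(2, "P")),
    z1 = quad(c(1, "C3'"), c(1, "O3'"), c(2, "P"), c(2, "O5'")),
    a  = quad(c(1, "O3'"), c(2, "P"), c(2, "O5'"), c(2, "C5'")),
    b  = quad(c(2, "P"), c(2, "O5'"), c(2, "C5'"), c(2, "C4'")),
    g  = quad(c(2, "O5'"), c(2, "C5'"), c(2, "C4'"), c(2, "C3'")),
    d2 = quad(c(2, "C5'"), c(2, "C4'"), c(2, "C3'"), c(2, "O3'")))
  gr <- igraph::graph_from_edgelist(B, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, nrow(at) - igraph::vcount(gr)))
  tdefs <- lapply(tors, function(q) {
    g2 <- igraph::delete_edges(gr, igraph::get_edge_ids(gr, q[2:3]))
    comp <- igraph::components(g2)$membership
    list(atoms = q, downstream = which(comp == comp[q[3]] &
                                         seq_len(nrow(at)) != q[3]))
  })
  structure(list(sequence = sequence, atoms = at, bonds = B,
                 torsions = tdefs), class = "dn_template")
}

#' @rdname dn_template
#' @export
dn_templates <- function() {
  b <- c("A", "C", "G", "U")
  seqs <- as.vector(outer(b, b, paste0))
  stats::setNames(lapply(seqs, dn_template), seqs)
}
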